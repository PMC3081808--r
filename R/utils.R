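#' Derive a reproducible child seed from a base seed and labels
#'
#' Folds a base seed and an arbitrary set of labels (treatment names,
#' replicate indices, stage names) into a deterministic 31-bit integer via a
#' polynomial rolling hash. Used so that every run in a factorial sweep, and
#' every retry of an invalid run, gets its own reproducible seed derived from
#' a single user-supplied base seed.
#'
#' @param base_seed integer base seed.
#' @param ... labels (coerced to character) identifying the substream.
#' @return an integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @examples
#' derive_seed(1, "set1", "n=16", 3)
#' @export
derive_seed <- function(base_seed, ...) {
  stopifnot(is.numeric(base_seed), length(base_seed) == 1L, is.finite(base_seed))
  m <- 2147483629 # largest prime < 2^31; keeps arithmetic exact in doubles
  key <- paste(c(format(base_seed, scientific = FALSE), as.character(unlist(list(...)))),
               collapse = "\r")
  h <- as.double(abs(base_seed)) %% m
  for (code in utf8ToInt(key)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h %% (m - 1L)) + 1L
}

# internal: single-value parameter checks with informative errors
check_scalar <- function(x, name, lo = -Inf, hi = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (integer && x != round(x)) {
    stop(sprintf("'%s' must be a whole number", name), call. = FALSE)
  }
  if (x < lo || x > hi) {
    stop(sprintf("'%s' must be in [%s, %s] (got %s)", name,
                 format(lo), format(hi), format(x)), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
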