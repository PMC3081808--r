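#' Emergent quantitative-genetic variance components
#'
#' Narrow-sense heritability is estimated by mid-parent regression: the OLS
#' slope of offspring phenotype on the mean of its two parents' phenotypes,
#' clamped to `[0, 1]` (raw slopes can stray outside under drift and
#' sampling noise, and a negative additive variance is meaningless).
#' Phenotypic variance `V_P` is the sample variance of the offspring
#' phenotypes, and additive genetic variance is `V_A = h2 * V_P`. These are
#' emergent properties of the evolving networks, never specified a priori.
#'
#' @param offspring_phenotypes numeric vector of offspring trait values.
#' @param midparent_phenotypes paired numeric vector of mid-parent trait
#'   values (same length, >= 3 pairs). Pairs with missing mid-parent values
#'   (founders) are dropped.
#' @return an object of class `gn_varcomp`: a list with `V_P`, `h2`, `V_A`
#'   and `n_pairs`. When the mid-parent values are (numerically) constant the
#'   slope is undefined and `h2`/`V_A` are `NA` while `V_P` is still
#'   returned.
#' @examples
#' variance_components(c(1, 2, 3, 4), c(1, 2, 3, 4)) # h2 = 1
#' @export
variance_components <- function(offspring_phenotypes, midparent_phenotypes) {
  if (length(offspring_phenotypes) != length(midparent_phenotypes)) {
    stop("offspring and mid-parent series must have equal length", call. = FALSE)
  }
  ok <- !is.na(offspring_phenotypes) & !is.na(midparent_phenotypes)
  z <- offspring_phenotypes[ok]
  m <- midparent_phenotypes[ok]
  if (length(z) < 3L) {
    stop("need at least 3 offspring/mid-parent pairs", call. = FALSE)
  }
  V_P <- stats::var(z)
  v_m <- stats::var(m)
  if (!is.finite(v_m) || v_m <= .Machine$double.eps * max(1, mean(m)^2)) {
    h2 <- NA_real_
    V_A <- NA_real_
  } else {
    h2 <- min(1, max(0, stats::cov(m, z) / v_m))
    V_A <- h2 * V_P
  }
  structure(list(V_P = V_P, h2 = h2, V_A = V_A, n_pairs = length(z)),
            class = "gn_varcomp")
}

#' @export
print.gn_varcomp <- function(x, ...) {
  cat(sprintf("<gn_varcomp> V_P = %.4g, h2 = %.4g, V_A = %.4g (n = %d pairs)\n",
              x$V_P, x$h2, x$V_A, x$n_pairs))
  invisible(x)
}

# internal: variance components of a population's current members (offspring
# paired with their stored mid-parent phenotypes); NAs when not estimable
pop_varcomp <- function(pop) {
  N <- population_size(pop)
  if (N < 3L || sum(!is.na(pop$midparent)) < 3L) {
    return(list(V_P = if (N >= 2L) stats::var(pop$phen) else NA_real_,
                h2 = NA_real_, V_A = NA_real_, n_pairs = 0L))
  }
  vc <- variance_components(pop$phen, pop$midparent)
  list(V_P = vc$V_P, h2 = vc$h2, V_A = vc$V_A, n_pairs = vc$n_pairs)
}
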