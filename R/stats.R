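#' Sequential (Type-I) ANOVA with percent variance explained
#'
#' Fits an ordinary least-squares model and decomposes the total sum of
#' squares sequentially in the order the terms appear in the formula, the
#' decomposition reported by the factorial analyses: each term's percent
#' variance is its sequential SS over the total SS times 100, so the term
#' rows plus the residual row sum to exactly 100.
#'
#' @param data data.frame of run outcomes.
#' @param formula model formula, e.g. `dNdt_slope ~ dEdt * comp_n * comp_r`.
#' @param as_factor character vector of predictor columns to convert to
#'   unordered factors before fitting (the simulation treatments are
#'   categorical designs, including dEdt). Columns already factors are left
#'   alone; variance-component predictors are kept numeric by omitting them.
#' @return an object of class `gn_anova` (a data.frame): rows per term plus
#'   `Residuals`, columns `term`, `df`, `ss`, `pct_var`, `F`, `p`. The fitted
#'   model's AIC is in `attr(, "aic")` and the fit itself in
#'   `attr(, "fit")`. Terms dropped for rank deficiency (aliased in the
#'   design) are reported with zero df and `NA` statistics and flagged in
#'   `attr(, "aliased")`.
#' @seealso [winner_glm()], [aic_select()], [log_ttr_model()]
#' @export
sequential_anova <- function(data, formula, as_factor = character()) {
  stopifnot(is.data.frame(data), inherits(formula, "formula"))
  data <- factorize(data, as_factor)
  fit <- stats::lm(formula, data = data)
  at <- stats::anova(fit)
  terms_all <- attr(stats::terms(fit), "term.labels")
  tab <- data.frame(term = rownames(at), df = at$Df, ss = at$`Sum Sq`,
                    F = at$`F value`, p = at$`Pr(>F)`)
  aliased <- setdiff(terms_all, tab$term)
  if (length(aliased)) {
    tab <- rbind(tab, data.frame(term = aliased, df = 0L, ss = 0,
                                 F = NA_real_, p = NA_real_))
  }
  total_ss <- sum(tab$ss)
  tab$pct_var <- 100 * tab$ss / total_ss
  tab <- tab[c("term", "df", "ss", "pct_var", "F", "p")]
  structure(tab, class = c("gn_anova", "data.frame"),
            aic = stats::AIC(fit), fit = fit, aliased = aliased,
            total_ss = total_ss)
}

#' @export
print.gn_anova <- function(x, digits = 4, ...) {
  cat("Sequential ANOVA (Type-I SS), AIC =", format(attr(x, "aic"), digits = 6), "\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  if (length(attr(x, "aliased"))) {
    cat("Aliased (rank-deficient) terms:", paste(attr(x, "aliased"), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Percent of variance explained by model terms
#'
#' @param tab a `gn_anova` table.
#' @param terms `NULL` for the model total (all non-residual rows summed), or
#'   a character vector of term labels.
#' @return named numeric vector of percentages (or a single total).
#' @export
variance_explained <- function(tab, terms = NULL) {
  stopifnot(inherits(tab, "gn_anova"))
  nonres <- tab[tab$term != "Residuals", ]
  if (is.null(terms)) {
    return(sum(nonres$pct_var))
  }
  missing <- setdiff(terms, nonres$term)
  if (length(missing)) {
    stop("term(s) not in table: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  stats::setNames(nonres$pct_var[match(terms, nonres$term)], terms)
}

#' Sequential analysis of deviance for the competition winner
#'
#' Fits a binomial GLM with logit link for the probability that the focal
#' species wins, and decomposes the deviance sequentially in formula order
#' with chi-square p-values. The decomposition telescopes exactly: the null
#' deviance minus all term deviances equals the residual deviance.
#'
#' @param data data.frame of run outcomes.
#' @param formula model formula; the response may be a binary 0/1 column, a
#'   logical, or the `winner` character column (`"focal"` is the success).
#' @param as_factor predictor columns to convert to factors (see
#'   [sequential_anova()]).
#' @return an object of class `gn_deviance` (a data.frame): a `NULL` row then
#'   one row per term, columns `term`, `df`, `deviance`, `resid_df`,
#'   `resid_dev`, `p`. The fit is in `attr(, "fit")`, its AIC in
#'   `attr(, "aic")`; `attr(, "separation")` flags fitted probabilities at
#'   the 0/1 boundary (coefficient estimates are then unstable, but the
#'   deviance decomposition is still valid).
#' @export
winner_glm <- function(data, formula, as_factor = character()) {
  stopifnot(is.data.frame(data), inherits(formula, "formula"))
  data <- factorize(data, as_factor)
  resp <- all.vars(formula)[1]
  if (is.character(data[[resp]])) {
    data[[resp]] <- as.integer(data[[resp]] == "focal")
  }
  if (!all(data[[resp]] %in% c(0, 1))) {
    stop("winner response must be binary (0/1, logical, or 'focal'/'competitor')",
         call. = FALSE)
  }
  fit <- suppressWarnings(stats::glm(formula, data = data, family = stats::binomial()))
  sep <- any(fit$fitted.values < 1e-10 | fit$fitted.values > 1 - 1e-10)
  if (sep) {
    warning("fitted probabilities at the 0/1 boundary: possible complete separation; coefficients unstable",
            call. = FALSE)
  }
  at <- suppressWarnings(stats::anova(fit, test = "Chisq"))
  tab <- data.frame(term = rownames(at), df = at$Df, deviance = at$Deviance,
                    resid_df = at$`Resid. Df`, resid_dev = at$`Resid. Dev`,
                    p = at$`Pr(>Chi)`)
  structure(tab, class = c("gn_deviance", "data.frame"),
            aic = stats::AIC(fit), fit = fit, separation = sep)
}

#' @export
print.gn_deviance <- function(x, digits = 4, ...) {
  cat("Sequential analysis of deviance (binomial, logit), AIC =",
      format(attr(x, "aic"), digits = 6), "\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  if (isTRUE(attr(x, "separation"))) cat("Warning: possible complete separation.\n")
  invisible(x)
}

#' Rank candidate models by AIC
#'
#' Fits every candidate on the same rows of `data` and ranks them by
#' `AIC = -2 logLik + 2 k` (standard AIC, not the small-sample AICc, given
#' the large simulation sample sizes).
#'
#' @param data data.frame of run outcomes.
#' @param models named list of formulas.
#' @param family `"gaussian"` (via [stats::lm()]) or `"binomial"` (logit GLM),
#'   applied to all candidates.
#' @param as_factor predictor columns converted to factors for every model.
#' @return a data.frame sorted by AIC: `model`, `k` (estimated parameters,
#'   including the error variance for gaussian fits), `aic`, `delta_aic`.
#'   Candidates that end up fitted to different row subsets (e.g. through
#'   `NA` in a predictor) are an error, since their AICs are not comparable.
#' @export
aic_select <- function(data, models, family = c("gaussian", "binomial"),
                       as_factor = character()) {
  stopifnot(is.data.frame(data), is.list(models), length(models) >= 2L)
  family <- match.arg(family)
  if (is.null(names(models)) || any(!nzchar(names(models)))) {
    names(models) <- paste0("M", seq_along(models))
  }
  data <- factorize(data, as_factor)
  if (family == "binomial") {
    resp <- all.vars(models[[1]])[1]
    if (is.character(data[[resp]])) {
      data[[resp]] <- as.integer(data[[resp]] == "focal")
    }
  }
  fits <- lapply(models, function(f) {
    if (family == "gaussian") stats::lm(f, data = data)
    else suppressWarnings(stats::glm(f, data = data, family = stats::binomial()))
  })
  ns <- vapply(fits, stats::nobs, numeric(1))
  if (length(unique(ns)) != 1L) {
    stop("models were fitted to different numbers of rows; AIC is not comparable",
         call. = FALSE)
  }
  aic <- vapply(fits, stats::AIC, numeric(1))
  k <- vapply(fits, function(f) attr(stats::logLik(f), "df"), numeric(1))
  out <- data.frame(model = names(models), k = k, aic = aic,
                    delta_aic = aic - min(aic))
  out <- out[order(out$aic), ]
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}

#' Sequential ANOVA of log time-to-resolution
#'
#' Time-to-resolution data are right-skewed, so the response is natural-log
#' transformed before the sequential decomposition (times are >= 1 by
#' construction, so the log is always defined). Censored runs carry the
#' generation cap as their time.
#'
#' @param data data.frame containing the response column.
#' @param formula model formula on the *untransformed* response, e.g.
#'   `time_to_resolution ~ comp_n * dEdt`.
#' @param as_factor predictor columns to convert to factors.
#' @return a `gn_anova` table for the log-transformed response.
#' @export
log_ttr_model <- function(data, formula, as_factor = character()) {
  resp <- all.vars(formula)[1]
  if (any(data[[resp]] < 1, na.rm = TRUE)) {
    stop("time-to-resolution values must be >= 1 for the log transform",
         call. = FALSE)
  }
  data[[paste0("log_", resp)]] <- log(data[[resp]])
  f2 <- stats::reformulate(attr(stats::terms(formula), "term.labels"),
                           response = paste0("log_", resp))
  sequential_anova(data, f2, as_factor = as_factor)
}

#' The factorial model menus compared by AIC
#'
#' Named formula lists for the three analyses: the initial-competition
#' response (focal dN/dt) modelled from network characteristics (`IN1..IN4`)
#' or from emergent variance components (`IV1..IV4`), the competition winner
#' (`CW1..CW4`), and log time-to-resolution (`TR1..TR4`). Column names match
#' the [factorial_runner()] output.
#'
#' @param analysis one of `"initial_network"`, `"initial_varcomp"`,
#'   `"winner"`, `"time_to_resolution"`.
#' @return a named list of formulas for [aic_select()].
#' @export
model_menu <- function(analysis = c("initial_network", "initial_varcomp",
                                    "winner", "time_to_resolution")) {
  analysis <- match.arg(analysis)
  switch(analysis,
    initial_network = list(
      IN1 = dNdt_slope ~ dEdt * comp_n * comp_topology * comp_mu * comp_r,
      IN2 = dNdt_slope ~ dEdt * comp_n * comp_r,
      IN3 = dNdt_slope ~ dEdt * comp_n,
      IN4 = dNdt_slope ~ dEdt + comp_n + comp_r
    ),
    initial_varcomp = list(
      IV1 = dNdt_slope ~ comp_V_A * comp_V_P * dEdt,
      IV2 = dNdt_slope ~ comp_V_A * dEdt,
      IV3 = dNdt_slope ~ comp_V_P * dEdt,
      IV4 = dNdt_slope ~ focal_V_A * focal_V_P * comp_V_A * comp_V_P * dEdt
    ),
    winner = list(
      CW1 = winner ~ comp_n * comp_r * dEdt,
      CW2 = winner ~ comp_n * dEdt,
      CW3 = winner ~ dEdt,
      CW4 = winner ~ comp_n + comp_r + dEdt
    ),
    time_to_resolution = list(
      TR1 = log_time_to_resolution ~ comp_n * comp_r * dEdt,
      TR2 = log_time_to_resolution ~ comp_n * dEdt,
      TR3 = log_time_to_resolution ~ comp_n,
      TR4 = log_time_to_resolution ~ comp_n + comp_r + dEdt
    )
  )
}

# internal: convert the named columns to unordered factors
factorize <- function(data, cols) {
  for (cn in cols) {
    if (!cn %in% names(data)) {
      stop(sprintf("column '%s' not present in data", cn), call. = FALSE)
    }
    if (!is.factor(data[[cn]])) data[[cn]] <- factor(data[[cn]])
  }
  data
}
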