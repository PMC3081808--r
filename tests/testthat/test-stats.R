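# a small balanced two-factor simulated dataset reused across blocks
make_toy <- function(seed = 1, n_per = 8, beta_a = 3, beta_b = 0.5) {
  set.seed(seed)
  d <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2", "b3"),
                   rep = seq_len(n_per))
  d$y <- beta_a * (d$A == "a2") + beta_b * (d$B == "b2") + rnorm(nrow(d))
  d
}

test_that("sequential ANOVA reproduces brute-force Type-I sums of squares", {
  d <- make_toy()
  tab <- sequential_anova(d, y ~ A * B, as_factor = c("A", "B"))
  ss_oracle <- oracle_seq_ss(d, "y", c("A", "B", "A:B"))
  got <- setNames(tab$ss[match(names(ss_oracle), tab$term)], names(ss_oracle))
  expect_equal(got, ss_oracle, tolerance = 1e-10)
  # percentages are SS / total SS and sum to 100 with the residual
  expect_equal(sum(tab$pct_var), 100)
  expect_equal(tab$ss / attr(tab, "total_ss") * 100, tab$pct_var)
  # decomposition is exact: term SS + residual SS = total SS
  expect_equal(sum(tab$ss), sum((d$y - mean(d$y))^2))
})

test_that("a response equal to a factor's group means loads 100% on that factor", {
  d <- expand.grid(A = c("a1", "a2", "a3"), rep = 1:10)
  d$y <- c(a1 = 1, a2 = 5, a3 = 9)[d$A]
  # an exact fit triggers the usual unreliable-F warning; the SS are exact
  tab <- suppressWarnings(sequential_anova(d, y ~ A, as_factor = "A"))
  expect_equal(variance_explained(tab), 100)
  expect_equal(variance_explained(tab, "A"), c(A = 100))
})

test_that("pure-noise predictors explain df/(n-1) of the variance on average", {
  set.seed(21)
  reps <- 300
  pct <- numeric(reps)
  n <- 60
  for (i in seq_len(reps)) {
    d <- data.frame(y = rnorm(n), g = sample(rep(letters[1:4], n / 4)))
    pct[i] <- variance_explained(sequential_anova(d, y ~ g, as_factor = "g"))
  }
  expected <- 100 * 3 / (n - 1) # E[R^2] = df/(n-1) under the null
  expect_lt(abs(mean(pct) - expected), 3 * sd(pct) / sqrt(reps))
})

test_that("the winner deviance decomposition telescopes exactly", {
  set.seed(31)
  d <- expand.grid(comp_n = c(16, 64, 256), dEdt = c(8e-3, 2e-4), rep = 1:30)
  logit <- -0.5 + 1.2 * (d$comp_n == 16) + 0.8 * (d$dEdt == 8e-3)
  d$winner <- ifelse(runif(nrow(d)) < plogis(logit), "focal", "competitor")
  tab <- winner_glm(d, winner ~ comp_n * dEdt, as_factor = c("comp_n", "dEdt"))
  null_dev <- tab$resid_dev[tab$term == "NULL"]
  expect_equal(null_dev - sum(tab$deviance, na.rm = TRUE),
               tab$resid_dev[nrow(tab)])
  # closed-form Bernoulli oracle for the null deviance: 2 * n * entropy
  p <- mean(d$winner == "focal")
  n <- nrow(d)
  expect_equal(null_dev, -2 * (n * p * log(p) + n * (1 - p) * log(1 - p)))
})

test_that("a perfectly determining factor absorbs essentially all deviance", {
  d <- expand.grid(g = c("x", "y"), rep = 1:40)
  d$winner <- ifelse(d$g == "x", 1L, 0L)
  tab <- suppressWarnings(winner_glm(d, winner ~ g, as_factor = "g"))
  expect_lt(tab$resid_dev[nrow(tab)], 1e-6)
  expect_true(isTRUE(attr(tab, "separation")))
})

test_that("AIC selection ranks candidates coherently", {
  d <- make_toy(seed = 41)
  # duplicate specifications tie exactly
  sel <- aic_select(d, list(M1 = y ~ A, M2 = y ~ A), as_factor = c("A", "B"))
  expect_equal(sel$delta_aic, c(0, 0))
  # a strongly structured response prefers the saturated model
  sel2 <- aic_select(d, list(sat = y ~ A * B, null = y ~ 1),
                     as_factor = c("A", "B"))
  expect_identical(sel2$model[1], "sat")
  # models on different row subsets are not comparable
  d2 <- d
  d2$x <- rnorm(nrow(d2))
  d2$x[1] <- NA
  expect_error(aic_select(d2, list(a = y ~ A, b = y ~ x)), "not comparable")
})

test_that("AIC prefers the generating model among nested gaussian candidates", {
  set.seed(51)
  wins <- 0L
  for (i in 1:60) {
    d <- data.frame(g = sample(rep(c("u", "v"), 15)))
    d$y <- rnorm(30) # generated WITHOUT a group effect
    sel <- aic_select(d, list(small = y ~ 1, big = y ~ g), as_factor = "g")
    wins <- wins + (sel$model[1] == "small")
  }
  expect_gt(wins, 30) # the smaller true model wins the majority
})

test_that("log time-to-resolution modelling shares the ANOVA machinery", {
  set.seed(61)
  d <- expand.grid(comp_n = c(16, 256), dEdt = c(8e-3, 2e-4), rep = 1:20)
  d$time_to_resolution <- round(exp(4 + 0.8 * (d$comp_n == 16) +
                                      0.5 * (d$dEdt == 2e-4) +
                                      rnorm(nrow(d), 0, 0.3)))
  tab <- log_ttr_model(d, time_to_resolution ~ comp_n * dEdt,
                       as_factor = c("comp_n", "dEdt"))
  ref <- sequential_anova(transform(d, ly = log(time_to_resolution)),
                          ly ~ comp_n * dEdt, as_factor = c("comp_n", "dEdt"))
  expect_equal(tab$ss, ref$ss)
  d$time_to_resolution[1] <- 0
  expect_error(log_ttr_model(d, time_to_resolution ~ comp_n), ">= 1")
})

test_that("the model menus are well-formed formula lists", {
  for (a in c("initial_network", "initial_varcomp", "winner",
              "time_to_resolution")) {
    menu <- model_menu(a)
    expect_identical(length(menu), 4L)
    expect_true(all(vapply(menu, inherits, logical(1), "formula")))
  }
  expect_identical(names(model_menu("winner")), c("CW1", "CW2", "CW3", "CW4"))
})

test_that("rank-deficient designs flag aliased terms instead of failing", {
  d <- make_toy()
  d$C <- d$A # C is a perfect alias of A
  tab <- sequential_anova(d, y ~ A + C, as_factor = c("A", "C"))
  expect_identical(attr(tab, "aliased"), "C")
  expect_identical(tab$df[tab$term == "C"], 0L)
})
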