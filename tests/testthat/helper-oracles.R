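# Independent reference implementations used as oracles. These are written
# in the most transparent way possible (explicit graph walks, closed-form
# sums) and stay independent of the package's vectorized internals.

# brute-force Boolean propagation: explicit breadth-first walk from gene 1,
# applying the 4-case functional map edge by edge
oracle_propagate <- function(chr) {
  n <- chr$n_genes
  state <- integer(n)
  reach <- logical(n)
  state[1] <- chr$root_state
  reach[1] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nxt <- integer(0)
    for (g in frontier) {
      tails <- which(chr$head == g) + 1L
      for (tl in tails) {
        hs <- state[g]
        fn <- chr$func[tl - 1L]
        # the functional map: on+activator -> on, on+repressor -> off,
        # off+activator -> off, off+repressor -> on
        state[tl] <- if (hs == 1L && fn == 1L) 1L
                     else if (hs == 1L && fn == 0L) 0L
                     else if (hs == 0L && fn == 1L) 0L
                     else 1L
        reach[tl] <- TRUE
        nxt <- c(nxt, tl)
      }
    }
    frontier <- nxt
  }
  list(states = state, reachable = reach)
}

# closed-form OLS slope from raw sums
oracle_ols_slope <- function(x, y) {
  n <- length(x)
  (sum(x * y) - sum(x) * sum(y) / n) / (sum(x^2) - sum(x)^2 / n)
}

# brute-force sequential (Type-I) sums of squares by explicit nested model
# fits: SS of term k = RSS(model with terms 1..k-1) - RSS(terms 1..k)
oracle_seq_ss <- function(data, response, terms) {
  rss <- function(fml) sum(stats::resid(stats::lm(fml, data = data))^2)
  fml0 <- stats::as.formula(paste(response, "~ 1"))
  out <- numeric(length(terms))
  prev <- rss(fml0)
  acc <- character(0)
  for (k in seq_along(terms)) {
    acc <- c(acc, terms[k])
    cur <- rss(stats::reformulate(acc, response = response))
    out[k] <- prev - cur
    prev <- cur
  }
  names(out) <- terms
  out
}

# chromosome invariant checks shared by closure/property tests
expect_valid_chromosome <- function(chr) {
  n <- chr$n_genes
  expect_length(chr$head, n - 1L)
  expect_length(chr$func, n - 1L)
  expect_true(all(chr$head >= 1L & chr$head <= n))
  expect_false(any(chr$head == seq(2L, n)))
  expect_true(all(chr$func %in% c(0L, 1L)))
  expect_true(chr$root_state %in% c(0L, 1L))
  # out-degrees always sum to n-1, so a terminal gene always exists
  od <- tabulate(chr$head, nbins = n)
  expect_identical(sum(od), n - 1L)
  expect_gte(sum(od == 0L), 1L)
}

# a small config that runs the whole protocol quickly in unit tests
tiny_config <- function(seed, comp_n = 8, ...) {
  competition_config(
    focal = species_params(8, "scale_free", r = 0.5, mu = 1e-3),
    competitor = species_params(comp_n, "scale_free", r = 0.5, mu = 1e-3),
    dEdt = 8e-3, K = 120, dispersers_per_species = 40,
    canalization_gens = 5, max_generations = 10, seed = seed, ...
  )
}
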