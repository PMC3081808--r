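test_that("chromosome construction enforces the encoding invariants", {
  expect_error(new_chromosome(1, 1, integer(0), integer(0)), "n_genes")
  expect_error(new_chromosome(3, 1, c(1, 3), c(1, 1)), "regulate itself")
  expect_error(new_chromosome(3, 1, c(1, 4), c(1, 1)), "gene indices")
  expect_error(new_chromosome(3, 1, c(1, 1), c(2, 0)), "0 .*or 1")
  expect_error(new_chromosome(3, 2, c(1, 1), c(1, 0)), "root_state")
  chr <- new_chromosome(3, 1, c(1, 1), c(1, 0))
  expect_s3_class(chr, "gn_chromosome")
  expect_valid_chromosome(chr)
})

test_that("generated chromosomes are valid for both topologies at any size", {
  set.seed(101)
  for (topology in c("random", "scale_free")) {
    # n = 2 leaves only one possible regulator
    chr2 <- generate_chromosome(2, topology)
    expect_identical(chr2$head, 1L)
    for (n in c(3, 8, 16, 64)) {
      chr <- generate_chromosome(n, topology)
      expect_valid_chromosome(chr)
      # sequential attachment means gene i's regulator precedes it
      expect_true(all(chr$head < seq(2L, n)))
    }
  }
  expect_error(generate_chromosome(1), "n_genes")
})

test_that("identical seeds generate bit-identical chromosomes", {
  set.seed(7)
  a <- generate_chromosome(64, "scale_free")
  set.seed(7)
  b <- generate_chromosome(64, "scale_free")
  expect_identical(a, b)
})

test_that("preferential attachment produces a heavier-tailed out-degree distribution", {
  # the lottery model concentrates edges on early hubs, so the per-network
  # out-degree variance must exceed the uniform-attachment variance
  od_var <- function(topology, draws) {
    set.seed(42)
    v <- numeric(draws)
    for (i in seq_len(draws)) {
      chr <- generate_chromosome(256, topology)
      v[i] <- stats::var(tabulate(chr$head, nbins = 256))
    }
    v
  }
  v_sf <- od_var("scale_free", 300)
  v_rn <- od_var("random", 300)
  expect_gt(mean(v_sf), mean(v_rn))
  # the gap is large, not marginal: scale-free more than double
  expect_gt(mean(v_sf), 2 * mean(v_rn))
})

test_that("state propagation follows the four-case functional map", {
  # on+activator -> on; on+repressor -> off; off+activator -> off;
  # off+repressor -> on
  cases <- expand.grid(root = c(1L, 0L), func = c(1L, 0L))
  for (k in seq_len(nrow(cases))) {
    chr <- new_chromosome(2, cases$root[k], 1L, cases$func[k])
    nv <- propagate_states(chr)
    expect_identical(nv$states[2], as.integer(cases$root[k] == cases$func[k]))
  }
})

test_that("a chain of activators transmits the root state unchanged", {
  for (root in c(0L, 1L)) {
    chr <- new_chromosome(10, root, head = 1:9, func = rep(1L, 9))
    nv <- propagate_states(chr)
    expect_identical(nv$states, rep(root, 10L))
    expect_true(all(nv$reachable))
    expect_identical(nv$reachable_order[1], 1L)
    expect_identical(sort(nv$reachable_order), 1:10)
  }
})

test_that("genes detached from the root by a cycle are off and unreachable", {
  # genes 2 and 3 regulate each other (possible only after a regulator
  # mutation); gene 4 hangs off the root
  chr <- new_chromosome(4, 1, head = c(3L, 2L, 1L), func = c(1L, 1L, 1L))
  nv <- propagate_states(chr)
  expect_identical(nv$states, c(1L, 0L, 0L, 1L))
  expect_identical(nv$reachable, c(TRUE, FALSE, FALSE, TRUE))
  expect_identical(nv$reachable_order, c(1L, 4L))
})

test_that("propagation matches the brute-force graph-walk oracle", {
  set.seed(202)
  for (rep_i in 1:40) {
    n <- sample(c(2, 3, 5, 8, 16, 33), 1)
    chr <- generate_chromosome(n, sample(c("random", "scale_free"), 1))
    # push some chromosomes through heavy mutation so rewired/cyclic
    # topologies are covered too
    if (rep_i %% 2 == 0) chr <- mutate(chr, 0.5)
    nv <- propagate_states(chr)
    oc <- oracle_propagate(chr)
    expect_identical(nv$states, oc$states)
    expect_identical(nv$reachable, oc$reachable)
  }
})

test_that("phenotype scales on-terminal fraction to the environmental range", {
  chr <- fixture_fig_network()
  expect_equal(phenotype(chr), 70)
  expect_equal(phenotype(chr, env_range = 280), 140)
  # all-on chain: single terminal gene, on
  expect_equal(phenotype(new_chromosome(5, 1, 1:4, rep(1L, 4))), 140)
  # root off on a pure-activator tree: everything off
  expect_equal(phenotype(new_chromosome(6, 0, rep(1L, 5), rep(1L, 5))), 0)
})

test_that("mutation respects mu, the forced-branch flips, and immutability", {
  set.seed(303)
  chr <- generate_chromosome(32, "scale_free")
  expect_identical(mutate(chr, 0), chr)
  flipped <- mutate(chr, 1, p_func = 1)
  expect_identical(flipped$func, 1L - chr$func)
  expect_identical(flipped$head, chr$head)
  expect_identical(flipped$root_state, chr$root_state)
  expect_error(mutate(chr, 1.2), "mu")
  # input never modified in place
  orig <- unclass(chr)
  invisible(mutate(chr, 1))
  expect_identical(unclass(chr), orig)
})

test_that("realized mutation rate matches the binomial expectation", {
  set.seed(404)
  n <- 64
  mu <- 0.01
  chr <- generate_chromosome(n, "random")
  reps <- 2000
  changed <- 0L
  for (i in seq_len(reps)) {
    m <- mutate(chr, mu)
    changed <- changed + sum(m$head != chr$head | m$func != chr$func)
  }
  trials <- reps * (n - 1)
  # a regulator redraw lands on the current regulator 1/(n-1) of the time,
  # so the observable change rate is mu * (1/2 + 1/2 * (n-2)/(n-1))
  p_obs <- mu * (0.5 + 0.5 * (n - 2) / (n - 1))
  se <- sqrt(p_obs * (1 - p_obs) / trials)
  expect_lt(abs(changed / trials - p_obs), 3 * se)
})

test_that("recombination copies, crosses and refuses incompatible parents", {
  set.seed(505)
  a <- generate_chromosome(16, "scale_free")
  b <- generate_chromosome(16, "scale_free")
  # r = 0: the child is exactly one parent
  child <- recombine(a, b, 0)
  expect_true(identical(child, a) || identical(child, b))
  # identical parents: child identical regardless of r
  expect_identical(recombine(a, a, 0.7), a)
  expect_error(recombine(a, generate_chromosome(8), 0.5), "incompatible")
  expect_error(recombine(a, b, -0.1), "'r'")
})

test_that("source-switch count matches the per-boundary geometric expectation", {
  # parents marked so the inheritance source is readable off the child:
  # identical topology, all-activator vs all-repressor functions, root 1 vs 0
  set.seed(606)
  n <- 64
  r <- 0.5
  head <- sample.int(n - 1, n - 1, replace = TRUE)
  head <- pmin(head, seq(2, n) - 1L) # keep regulator < gene for validity
  a <- new_chromosome(n, 1, head, rep(1L, n - 1))
  b <- new_chromosome(n, 0, head, rep(0L, n - 1))
  reps <- 2000
  switches <- numeric(reps)
  for (i in seq_len(reps)) {
    ch <- recombine(a, b, r)
    src <- c(ch$root_state, ch$func) # 1 = from a, 0 = from b
    switches[i] <- sum(diff(src) != 0)
  }
  expected <- r * (n - 1)
  se <- sd(switches) / sqrt(reps)
  expect_lt(abs(mean(switches) - expected), 3 * se)
})

test_that("mutation and recombination closure: invariants survive repeated application", {
  set.seed(707)
  a <- generate_chromosome(24, "scale_free")
  b <- generate_chromosome(24, "random")
  for (i in 1:50) {
    a <- mutate(recombine(a, b, 0.5), 0.2)
    b <- mutate(b, 0.2)
    expect_valid_chromosome(a)
    expect_valid_chromosome(b)
  }
})

test_that("edge list export matches the chromosome and writes clean TSV", {
  chr <- fixture_fig_network()
  el <- edge_list(chr)
  expect_identical(el$tail, 2:13)
  expect_identical(el$head, chr$head)
  expect_identical(el$func, chr$func)
  path <- withr::local_tempfile(fileext = ".tsv")
  edge_list(chr, path)
  back <- utils::read.delim(path)
  expect_identical(back$head, el$head)
})
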