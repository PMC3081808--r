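# Vectorized internals shared by the single-chromosome API and the
# population life cycle. A cohort of M genotypes with n genes is held as:
#   root: integer M        (state of gene 1, 0/1)
#   head: integer (n-1) x M (row i = regulator gene index of gene i+1, in 1..n,
#                            never equal to i+1)
#   func: integer (n-1) x M (row i = 1 activator / 0 repressor for gene i+1)
# All functions here assume validated inputs; validation lives in the
# exported wrappers.

# column-wise cumulative sums of a numeric matrix via one global cumsum;
# avoids per-column apply() overhead in hot loops
col_cumsum <- function(m) {
  nr <- nrow(m)
  nc <- ncol(m)
  g <- cumsum(as.numeric(m))
  if (nc > 1L) {
    offset <- rep(c(0, g[nr * seq_len(nc - 1L)]), each = nr)
    g <- g - offset
  }
  matrix(g, nr, nc)
}

# generate M independent genotypes: gene i (i = 2..n) attaches below one of
# genes 1..i-1; uniformly for "random", with probability proportional to
# (current out-degree + 1) for "scale_free" (lottery model with +1 bootstrap
# so zero-degree genes stay attachable)
founders_engine <- function(n, topology, M) {
  head <- matrix(0L, n - 1L, M)
  if (topology == "random" || n == 2L) {
    for (i in 2:n) {
      head[i - 1L, ] <- if (i == 2L) 1L else sample.int(i - 1L, M, replace = TRUE)
    }
  } else {
    # lottery with weight (out-degree + 1): equivalent to attaching gene i
    # uniformly with probability (i-1)/(2i-3) (the "+1" mass, total i-1) and
    # otherwise repeating the head of a uniformly chosen existing edge (the
    # out-degree mass, total i-2); O(1) per draw instead of a weight scan
    col0 <- 0:(M - 1L) * (n - 1L)
    head[1L, ] <- 1L
    for (i in 3:n) {
      ug <- sample.int(i - 1L, M, replace = TRUE)
      j <- sample.int(i - 2L, M, replace = TRUE)
      eh <- head[j + col0]
      uniform <- stats::runif(M) < (i - 1) / (2 * i - 3)
      head[i - 1L, ] <- ifelse(uniform, ug, eh)
    }
  }
  list(
    head = head,
    func = matrix(sample(0:1, (n - 1L) * M, replace = TRUE), n - 1L, M),
    root = sample(0:1, M, replace = TRUE)
  )
}

# per-genotype out-degree matrix (n x M)
out_degree_engine <- function(head, n, M) {
  counts <- tabulate(head + rep(0:(M - 1L) * n, each = n - 1L), nbins = n * M)
  matrix(as.integer(counts), n, M)
}

# propagate Boolean states from gene 1 through each genotype.
# state(tail) = 1 iff state(head) == func (on+activator -> on,
# off+repressor -> on, otherwise off). Genes unreachable from gene 1
# (possible after regulator mutations create detached cycles) keep state 0
# and are flagged unreachable.
propagate_engine <- function(head, func, root, n, M) {
  states <- matrix(0L, n, M)
  reach <- matrix(FALSE, n, M)
  states[1L, ] <- as.integer(root)
  reach[1L, ] <- TRUE
  collin <- rep(0:(M - 1L) * n, each = n - 1L)
  headlin <- as.integer(head) + collin             # where each gene's regulator lives
  genelin <- rep(2:n, times = M) + collin          # where each gene itself lives
  pending <- seq_along(genelin)
  for (iter in seq_len(n)) {
    ready <- reach[headlin[pending]]
    todo <- pending[ready]
    if (length(todo) == 0L) break
    g <- genelin[todo]
    states[g] <- as.integer(states[headlin[todo]] == func[todo])
    reach[g] <- TRUE
    pending <- pending[!ready]
  }
  list(states = states, reachable = reach)
}

# trait value: env_range * (on terminal genes) / (terminal genes);
# terminal = out-degree 0, which is never empty (n-1 edges over n genes)
phenotypes_engine <- function(head, func, root, n, M, env_range) {
  pr <- propagate_engine(head, func, root, n, M)
  term <- out_degree_engine(head, n, M) == 0L
  env_range * .colSums(pr$states * term, n, M) / .colSums(term, n, M)
}

# free recombination of whole-gene blocks: element sequence is
# [root, gene2 block, ..., gene n block]; element 1 comes from a uniformly
# chosen parent; before each subsequent element the source switches with
# probability r. p1/p2 index parent columns of the supplied matrices.
recombine_engine <- function(head, func, root, p1, p2, r, n) {
  M <- length(p1)
  sw <- matrix(stats::runif(n * M) < r, n, M)
  sw[1L, ] <- sample(c(TRUE, FALSE), M, replace = TRUE) # starting parent
  src <- col_cumsum(sw) %% 2 # 0 = parent p1 supplies, 1 = parent p2
  root_src <- src[1L, ]
  child_root <- ifelse(root_src == 0, root[p1], root[p2])
  srcE <- as.vector(src[-1L, , drop = FALSE])
  pcol <- ifelse(srcE == 0, rep(p1, each = n - 1L), rep(p2, each = n - 1L))
  # keep this a plain vector: an integer matrix subscript would be read as
  # (row, col) coordinate pairs whenever M == 2
  lin <- as.vector((pcol - 1L) * (n - 1L) + rep(seq_len(n - 1L), times = M))
  list(
    head = matrix(head[lin], n - 1L, M),
    func = matrix(func[lin], n - 1L, M),
    root = as.integer(child_root)
  )
}

# per-element mutation: each of the n-1 gene blocks mutates with probability
# mu; a mutating block flips its function bit with probability p_func,
# otherwise redraws its regulator uniformly among all genes except itself.
# The root state never mutates.
mutate_engine <- function(head, func, mu, p_func = 0.5) {
  n1 <- nrow(head)
  idx <- which(stats::runif(length(head)) < mu)
  if (length(idx)) {
    flip <- stats::runif(length(idx)) < p_func
    fi <- idx[flip]
    func[fi] <- 1L - func[fi]
    hi <- idx[!flip]
    if (length(hi)) {
      gene <- ((hi - 1L) %% n1) + 2L          # the gene whose block mutates
      d <- sample.int(n1, length(hi), replace = TRUE) # n1 = n - 1 candidates
      head[hi] <- d + as.integer(d >= gene)   # skip self
    }
  }
  list(head = head, func = func)
}
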