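#' Construct a gene-network chromosome
#'
#' A chromosome is the heritable encoding of one individual's Boolean
#' gene-regulatory network. Gene 1 is the upstream-most (root) gene and
#' carries only a heritable on/off state. Every other gene `i` (2..n) carries
#' a two-part block: the index of its single regulator (`head`, any gene
#' except `i` itself) and a function bit (`func`, 1 = activator,
#' 0 = repressor). Because each non-root gene contributes exactly one edge,
#' the out-degrees always sum to `n - 1` and at least one gene has
#' out-degree 0 (a terminal gene) in every chromosome, including after
#' mutation.
#'
#' @param n_genes number of genes (>= 2).
#' @param root_state 0/1 state of gene 1.
#' @param head integer vector of length `n_genes - 1`; entry `i` is the
#'   regulator of gene `i + 1`.
#' @param func 0/1 vector of length `n_genes - 1`; 1 = activator,
#'   0 = repressor.
#' @return an object of class `gn_chromosome`.
#' @seealso [generate_chromosome()], [propagate_states()], [phenotype()]
#' @export
new_chromosome <- function(n_genes, root_state, head, func) {
  check_scalar(n_genes, "n_genes", lo = 2, integer = TRUE)
  check_scalar(root_state, "root_state", lo = 0, hi = 1, integer = TRUE)
  n <- as.integer(n_genes)
  head <- as.integer(head)
  func <- as.integer(func)
  if (length(head) != n - 1L || length(func) != n - 1L) {
    stop("'head' and 'func' must have length n_genes - 1", call. = FALSE)
  }
  if (anyNA(head) || any(head < 1L) || any(head > n)) {
    stop("'head' entries must be gene indices in 1..n_genes", call. = FALSE)
  }
  if (any(head == seq(2L, n))) {
    stop("no gene may regulate itself", call. = FALSE)
  }
  if (anyNA(func) || any(func != 0L & func != 1L)) {
    stop("'func' entries must be 0 (repressor) or 1 (activator)", call. = FALSE)
  }
  structure(
    list(n_genes = n, root_state = as.integer(root_state),
         head = head, func = func),
    class = "gn_chromosome"
  )
}

#' @export
print.gn_chromosome <- function(x, ...) {
  nv <- propagate_states(x)
  cat(sprintf("<gn_chromosome> %d genes, root state %d, %d terminal genes (%d on), phenotype %.4g\n",
              x$n_genes, x$root_state, length(nv$terminal_set),
              sum(nv$states[nv$terminal_set]), phenotype(x)))
  invisible(x)
}

#' Generate a random chromosome with a given network topology
#'
#' Genes are added sequentially: gene `i` attaches below one of genes
#' `1..i-1`. Under `"random"` topology the regulator is drawn uniformly; under
#' `"scale_free"` it is drawn by a lottery model with probability
#' proportional to (current out-degree + 1), producing a heavy-tailed
#' out-degree distribution by preferential attachment. Function bits and the
#' root state are drawn uniformly. Randomness comes from the R session RNG,
#' so wrap calls in [set.seed()] for reproducibility.
#'
#' @param n_genes number of genes (>= 2).
#' @param topology `"random"` or `"scale_free"`.
#' @return a [new_chromosome()] object.
#' @examples
#' set.seed(1)
#' chr <- generate_chromosome(16, "scale_free")
#' phenotype(chr)
#' @export
generate_chromosome <- function(n_genes, topology = c("scale_free", "random")) {
  check_scalar(n_genes, "n_genes", lo = 2, integer = TRUE)
  topology <- match.arg(topology)
  n <- as.integer(n_genes)
  f <- founders_engine(n, topology, 1L)
  new_chromosome(n, f$root[1L], f$head[, 1L], f$func[, 1L])
}

#' Propagate Boolean states through a chromosome's network
#'
#' Starting from the root gene's heritable state, each reachable gene takes
#' state 1 iff its regulator's state equals its function bit: an "on"
#' regulator activates through an activator edge and silences through a
#' repressor edge; an "off" regulator does the reverse. Genes not reachable
#' from gene 1 (possible only after regulator mutations detach a cycle) are
#' assigned state 0 and flagged unreachable.
#'
#' @param chr a `gn_chromosome`.
#' @return an object of class `gn_network_view` with fields `states` (0/1 per
#'   gene), `reachable` (logical per gene), `out_degree` (integer per gene),
#'   `terminal_set` (indices of out-degree-0 genes) and `reachable_order`
#'   (gene indices in evaluation order, parents before children).
#' @export
propagate_states <- function(chr) {
  stopifnot(inherits(chr, "gn_chromosome"))
  n <- chr$n_genes
  pr <- propagate_engine(matrix(chr$head), matrix(chr$func), chr$root_state, n, 1L)
  od <- out_degree_engine(matrix(chr$head), n, 1L)[, 1L]
  states <- pr$states[, 1L]
  reach <- pr$reachable[, 1L]
  # evaluation order: breadth-first from the root over the child lists
  order <- integer(0)
  frontier <- 1L
  children <- split(seq(2L, n), chr$head)
  while (length(frontier)) {
    order <- c(order, frontier)
    frontier <- unlist(children[as.character(frontier)], use.names = FALSE)
  }
  structure(
    list(states = states, reachable = reach, out_degree = od,
         terminal_set = which(od == 0L), reachable_order = order),
    class = "gn_network_view"
  )
}

#' Express a chromosome as a quantitative trait value
#'
#' The phenotype is the fraction of terminal genes (out-degree 0) in the
#' "on" state, scaled to the environmental range: a network with 8 terminal
#' genes of which 4 are on and the default range of 140 has phenotype 70.
#' Coarser networks can realise fewer distinct trait values, which is the
#' resolution cost of a small network.
#'
#' @param chr a `gn_chromosome`.
#' @param env_range positive scalar, the environmental range (default 140).
#' @return phenotype in `[0, env_range]`.
#' @export
phenotype <- function(chr, env_range = 140) {
  stopifnot(inherits(chr, "gn_chromosome"))
  check_scalar(env_range, "env_range", lo = .Machine$double.eps)
  phenotypes_engine(matrix(chr$head), matrix(chr$func), chr$root_state,
                    chr$n_genes, 1L, env_range)
}

#' Mutate a chromosome
#'
#' Each of the `n - 1` gene blocks mutates independently with probability
#' `mu`. A mutating block either flips its function bit (activator <->
#' repressor) or redraws its regulator uniformly among all genes except
#' itself (rewiring the topology); the two kinds are equally likely by
#' default. The root state never mutates. The input is not modified.
#'
#' @param chr a `gn_chromosome`.
#' @param mu per-block mutation probability in `[0, 1]`.
#' @param p_func probability that a mutation hits the function bit rather
#'   than the regulator (default 0.5).
#' @return a new `gn_chromosome`.
#' @export
mutate <- function(chr, mu, p_func = 0.5) {
  stopifnot(inherits(chr, "gn_chromosome"))
  check_scalar(mu, "mu", lo = 0, hi = 1)
  check_scalar(p_func, "p_func", lo = 0, hi = 1)
  m <- mutate_engine(matrix(chr$head), matrix(chr$func), mu, p_func)
  new_chromosome(chr$n_genes, chr$root_state, m$head[, 1L], m$func[, 1L])
}

#' Recombine two parental chromosomes
#'
#' Free recombination over the element sequence `[root state, gene 2 block,
#' ..., gene n block]`, with each gene's regulator index and function bit
#' inherited as one block. The parent supplying element 1 is chosen with
#' equal probability; before each subsequent element the source parent
#' switches with probability `r`.
#'
#' @param chrA,chrB parental `gn_chromosome`s with equal `n_genes`.
#' @param r per-boundary recombination probability in `[0, 1]`.
#' @return a new `gn_chromosome`.
#' @export
recombine <- function(chrA, chrB, r) {
  stopifnot(inherits(chrA, "gn_chromosome"), inherits(chrB, "gn_chromosome"))
  check_scalar(r, "r", lo = 0, hi = 1)
  if (chrA$n_genes != chrB$n_genes) {
    stop("incompatible cross: parents have different numbers of genes",
         call. = FALSE)
  }
  n <- chrA$n_genes
  off <- recombine_engine(cbind(chrA$head, chrB$head),
                          cbind(chrA$func, chrB$func),
                          c(chrA$root_state, chrB$root_state),
                          p1 = 1L, p2 = 2L, r = r, n = n)
  new_chromosome(n, off$root[1L], off$head[, 1L], off$func[, 1L])
}

#' Export a chromosome's network as an edge list
#'
#' @param chr a `gn_chromosome`.
#' @param path optional file path; when given, the edge list is written as
#'   tab-separated text with a header.
#' @return (invisibly when writing) a data.frame with columns `head`, `tail`
#'   and `func` (1 = activator, 0 = repressor).
#' @export
edge_list <- function(chr, path = NULL) {
  stopifnot(inherits(chr, "gn_chromosome"))
  el <- data.frame(head = chr$head, tail = seq(2L, chr$n_genes),
                   func = chr$func)
  if (!is.null(path)) {
    utils::write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(el))
  }
  el
}
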