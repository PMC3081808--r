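#' Species-level genetic architecture and demographic rates
#'
#' @param n_genes network size; the factorial treatments use
#'   16, 32, 64, 128 or 256, but any value >= 2 is accepted.
#' @param topology `"scale_free"` (preferential attachment) or `"random"`.
#' @param r recombination rate in `[0, 1]` (treatment values 0.05 and 0.5).
#' @param mu per-block mutation rate in `[0, 1]` (treatment values 1e-3 and
#'   1e-5).
#' @param lambda_fecundity Poisson mean number of offspring per mating
#'   (default 1.5).
#' @return an object of class `gn_species`.
#' @export
species_params <- function(n_genes = 16, topology = c("scale_free", "random"),
                           r = 0.5, mu = 1e-3, lambda_fecundity = 1.5) {
  check_scalar(n_genes, "n_genes", lo = 2, integer = TRUE)
  topology <- match.arg(topology)
  check_scalar(r, "r", lo = 0, hi = 1)
  check_scalar(mu, "mu", lo = 0, hi = 1)
  check_scalar(lambda_fecundity, "lambda_fecundity", lo = 0)
  structure(list(n_genes = as.integer(n_genes), topology = topology, r = r,
                 mu = mu, lambda_fecundity = lambda_fecundity),
            class = "gn_species")
}

# internal population container: genotype matrices plus cached phenotypes and
# stored mid-parent phenotypes (NA for founders)
new_population <- function(species_id, params, root, head, func, phen,
                           midparent) {
  structure(list(species_id = species_id, params = params, root = root,
                 head = head, func = func, phen = phen, midparent = midparent),
            class = "gn_population")
}

#' Found a population of random genotypes
#'
#' Every founder receives an independently generated network (topology drawn
#' under the species' attachment rule), a uniform root state, and uniform
#' function bits; founder mid-parent phenotypes are undefined (`NA`).
#'
#' @param params a [species_params()] object.
#' @param size number of founders (default K = 500).
#' @param species_id label carried through logs.
#' @param env_range environmental range for phenotype scaling.
#' @return a `gn_population`.
#' @export
found_population <- function(params, size = 500, species_id = "sp",
                             env_range = 140) {
  stopifnot(inherits(params, "gn_species"))
  check_scalar(size, "size", lo = 1, integer = TRUE)
  size <- as.integer(size)
  f <- founders_engine(params$n_genes, params$topology, size)
  phen <- phenotypes_engine(f$head, f$func, f$root, params$n_genes, size,
                            env_range)
  new_population(species_id, params, f$root, f$head, f$func, phen,
                 rep(NA_real_, size))
}

#' @export
print.gn_population <- function(x, ...) {
  cat(sprintf("<gn_population> '%s': %d individuals, %d genes (%s), r=%g, mu=%g\n",
              x$species_id, population_size(x), x$params$n_genes,
              x$params$topology, x$params$r, x$params$mu))
  invisible(x)
}

#' Number of individuals in a population
#' @param pop a `gn_population`.
#' @return integer count.
#' @export
population_size <- function(pop) length(pop$phen)

# internal: keep only the indexed individuals
subset_population <- function(pop, idx) {
  pop$root <- pop$root[idx]
  pop$head <- pop$head[, idx, drop = FALSE]
  pop$func <- pop$func[, idx, drop = FALSE]
  pop$phen <- pop$phen[idx]
  pop$midparent <- pop$midparent[idx]
  pop
}

#' Extract a single individual's chromosome from a population
#' @param pop a `gn_population`.
#' @param i individual index.
#' @return a `gn_chromosome`.
#' @export
get_chromosome <- function(pop, i) {
  stopifnot(inherits(pop, "gn_population"))
  check_scalar(i, "i", lo = 1, hi = population_size(pop), integer = TRUE)
  new_chromosome(pop$params$n_genes, pop$root[i], pop$head[, i], pop$func[, i])
}

#' Gaussian relative fitness of a phenotype against the optimum
#'
#' `RF = exp(-Delta^2 / (2 * omega^2))` with `Delta = |env_value - phenotype|`.
#' `omega` sets the breadth of the stabilizing-selection function, in trait
#' units: larger `omega` tolerates larger phenotype-environment mismatches.
#' RF gates survival only; it never affects fecundity. The default breadth
#' of 20 trait units is the smallest round value at which populations of
#' every studied architecture are demographically viable given the
#' Poisson(1.5) fecundity and canalize without collapsing to monomorphism
#' (see the methods vignette for the calibration).
#'
#' @param phenotype numeric vector of trait values.
#' @param env_value the current environmental optimum.
#' @param omega selection breadth in trait units (> 0, default 20).
#' @return fitness values in `(0, 1]`.
#' @export
relative_fitness <- function(phenotype, env_value, omega = 20) {
  check_scalar(omega, "omega", lo = .Machine$double.eps)
  check_scalar(env_value, "env_value")
  exp(-((env_value - phenotype)^2) / (2 * omega^2))
}

#' Produce the offspring generation by random mating
#'
#' Individuals are sexually reproducing hermaphrodites that mate at random:
#' each individual initiates one mating with a partner drawn uniformly from
#' the rest of the population (no selfing; an individual may be chosen as
#' partner by several initiators). Each mating yields `Poisson(lambda)`
#' offspring; each offspring chromosome is a recombinant of the two parents,
#' then mutated, and stores the parental mid-parent phenotype.
#'
#' @param pop a `gn_population` with at least 2 members (fewer returns an
#'   empty offspring cohort; the population is no longer viable).
#' @param env_range environmental range for phenotype scaling.
#' @return a `gn_population` of offspring (possibly empty).
#' @export
reproduce <- function(pop, env_range = 140) {
  stopifnot(inherits(pop, "gn_population"))
  N <- population_size(pop)
  par <- pop$params
  if (N < 2L) {
    return(subset_population(pop, integer(0)))
  }
  q <- sample.int(N - 1L, N, replace = TRUE)
  partner <- q + as.integer(q >= seq_len(N)) # uniform over the N-1 others
  k <- stats::rpois(N, par$lambda_fecundity)
  M <- sum(k)
  if (M == 0L) {
    return(subset_population(pop, integer(0)))
  }
  p1 <- rep.int(seq_len(N), k)
  p2 <- rep.int(partner, k)
  off <- recombine_engine(pop$head, pop$func, pop$root, p1, p2, par$r,
                          par$n_genes)
  mut <- mutate_engine(off$head, off$func, par$mu)
  phen <- phenotypes_engine(mut$head, mut$func, off$root, par$n_genes, M,
                            env_range)
  new_population(pop$species_id, par, off$root, mut$head, mut$func, phen,
                 (pop$phen[p1] + pop$phen[p2]) / 2)
}

#' Viability selection against the environmental optimum
#'
#' Each individual survives iff a uniform(0,1) draw does not exceed its
#' Gaussian relative fitness. Applied to the offspring cohort after all
#' parents have been discarded (non-overlapping generations).
#'
#' @param pop offspring `gn_population`.
#' @param env_value current environmental optimum.
#' @param omega selection breadth.
#' @return the surviving `gn_population` (possibly empty = extinction).
#' @export
viability_select <- function(pop, env_value, omega) {
  stopifnot(inherits(pop, "gn_population"))
  M <- population_size(pop)
  if (M == 0L) return(pop)
  rf <- relative_fitness(pop$phen, env_value, omega)
  subset_population(pop, which(stats::runif(M) <= rf))
}

#' Enforce the carrying capacity by random culling
#'
#' If the population exceeds `K`, uniformly random individuals are removed
#' until exactly `K` remain (density-dependent mortality ignores phenotype).
#'
#' @param pop a `gn_population`.
#' @param K carrying capacity (default 500).
#' @return the culled `gn_population`.
#' @export
cull_to_capacity <- function(pop, K = 500) {
  stopifnot(inherits(pop, "gn_population"))
  check_scalar(K, "K", lo = 1, integer = TRUE)
  N <- population_size(pop)
  if (N <= K) return(pop)
  subset_population(pop, sample.int(N, K))
}

#' One complete single-species generation
#'
#' Reproduction, death of all parents, viability selection against the
#' current optimum, then carrying-capacity culling: the three-stage death
#' schedule of the model.
#'
#' @param pop a `gn_population`.
#' @param env_value current environmental optimum.
#' @param omega selection breadth.
#' @param K carrying capacity.
#' @param env_range environmental range for phenotype scaling.
#' @return the next generation's `gn_population` (empty on extinction).
#' @export
step_generation <- function(pop, env_value, omega = 20, K = 500,
                            env_range = 140) {
  off <- reproduce(pop, env_range)
  surv <- viability_select(off, env_value, omega)
  cull_to_capacity(surv, K)
}
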