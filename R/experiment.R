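#' Configuration of one two-species competition run
#'
#' The protocol: each species is founded with `K` random individuals in its
#' own patch and evolves alone for `canalization_gens` generations (the
#' canalization period, which purges the excess phenotypic and genotypic
#' variance of random founding). A single dispersal event then moves
#' `dispersers_per_species` randomly chosen survivors of each species into a
#' shared third patch (all others are killed), where the two species compete
#' under one pooled carrying capacity while being selected against the same
#' moving optimum. The run ends at the first extinction or after
#' `max_generations` of competition.
#'
#' @param focal,competitor [species_params()] for the two species. The focal
#'   species defaults to the fixed reference architecture: 16 genes,
#'   scale-free topology, r = 0.05, mu = 1e-3 (the low recombination rate is
#'   what keeps the focal's standing load moderate; the competitor's rate is
#'   a treatment).
#' @param dEdt per-generation rate of environmental change, expressed as a
#'   fraction of the environmental range: the treatment grids run from 8e-3
#'   (1.12 trait units per generation on the default range, a fast
#'   fluctuation that sweeps the range several times in a 1000-generation
#'   run) down to 2e-4 (0.028 units per generation, nearly static). On this
#'   scale a species must hold additive variance of roughly
#'   `1.1 * dEdt * env_range * omega` squared units to track the optimum
#'   (about 25 at the fastest rate under the defaults).
#' @param omega selection breadth in trait units (default 20; see
#'   [relative_fitness()] and the methods vignette for the calibration).
#' @param K carrying capacity, per patch and pooled in the competition patch.
#' @param env_init starting optimum (default 70).
#' @param env_range environmental range (default 140).
#' @param canalization_gens single-species generations before dispersal.
#' @param dispersers_per_species individuals of each species moved to the
#'   competition patch (must not exceed `K`).
#' @param max_generations cap on competition generations (default 1000).
#' @param seed integer seed for the run; every source of randomness in the
#'   run flows from it.
#' @return an object of class `gn_config`.
#' @export
competition_config <- function(focal = species_params(r = 0.05),
                               competitor = species_params(),
                               dEdt = 8e-3,
                               omega = 20,
                               K = 500,
                               env_init = 70,
                               env_range = 140,
                               canalization_gens = 20,
                               dispersers_per_species = 200,
                               max_generations = 1000,
                               seed = 1) {
  stopifnot(inherits(focal, "gn_species"), inherits(competitor, "gn_species"))
  check_scalar(dEdt, "dEdt", lo = 0)
  check_scalar(omega, "omega", lo = .Machine$double.eps)
  check_scalar(K, "K", lo = 2, integer = TRUE)
  check_scalar(env_range, "env_range", lo = .Machine$double.eps)
  check_scalar(env_init, "env_init", lo = 0, hi = env_range)
  check_scalar(canalization_gens, "canalization_gens", lo = 0, integer = TRUE)
  check_scalar(dispersers_per_species, "dispersers_per_species",
               lo = 1, hi = K, integer = TRUE)
  check_scalar(max_generations, "max_generations", lo = 1, integer = TRUE)
  check_scalar(seed, "seed", integer = TRUE)
  structure(list(focal = focal, competitor = competitor, dEdt = dEdt,
                 omega = omega, K = as.integer(K), env_init = env_init,
                 env_range = env_range,
                 canalization_gens = as.integer(canalization_gens),
                 dispersers_per_species = as.integer(dispersers_per_species),
                 max_generations = as.integer(max_generations),
                 seed = as.integer(seed)),
            class = "gn_config")
}

# internal: preallocated per-generation log (two rows per generation, one per
# species), filled in place and trimmed to a data.frame at the end of a run
new_genlog <- function(capacity) {
  env <- new.env(parent = emptyenv())
  env$i <- 0L
  env$phase <- character(capacity)
  env$generation <- integer(capacity)
  env$competition_gen <- integer(capacity)
  env$species <- character(capacity)
  env$N <- integer(capacity)
  env$mean_phenotype <- numeric(capacity)
  env$V_P <- numeric(capacity)
  env$V_A <- numeric(capacity)
  env$h2 <- numeric(capacity)
  env$env_value <- numeric(capacity)
  env
}

log_row <- function(lg, phase, gen, comp_gen, pop, env_value) {
  vc <- pop_varcomp(pop)
  i <- lg$i <- lg$i + 1L
  lg$phase[i] <- phase
  lg$generation[i] <- gen
  lg$competition_gen[i] <- comp_gen
  lg$species[i] <- pop$species_id
  lg$N[i] <- population_size(pop)
  lg$mean_phenotype[i] <- if (population_size(pop)) mean(pop$phen) else NA_real_
  lg$V_P[i] <- vc$V_P %||% NA_real_
  lg$V_A[i] <- vc$V_A
  lg$h2[i] <- vc$h2
  lg$env_value[i] <- env_value
  invisible(lg)
}

genlog_frame <- function(lg) {
  i <- seq_len(lg$i)
  data.frame(phase = lg$phase[i], generation = lg$generation[i],
             competition_gen = lg$competition_gen[i], species = lg$species[i],
             N = lg$N[i], mean_phenotype = lg$mean_phenotype[i],
             V_P = lg$V_P[i], V_A = lg$V_A[i], h2 = lg$h2[i],
             env = lg$env_value[i])
}

# internal: one attempt at the full protocol; NULL if a species dies during
# canalization (the attempt is invalid and the run is re-seeded)
run_attempt <- function(cfg) {
  # treatment rates are fractions of the environmental range per generation
  # (8e-3 -> 1.12 trait units/gen on the default range); see the vignette
  env <- environment_state(cfg$env_init, cfg$dEdt * cfg$env_range,
                           c(0, cfg$env_range))
  pf <- found_population(cfg$focal, cfg$K, "focal", cfg$env_range)
  pc <- found_population(cfg$competitor, cfg$K, "competitor", cfg$env_range)
  lg <- new_genlog(2L * (cfg$canalization_gens + cfg$max_generations) + 2L)

  for (g in seq_len(cfg$canalization_gens)) {
    pf <- step_generation(pf, env$value, cfg$omega, cfg$K, cfg$env_range)
    pc <- step_generation(pc, env$value, cfg$omega, cfg$K, cfg$env_range)
    if (population_size(pf) == 0L || population_size(pc) == 0L) return(NULL)
    log_row(lg, "canalization", g, NA_integer_, pf, env$value)
    log_row(lg, "canalization", g, NA_integer_, pc, env$value)
    env <- step_environment(env)
  }

  # dispersal: 200 random survivors per species (all, with a warning, if a
  # species has fewer); everyone else is killed
  disperse <- function(pop) {
    N <- population_size(pop)
    if (N < cfg$dispersers_per_species) {
      warning(sprintf("species '%s' has only %d survivors at dispersal; all dispersed",
                      pop$species_id, N), call. = FALSE)
      return(pop)
    }
    subset_population(pop, sample.int(N, cfg$dispersers_per_species))
  }
  pf <- disperse(pf)
  pc <- disperse(pc)
  log_row(lg, "dispersal", gen0 <- cfg$canalization_gens, 0L, pf, env$value)
  log_row(lg, "dispersal", gen0, 0L, pc, env$value)

  start_vc <- list(focal = pop_varcomp(pf), competitor = pop_varcomp(pc))

  resolved <- FALSE
  t_res <- NA_integer_
  Nf_series <- integer(0)
  for (t in seq_len(cfg$max_generations)) {
    # both species reproduce and face viability selection independently,
    # then one pooled carrying capacity limits the whole community
    of <- viability_select(reproduce(pf, cfg$env_range), env$value, cfg$omega)
    oc <- viability_select(reproduce(pc, cfg$env_range), env$value, cfg$omega)
    nf <- population_size(of)
    nc <- population_size(oc)
    if (nf + nc > cfg$K) {
      keep <- sample.int(nf + nc, cfg$K)
      of <- subset_population(of, keep[keep <= nf])
      oc <- subset_population(oc, keep[keep > nf] - nf)
      nf <- population_size(of)
      nc <- population_size(oc)
    }
    pf <- of
    pc <- oc
    log_row(lg, "competition", gen0 + t, t, pf, env$value)
    log_row(lg, "competition", gen0 + t, t, pc, env$value)
    Nf_series <- c(Nf_series, nf)
    env <- step_environment(env)
    if (nf == 0L || nc == 0L) {
      resolved <- TRUE
      t_res <- t
      break
    }
  }

  # winner: survivor at first extinction; at the cap, the larger final
  # population (ties broken uniformly at random). Simultaneous extinction in
  # one generation is likewise a random tie.
  nf <- population_size(pf)
  nc <- population_size(pc)
  winner <- if (nf > nc) "focal" else if (nc > nf) "competitor"
            else sample(c("focal", "competitor"), 1L)
  list(
    generations = genlog_frame(lg),
    Nf_series = Nf_series,
    winner = winner,
    resolved = resolved,
    time_to_resolution = if (resolved) t_res else cfg$max_generations,
    start_varcomp = start_vc
  )
}

#' Run one two-species competition
#'
#' Executes the full canalization / dispersal / competition protocol for a
#' [competition_config()]. A run in which either species goes extinct during
#' canalization is invalid and is retried with a fresh seed derived from the
#' configured one (the attempt count is reported).
#'
#' @param cfg a `gn_config`.
#' @param max_attempts retries allowed for canalization extinctions.
#' @return an object of class `gn_run`: a list with `config`, `seed_used`,
#'   `attempts`, a per-generation data.frame `generations` (phase, generation,
#'   competition_gen, species, N, mean_phenotype, V_P, V_A, h2, env) and an
#'   `outcomes` list holding `dNdt_slope` (OLS slope of focal N on time over
#'   the first 20 competition generations), `winner`, `resolved`,
#'   `time_to_resolution`, and each species' variance components at the start
#'   of competition (`focal_V_A`, `focal_V_P`, `comp_V_A`, `comp_V_P`).
#' @examples
#' \donttest{
#' cfg <- competition_config(max_generations = 20, seed = 42)
#' run <- run_competition(cfg)
#' run$outcomes$dNdt_slope
#' }
#' @export
run_competition <- function(cfg, max_attempts = 100) {
  stopifnot(inherits(cfg, "gn_config"))
  seed <- cfg$seed
  for (attempt in seq_len(max_attempts)) {
    set.seed(seed)
    res <- run_attempt(cfg)
    if (!is.null(res)) {
      first20 <- res$Nf_series[seq_len(min(20L, length(res$Nf_series)))]
      out <- list(
        dNdt_slope = dNdt_slope(first20),
        winner = res$winner,
        resolved = res$resolved,
        time_to_resolution = res$time_to_resolution,
        focal_V_A = res$start_varcomp$focal$V_A,
        focal_V_P = res$start_varcomp$focal$V_P,
        comp_V_A = res$start_varcomp$competitor$V_A,
        comp_V_P = res$start_varcomp$competitor$V_P
      )
      return(structure(list(config = cfg, seed_used = seed, attempts = attempt,
                            generations = res$generations, outcomes = out),
                       class = "gn_run"))
    }
    seed <- derive_seed(cfg$seed, "retry", attempt)
  }
  stop(sprintf("no valid run in %d attempts (extinction during canalization every time)",
               max_attempts), call. = FALSE)
}

#' @export
print.gn_run <- function(x, ...) {
  o <- x$outcomes
  cat(sprintf("<gn_run> seed %d (%d attempt%s): winner = %s, time-to-resolution = %d%s, focal dN/dt = %.4g\n",
              x$seed_used, x$attempts, if (x$attempts > 1) "s" else "",
              o$winner, o$time_to_resolution,
              if (o$resolved) "" else " (censored)", o$dNdt_slope))
  invisible(x)
}

#' OLS slope of population size on time
#'
#' The competitive-impact metric: the least-squares slope of the focal
#' species' population size over the first 20 generations of competition
#' (fewer points are used if the run resolved earlier; a single point gives
#' `NA`).
#'
#' @param N_series population sizes at competition generations 1, 2, ...
#' @param generations optional time index (defaults to `seq_along(N_series)`).
#' @return the slope, in individuals per generation.
#' @examples
#' dNdt_slope(100 + 5 * (1:20)) # exactly 5
#' @export
dNdt_slope <- function(N_series, generations = seq_along(N_series)) {
  stopifnot(length(N_series) == length(generations))
  if (length(N_series) < 2L) return(NA_real_)
  stats::cov(generations, N_series) / stats::var(generations)
}

#' Treatment grids used by the factorial experiments
#'
#' Named presets for the competitor-architecture sweeps: `"set1"` crosses
#' five network sizes, two topologies, two recombination rates and two
#' mutation rates with the five faster rates of environmental change;
#' `"set2"` drops topology and mutation rate (no effect was observed) and
#' keeps the five faster dEdt levels; `"set2-slow"` uses the four
#' order-of-magnitude-slower dEdt levels at which large-network competitors
#' can win.
#'
#' @param name `"set1"`, `"set2"` or `"set2-slow"`.
#' @return a data.frame with one row per treatment combination, columns
#'   `comp_n`, `comp_topology`, `comp_r`, `comp_mu`, `dEdt`.
#' @export
preset_design <- function(name = c("set1", "set2", "set2-slow")) {
  name <- match.arg(name)
  sizes <- c(16, 32, 64, 128, 256)
  fast <- c(8e-3, 6e-3, 4e-3, 2e-3, 1e-3)
  slow <- c(8e-4, 6e-4, 4e-4, 2e-4)
  switch(name,
    "set1" = expand.grid(comp_n = sizes,
                         comp_topology = c("scale_free", "random"),
                         comp_r = c(0.05, 0.5), comp_mu = c(1e-3, 1e-5),
                         dEdt = fast, stringsAsFactors = FALSE),
    "set2" = expand.grid(comp_n = sizes, comp_topology = "scale_free",
                         comp_r = c(0.05, 0.5), comp_mu = 1e-3,
                         dEdt = fast, stringsAsFactors = FALSE),
    "set2-slow" = expand.grid(comp_n = sizes, comp_topology = "scale_free",
                              comp_r = c(0.05, 0.5), comp_mu = 1e-3,
                              dEdt = slow, stringsAsFactors = FALSE)
  )
}

#' Run a factorial design of competition simulations
#'
#' Executes `replicates` runs of every treatment row, with a deterministic
#' per-run seed derived from `base_seed`, the treatment values and the
#' replicate index, so the same call always reproduces the same table.
#'
#' @param design data.frame of treatments; recognised columns are `comp_n`,
#'   `comp_topology`, `comp_r`, `comp_mu` (competitor architecture), `dEdt`,
#'   `omega`, and any [competition_config()] scalar field (e.g.
#'   `max_generations`, `canalization_gens`). Unrecognised columns are an
#'   error. See [preset_design()].
#' @param replicates runs per treatment (>= 1).
#' @param base_seed integer master seed.
#' @param ... fixed overrides applied to every run (passed to
#'   [competition_config()]), e.g. `max_generations = 20` for
#'   initial-competition sweeps, or `focal = species_params(r = 0.05)`.
#' @param verbose print a progress line per treatment.
#' @return a data.frame with one row per run: the treatment columns,
#'   `replicate`, `seed`, `attempts`, and outcomes `dNdt_slope`, `winner`,
#'   `resolved`, `time_to_resolution`, `focal_V_A`, `focal_V_P`, `comp_V_A`,
#'   `comp_V_P`.
#' @export
factorial_runner <- function(design, replicates, base_seed, ...,
                             verbose = FALSE) {
  stopifnot(is.data.frame(design), nrow(design) >= 1L)
  check_scalar(replicates, "replicates", lo = 1, integer = TRUE)
  check_scalar(base_seed, "base_seed", integer = TRUE)
  comp_cols <- c(comp_n = "n_genes", comp_topology = "topology",
                 comp_r = "r", comp_mu = "mu")
  cfg_cols <- c("dEdt", "omega", "K", "env_init", "env_range",
                "canalization_gens", "dispersers_per_species",
                "max_generations")
  bad <- setdiff(names(design), c(names(comp_cols), cfg_cols))
  if (length(bad)) {
    stop("unknown design column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  fixed <- list(...)
  rows <- vector("list", nrow(design) * replicates)
  ri <- 0L
  for (i in seq_len(nrow(design))) {
    trt <- design[i, , drop = FALSE]
    sp_args <- lapply(intersect(names(comp_cols), names(trt)),
                      function(cn) trt[[cn]])
    names(sp_args) <- comp_cols[intersect(names(comp_cols), names(trt))]
    cfg_args <- as.list(trt[intersect(cfg_cols, names(trt))])
    cfg_args <- utils::modifyList(cfg_args, fixed)
    if (!("competitor" %in% names(cfg_args))) {
      base_comp <- cfg_args$competitor %||% species_params()
      cfg_args$competitor <- do.call(species_params, utils::modifyList(
        list(n_genes = base_comp$n_genes, topology = base_comp$topology,
             r = base_comp$r, mu = base_comp$mu), sp_args))
    }
    trt_key <- paste(names(trt), unlist(lapply(trt, format)), sep = "=",
                     collapse = ";")
    if (verbose) {
      message(sprintf("[%d/%d] %s", i, nrow(design), trt_key))
    }
    for (rep_i in seq_len(replicates)) {
      cfg_args$seed <- derive_seed(base_seed, trt_key, rep_i)
      run <- run_competition(do.call(competition_config, cfg_args))
      o <- run$outcomes
      rows[[ri <- ri + 1L]] <- cbind(
        trt,
        data.frame(replicate = rep_i, seed = run$seed_used,
                   attempts = run$attempts, dNdt_slope = o$dNdt_slope,
                   winner = o$winner, resolved = o$resolved,
                   time_to_resolution = o$time_to_resolution,
                   focal_V_A = o$focal_V_A, focal_V_P = o$focal_V_P,
                   comp_V_A = o$comp_V_A, comp_V_P = o$comp_V_P)
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
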