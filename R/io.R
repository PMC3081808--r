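#' Load a competition configuration or design grid from a YAML file
#'
#' The file mirrors [competition_config()]: scalar keys (`dEdt`, `omega`,
#' `K`, `env_init`, `env_range`, `canalization_gens`,
#' `dispersers_per_species`, `max_generations`, `seed`) plus nested `focal:`
#' and `competitor:` blocks with [species_params()] keys (`n_genes`,
#' `topology`, `r`, `mu`, `lambda_fecundity`). Omitted keys take the model
#' defaults (focal: 16 genes, scale-free; K = 500; lambda = 1.5; range 140).
#' Unknown keys are rejected by name. Two sweep keys are also understood:
#' `design: <preset name>` (see [preset_design()]) and `replicates:`.
#'
#' @param path path to a YAML file; an empty file yields all defaults.
#' @return a `gn_config`, with attributes `design` (data.frame or `NULL`) and
#'   `replicates` when the file describes a sweep.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config file must contain a YAML mapping", call. = FALSE)
  sp_keys <- c("n_genes", "topology", "r", "mu", "lambda_fecundity")
  cfg_keys <- c("focal", "competitor", "dEdt", "omega", "K", "env_init",
                "env_range", "canalization_gens", "dispersers_per_species",
                "max_generations", "seed")
  sweep_keys <- c("design", "replicates")
  bad <- setdiff(names(raw), c(cfg_keys, sweep_keys))
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  build_species <- function(x, who) {
    if (is.null(x)) x <- list()
    bad <- setdiff(names(x), sp_keys)
    if (length(bad)) {
      stop(sprintf("unknown key(s) under '%s': %s", who,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    do.call(species_params, x)
  }
  args <- raw[setdiff(intersect(names(raw), cfg_keys), c("focal", "competitor"))]
  args$focal <- build_species(raw$focal, "focal")
  args$competitor <- build_species(raw$competitor, "competitor")
  cfg <- do.call(competition_config, args)
  if (!is.null(raw$design)) {
    attr(cfg, "design") <- preset_design(raw$design)
    attr(cfg, "replicates") <- raw$replicates %||% 40
  }
  cfg
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run bit-exactly: the full
#' configuration, the base and actually-used seeds, the attempt count,
#' package version and a timestamp.
#'
#' @param run a `gn_run` from [run_competition()].
#' @param path output JSON path.
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(run, path) {
  stopifnot(inherits(run, "gn_run"))
  cfg <- run$config
  manifest <- list(
    config = list(
      focal = unclass(cfg$focal), competitor = unclass(cfg$competitor),
      dEdt = cfg$dEdt, omega = cfg$omega, K = cfg$K, env_init = cfg$env_init,
      env_range = cfg$env_range, canalization_gens = cfg$canalization_gens,
      dispersers_per_species = cfg$dispersers_per_species,
      max_generations = cfg$max_generations, seed = cfg$seed
    ),
    seed_used = run$seed_used,
    attempts = run$attempts,
    package_version = as.character(utils::packageVersion("grncompete")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

#' Serialize a chromosome to JSON (and back)
#'
#' @param chr a `gn_chromosome`.
#' @param path optional file path; omitted, the JSON string is returned.
#' @return `chromosome_to_json()`: a JSON string (or invisibly, when
#'   writing to file); `chromosome_from_json()`: a `gn_chromosome`.
#' @export
chromosome_to_json <- function(chr, path = NULL) {
  stopifnot(inherits(chr, "gn_chromosome"))
  x <- list(n_genes = chr$n_genes, root_state = chr$root_state,
            head = chr$head, func = chr$func)
  if (is.null(path)) {
    return(as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)))
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(chromosome_to_json(chr))
}

#' @param json a JSON string or file path produced by [chromosome_to_json()].
#' @rdname chromosome_to_json
#' @export
chromosome_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  new_chromosome(x$n_genes, x$root_state, x$head, x$func)
}

#' The 13-gene worked-example chromosome
#'
#' A small network used throughout the documentation and tests: 13 genes in
#' a three-level tree below the root (root state "on"), with 8 terminal
#' genes of which exactly 4 propagate to the "on" state, so the phenotype is
#' `140 / 8 * 4 = 70` at the default environmental range. This is a
#' synthetic exemplar constructed to have those properties.
#'
#' @return a `gn_chromosome` with 13 genes.
#' @examples
#' chr <- fixture_fig_network()
#' phenotype(chr) # 70
#' @export
fixture_fig_network <- function() {
  new_chromosome(
    n_genes = 13,
    root_state = 1,
    #        gene:  2  3  4  5  6  7  8  9 10 11 12 13
    head = c(       1, 1, 1, 2, 2, 2, 3, 3, 4, 4, 5, 5),
    func = c(       1, 0, 1, 1, 0, 1, 0, 1, 1, 0, 1, 0)
  )
}

#' Write per-generation and summary CSV logs
#'
#' @param run a `gn_run`.
#' @param gen_path path for the per-generation log CSV (optional).
#' @param thin write every `thin`-th generation of the per-generation log
#'   (default 1 = all).
#' @return the per-generation data.frame, invisibly.
#' @export
write_run_log <- function(run, gen_path = NULL, thin = 1) {
  stopifnot(inherits(run, "gn_run"))
  check_scalar(thin, "thin", lo = 1, integer = TRUE)
  g <- run$generations
  if (thin > 1) g <- g[g$generation %% thin == 0L | g$generation <= 1L, ]
  if (!is.null(gen_path)) {
    utils::write.csv(g, gen_path, row.names = FALSE)
  }
  invisible(g)
}

#' Write a factorial results table as CSV
#'
#' @param results the data.frame from [factorial_runner()].
#' @param path output CSV path.
#' @return `results`, invisibly.
#' @export
write_results <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE)
  invisible(results)
}
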