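#' Run the conformational-diversity workflow and write report files
#'
#' Reads every configured conformer, builds the pairwise C-alpha RMSD
#' matrix, locates the maximum-diversity pair, computes its per-residue
#' Z-score profile and (when site residues are configured) the site
#' flexibility report. Writes `rmsd_matrix.tsv`, `max_pair.json`,
#' `zscore_profile.tsv` and `site_report.json` into the output directory.
#'
#' @param config A configuration list (see [read_run_config()]) or path to a
#'   YAML file. Required fields: `structures` (list of `list(path =, chain =)`
#'   entries, or in-memory `confdock_structure` objects under `objects`),
#'   `out_dir`. Optional: `site` (integer residue numbers).
#' @return Named character vector of the written file paths, invisibly.
#' @export
run_diversity <- function(config) {
  cfg <- read_run_config(config)
  traces <- config_traces(cfg)
  if (length(traces) < 2) stop("need >=2 conformers", call. = FALSE)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  m <- pairwise_rmsd(traces)
  pair <- max_diversity_pair(m)
  prof <- zscore_profile(traces[[pair$conformer_a]],
                         traces[[pair$conformer_b]])

  paths <- c(
    rmsd_matrix = file.path(cfg$out_dir, "rmsd_matrix.tsv"),
    max_pair = file.path(cfg$out_dir, "max_pair.json"),
    zscore_profile = file.path(cfg$out_dir, "zscore_profile.tsv"),
    site_report = file.path(cfg$out_dir, "site_report.json")
  )
  write_tsv_matrix(m, paths["rmsd_matrix"])
  jsonlite::write_json(as.list(pair), paths["max_pair"], auto_unbox = TRUE,
                       digits = NA)
  utils::write.table(as.data.frame(prof), paths["zscore_profile"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cfg$site)) {
    rep <- site_flexibility(prof, cfg$site)
    jsonlite::write_json(
      list(site = as.data.frame(rep),
           fraction_below_zero = attr(rep, "fraction_below_zero"),
           verdict = attr(rep, "verdict"),
           missing = attr(rep, "missing")),
      paths["site_report"], auto_unbox = TRUE, digits = NA
    )
  } else {
    jsonlite::write_json(list(site = NULL, verdict = "no site configured"),
                         paths["site_report"], auto_unbox = TRUE)
  }
  invisible(paths)
}

#' Run the ensemble re-docking workflow and write report files
#'
#' Docks the configured ligand against every conformer with the configured
#' engine and repeat count, and writes `affinities.tsv` (one row per run),
#' `summary.json` (per-conformer mean +/- sample SD and the pooled
#' distribution) and `histogram.tsv` (relative frequencies in percent).
#'
#' @param config Configuration list or YAML path. Required: `structures` (or
#'   `objects`), `ligand` (path or `ligand_pose`), `box` (`list(residue =,
#'   chain =, edge =)`), `engine`, `out_dir`. Optional: `n_repeats` (default
#'   100), `base_seed` (default 1), `bin_width` (default 0.25).
#' @return Named character vector of written paths, invisibly.
#' @export
run_dock <- function(config) {
  cfg <- read_run_config(config)
  structures <- config_structures(cfg)
  engine <- cfg$engine %||% list(type = "mock")
  if (identical(engine$type, "external")) {
    exe <- engine$executable
    if (is.null(exe) || (!file.exists(exe) && Sys.which(exe) == "")) {
      stop("docking engine executable not found: ", exe %||% "<unset>",
           call. = FALSE)
    }
  }
  ligand <- cfg$ligand
  if (is.character(ligand)) ligand <- read_ligand_pose(ligand)
  box_fun <- function(s) docking_box(s, cfg$box$chain %||% "A",
                                     cfg$box$residue,
                                     edge = cfg$box$edge %||% 14)
  tab <- ensemble_dock(structures, ligand, box_fun, engine,
                       n_repeats = cfg$n_repeats %||% 100,
                       base_seed = cfg$base_seed %||% 1)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    affinities = file.path(cfg$out_dir, "affinities.tsv"),
    summary = file.path(cfg$out_dir, "summary.json"),
    histogram = file.path(cfg$out_dir, "histogram.tsv")
  )
  utils::write.table(as.data.frame(tab$records), paths["affinities"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(by_conformer = as.data.frame(tab$by_conformer),
         pooled = as.data.frame(tab$pooled)),
    paths["summary"], auto_unbox = TRUE, digits = NA
  )
  utils::write.table(
    as.data.frame(affinity_histogram(tab, cfg$bin_width %||% 0.25)),
    paths["histogram"], sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(paths)
}

#' Compute a drug-likeness profile and write it as JSON and TSV
#'
#' @param input SMILES string, SDF text or path.
#' @param logp_method Passed to [druglikeness()].
#' @param out_dir Output directory (default `"."`); writes
#'   `druglikeness.json` and `druglikeness.tsv`.
#' @return The profile tibble, invisibly.
#' @export
run_druglikeness <- function(input, logp_method = "crippen",
                             out_dir = ".") {
  prof <- druglikeness(parse_molecule(input), logp_method = logp_method)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(as.list(as.data.frame(prof)),
                       file.path(out_dir, "druglikeness.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(as.data.frame(prof),
                     file.path(out_dir, "druglikeness.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prof)
}

#' Read and validate a run configuration
#'
#' @param config A list, or path to a YAML file with the same fields.
#' @return The validated configuration list.
#' @export
read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or YAML path",
                             call. = FALSE)
  if (is.null(config$out_dir)) stop("config needs 'out_dir'", call. = FALSE)
  for (s in config$structures) {
    if (!is.null(s$path) && !file.exists(s$path)) {
      stop("structure file not found: ", s$path, call. = FALSE)
    }
  }
  if (!is.null(config$n_repeats) && config$n_repeats < 1) {
    stop("n_repeats must be >= 1", call. = FALSE)
  }
  config
}

config_structures <- function(cfg) {
  if (!is.null(cfg$objects)) return(cfg$objects)
  if (is.null(cfg$structures) || length(cfg$structures) == 0) {
    stop("config lists no structures", call. = FALSE)
  }
  out <- list()
  for (s in cfg$structures) {
    id <- s$id %||% paste0(sub("\\.[^.]*$", "", basename(s$path)),
                           ":", s$chain %||% "A")
    out[[id]] <- read_structure(s$path, id = id)
  }
  out
}

config_traces <- function(cfg) {
  if (!is.null(cfg$objects)) {
    return(lapply(cfg$objects, ca_trace,
                  chain = cfg$chain %||% "A"))
  }
  structures <- list()
  traces <- list()
  for (s in cfg$structures) {
    id <- s$id %||% paste0(sub("\\.[^.]*$", "", basename(s$path)),
                           ":", s$chain %||% "A")
    st <- read_structure(s$path, id = id)
    traces[[id]] <- ca_trace(st, s$chain %||% "A")
  }
  traces
}

write_tsv_matrix <- function(m, path) {
  df <- data.frame(conformer = rownames(m), unclass(m)[,], check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
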