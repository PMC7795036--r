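#' Pipeline configuration
#'
#' One namespace for every tunable of the workflow, with the standard
#' defaults: pocket presence fraction 0.40, residue-assignment cutoff
#' 4.0 A, strong-coupling display threshold 0.75, activation-state
#' thresholds 8 A (active) and 0 A (inactive).  Serializes losslessly to
#' JSON via [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param ensemble list describing the ensemble source: one of `pdb_dir`,
#'   `multi_model`, or `trajectory` + `topology`; optional `chain`,
#'   `residues` (range string), `state` (per-frame tags).
#' @param delta list: `preset` or `anchors` (4 residue ids), plus
#'   `active_threshold`, `inactive_threshold`.
#' @param sites list: `pockets` (dummy-atom file(s)) or `site_lists`
#'   (residue-list file); `presence`, `cutoff`, optional `orthosteric`
#'   (residue ids), `exclude` (labels).
#' @param report list: `strong_threshold`, `rounded_above_mean`.
#' @param seed integer seed recorded in the run log.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(ensemble = list(), delta = list(),
                            sites = list(), report = list(), seed = 1L) {
  defaults <- list(
    ensemble = list(pdb_dir = NULL, multi_model = NULL, trajectory = NULL,
                    topology = NULL, chain = NULL, residues = NULL,
                    state = "unknown"),
    delta = list(preset = NULL, anchors = NULL,
                 active_threshold = 8, inactive_threshold = 0),
    sites = list(pockets = NULL, site_lists = NULL, presence = 0.40,
                 cutoff = 4.0, orthosteric = NULL, exclude = NULL),
    report = list(strong_threshold = 0.75, rounded_above_mean = FALSE),
    seed = 1L)
  cfg <- defaults
  cfg$ensemble[names(ensemble)] <- ensemble
  cfg$delta[names(delta)] <- delta
  cfg$sites[names(sites)] <- sites
  cfg$report[names(report)] <- report
  cfg$seed <- as.integer(seed)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline configuration (JSON)
#'
#' @param config a `pipeline_config`.
#' @param file path.
#' @return `read_pipeline_config` returns the config; the writer returns
#'   `file` invisibly.
#' @export
write_pipeline_config <- function(config, file) {
  jsonlite::write_json(unclass(config), file, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(file)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(file) {
  raw <- jsonlite::fromJSON(file, simplifyVector = TRUE)
  pipeline_config(ensemble = raw$ensemble, delta = raw$delta,
                  sites = raw$sites, report = raw$report, seed = raw$seed)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("[", name, "] ", conditionMessage(e), call. = FALSE))
}

#' Run the full site-ranking workflow
#'
#' Executes load, superpose, activation variable, site definition,
#' coupling matrix, site scoring and ranking, and (when `out_dir` is
#' given) writes the activation-variable table, the full / long / strong
#' coupling matrices, per-site sub-matrices, the ranking (TSV + JSON) and
#' a machine-readable run log with the exact configuration, seed and
#' package version.
#'
#' @param config a `pipeline_config` (or path to its JSON form).
#' @param out_dir optional output directory.
#' @return the report bundle, invisibly: `ensemble`, `delta`, `coupling`,
#'   `sites`, `scores`, `ranking`, `config`, `log`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  ec <- config$ensemble
  src <- if (!is.null(ec$pdb_dir)) ec$pdb_dir
    else if (!is.null(ec$multi_model)) ec$multi_model
    else if (!is.null(ec$trajectory))
      list(trajectory = ec$trajectory, topology = ec$topology)
    else stop("[load] no ensemble source in configuration")
  ens <- .stage("load", load_ensemble(src, chain = ec$chain,
                                      residues = ec$residues,
                                      state = ec$state))
  ens <- .stage("superpose", superpose_ensemble(ens, reference = 1L))
  spec <- .stage("delta", resolve_delta_spec(config$delta$preset, ens,
                                             anchors = config$delta$anchors))
  dl <- .stage("delta", compute_delta(ens, spec))
  states <- classify_state(dl, config$delta$active_threshold,
                           config$delta$inactive_threshold)

  sc <- config$sites
  sites <- .stage("sites", {
    out <- list()
    if (!is.null(sc$pockets)) {
      clouds <- parse_pocket_output(sc$pockets, n_frames = n_frames(ens))
      clouds <- presence_filter(clouds, sc$presence)
      if (length(clouds) == 0L) stop("no pockets pass the presence filter")
      out <- c(out, lapply(clouds, assign_site_residues, ensemble = ens,
                           cutoff = sc$cutoff))
    }
    if (!is.null(sc$site_lists))
      out <- c(out, load_site_lists(sc$site_lists, ens))
    if (length(out) == 0L) stop("no site source in configuration")
    filter_sites(out, orthosteric_residues = sc$orthosteric,
                 exclude = sc$exclude)
  })
  if (length(sites) == 0L) stop("[sites] all sites filtered out")

  cm <- .stage("coupling", compute_coupling_matrix(ens, dl))
  scores <- .stage("coupling", lapply(sites, compute_csite, matrix = cm))
  ranking <- .stage("rank",
                    rank_sites(scores,
                               rounded = isTRUE(config$report$rounded_above_mean)))

  log <- list(package_version = as.character(utils::packageVersion("allodyn")),
              seed = config$seed,
              n_frames = n_frames(ens), n_residues = n_residues(ens),
              n_sites = length(sites),
              n_invalid_couplings = cm$n_invalid,
              state_counts = as.list(table(states)),
              config = unclass(config))
  bundle <- list(ensemble = ens, delta = dl, states = states, coupling = cm,
                 sites = sites, scores = scores, ranking = ranking,
                 config = config, log = log)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_delta_table(dl, file.path(out_dir, "delta.tsv"),
                      active_threshold = config$delta$active_threshold,
                      inactive_threshold = config$delta$inactive_threshold)
    export_coupling_matrix(cm, file.path(out_dir, "coupling_wide.tsv"),
                           "wide")
    export_coupling_matrix(cm, file.path(out_dir, "coupling_long.tsv"),
                           "long")
    export_coupling_matrix(cm, file.path(out_dir, "coupling_strong.tsv"),
                           "strong",
                           threshold = config$report$strong_threshold)
    for (s in scores) {
      f <- file.path(out_dir,
                     paste0("site_", gsub("[^A-Za-z0-9_.-]", "_",
                                          s$site_label), "_submatrix.tsv"))
      utils::write.table(round(s$submatrix, 6), f, sep = "\t",
                         quote = FALSE, col.names = NA)
    }
    export_ranking(ranking, file.path(out_dir, "ranking.tsv"), "tsv")
    export_ranking(ranking, file.path(out_dir, "ranking.json"), "json")
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  invisible(bundle)
}

#' Render a human-readable run summary
#'
#' Covers the activation-variable distribution by state, the
#' strong-coupling count, and the ranked sites with their top pairs.
#'
#' @param bundle result of [run_pipeline()].
#' @param strong_threshold display threshold for strong couplings.
#' @return character vector of report lines, invisibly; also printed.
#' @export
render_report <- function(bundle, strong_threshold = 0.75) {
  dl <- bundle$delta
  lines <- c(
    "== allosteric coupling report ==",
    sprintf("frames: %d   residues: %d   sites: %d",
            n_frames(bundle$ensemble), n_residues(bundle$ensemble),
            length(bundle$sites)),
    "delta by state:")
  for (st in unique(bundle$states)) {
    v <- dl$delta[bundle$states == st]
    lines <- c(lines, sprintf("  %-12s n=%3d  delta %6.2f .. %6.2f (mean %6.2f)",
                              st, length(v), min(v), max(v), mean(v)))
  }
  nstrong <- sum(strong_coupling_mask(bundle$coupling,
                                      strong_threshold)) / 2
  lines <- c(lines,
             sprintf("strong couplings (|c| > %.2f): %d residue pairs",
                     strong_threshold, nstrong),
             sprintf("ranking (mean C_site = %.2f):",
                     attr(bundle$ranking, "mean_c_site")))
  r <- bundle$ranking
  for (k in seq_len(nrow(r))) {
    tp <- if (is.na(r$top_pair_i[k])) "" else
      sprintf("  top pair %s - %s (c = %+.2f)",
              r$top_pair_i[k], r$top_pair_j[k], r$top_pair_c[k])
    lines <- c(lines, sprintf("  %2d. %-10s C_site %.2f%s%s",
                              r$rank[k], r$site_label[k], r$c_site[k],
                              ifelse(r$above_mean[k], " *", "  "), tp))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
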