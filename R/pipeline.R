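#' Assemble a pipeline run configuration
#'
#' Defaults mirror the standard analysis constants: 1000 bootstrap
#' datasets, 90% confidence level, transition rate `w = 5` degrees, and
#' lifestyle thresholds 45/80 degrees Celsius. Inputs come either from
#' files (`binding_file`, `stability_file`, `tree_file`,
#' `calibration_file`) or from the built-in trait-tree simulator
#' (`simulate = list(...)` arguments for [simulate_trait_tree()]).
#'
#' @param ... Named fields overriding the defaults below.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(seed = 1L, n_boot = 1000L, level = 0.90, w = 5,
              thresholds = c(45, 80), out_dir = NULL,
              binding_file = NULL, stability_file = NULL,
              tree_file = NULL, calibration_file = NULL,
              simulate = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(cfg, over)
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param file Path to a YAML file whose keys are [run_config()] fields.
#' @return A `run_config`.
#' @export
read_run_config <- function(file) {
  do.call(run_config, yaml::read_yaml(file))
}

#' Run the OGT-inference pipeline end to end
#'
#' Orchestrates the full analysis for a batch of proteins: determine each
#' protein's thermal stability range from its melt profile, restrict its
#' binding profile to that range, fit the skewed peak model, bootstrap the
#' peak-temperature confidence interval, convert the optimum into an OGT
#' estimate with a lifestyle class, and (when a tree is available) paint
#' the estimates onto the phylogeny and emit the evolutionary trajectory
#' table. Proteins are processed in isolation: one pathological profile is
#' reported as failed without sinking the batch.
#'
#' The run is deterministic given `cfg$seed`: per-protein bootstrap seeds
#' are derived from it up front. When `cfg$out_dir` is set, results are
#' written there (TSV tables, annotated newick plus sidecar, and a JSON
#' manifest recording the configuration, its hash, package version and
#' every seed used); a run directory is never reused for reading.
#'
#' @param cfg A [run_config()] (or a YAML path accepted by
#'   [read_run_config()]).
#' @return A list (the run manifest, returned invisibly when written):
#'   `ogt_table` (per-protein data frame), `estimates`, `boots`,
#'   `stability`, `annotated_tree` (or NULL), `trajectory` (or NULL),
#'   `calibration` (or NULL), `failures`, `config`, `config_hash`,
#'   `seeds`, `outputs`.
#' @examples
#' \donttest{
#' cfg <- run_config(simulate = list(n_leaves = 3), n_boot = 30, seed = 2)
#' man <- run_pipeline(cfg)
#' man$ogt_table
#' }
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  for (f in c("binding_file", "stability_file", "tree_file",
              "calibration_file")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("configuration error: ", f, " '", cfg[[f]], "' does not exist")
  }
  if (is.null(cfg$simulate) && is.null(cfg$binding_file))
    stop("configuration error: provide 'binding_file' or 'simulate'")

  truth <- NULL
  tree <- NULL
  stab_profiles <- list()
  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    sim_args$seed <- cfg$seed
    sim <- do.call(simulate_trait_tree, sim_args)
    binding <- sim$profiles
    tree <- sim$tree
    truth <- sim$ogt
  } else {
    binding <- read_profiles(cfg$binding_file, assay_kind = "binding")
    if (!is.null(cfg$stability_file))
      stab_profiles <- read_profiles(cfg$stability_file,
                                     assay_kind = "stability")
    if (!is.null(cfg$tree_file)) tree <- read_newick(cfg$tree_file)
  }

  ids <- names(binding)
  set.seed(as.integer(cfg$seed))
  boot_seeds <- stats::setNames(sample.int(.Machine$integer.max - 1L,
                                           length(ids)), ids)

  stability <- list()
  boots <- list()
  estimates <- list()
  failures <- list()
  for (id in ids) {
    res <- tryCatch({
      prof <- binding[[id]]
      fit_range <- NULL
      if (id %in% names(stab_profiles)) {
        sr <- stable_range(stab_profiles[[id]])
        stability[[id]] <- sr
        prof <- restrict_to_stable(prof, sr)
      }
      bt <- bootstrap_peak_ci(prof, n_boot = cfg$n_boot, level = cfg$level,
                              seed = boot_seeds[[id]], w = cfg$w)
      estimates[[id]] <- infer_ogt(id, bt, thresholds = cfg$thresholds)
      boots[[id]] <- bt
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) failures[[id]] <- res
  }
  if (!length(estimates))
    stop("pipeline produced no estimates; first failure: ",
         if (length(failures)) failures[[1L]] else "none recorded")

  ogt_table <- ogt_estimates_df(estimates)
  annotated <- NULL
  trajectory <- NULL
  if (!is.null(tree)) {
    present <- ogt_table[ogt_table$label %in%
                           c(tree$tip.label, tree$node.label), ]
    annotated <- annotate_nodes(tree, present)
    trajectory <- trajectory_table(annotated)
  }
  calibration <- NULL
  if (!is.null(cfg$calibration_file)) {
    cal <- read_calibration(cfg$calibration_file)
    calibration <- list(table = cal, cor = pearson_r(cal))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("ogtrace")),
    config = unclass(cfg),
    config_hash = config_hash(cfg),
    seeds = list(root = cfg$seed, bootstrap = as.list(boot_seeds)),
    ogt_table = ogt_table,
    estimates = estimates,
    boots = boots,
    stability = stability,
    annotated_tree = annotated,
    trajectory = trajectory,
    calibration = calibration,
    truth = truth,
    failures = failures,
    outputs = character())

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(name) file.path(cfg$out_dir, name)
    write_ogt_tsv(estimates, out("ogt_estimates.tsv"))
    write_bootstrap_tsv(boots, out("bootstrap_ci.tsv"))
    outputs <- c("ogt_estimates.tsv", "bootstrap_ci.tsv")
    if (length(stability)) {
      write_stability_tsv(stability, out("stability.tsv"))
      outputs <- c(outputs, "stability.tsv")
    }
    if (!is.null(annotated)) {
      write_newick(annotated, out("annotated_tree.nwk"),
                   sidecar = out("annotated_tree.tsv"))
      utils::write.table(trajectory, out("trajectory.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
      outputs <- c(outputs, "annotated_tree.nwk", "annotated_tree.tsv",
                   "trajectory.tsv")
    }
    manifest$outputs <- outputs
    json <- manifest[c("package_version", "config", "config_hash", "seeds",
                       "outputs")]
    json$failures <- manifest$failures
    jsonlite::write_json(json, out("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, null = "null")
  }
  manifest
}

## md5 of the canonical YAML rendering of the configuration; the output
## destination does not change the analysis, so it is excluded
config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$out_dir <- NULL
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg, tmp)
  unname(tools::md5sum(tmp))
}
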