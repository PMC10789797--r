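#' Default generating parameters for simulated binding assays
#'
#' The standard assay design simulated throughout the package: an 11-point
#' temperature grid from 0 to 100 degrees Celsius at 10-degree intervals
#' with 3 independent replicates (33 datapoints), fluorescence generated
#' from the skewed peak model with a moderately asymmetric peak and
#' additive Gaussian noise at 2% of the peak intensity.
#'
#' @return A named list: `temperatures`, `n_replicates`, `true_params`
#'   (`F0`, `F_star`, `t_star`, `s_L`, `s_R`, `w`), `noise_sd`.
#' @export
default_sim_config <- function() {
  list(temperatures = seq(0, 100, by = 10),
       n_replicates = 3L,
       true_params = list(F0 = 100, F_star = 1000, t_star = 50,
                          s_L = 8, s_R = 12, w = 5),
       noise_sd = 20)
}

#' Simulate a replicate Mant-GDP binding profile
#'
#' Generates each datapoint as the skewed peak model evaluated at the grid
#' temperature plus additive Gaussian noise, truncated at zero
#' (fluorescence cannot be negative). The generating parameters are
#' returned alongside the profile so recovery can be checked.
#'
#' @param protein_id Label for the simulated protein.
#' @param temperatures Assay grid in degrees Celsius.
#' @param n_replicates Replicates per temperature.
#' @param true_params Generating parameters for [peak_fluorescence()].
#' @param noise_sd Additive noise standard deviation in arbitrary units;
#'   `noise_frac` may be given instead, as a fraction of `F_star`.
#' @param noise_frac Optional relative noise level (overrides `noise_sd`).
#' @param seed Integer seed; the same seed reproduces the profile exactly.
#' @return A list with `profile` (a [fluor_profile]) and `truth` (the
#'   generating parameters and noise level).
#' @examples
#' sim <- simulate_binding_profile(seed = 1)
#' sim$profile
#' @export
simulate_binding_profile <- function(protein_id = "sim",
                                     temperatures = seq(0, 100, by = 10),
                                     n_replicates = 3L,
                                     true_params = default_sim_config()$true_params,
                                     noise_sd = 20, noise_frac = NULL,
                                     seed = 1L) {
  if (!is.null(noise_frac)) noise_sd <- noise_frac * true_params$F_star
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  if (n_replicates < 1L) stop("'n_replicates' must be at least 1")
  set.seed(as.integer(seed))
  mu <- peak_fluorescence(temperatures, true_params)
  m <- matrix(rep(mu, each = n_replicates), nrow = n_replicates)
  if (noise_sd > 0)
    m <- pmax(m + stats::rnorm(length(m), 0, noise_sd), 0)
  list(profile = fluor_profile(protein_id, temperatures, m, "binding"),
       truth = c(true_params, list(noise_sd = noise_sd, seed = seed)))
}

#' Simulate a ThermoFluor melt profile
#'
#' Produces a unimodal melt curve whose replicate-mean maximum falls on
#' the grid point nearest `melt_t`: a logistic rise of dye fluorescence as
#' the protein unfolds, followed by a linear decay past the transition
#' (signal loss from aggregation). Only the argmax is consumed downstream,
#' so the exact flank shapes are cosmetic.
#'
#' @param protein_id Label.
#' @param melt_t Unfolding transition temperature in degrees Celsius, on
#'   or near the grid.
#' @param temperatures Assay grid.
#' @param n_replicates Replicates per temperature.
#' @param base,amplitude Baseline and rise of the melt curve (a.u.).
#' @param noise_sd Additive Gaussian noise (a.u.).
#' @param seed Integer seed.
#' @return A [fluor_profile] with `assay_kind = "stability"`.
#' @examples
#' stable_range(simulate_thermofluor(melt_t = 70, seed = 1))
#' @export
simulate_thermofluor <- function(protein_id = "sim", melt_t = 70,
                                 temperatures = seq(0, 100, by = 10),
                                 n_replicates = 3L, base = 200,
                                 amplitude = 800, noise_sd = 0, seed = 1L) {
  grid_peak <- temperatures[which.min(abs(temperatures - melt_t))]
  rise <- 1 / (1 + exp(-(temperatures - (grid_peak - 10)) / 4))
  decay <- ifelse(temperatures > grid_peak,
                  1 - 0.04 * (temperatures - grid_peak), 1)
  mu <- base + amplitude * rise * pmax(decay, 0.05)
  ## guarantee the mean argmax sits exactly on the intended grid point
  mu[temperatures == grid_peak] <- base + amplitude * 1.05
  set.seed(as.integer(seed))
  m <- matrix(rep(mu, each = n_replicates), nrow = n_replicates)
  if (noise_sd > 0) m <- pmax(m + stats::rnorm(length(m), 0, noise_sd), 0)
  fluor_profile(protein_id, temperatures, m, "stability")
}

#' Simulate a set of ancestral reconstructions around a known truth
#'
#' Emulates running several ASR engines on the same node: each method's
#' sequence differs from the planted truth at independently chosen sites
#' at that method's error rate (substitutions drawn uniformly from the
#' other 19 residues), and per-site posterior probabilities are drawn from
#' Beta distributions that sit near 1 at correct sites and lower at
#' erroneous ones.
#'
#' @param true_seq Planted amino-acid truth (no gaps needed).
#' @param per_method_error Numeric vector of per-method substitution error
#'   rates in `[0, 0.5)`; its length sets the number of methods.
#' @param pp_model List with Beta shape pairs `correct` and `wrong`
#'   (defaults Beta(20, 2) and Beta(4, 4)).
#' @param method_ids Optional method labels.
#' @param seed Integer seed.
#' @return A list with `recs` (list of [ancestral_reconstruction()]),
#'   `truth` (the input sequence) and `error_sites` (list of substituted
#'   positions per method).
#' @export
simulate_asr_set <- function(true_seq,
                             per_method_error = c(0.05, 0.08, 0.10),
                             pp_model = list(correct = c(20, 2),
                                             wrong = c(4, 4)),
                             method_ids = NULL, seed = 1L) {
  if (any(per_method_error < 0 | per_method_error >= 0.5))
    stop("error rates must lie in [0, 0.5)")
  true_chars <- strsplit(toupper(true_seq), "")[[1]]
  bad <- setdiff(unique(true_chars), AA_ALPHABET)
  if (length(bad)) stop("invalid residue(s) in truth: ", paste(bad, collapse = ", "))
  n <- length(true_chars)
  k <- length(per_method_error)
  if (is.null(method_ids)) method_ids <- paste0("method", seq_len(k))
  residues <- setdiff(AA_ALPHABET, "-")
  set.seed(as.integer(seed))
  recs <- vector("list", k)
  err_sites <- vector("list", k)
  for (m in seq_len(k)) {
    chars <- true_chars
    hit <- which(stats::runif(n) < per_method_error[m] & true_chars != "-")
    for (i in hit)
      chars[i] <- sample(setdiff(residues, true_chars[i]), 1L)
    pp <- rep(NA_real_, n)
    correct <- chars == true_chars & chars != "-"
    wrong <- chars != true_chars & chars != "-"
    pp[correct] <- stats::rbeta(sum(correct), pp_model$correct[1L],
                                pp_model$correct[2L])
    pp[wrong] <- stats::rbeta(sum(wrong), pp_model$wrong[1L],
                              pp_model$wrong[2L])
    recs[[m]] <- ancestral_reconstruction(method_ids[m],
                                          paste(chars, collapse = ""), pp)
    err_sites[[m]] <- hit
  }
  list(recs = recs, truth = toupper(true_seq), error_sites = err_sites)
}

#' Simulate OGT evolution on a random tree with per-node assay data
#'
#' End-to-end fixture for the whole pipeline: draws a random rooted
#' topology, evolves the OGT from the root value by independent Gaussian
#' steps on each branch (a Brownian-style walk used purely as a test
#' harness), and attaches to every node a simulated binding profile whose
#' generating peak temperature equals that node's OGT.
#'
#' @param n_leaves Number of tips (at least 2).
#' @param root_ogt Root OGT in degrees Celsius.
#' @param step_sd Standard deviation of the per-branch OGT step (degrees
#'   Celsius); 0 keeps every node at `root_ogt`.
#' @param noise_frac Relative assay noise for the per-node profiles.
#' @param seed Integer seed.
#' @return A list with `tree` (a labelled rooted `phylo`), `ogt` (named
#'   vector of true node OGTs), `profiles` (named list of binding
#'   [fluor_profile]s) and `seed`.
#' @export
simulate_trait_tree <- function(n_leaves = 6L, root_ogt = 65.5,
                                step_sd = 3, noise_frac = 0.02, seed = 1L) {
  if (n_leaves < 2L) stop("'n_leaves' must be at least 2")
  if (step_sd < 0) stop("'step_sd' must be non-negative")
  set.seed(as.integer(seed))
  tr <- ape::rtree(n_leaves, rooted = TRUE)
  tr$tip.label <- paste0("T", seq_len(n_leaves))
  tr$node.label <- paste0("N", seq_len(tr$Nnode))
  n_nodes <- n_leaves + tr$Nnode
  root <- n_leaves + 1L
  ogt_num <- rep(NA_real_, n_nodes)
  ogt_num[root] <- root_ogt
  ## edges in ape preorder: parents are assigned before their children
  ord <- ape::reorder.phylo(tr, "cladewise")$edge
  for (e in seq_len(nrow(ord))) {
    par <- ord[e, 1L]; child <- ord[e, 2L]
    ogt_num[child] <- ogt_num[par] + stats::rnorm(1L, 0, step_sd)
  }
  labels <- c(tr$tip.label, tr$node.label)
  ogt <- stats::setNames(ogt_num, labels)
  ## per-node sub-seeds drawn up front from the root seed
  prof_seeds <- sample.int(.Machine$integer.max - 1L, n_nodes)
  profiles <- list()
  for (i in seq_len(n_nodes)) {
    p <- default_sim_config()$true_params
    p$t_star <- ogt_num[i]
    profiles[[labels[i]]] <- simulate_binding_profile(
      protein_id = labels[i], true_params = p, noise_frac = noise_frac,
      seed = prof_seeds[i])$profile
  }
  list(tree = tr, ogt = ogt, profiles = profiles, seed = as.integer(seed))
}
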