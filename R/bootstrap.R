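#' Resample a profile's replicates with replacement
#'
#' Case-resampling within temperature: at each temperature independently,
#' the replicate values are redrawn with replacement from that
#' temperature's observed replicates (for the standard design, three out of
#' three values sampled with return). Temperatures are unchanged.
#'
#' @param profile A [fluor_profile].
#' @return A [fluor_profile] of identical shape with resampled replicates.
#'   Uses the current RNG state; seed upstream for reproducibility.
#' @export
resample_profile <- function(profile) {
  stopifnot(inherits(profile, "fluor_profile"))
  nrep <- nrow(profile$fluorescence)
  m <- profile$fluorescence
  for (j in seq_len(ncol(m)))
    m[, j] <- m[sample.int(nrep, nrep, replace = TRUE), j]
  fluor_profile(profile$protein_id, profile$temperatures, m,
                profile$assay_kind)
}

#' Order-statistic percentile with linear interpolation
#'
#' The "type 7" convention: the p-th percentile of a sorted sample of size n
#' sits at index `1 + p*(n - 1)`, with linear interpolation between
#' adjacent order statistics. `p = 0` gives the minimum, `p = 1` the
#' maximum.
#'
#' @param values Non-empty numeric vector.
#' @param p Fraction(s) in `[0, 1]`.
#' @return Numeric vector of percentiles, one per `p`.
#' @export
percentile <- function(values, p) {
  if (length(values) == 0L) stop("'values' must be non-empty")
  if (any(p < 0 | p > 1)) stop("'p' must be in [0, 1]")
  unname(stats::quantile(values, probs = p, type = 7, names = FALSE))
}

#' Bootstrap percentile confidence interval for the peak temperature
#'
#' Builds `n_boot` bootstrap datasets by resampling replicates within each
#' temperature ([resample_profile()]), refits the skewed peak model to each
#' ([fit_peak()]), and forms the percentile confidence interval of the peak
#' temperature from the bootstrap distribution: for the default 90% level,
#' the 5th and 95th percentiles. The point estimate is always the fit to
#' the original, un-resampled data, never a bootstrap summary.
#'
#' All resampling indices are drawn up front from `seed`, so the result is
#' reproducible and independent of the order in which refits run. Bootstrap
#' refits start from the full-data solution (single start); refits that do
#' not converge, or whose peak is not identifiable, are dropped and counted
#' in `n_failed`. More than 10% failures aborts with an error naming the
#' count.
#'
#' @param profile A [fluor_profile] meeting the [fit_peak()] preconditions.
#' @param n_boot Number of bootstrap datasets (default 1000).
#' @param level Confidence level in (0, 1) (default 0.90).
#' @param seed Integer seed for the resampling stream.
#' @param fit_range,w,control Passed to [fit_peak()].
#' @return An object of class `peak_boot`: list with `protein_id`,
#'   `point_estimate`, `samples` (successful bootstrap `t_star` values),
#'   `ci_lower`, `ci_upper`, `level`, `n_boot`, `n_failed`, `seed`, and the
#'   full-data `fit`.
#' @examples
#' prof <- simulate_binding_profile(noise_sd = 20, seed = 3)$profile
#' bootstrap_peak_ci(prof, n_boot = 50, seed = 7)
#' @export
bootstrap_peak_ci <- function(profile, n_boot = 1000L, level = 0.90,
                              seed = 1L, fit_range = NULL, w = 5,
                              control = list()) {
  stopifnot(inherits(profile, "fluor_profile"))
  if (!(level > 0 && level < 1)) stop("'level' must be in (0, 1)")
  if (n_boot < 1L) stop("'n_boot' must be positive")

  full <- fit_peak(profile, fit_range = fit_range, w = w, control = control)
  if (!full$identifiable)
    stop("full-data fit is not identifiable; no peak to bootstrap")
  prof <- full$profile  # already restricted to fit_range
  nrep <- nrow(prof$fluorescence)
  ntemp <- ncol(prof$fluorescence)

  ## one root seed; all index draws happen before any refit
  set.seed(as.integer(seed))
  idx <- array(sample.int(nrep, n_boot * ntemp * nrep, replace = TRUE),
               dim = c(n_boot, ntemp, nrep))

  samples <- numeric(0)
  n_failed <- 0L
  init <- full$params
  for (b in seq_len(n_boot)) {
    m <- prof$fluorescence
    for (j in seq_len(ntemp)) m[, j] <- prof$fluorescence[idx[b, j, ], j]
    bp <- fluor_profile(prof$protein_id, prof$temperatures, m, prof$assay_kind)
    fb <- tryCatch(
      fit_peak(bp, init = init, w = w, n_starts = 1L, control = control),
      error = function(e) NULL)
    if (is.null(fb) || !fb$converged || !fb$identifiable) {
      n_failed <- n_failed + 1L
    } else {
      samples <- c(samples, fb$params$t_star)
    }
  }
  if (n_failed > 0.10 * n_boot)
    stop("bootstrap quality failure: ", n_failed, " of ", n_boot,
         " bootstrap fits failed (>10%)")
  alpha <- (1 - level) / 2
  ci <- percentile(samples, c(alpha, 1 - alpha))
  structure(
    list(protein_id = prof$protein_id,
         point_estimate = full$params$t_star,
         samples = samples,
         ci_lower = ci[1L], ci_upper = ci[2L],
         level = level, n_boot = as.integer(n_boot), n_failed = n_failed,
         seed = as.integer(seed), fit = full),
    class = "peak_boot")
}

#' @export
print.peak_boot <- function(x, digits = 3, ...) {
  cat(sprintf("Bootstrap peak temperature for '%s'\n", x$protein_id))
  cat(sprintf("  t* = %.*f degC, %d%% CI: %.*f-%.*f degC\n",
              digits, x$point_estimate, round(100 * x$level),
              digits, x$ci_lower, digits, x$ci_upper))
  cat(sprintf("  %d bootstrap datasets (%d failed fits dropped), seed %d\n",
              x$n_boot, x$n_failed, x$seed))
  invisible(x)
}

#' Write bootstrap results as a TSV table
#'
#' One row per protein with columns `protein_id`, `t_star`, `ci_lower`,
#' `ci_upper`, `level`, `n_boot`, `n_failed`, `seed`.
#'
#' @param boots A `peak_boot` or list of them.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_bootstrap_tsv <- function(boots, file) {
  if (inherits(boots, "peak_boot")) boots <- list(boots)
  d <- do.call(rbind, lapply(boots, function(b)
    data.frame(protein_id = b$protein_id, t_star = b$point_estimate,
               ci_lower = b$ci_lower, ci_upper = b$ci_upper,
               level = b$level, n_boot = b$n_boot, n_failed = b$n_failed,
               seed = b$seed)))
  utils::write.table(d, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}
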