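#' Unfolding transition temperature from a ThermoFluor melt profile
#'
#' In a dye-based thermal-shift assay the fluorescence rises as the protein
#' unfolds and exposes hydrophobic surface; the grid temperature with the
#' highest replicate-mean intensity marks the transition from partial to
#' complete unfolding. Ties at the maximum resolve to the lowest tied
#' temperature (the conservative choice for the downstream stable range).
#'
#' @param profile A [fluor_profile] with `assay_kind = "stability"` and at
#'   least 3 temperatures.
#' @return The transition temperature in degrees Celsius.
#' @export
melting_transition <- function(profile) {
  stopifnot(inherits(profile, "fluor_profile"))
  if (profile$assay_kind != "stability")
    stop("melting_transition() expects a stability (ThermoFluor) profile")
  if (length(profile$temperatures) < 3L)
    stop("at least 3 temperatures are required")
  m <- profile_means(profile)
  if (diff(range(m)) == 0)
    stop("flat melt profile: no transition detectable")
  profile$temperatures[which.max(m)]  # which.max takes the first (lowest) tie
}

#' Stable temperature range from a melt profile
#'
#' The protein is considered stable from the lowest assayed temperature up
#' to the last grid point before the unfolding transition
#' ([melting_transition()]): `stable_max = t_transition - grid_step`, where
#' the grid step is the minimal spacing between consecutive assayed
#' temperatures. The upper bound is therefore resolved only to the grid
#' step and is an approximate upper limit, not a melting midpoint.
#'
#' @param profile A stability [fluor_profile].
#' @return An object of class `stability_result`: list with `protein_id`,
#'   `t_transition`, `stable_min`, `stable_max`, `grid_step` (all degrees
#'   Celsius).
#' @examples
#' prof <- simulate_thermofluor(melt_t = 70, seed = 1)
#' stable_range(prof)  # stable 0-60 degC
#' @export
stable_range <- function(profile) {
  t_trans <- melting_transition(profile)
  temps <- profile$temperatures
  grid_step <- min(diff(temps))
  if (t_trans <= temps[1L])
    stop("transition at the lowest assayed temperature: no stable range")
  structure(
    list(protein_id = profile$protein_id,
         t_transition = t_trans,
         stable_min = temps[1L],
         stable_max = t_trans - grid_step,
         grid_step = grid_step),
    class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("Thermal stability of '%s': stable %g-%g degC (transition at %g degC, grid step %g)\n",
              x$protein_id, x$stable_min, x$stable_max, x$t_transition,
              x$grid_step))
  invisible(x)
}

#' Restrict a binding profile to the stable temperature range
#'
#' Filters a binding profile to temperatures inside
#' `[stable_min, stable_max]` so the peak fit only uses measurements taken
#' where the protein is folded. Order is preserved; no datapoint is
#' duplicated.
#'
#' @param binding A [fluor_profile] with `assay_kind = "binding"`.
#' @param stability A `stability_result` from [stable_range()].
#' @return The filtered [fluor_profile].
#' @export
restrict_to_stable <- function(binding, stability) {
  stopifnot(inherits(binding, "fluor_profile"),
            inherits(stability, "stability_result"))
  if (binding$assay_kind != "binding")
    stop("restrict_to_stable() expects a binding profile")
  keep <- binding$temperatures >= stability$stable_min &
    binding$temperatures <= stability$stable_max
  if (sum(keep) < 3L)
    stop("fewer than 3 temperatures survive the stable-range restriction; ",
         "peak fit infeasible")
  fluor_profile(binding$protein_id,
                binding$temperatures[keep],
                binding$fluorescence[, keep, drop = FALSE],
                "binding")
}

#' Write stability results as a TSV table
#'
#' @param results A `stability_result` or list of them.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_stability_tsv <- function(results, file) {
  if (inherits(results, "stability_result")) results <- list(results)
  d <- do.call(rbind, lapply(results, function(s)
    data.frame(protein_id = s$protein_id, t_transition = s$t_transition,
               stable_min = s$stable_min, stable_max = s$stable_max)))
  utils::write.table(d, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}
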