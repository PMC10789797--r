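#' Calibration organisms with known growth optima
#'
#' The calibration table pairing organisms of known optimal growth
#' temperature (OGT) with their measured optimal GDP-binding temperature.
#' Two versions ship because the source publication prints two slightly
#' different sets of binding optima for the same four organisms (MK-D1,
#' baker's yeast, human, E. coli): the set quoted with the correlation
#' methodology (`"methods"`) and the set quoted with the assay results
#' (`"results"`). The discrepancy is documented, not resolved; see the
#' package vignette.
#'
#' @param which `"methods"` (default) or `"results"`.
#' @return A data frame with columns `organism`, `ogt_C`,
#'   `binding_optimum_C`.
#' @export
calibration_table <- function(which = c("methods", "results")) {
  which <- match.arg(which)
  if (which == "methods") {
    data.frame(
      organism = c("MK-D1", "S. cerevisiae", "H. sapiens", "E. coli"),
      ogt_C = c(20, 28, 37, 37),
      binding_optimum_C = c(19.9, 32.2, 33.5, 43.4))
  } else {
    data.frame(
      organism = c("MK-D1", "S. cerevisiae", "H. sapiens", "E. coli"),
      ogt_C = c(20, 28, 37, 37),
      binding_optimum_C = c(20.5, 34.6, 40.1, 40.2))
  }
}

#' Pearson correlation between known OGT and binding optimum
#'
#' Product-moment correlation of the calibration pairs (OGT as the
#' independent variable, binding optimum as the dependent one).
#'
#' @param points A data frame with numeric columns `ogt_C` and
#'   `binding_optimum_C` (e.g. from [calibration_table()] or
#'   [read_calibration()]), at least 3 rows, both columns non-constant and
#'   within plausible assay range (-5 to 120 degrees Celsius).
#' @return An object of class `calibration_cor`: list with `r` and `n`.
#' @examples
#' pearson_r(calibration_table("methods"))
#' @export
pearson_r <- function(points) {
  if (!all(c("ogt_C", "binding_optimum_C") %in% names(points)))
    stop("'points' needs columns 'ogt_C' and 'binding_optimum_C'")
  x <- points$ogt_C
  y <- points$binding_optimum_C
  if (length(x) < 3L) stop("at least 3 calibration points are required")
  if (anyNA(x) || anyNA(y) || any(!is.finite(c(x, y))))
    stop("calibration temperatures must be finite")
  if (any(c(x, y) < -5 | c(x, y) > 120))
    stop("calibration temperatures outside the plausible range [-5, 120] degC")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance in a coordinate: correlation undefined")
  structure(list(r = stats::cor(x, y), n = length(x)),
            class = "calibration_cor")
}

#' @export
print.calibration_cor <- function(x, digits = 4, ...) {
  cat(sprintf("Pearson correlation OGT vs binding optimum: r = %.*f (n = %d)\n",
              digits, x$r, x$n))
  invisible(x)
}

#' Read a calibration table from TSV
#'
#' Expects columns `organism`, `ogt_C`, `binding_optimum_C`.
#'
#' @param file Path to a tab-separated file with header.
#' @return A data frame suitable for [pearson_r()].
#' @export
read_calibration <- function(file) {
  d <- utils::read.table(file, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("organism", "ogt_C", "binding_optimum_C")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  d
}

#' Classify thermal lifestyle from an OGT
#'
#' Step classification of growth-temperature optimum into mesophile
#' (below `thresholds[1]`), moderate thermophile (between the thresholds),
#' and hyperthermophile (at or above `thresholds[2]`). Default cut points
#' 45 and 80 degrees Celsius.
#'
#' @param ogt Numeric vector of optimal growth temperatures (degrees
#'   Celsius), finite.
#' @param thresholds Increasing numeric length-2 vector of class
#'   boundaries.
#' @return Character vector in `{"mesophile", "moderate_thermophile",
#'   "hyperthermophile"}`.
#' @examples
#' classify_lifestyle(c(33.8, 64, 84.9))
#' @export
classify_lifestyle <- function(ogt, thresholds = c(45, 80)) {
  if (anyNA(ogt) || any(!is.finite(ogt))) stop("'ogt' must be finite")
  if (length(thresholds) != 2L || thresholds[1L] >= thresholds[2L])
    stop("'thresholds' must be two increasing temperatures")
  out <- ifelse(ogt < thresholds[1L], "mesophile",
                ifelse(ogt < thresholds[2L], "moderate_thermophile",
                       "hyperthermophile"))
  out
}

#' Convert a bootstrap binding optimum into an OGT estimate
#'
#' By default the optimal GDP-binding temperature is taken directly as a
#' proxy for the organism's OGT (no regression adjustment); the bootstrap
#' confidence interval is carried through unchanged and a thermal
#' lifestyle is attached via [classify_lifestyle()]. An optional linear
#' calibration maps the binding optimum through a least-squares line
#' fitted to a calibration table (OGT regressed on binding optimum); it is
#' off by default.
#'
#' @param label Name of the protein or tree node.
#' @param peak A `peak_boot` from [bootstrap_peak_ci()], or a list with
#'   `point_estimate`, `ci_lower`, `ci_upper`.
#' @param thresholds Lifestyle thresholds, see [classify_lifestyle()].
#' @param calibration Optional calibration data frame (columns `ogt_C`,
#'   `binding_optimum_C`); when supplied, the estimate and its CI are
#'   mapped through the fitted calibration line.
#' @return An object of class `ogt_estimate`: list with `label`, `ogt`,
#'   `ci_lower`, `ci_upper`, `lifestyle`.
#' @examples
#' est <- infer_ogt("AncEF-1A", list(point_estimate = 52.9,
#'                                   ci_lower = 51.2, ci_upper = 55.6))
#' est
#' @export
infer_ogt <- function(label, peak, thresholds = c(45, 80),
                      calibration = NULL) {
  ogt <- peak$point_estimate
  lo <- peak$ci_lower
  hi <- peak$ci_upper
  if (!is.null(calibration)) {
    fit <- stats::lm(ogt_C ~ binding_optimum_C, data = calibration)
    tr <- function(v) unname(stats::predict(fit,
      newdata = data.frame(binding_optimum_C = v)))
    ogt <- tr(ogt); lo <- tr(lo); hi <- tr(hi)
  }
  structure(
    list(label = label, ogt = ogt, ci_lower = lo, ci_upper = hi,
         lifestyle = classify_lifestyle(ogt, thresholds)),
    class = "ogt_estimate")
}

#' @export
print.ogt_estimate <- function(x, digits = 3, ...) {
  cat(sprintf("OGT estimate for '%s': %.*g degC (CI %.*g-%.*g), %s\n",
              x$label, digits, x$ogt, digits, x$ci_lower, digits,
              x$ci_upper, x$lifestyle))
  invisible(x)
}

ogt_estimates_df <- function(estimates) {
  if (inherits(estimates, "ogt_estimate")) estimates <- list(estimates)
  do.call(rbind, lapply(estimates, function(e)
    data.frame(label = e$label, ogt = e$ogt, ci_lower = e$ci_lower,
               ci_upper = e$ci_upper, lifestyle = e$lifestyle)))
}

#' Write OGT estimates as a TSV table
#'
#' Columns `label`, `ogt`, `ci_lower`, `ci_upper`, `lifestyle`.
#'
#' @param estimates An `ogt_estimate` or list of them.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_ogt_tsv <- function(estimates, file) {
  utils::write.table(ogt_estimates_df(estimates), file, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}
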