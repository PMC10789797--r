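#' Replicate fluorescence-temperature profile
#'
#' Container for one protein's fluorescence measurements across an ordered
#' temperature grid, either from a Mant-GDP binding assay (`assay_kind =
#' "binding"`) or a ThermoFluor thermal-shift assay (`assay_kind =
#' "stability"`). Replicates are rows, temperatures columns.
#'
#' @param protein_id Character label for the protein.
#' @param temperatures Numeric vector of assay temperatures in degrees
#'   Celsius, strictly increasing, at least two.
#' @param fluorescence Numeric matrix of intensities (arbitrary units),
#'   `n_replicates` rows by `length(temperatures)` columns. A vector is
#'   accepted for a single replicate.
#' @param assay_kind `"binding"` or `"stability"`.
#'
#' @return An object of class `fluor_profile`: a list with the validated
#'   fields above.
#' @examples
#' temps <- seq(0, 100, by = 10)
#' f <- matrix(rep(100 + 400 * exp(-((temps - 50) / 12)^2), each = 3) , nrow = 3)
#' p <- fluor_profile("demo", temps, f)
#' p
#' @export
fluor_profile <- function(protein_id, temperatures, fluorescence,
                          assay_kind = c("binding", "stability")) {
  assay_kind <- match.arg(assay_kind)
  if (!is.character(protein_id) || length(protein_id) != 1L || is.na(protein_id))
    stop("'protein_id' must be a single string")
  temperatures <- as.numeric(temperatures)
  if (length(temperatures) < 2L)
    stop("at least 2 temperatures are required")
  if (anyNA(temperatures) || any(!is.finite(temperatures)))
    stop("temperatures must be finite")
  if (any(diff(temperatures) <= 0))
    stop("temperatures must be strictly increasing")
  if (is.vector(fluorescence) && !is.matrix(fluorescence))
    fluorescence <- matrix(fluorescence, nrow = 1L)
  fluorescence <- as.matrix(fluorescence)
  storage.mode(fluorescence) <- "double"
  if (ncol(fluorescence) != length(temperatures))
    stop("fluorescence must have one column per temperature (got ",
         ncol(fluorescence), " columns for ", length(temperatures),
         " temperatures)")
  if (nrow(fluorescence) < 1L)
    stop("at least 1 replicate is required")
  if (anyNA(fluorescence) || any(!is.finite(fluorescence)))
    stop("all fluorescence intensities must be finite")
  if (any(fluorescence < 0))
    stop("fluorescence intensities must be non-negative")
  structure(
    list(protein_id = protein_id,
         temperatures = temperatures,
         fluorescence = fluorescence,
         assay_kind = assay_kind),
    class = "fluor_profile")
}

#' @export
print.fluor_profile <- function(x, ...) {
  cat(sprintf("Fluorescence profile '%s' (%s assay)\n", x$protein_id, x$assay_kind))
  cat(sprintf("  %d temperatures: %g..%g degC, %d replicate(s), %d datapoints\n",
              length(x$temperatures), min(x$temperatures), max(x$temperatures),
              nrow(x$fluorescence), length(x$fluorescence)))
  invisible(x)
}

n_datapoints <- function(profile) length(profile$fluorescence)

#' Replicate-mean fluorescence per temperature
#'
#' @param profile A [fluor_profile].
#' @return Numeric vector of column means, one per temperature.
#' @export
profile_means <- function(profile) {
  stopifnot(inherits(profile, "fluor_profile"))
  colMeans(profile$fluorescence)
}

#' Pooled within-temperature replicate standard deviation
#'
#' Square root of the mean per-temperature replicate variance. Zero when
#' there is a single replicate.
#'
#' @param profile A [fluor_profile].
#' @return A single non-negative number (arbitrary units).
#' @export
pooled_replicate_sd <- function(profile) {
  stopifnot(inherits(profile, "fluor_profile"))
  if (nrow(profile$fluorescence) < 2L) return(0)
  sqrt(mean(apply(profile$fluorescence, 2L, stats::var)))
}

#' Read fluorescence profiles from a delimited file
#'
#' Expects a header and columns `protein_id`, `temperature_C`, `replicate`,
#' `fluorescence`, plus an optional `assay_kind` column (defaulting to the
#' `assay_kind` argument). The field separator is inferred from the file
#' extension (`.csv` = comma, otherwise tab).
#'
#' @param file Path to a CSV/TSV file.
#' @param assay_kind Assay kind used when the file carries no
#'   `assay_kind` column.
#' @return A named list of [fluor_profile] objects, one per protein.
#' @export
read_profiles <- function(file, assay_kind = c("binding", "stability")) {
  assay_kind <- match.arg(assay_kind)
  sep <- if (grepl("\\.csv$", file, ignore.case = TRUE)) "," else "\t"
  d <- utils::read.table(file, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  need <- c("protein_id", "temperature_C", "replicate", "fluorescence")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  out <- lapply(split(d, d$protein_id), function(dp) {
    kind <- if ("assay_kind" %in% names(dp)) unique(dp$assay_kind)[1L] else assay_kind
    temps <- sort(unique(dp$temperature_C))
    reps <- sort(unique(dp$replicate))
    m <- matrix(NA_real_, nrow = length(reps), ncol = length(temps))
    for (i in seq_len(nrow(dp))) {
      m[match(dp$replicate[i], reps), match(dp$temperature_C[i], temps)] <-
        dp$fluorescence[i]
    }
    if (anyNA(m))
      stop("incomplete replicate x temperature grid for protein '",
           dp$protein_id[1L], "'")
    fluor_profile(dp$protein_id[1L], temps, m, kind)
  })
  out
}

#' Write fluorescence profiles to a delimited file
#'
#' Long format with columns `protein_id`, `temperature_C`, `replicate`,
#' `fluorescence`, `assay_kind`, readable by [read_profiles()].
#'
#' @param profiles A [fluor_profile] or list of them.
#' @param file Output path; `.csv` writes comma-separated, anything else tab.
#' @return `file`, invisibly.
#' @export
write_profiles <- function(profiles, file) {
  if (inherits(profiles, "fluor_profile")) profiles <- list(profiles)
  rows <- do.call(rbind, lapply(profiles, function(p) {
    nrep <- nrow(p$fluorescence)
    data.frame(protein_id = p$protein_id,
               temperature_C = rep(p$temperatures, each = nrep),
               replicate = rep(seq_len(nrep), times = length(p$temperatures)),
               fluorescence = as.vector(p$fluorescence),
               assay_kind = p$assay_kind)
  }))
  sep <- if (grepl("\\.csv$", file, ignore.case = TRUE)) "," else "\t"
  utils::write.table(rows, file, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(file)
}
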