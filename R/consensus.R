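AA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "-")

#' One method's ancestral sequence reconstruction
#'
#' An aligned ancestral amino-acid sequence, as produced by one
#' reconstruction engine (e.g. an empirical-Bayes, marginal or joint ASR
#' run), together with the per-column posterior probability of the
#' reconstructed state. Gap columns carry no posterior probability
#' (`NA`).
#'
#' @param method_id Label for the reconstruction method.
#' @param sequence Aligned amino-acid string over the 20-letter alphabet
#'   plus gap `-`.
#' @param site_pp Numeric vector of per-column posterior probabilities in
#'   `[0, 1]`, same length as the sequence; `NA` allowed (and expected) at
#'   gap columns.
#' @return An object of class `asr_reconstruction`.
#' @export
ancestral_reconstruction <- function(method_id, sequence, site_pp) {
  stopifnot(is.character(method_id), length(method_id) == 1L)
  sequence <- toupper(as.character(sequence))
  chars <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad))
    stop("invalid residue character(s): ", paste(bad, collapse = ", "))
  site_pp <- as.numeric(site_pp)
  if (length(site_pp) != length(chars))
    stop("length(site_pp) must equal the aligned sequence length (",
         length(site_pp), " vs ", length(chars), ")")
  ok <- is.na(site_pp) | (site_pp >= 0 & site_pp <= 1)
  if (!all(ok)) stop("posterior probabilities must lie in [0, 1]")
  structure(list(method_id = method_id, sequence = sequence,
                 chars = chars, site_pp = site_pp),
            class = "asr_reconstruction")
}

#' @export
print.asr_reconstruction <- function(x, ...) {
  cat(sprintf("Ancestral reconstruction '%s': %d aligned columns, mean PP %.3f\n",
              x$method_id, length(x$chars), mean(x$site_pp, na.rm = TRUE)))
  invisible(x)
}

#' Consensus of multiple ancestral reconstructions
#'
#' Combines two or more aligned ancestral reconstructions into a single
#' consensus sequence, automating the curation of columns where the
#' methods disagree. Per column:
#' \enumerate{
#'   \item if all methods agree, that state is kept;
#'   \item otherwise the majority state wins (gap counts as a votable
#'     state);
#'   \item vote ties are broken by the highest posterior probability among
#'     the tied states (a state's PP at a column is the maximum over the
#'     methods carrying it there; gaps carry no PP and so lose PP
#'     tie-breaks to any residue);
#'   \item remaining ties fall back to lexicographic residue order.
#' }
#' When a `reference` (neighbouring sequence in the alignment) is
#' supplied, disagreeing columns prefer the reference state whenever it is
#' among the observed states there, before the vote.
#'
#' The consensus PP of a column is the maximum PP among the methods
#' carrying the chosen state. Columns where the consensus is a gap carry
#' no PP and are removed from the unaligned export.
#'
#' @param recs List of at least two [ancestral_reconstruction()] objects
#'   of equal aligned length (align them first; alignment itself is out of
#'   scope here).
#' @param reference Optional aligned reference sequence (string of the
#'   same length) used to resolve disagreements.
#' @return An object of class `asr_consensus`: list with `sequence`
#'   (aligned consensus string), `unaligned` (gaps removed), `site_pp`
#'   (per aligned column; `NA` at gap columns), `mean_pp` (mean over
#'   non-gap consensus columns), `disagreement_sites` (1-based aligned
#'   column indices where the inputs are not unanimous), `n_methods`.
#' @examples
#' r1 <- ancestral_reconstruction("m1", "MKAL", c(0.99, 0.9, 0.8, 0.95))
#' r2 <- ancestral_reconstruction("m2", "MKSL", c(0.98, 0.9, 0.7, 0.90))
#' r3 <- ancestral_reconstruction("m3", "MKAL", c(0.97, 0.8, 0.9, 0.99))
#' consensus_sequence(list(r1, r2, r3))
#' @export
consensus_sequence <- function(recs, reference = NULL) {
  if (length(recs) < 2L)
    stop("at least 2 reconstructions are required")
  stopifnot(all(vapply(recs, inherits, logical(1), "asr_reconstruction")))
  len <- unique(vapply(recs, function(r) length(r$chars), integer(1)))
  if (length(len) != 1L)
    stop("reconstructions have unequal aligned lengths (",
         paste(len, collapse = ", "), "); align them before building a consensus")
  ref_chars <- NULL
  if (!is.null(reference)) {
    ref_chars <- strsplit(toupper(as.character(reference)), "")[[1]]
    if (length(ref_chars) != len)
      stop("reference length must match the aligned length")
  }
  states <- vapply(recs, function(r) r$chars, character(len))
  pps <- vapply(recs, function(r) r$site_pp, numeric(len))
  if (len == 1L) { states <- matrix(states, nrow = 1L); pps <- matrix(pps, nrow = 1L) }

  cons <- character(len)
  cons_pp <- rep(NA_real_, len)
  disagree <- logical(len)
  for (i in seq_len(len)) {
    st <- states[i, ]
    pp <- pps[i, ]
    uniq <- unique(st)
    if (length(uniq) == 1L) {
      chosen <- uniq
    } else {
      disagree[i] <- TRUE
      if (!is.null(ref_chars) && ref_chars[i] %in% uniq) {
        chosen <- ref_chars[i]
      } else {
        votes <- table(st)
        top <- names(votes)[votes == max(votes)]
        if (length(top) > 1L) {
          ## PP tie-break: a state's PP is the max over carriers; gaps have none
          state_pp <- vapply(top, function(s) {
            v <- pp[st == s & s != "-"]
            if (!length(v) || all(is.na(v))) -1 else max(v, na.rm = TRUE)
          }, numeric(1))
          top <- top[state_pp == max(state_pp)]
        }
        chosen <- sort(top)[1L]  # lexicographic fallback
      }
    }
    cons[i] <- chosen
    if (chosen != "-") {
      v <- pps[i, states[i, ] == chosen]
      cons_pp[i] <- if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
    }
  }
  nongap <- cons != "-"
  if (!any(nongap)) stop("all-gap consensus")
  structure(
    list(sequence = paste(cons, collapse = ""),
         unaligned = paste(cons[nongap], collapse = ""),
         site_pp = cons_pp,
         mean_pp = mean(cons_pp[nongap], na.rm = TRUE),
         disagreement_sites = which(disagree),
         n_methods = length(recs),
         method_ids = vapply(recs, `[[`, character(1), "method_id")),
    class = "asr_consensus")
}

#' @export
print.asr_consensus <- function(x, ...) {
  cat(sprintf("Consensus of %d reconstructions (%s)\n", x$n_methods,
              paste(x$method_ids, collapse = ", ")))
  cat(sprintf("  %d aligned columns, %d disagreement site(s), mean PP %.4f\n",
              nchar(x$sequence), length(x$disagreement_sites), x$mean_pp))
  invisible(x)
}

#' Mean posterior probability of a consensus
#'
#' Arithmetic mean of the per-column consensus posterior probabilities over
#' the non-gap consensus columns.
#'
#' @param result An `asr_consensus` from [consensus_sequence()].
#' @return A fraction in `[0, 1]`.
#' @export
mean_posterior <- function(result) {
  stopifnot(inherits(result, "asr_consensus"))
  nongap <- strsplit(result$sequence, "")[[1]] != "-"
  if (!any(nongap)) stop("all-gap consensus")
  mean(result$site_pp[nongap], na.rm = TRUE)
}

#' Tabulate the columns where reconstructions disagree
#'
#' One row per disagreement column, listing each method's state, the
#' consensus choice and its posterior probability — the raw material for
#' manual curation of the consensus.
#'
#' @param recs The list of reconstructions passed to
#'   [consensus_sequence()].
#' @param result The corresponding `asr_consensus`.
#' @return A data frame with columns `column`, one `state_<method>` per
#'   method, `chosen`, `chosen_pp`.
#' @export
disagreement_report <- function(recs, result) {
  stopifnot(inherits(result, "asr_consensus"))
  cols <- result$disagreement_sites
  cons_chars <- strsplit(result$sequence, "")[[1]]
  out <- data.frame(column = cols)
  for (r in recs)
    out[[paste0("state_", r$method_id)]] <- r$chars[cols]
  out$chosen <- cons_chars[cols]
  out$chosen_pp <- result$site_pp[cols]
  out
}

#' Read aligned reconstructions from FASTA plus PP tables
#'
#' The FASTA holds one aligned record per reconstruction method (record
#' names are the method ids); each method's per-column posterior
#' probabilities come from a TSV with columns `column` (1-based aligned
#' index) and `pp`. Columns absent from a PP table (typically gap columns)
#' get `NA`.
#'
#' @param fasta Path to an aligned FASTA file.
#' @param pp_files Named character vector of TSV paths, names matching the
#'   FASTA record names.
#' @return A list of [ancestral_reconstruction()] objects.
#' @export
read_reconstructions <- function(fasta, pp_files) {
  seqs <- Biostrings::readAAStringSet(fasta)
  ids <- names(seqs)
  miss <- setdiff(ids, names(pp_files))
  if (length(miss))
    stop("no PP table supplied for method(s): ", paste(miss, collapse = ", "))
  lapply(ids, function(id) {
    s <- as.character(seqs[[id]])
    pp <- rep(NA_real_, nchar(s))
    tab <- utils::read.table(pp_files[[id]], header = TRUE, sep = "\t")
    pp[tab$column] <- tab$pp
    ancestral_reconstruction(id, s, pp)
  })
}

#' Write a consensus sequence and its site report
#'
#' Writes the unaligned consensus as FASTA and, when `report_file` is
#' given, a per-column TSV (`column`, `state`, `pp`, `disagreement`).
#'
#' @param result An `asr_consensus`.
#' @param fasta Output FASTA path.
#' @param name FASTA record name.
#' @param report_file Optional TSV path for the site report.
#' @return `fasta`, invisibly.
#' @export
write_consensus <- function(result, fasta, name = "consensus",
                            report_file = NULL) {
  stopifnot(inherits(result, "asr_consensus"))
  x <- Biostrings::AAStringSet(result$unaligned)
  names(x) <- name
  Biostrings::writeXStringSet(x, fasta)
  if (!is.null(report_file)) {
    chars <- strsplit(result$sequence, "")[[1]]
    d <- data.frame(column = seq_along(chars), state = chars,
                    pp = result$site_pp,
                    disagreement = seq_along(chars) %in%
                      result$disagreement_sites)
    utils::write.table(d, report_file, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(fasta)
}
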