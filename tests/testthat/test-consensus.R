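rec <- function(id, seq, pp) ancestral_reconstruction(id, seq, pp)

test_that("reconstruction constructor validates residues and probabilities", {
  r <- rec("m1", "MK-L", c(0.9, 0.8, NA, 0.7))
  expect_s3_class(r, "asr_reconstruction")
  expect_error(rec("m1", "MKXL", c(0.9, 0.8, 0.5, 0.7)), "invalid residue")
  expect_error(rec("m1", "MKL", c(0.9, 0.8)), "length")
  expect_error(rec("m1", "MKL", c(0.9, 0.8, 1.2)), "\\[0, 1\\]")
})

test_that("unanimous input reproduces itself with max-PP columns", {
  r1 <- rec("a", "MKAL", c(0.99, 0.90, 0.80, 0.95))
  r2 <- rec("b", "MKAL", c(0.98, 0.95, 0.70, 0.90))
  r3 <- rec("c", "MKAL", c(0.97, 0.80, 0.90, 0.99))
  cons <- consensus_sequence(list(r1, r2, r3))
  expect_equal(cons$sequence, "MKAL")
  expect_equal(cons$unaligned, "MKAL")
  expect_length(cons$disagreement_sites, 0)
  expect_equal(cons$site_pp, c(0.99, 0.95, 0.90, 0.99))
  expect_equal(cons$mean_pp, mean(c(0.99, 0.95, 0.90, 0.99)))
  expect_equal(nrow(disagreement_report(list(r1, r2, r3), cons)), 0L)
})

test_that("majority vote, PP tie-break and lexicographic fallback all fire", {
  # 2-of-3 majority beats a higher-PP minority state
  r1 <- rec("a", "A", 0.50)
  r2 <- rec("b", "A", 0.55)
  r3 <- rec("c", "S", 0.99)
  cons <- consensus_sequence(list(r1, r2, r3))
  expect_equal(cons$sequence, "A")
  expect_equal(cons$disagreement_sites, 1L)
  expect_equal(cons$site_pp, 0.55)  # max PP among carriers of the winner
  # three-way vote tie: PP decides
  t1 <- rec("a", "A", 0.51); t2 <- rec("b", "S", 0.88); t3 <- rec("c", "T", 0.60)
  expect_equal(consensus_sequence(list(t1, t2, t3))$sequence, "S")
  # vote tie with equal PPs: lexicographic residue order
  u1 <- rec("a", "T", 0.7); u2 <- rec("b", "C", 0.7); u3 <- rec("c", "W", 0.7)
  expect_equal(consensus_sequence(list(u1, u2, u3))$sequence, "C")
  # gap carries no PP, so a residue wins the tie-break against a gap
  g1 <- rec("a", "-", NA); g2 <- rec("b", "A", 0.4)
  expect_equal(consensus_sequence(list(g1, g2))$sequence, "A")
  # a strict gap majority wins and drops the column from the export
  g3 <- rec("c", "-", NA)
  cg <- consensus_sequence(list(rec("a", "-A", c(NA, 0.9)),
                                rec("b", "-A", c(NA, 0.8)),
                                rec("c", "KA", c(0.9, 0.7))))
  expect_equal(cg$sequence, "-A")
  expect_equal(cg$unaligned, "A")
  expect_true(is.na(cg$site_pp[1]))
})

test_that("consensus is invariant under the order of input reconstructions", {
  set.seed(5)
  sim <- simulate_asr_set(paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                       120, replace = TRUE), collapse = ""),
                          per_method_error = c(0.1, 0.15, 0.2), seed = 8)
  c1 <- consensus_sequence(sim$recs)
  c2 <- consensus_sequence(rev(sim$recs))
  c3 <- consensus_sequence(sim$recs[c(2, 1, 3)])
  expect_equal(c1$sequence, c2$sequence)
  expect_equal(c1$sequence, c3$sequence)
  expect_equal(c1$disagreement_sites, c2$disagreement_sites)
})

test_that("the reference-sequence mode prefers the neighbour's state", {
  r1 <- rec("a", "AK", c(0.5, 0.9))
  r2 <- rec("b", "SK", c(0.9, 0.9))
  r3 <- rec("c", "TK", c(0.7, 0.9))
  # without a reference, PP picks S; the reference flips it to T
  expect_equal(consensus_sequence(list(r1, r2, r3))$sequence, "SK")
  expect_equal(consensus_sequence(list(r1, r2, r3), reference = "TW")$sequence,
               "TK")
  # a reference state absent from the column has no effect
  expect_equal(consensus_sequence(list(r1, r2, r3), reference = "YK")$sequence,
               "SK")
})

test_that("mean posterior averages non-gap consensus columns", {
  r1 <- rec("a", "MKL", c(1.0, 0.8, 0.9))
  r2 <- rec("b", "MKL", c(1.0, 0.8, 0.9))
  cons <- consensus_sequence(list(r1, r2))
  expect_equal(mean_posterior(cons), 0.9)
  expect_equal(mean_posterior(cons), cons$mean_pp)
  # all-unanimous all-PP-1 input: exactly 1
  p1 <- rec("a", "MARV", rep(1, 4)); p2 <- rec("b", "MARV", rep(1, 4))
  expect_identical(mean_posterior(consensus_sequence(list(p1, p2))), 1)
  # independent summation oracle on a longer random PP list
  set.seed(11)
  pp <- round(runif(100), 3)
  seqs <- paste(rep("K", 100), collapse = "")
  cons2 <- consensus_sequence(list(rec("a", seqs, pp), rec("b", seqs, pp)))
  expect_equal(mean_posterior(cons2), sum(pp) / 100)
})

test_that("disagreement report has one row per planted disagreement", {
  base <- strsplit(paste(rep("ACDEFGHIKL", 5), collapse = ""), "")[[1]]
  alt <- base
  planted <- c(3, 9, 17, 22, 31, 40, 48)
  alt[planted] <- "W"
  r1 <- rec("m1", paste(base, collapse = ""), rep(0.9, 50))
  r2 <- rec("m2", paste(base, collapse = ""), rep(0.8, 50))
  r3 <- rec("m3", paste(alt, collapse = ""), rep(0.7, 50))
  cons <- consensus_sequence(list(r1, r2, r3))
  rep_tab <- disagreement_report(list(r1, r2, r3), cons)
  expect_equal(nrow(rep_tab), 7L)
  expect_equal(rep_tab$column, planted)
  expect_equal(rep_tab$chosen, base[planted])  # 2-of-3 majority everywhere
  expect_equal(names(rep_tab), c("column", "state_m1", "state_m2",
                                 "state_m3", "chosen", "chosen_pp"))
})

test_that("consensus of noisy triplets beats the best single method", {
  set.seed(13)
  truth <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 150,
                        replace = TRUE), collapse = "")
  gains <- replicate(50, {
    seed <- sample.int(1e6, 1)
    sim <- simulate_asr_set(truth, per_method_error = c(0.1, 0.15, 0.2),
                            seed = seed)
    tc <- strsplit(truth, "")[[1]]
    acc <- function(s) mean(strsplit(s, "")[[1]] == tc)
    best <- max(vapply(sim$recs, function(r) acc(r$sequence), numeric(1)))
    acc(consensus_sequence(sim$recs)$sequence) - best
  })
  expect_gte(mean(gains), 0)
})

test_that("unequal lengths are refused with an instruction to align", {
  r1 <- rec("a", "MKL", c(0.9, 0.9, 0.9))
  r2 <- rec("b", "MK", c(0.9, 0.9))
  expect_error(consensus_sequence(list(r1, r2)), "align")
  expect_error(consensus_sequence(list(r1)), "at least 2")
})

test_that("consensus FASTA and PP tables round-trip through files", {
  sim <- simulate_asr_set("MKALWGDEVRT", per_method_error = c(0, 0.1, 0.1),
                          seed = 3)
  fa <- withr::local_tempfile(fileext = ".fasta")
  pps <- character(3)
  for (i in 1:3) {
    pps[i] <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
    r <- sim$recs[[i]]
    keep <- !is.na(r$site_pp)
    write.table(data.frame(column = which(keep), pp = r$site_pp[keep]),
                pps[i], sep = "\t", row.names = FALSE, quote = FALSE)
  }
  seqs <- Biostrings::AAStringSet(vapply(sim$recs, `[[`, character(1),
                                         "sequence"))
  names(seqs) <- vapply(sim$recs, `[[`, character(1), "method_id")
  Biostrings::writeXStringSet(seqs, fa)
  back <- read_reconstructions(fa, setNames(pps, names(seqs)))
  expect_equal(vapply(back, `[[`, character(1), "sequence"),
               vapply(sim$recs, `[[`, character(1), "sequence"))
  expect_equal(back[[2]]$site_pp, sim$recs[[2]]$site_pp)
  # consensus export
  cons <- consensus_sequence(sim$recs)
  out_fa <- withr::local_tempfile(fileext = ".fasta")
  out_tsv <- withr::local_tempfile(fileext = ".tsv")
  write_consensus(cons, out_fa, name = "anc", report_file = out_tsv)
  got <- Biostrings::readAAStringSet(out_fa)
  expect_equal(as.character(got[[1]]), cons$unaligned)
  site <- read.delim(out_tsv)
  expect_equal(nrow(site), nchar(cons$sequence))
})
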