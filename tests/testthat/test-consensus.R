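test_that("pairwise identity handles matches, gaps, and denominators", {
  expect_equal(pairwise_identity("ACDE", "ACDE"), 100)
  expect_equal(pairwise_identity("ACDE", "ACDF"), 75)
  # symmetric; gap columns dropped under the shared-column policy
  expect_equal(pairwise_identity("AC-E", "ACDE"), pairwise_identity("ACDE", "AC-E"))
  expect_equal(pairwise_identity("AC-E", "ACDE"), 100)
  expect_equal(pairwise_identity("AC-E", "ACDE", policy = "alignment"), 75)
  expect_error(pairwise_identity("A---", "-CDE"), "disjoint")
})

test_that("simulated family realizes its identity targets exactly", {
  set.seed(11)
  ref <- paste(sample(consenz:::AA20, 100, replace = TRUE), collapse = "")
  aln <- simulate_homolog_family(ref, identities = c(100, 60, 60, 80), seed = 3)
  ids <- vapply(aln$seqs[-1], pairwise_identity, numeric(1), b = aln$seqs[1])
  expect_equal(unname(ids), c(100, 60, 60, 80), tolerance = 2 / 100)
  # substitution count is forced, so 60% is exact at L = 100
  expect_equal(unname(ids[2]), 60)
})

test_that("homolog curation applies the window and redundancy rules", {
  set.seed(5)
  ref <- paste(sample(consenz:::AA20, 100, replace = TRUE), collapse = "")
  aln <- simulate_homolog_family(
    ref, identities = c(20, 35, 50, 65, 80, 92, 100, 25, 96), seed = 9)
  cur <- filter_homologs(aln, min_id = 30, max_id = 90, redundancy_cutoff = 95)
  lg <- cur$log

  # reference always retained
  expect_true(lg$kept[lg$id == "TARGET"])
  # window rule: 20, 25, 92 outside [30, 90]; 100 and 96 too
  window_removed <- lg$id[!lg$kept & lg$rule == "identity_window"]
  expect_setequal(window_removed,
                  c("HOM001", "HOM006", "HOM007", "HOM008", "HOM009"))
  # survivors all inside the window
  kept_ids <- lg$identity_to_reference[lg$kept & lg$id != "TARGET"]
  expect_true(all(kept_ids >= 30 & kept_ids <= 90))

  # a duplicate of the reference is removed by the redundancy rule when
  # it passes the window (construct identity 90 twice: second is a
  # near-duplicate of the first with identity 100 > 95)
  rows <- c(aln$seqs[1], aln$seqs[5], aln$seqs[5])
  names(rows) <- c("TARGET", "K1", "K2")
  cur2 <- filter_homologs(alignment(rows, "TARGET"))
  expect_equal(cur2$log$rule[cur2$log$id == "K2"], "redundancy")

  # idempotence: re-curating the curated set removes nothing
  cur3 <- filter_homologs(cur$alignment)
  expect_true(all(cur3$log$kept))
})

test_that("profiles count residues per column with X and gaps excluded", {
  rows <- c(REF = "AD-X", H1 = "AD-D", H2 = "AE-D", H3 = "A-XD")
  aln <- alignment(rows, "REF")
  prof <- build_profile(aln)
  expect_equal(unname(prof$counts["A", 1]), 4L)
  expect_equal(unname(prof$counts["D", 2]), 2L)
  expect_equal(unname(prof$counts["E", 2]), 1L)
  expect_equal(unname(prof$gap_count[2]), 1L)
  # all-gap-or-X column
  expect_equal(unname(prof$gap_count[3]), 3L)
  expect_equal(unname(prof$x_count[3]), 1L)
  expect_equal(sum(prof$counts[, 3]), 0L)
  # frequencies sum to 1 whenever any residue is present
  freq <- profile_frequencies(prof)
  present <- colSums(prof$counts) > 0
  expect_true(all(abs(colSums(freq[, present, drop = FALSE]) - 1) < 1e-12))
})

test_that("profile frequencies match a naive recount on a random alignment", {
  set.seed(21)
  ref <- paste(sample(consenz:::AA20, 40, replace = TRUE), collapse = "")
  aln <- simulate_homolog_family(ref, identities = round(runif(15, 35, 85)),
                                 seed = 2)
  prof <- build_profile(aln)
  m <- do.call(rbind, strsplit(aln$seqs, ""))
  for (j in sample(ncol(m), 10)) {
    tab <- table(factor(m[, j], levels = consenz:::AA20))
    expect_equal(unname(prof$counts[, j]), as.integer(tab))
  }
})

test_that("consensus calls use the alphabetical tie rule and map coordinates", {
  rows <- c(REF = "A-CD", H1 = "D-CD", H2 = "E-CD", H3 = "D-CE")
  aln <- alignment(rows, "REF")
  calls <- call_consensus(build_profile(aln), aln)
  # column 1: 2 D vs 1 E vs 1 A -> D, no tie
  expect_equal(calls$consensus_aa[calls$column == 1], "D")
  # column 4: 3 D, 1 E
  expect_equal(calls$consensus_aa[calls$column == 4], "D")
  # gap column of the reference yields no target position
  expect_false(2 %in% calls$column)  # all-gap column: no call at all
  expect_equal(calls$target_position[calls$column == 3], 2)
  expect_equal(calls$target_position[calls$column == 4], 3)

  # forced 50/50 tie broken alphabetically and flagged
  rows2 <- c(REF = "N", H1 = "D", H2 = "D", H3 = "E", H4 = "E")
  # 2 D, 2 E, 1 N -> D vs E tie at 0.4? no: max is D/E at 2/5 each
  aln2 <- alignment(rows2, "REF")
  calls2 <- call_consensus(build_profile(aln2), aln2, min_frequency = 0.5)
  expect_equal(calls2$consensus_aa, "D")
  expect_true(calls2$tie)
  expect_true(calls2$low_confidence)
})

test_that("candidate positions keep non-consensus targets above threshold", {
  calls <- data.frame(
    column = 1:4, consensus_aa = c("D", "A", "D", "E"),
    frequency = c(0.55, 0.90, 0.45, 0.61), tie = FALSE, low_confidence = FALSE,
    target_position = c(130L, 2L, 3L, 4L), target_aa = c("N", "A", "N", "Q"),
    stringsAsFactors = FALSE)
  out <- candidate_positions(calls, min_frequency = 0.5)
  expect_equal(out$mutation, c("Q4E", "N130D"))  # sorted by frequency desc
  expect_equal(out$frequency, c(0.61, 0.55))
  # target equal to consensus never emitted; sub-threshold excluded
  expect_false("A2A" %in% out$mutation)
  expect_false("N3D" %in% out$mutation)
  # boundary: threshold 0.6 excludes the 0.55 call
  expect_equal(candidate_positions(calls, min_frequency = 0.6)$mutation, "Q4E")
})

test_that("forced-column families produce the requested consensus fraction", {
  set.seed(31)
  ref <- paste(sample(setdiff(consenz:::AA20, "D"), 30, replace = TRUE),
               collapse = "")
  aln <- simulate_homolog_family(ref, identities = rep(70, 19), seed = 4,
                                 forced_column = list(column = 7, aa = "D",
                                                      fraction = 0.55))
  calls <- call_consensus(build_profile(aln), aln)
  row <- calls[calls$column == 7, ]
  expect_equal(row$consensus_aa, "D")
  expect_equal(row$frequency, 0.55)
})

test_that("alignment rows round-trip through ungapping", {
  rows <- c(REF = "AC-DE-", H1 = "A-CDEF")
  aln <- alignment(rows, "REF")
  expect_equal(ungap(aln$seqs), c("ACDE", "ACDEF"))
})

test_that("FASTA round-trips alignments through disk", {
  rows <- c(TARGET = "ACD-EF", HOM001 = "ACDYEF")
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(rows, path)
  back <- read_alignment(path, "TARGET")
  expect_equal(stats::setNames(back$seqs, back$ids), rows)
})
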