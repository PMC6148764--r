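#' Percent identity between two gapped rows
#'
#' Identity is computed over alignment columns; the denominator policy
#' controls which columns count. The default (`"shared"`) uses columns
#' where both rows carry a residue, which makes the measure symmetric and
#' insensitive to terminal gaps.
#'
#' @param a,b Gapped sequences of equal length.
#' @param policy Denominator: `"shared"` (columns where both rows are
#'   non-gap; default), `"shorter"` (ungapped length of the shorter row),
#'   or `"alignment"` (all alignment columns).
#' @return Percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(a, b, policy = c("shared", "shorter", "alignment")) {
  policy <- match.arg(policy)
  if (nchar(a) != nchar(b)) stop("rows must have equal aligned length")
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  both <- av != "-" & bv != "-"
  if (!any(both))
    stop("rows share no non-gap column (disjoint coverage)")
  matches <- sum(av[both] == bv[both])
  denom <- switch(policy,
    shared    = sum(both),
    shorter   = min(sum(av != "-"), sum(bv != "-")),
    alignment = length(av)
  )
  100 * matches / denom
}

#' Curate a homolog alignment by identity window and redundancy removal
#'
#' Two rules, mirroring common consensus-design practice: (1) keep only
#' homologs whose identity to the reference lies within
#' `[min_id, max_id]` (too-close homologs add no information, too-distant
#' ones add noise); (2) among survivors, remove near-duplicates — a single
#' greedy pass in input order drops any row whose identity to an
#' already-retained row exceeds `redundancy_cutoff`, avoiding bias from
#' repeated near-identical sequences. The reference row is always kept.
#'
#' @param aln An [alignment()] object containing the reference row.
#' @param min_id,max_id Identity window (percent) relative to the reference.
#' @param redundancy_cutoff Pairwise identity (percent) above which a row
#'   is considered redundant with an already-retained row.
#' @param policy Identity denominator policy, see [pairwise_identity()].
#' @return A list with `alignment` (the curated subset, reference first
#'   among retained order) and `log`, a data frame with one row per input
#'   sequence: `id`, `identity_to_reference`, `kept`, `rule`
#'   (`NA`, `"identity_window"` or `"redundancy"`), `detail`.
#' @export
filter_homologs <- function(aln, min_id = 30, max_id = 90,
                            redundancy_cutoff = 95, policy = "shared") {
  stopifnot(inherits(aln, "aa_alignment"))
  ref <- alignment_row(aln, aln$reference_id)
  n <- length(aln$ids)
  id_to_ref <- numeric(n)
  kept <- logical(n)
  rule <- rep(NA_character_, n)
  detail <- rep(NA_character_, n)

  retained_idx <- integer(0)
  for (i in seq_len(n)) {
    is_ref <- aln$ids[i] == aln$reference_id
    id_to_ref[i] <- if (is_ref) 100 else pairwise_identity(aln$seqs[i], ref, policy)
    if (is_ref) {
      kept[i] <- TRUE
      retained_idx <- c(retained_idx, i)
      next
    }
    if (id_to_ref[i] < min_id || id_to_ref[i] > max_id) {
      rule[i] <- "identity_window"
      detail[i] <- sprintf("identity to reference %.2f%% outside [%g, %g]",
                           id_to_ref[i], min_id, max_id)
      next
    }
    redundant_with <- NA_character_
    red_val <- NA_real_
    for (j in retained_idx) {
      pid <- pairwise_identity(aln$seqs[i], aln$seqs[j], policy)
      if (pid > redundancy_cutoff) {
        redundant_with <- aln$ids[j]
        red_val <- pid
        break
      }
    }
    if (!is.na(redundant_with)) {
      rule[i] <- "redundancy"
      detail[i] <- sprintf("identity %.2f%% > %g%% to retained '%s'",
                           red_val, redundancy_cutoff, redundant_with)
    } else {
      kept[i] <- TRUE
      retained_idx <- c(retained_idx, i)
    }
  }

  if (sum(kept) < 2L)
    stop("no homologs survive curation; relax the identity window")
  log <- data.frame(
    id = aln$ids, identity_to_reference = id_to_ref,
    kept = kept, rule = rule, detail = detail,
    stringsAsFactors = FALSE
  )
  list(alignment = subset_alignment(aln, aln$ids[kept]), log = log)
}

#' Per-column residue frequency profiles
#'
#' Counts the 20 standard amino acids per alignment column. `X`
#' (unknown residue) and gaps are tallied separately and excluded from
#' frequencies, so a column's frequencies always sum to 1 over observed
#' standard residues.
#'
#' @param aln An [alignment()] object.
#' @return An object of class `position_profile`: list with `counts`
#'   (20 x n_columns integer matrix, rows named by amino acid),
#'   `gap_count`, `x_count` (integer vectors), `n_rows`.
#' @export
build_profile <- function(aln) {
  stopifnot(inherits(aln, "aa_alignment"))
  m <- alignment_matrix(aln)
  ncol_aln <- ncol(m)
  counts <- matrix(0L, nrow = length(AA20), ncol = ncol_aln,
                   dimnames = list(AA20, NULL))
  for (aa in AA20) counts[aa, ] <- colSums(m == aa)
  gap_count <- colSums(m == "-")
  x_count <- colSums(m == "X")
  stopifnot(all(colSums(counts) + gap_count + x_count == nrow(m)))
  structure(
    list(counts = counts, gap_count = gap_count, x_count = x_count,
         n_rows = nrow(m)),
    class = "position_profile"
  )
}

#' Column frequencies from a profile
#'
#' @param profile A [build_profile()] result.
#' @return 20 x n_columns matrix of frequencies (NaN for empty columns).
#' @export
profile_frequencies <- function(profile) {
  sweep(profile$counts, 2, colSums(profile$counts), "/")
}

#' Call the consensus residue per column, mapped to target coordinates
#'
#' For every column with at least one standard residue, the consensus is
#' the most frequent amino acid (ties broken alphabetically and flagged).
#' The column is mapped to 1-based positions of the ungapped reference;
#' columns where the reference is gapped get `NA` positions.
#'
#' @param profile A [build_profile()] result derived from `aln`.
#' @param aln The source [alignment()].
#' @param min_frequency Calls below this consensus frequency are flagged
#'   `low_confidence`. Default 0.5: a residue carried by the majority of
#'   homologs.
#' @return Data frame of class `consensus_calls`: `column`,
#'   `consensus_aa`, `frequency`, `tie`, `low_confidence`,
#'   `target_position`, `target_aa`.
#' @export
call_consensus <- function(profile, aln, min_frequency = 0.5) {
  stopifnot(inherits(profile, "position_profile"), inherits(aln, "aa_alignment"))
  m <- ncol(profile$counts)
  refv <- strsplit(alignment_row(aln, aln$reference_id), "")[[1]]
  if (length(refv) != m)
    stop("profile and alignment have different column counts")
  target_position <- ifelse(refv == "-", NA_integer_, cumsum(refv != "-"))
  target_aa <- ifelse(refv == "-", NA_character_, refv)

  totals <- colSums(profile$counts)
  freq <- profile_frequencies(profile)
  out <- lapply(seq_len(m), function(j) {
    if (totals[j] == 0L) return(NULL)
    f <- freq[, j]
    top <- max(f)
    winners <- AA20[f == top]  # AA20 is alphabetical, so [1] is the tie rule
    data.frame(
      column = j, consensus_aa = winners[1], frequency = top,
      tie = length(winners) > 1L, low_confidence = top < min_frequency,
      target_position = target_position[j], target_aa = target_aa[j],
      stringsAsFactors = FALSE
    )
  })
  calls <- do.call(rbind, out)
  class(calls) <- c("consensus_calls", "data.frame")
  calls
}

#' Candidate substitution positions from consensus calls
#'
#' Retains calls where the target residue differs from the consensus and
#' the consensus frequency reaches `min_frequency`, sorted by descending
#' frequency — the candidate list for downstream structural filtering.
#'
#' @param calls A [call_consensus()] result.
#' @param min_frequency Minimum consensus frequency to propose a
#'   substitution.
#' @return Data frame: `target_position`, `target_aa`, `consensus_aa`,
#'   `frequency`, `mutation` (e.g. `"N130D"`).
#' @export
candidate_positions <- function(calls, min_frequency = 0.5) {
  keep <- !is.na(calls$target_position) &
    calls$target_aa != calls$consensus_aa &
    calls$frequency >= min_frequency
  out <- calls[keep, c("target_position", "target_aa", "consensus_aa", "frequency")]
  out <- out[order(-out$frequency, out$target_position), , drop = FALSE]
  out$mutation <- paste0(out$target_aa, out$target_position, out$consensus_aa)
  rownames(out) <- NULL
  out
}

#' Write a homolog-curation report as TSV
#'
#' @param curated A [filter_homologs()] result.
#' @param path Output path.
#' @export
write_curation_report <- function(curated, path) {
  utils::write.table(curated$log, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
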