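check_iupac <- function(x) {
  chars <- strsplit(toupper(x), "")[[1]]
  bad <- !chars %in% names(IUPAC_NT)
  if (any(bad))
    stop("invalid IUPAC nucleotide code(s): ",
         paste(unique(chars[bad]), collapse = ", "))
  chars
}

#' Expand a degenerate codon
#'
#' Enumerates every concrete codon a degenerate triplet encodes
#' (Cartesian product of its IUPAC codes) and translates each under the
#' standard genetic code. `NNK` (N = A/C/G/T, K = G/T) expands to 32
#' codons covering all 20 amino acids with a single stop (TAG), which is
#' why it is the workhorse of site-saturation mutagenesis.
#'
#' @param codon Degenerate triplet, e.g. `"NNK"`.
#' @return List: `codons` (character vector), `aa_counts` (named integer
#'   vector over the 20 amino acids), `stop_count`, `total`.
#' @export
expand_degenerate <- function(codon) {
  chars <- check_iupac(codon)
  if (length(chars) != 3L) stop("a codon must have exactly 3 positions")
  grid <- expand.grid(IUPAC_NT[[chars[3]]], IUPAC_NT[[chars[2]]],
                      IUPAC_NT[[chars[1]]], stringsAsFactors = FALSE)
  codons <- paste0(grid[[3]], grid[[2]], grid[[1]])
  codons <- sort(codons)
  aa <- Biostrings::GENETIC_CODE[codons]
  counts <- stats::setNames(integer(length(AA20)), AA20)
  tab <- table(aa[aa != "*"])
  counts[names(tab)] <- as.integer(tab)
  list(codons = codons, aa_counts = counts,
       stop_count = sum(aa == "*"), total = length(codons))
}

#' Reverse complement with IUPAC ambiguity codes
#'
#' @param seq Nucleotide string, possibly degenerate.
#' @return The reverse complement under extended complement rules
#'   (so `revcomp("NNK") == "MNN"`).
#' @export
reverse_complement_iupac <- function(seq) {
  check_iupac(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(seq))))
}

#' Design a QuikChange-style saturation-mutagenesis primer pair
#'
#' The forward primer is the coding-strand slice centered on the target
#' codon with that codon replaced by the degenerate scheme; the reverse
#' primer is its full IUPAC reverse complement, so the pair anneals
#' perfectly to the template everywhere except inside the target codon.
#' A simple GC-content melting-temperature estimate
#' (`64.9 + 41*(GC - 16.4)/length`, degenerate bases counted by expected
#' GC) is attached for QC only.
#'
#' @param cds Coding sequence (A/C/G/T string, length divisible by 3).
#' @param codon_index 1-based codon to saturate.
#' @param scheme Degenerate codon, default `"NNK"`.
#' @param flank Template nucleotides kept on each side of the codon.
#' @return List of class `primer_pair`: `forward`, `reverse`,
#'   `target_codon_index`, `wt_codon`, `scheme`, `flank`, `tm_forward`.
#' @export
design_mutagenic_primers <- function(cds, codon_index, scheme = "NNK",
                                     flank = 15L) {
  cds <- toupper(cds)
  if (grepl("[^ACGT]", cds)) stop("CDS must contain only A/C/G/T")
  L <- nchar(cds)
  if (L %% 3L != 0L) stop("CDS length must be divisible by 3")
  n_codons <- L %/% 3L
  if (codon_index < 1L || codon_index > n_codons)
    stop("codon_index out of range; valid range is 1..", n_codons)
  start <- (codon_index - 1L) * 3L + 1L
  if (start - flank < 1L || start + 2L + flank > L)
    stop("flank extends past sequence end; maximum flank here is ",
         min(start - 1L, L - start - 2L))
  up <- substr(cds, start - flank, start - 1L)
  down <- substr(cds, start + 3L, start + 2L + flank)
  forward <- paste0(up, toupper(scheme), down)
  reverse <- reverse_complement_iupac(forward)
  gc_expected <- function(s) {
    sum(vapply(strsplit(s, "")[[1]], function(ch) {
      opts <- IUPAC_NT[[ch]]
      mean(opts %in% c("G", "C"))
    }, numeric(1)))
  }
  tm <- 64.9 + 41 * (gc_expected(forward) - 16.4) / nchar(forward)
  structure(list(forward = forward, reverse = reverse,
                 target_codon_index = codon_index,
                 wt_codon = substr(cds, start, start + 2L),
                 scheme = toupper(scheme), flank = flank,
                 tm_forward = tm),
            class = "primer_pair")
}

#' @export
print.primer_pair <- function(x, ...) {
  cat(sprintf("Saturation primer pair, codon %d (%s -> %s), flank %d nt, Tm ~ %.1f C\n  F: 5'-%s-3'\n  R: 5'-%s-3'\n",
              x$target_codon_index, x$wt_codon, x$scheme, x$flank,
              x$tm_forward, x$forward, x$reverse))
  invisible(x)
}

## Per-amino-acid draw probabilities of a scheme; stop codons keep their
## probability mass but map to no amino acid (wasted colonies).
scheme_probabilities <- function(scheme, weights = NULL) {
  exp <- expand_degenerate(scheme)
  if (is.null(weights)) {
    w <- rep(1, exp$total)
  } else {
    if (length(weights) != exp$total || any(weights < 0))
      stop("weights must be a non-negative vector over the scheme's ",
           exp$total, " codons")
    w <- as.numeric(weights[exp$codons])
    if (anyNA(w)) w <- as.numeric(weights)
  }
  w <- w / sum(w)
  aa <- Biostrings::GENETIC_CODE[exp$codons]
  p <- vapply(AA20, function(a) sum(w[aa == a]), numeric(1))
  p
}

#' Probability that a colony library covers all 20 amino acids
#'
#' With `n` colonies drawn i.i.d. over the scheme's codons, the chance
#' every amino acid is seen at least once is computed by exact
#' inclusion–exclusion over amino-acid subsets,
#' `sum over S of (-1)^|S| (1 - p(S))^n`, where `p(S)` is the summed draw
#' probability of the amino acids in `S`. Amino acids are grouped by
#' equal probability so the alternating sum stays small; stop codons
#' contribute only their own (wasted) probability mass.
#'
#' @param scheme Degenerate codon.
#' @param n_colonies Number of colonies.
#' @param weights Optional per-codon weight vector (transformation bias).
#' @return Probability in `[0, 1]`.
#' @export
coverage_probability <- function(scheme, n_colonies, weights = NULL) {
  if (n_colonies < 0) stop("n_colonies must be non-negative")
  p <- scheme_probabilities(scheme, weights)
  if (any(p == 0))
    stop("scheme cannot encode amino acid(s): ",
         paste(names(p)[p == 0], collapse = ", "))
  if (n_colonies == 0) return(0)
  groups <- table(round(p, 15))
  pvals <- as.numeric(names(groups))
  mult <- as.integer(groups)
  terms <- data.frame(coef = 1, mass = 0)
  for (g in seq_along(pvals)) {
    j <- 0:mult[g]
    expanded <- do.call(rbind, lapply(seq_len(nrow(terms)), function(t) {
      data.frame(coef = terms$coef[t] * (-1)^j * choose(mult[g], j),
                 mass = terms$mass[t] + j * pvals[g])
    }))
    key <- round(expanded$mass, 12)
    agg <- stats::aggregate(expanded$coef, by = list(mass = key), FUN = sum)
    terms <- data.frame(coef = agg$x, mass = agg$mass)
  }
  prob <- sum(terms$coef * (1 - terms$mass)^n_colonies)
  min(max(prob, 0), 1)
}

#' Smallest library size reaching a coverage confidence
#'
#' Binary search over `n` (coverage probability is non-decreasing in
#' `n`), returning the smallest `n` with
#' `coverage_probability(scheme, n) >= confidence`.
#'
#' @param scheme Degenerate codon.
#' @param confidence Target probability of full coverage, in (0, 1).
#' @param weights Optional per-codon weights.
#' @return Integer number of colonies.
#' @export
colonies_for_coverage <- function(scheme, confidence = 0.95, weights = NULL) {
  if (confidence <= 0 || confidence >= 1)
    stop("confidence must be strictly between 0 and 1")
  hi <- 1L
  while (coverage_probability(scheme, hi, weights) < confidence) hi <- hi * 2L
  lo <- 0L
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (coverage_probability(scheme, mid, weights) >= confidence) hi <- mid
    else lo <- mid
  }
  hi
}

#' Library coverage report
#'
#' @param scheme Degenerate codon.
#' @param n_colonies Library size.
#' @param weights Optional per-codon weights.
#' @return List of class `library_coverage`: scheme, codon totals,
#'   per-amino-acid codon counts, stop count, `n_colonies`,
#'   `p_full_coverage`.
#' @export
library_coverage <- function(scheme, n_colonies, weights = NULL) {
  exp <- expand_degenerate(scheme)
  structure(list(
    scheme = toupper(scheme), total_codons = exp$total,
    aa_codon_counts = exp$aa_counts, stop_codon_count = exp$stop_count,
    n_colonies = n_colonies,
    p_full_coverage = coverage_probability(scheme, n_colonies, weights)
  ), class = "library_coverage")
}

#' @export
print.library_coverage <- function(x, ...) {
  cat(sprintf("%s library: %d codons (%d stop), %d colonies -> P(all 20 aa) = %.4f\n",
              x$scheme, x$total_codons, x$stop_codon_count,
              x$n_colonies, x$p_full_coverage))
  invisible(x)
}
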