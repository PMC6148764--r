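#' Read protein sequences from FASTA
#'
#' Thin wrapper over [Biostrings::readAAStringSet()] returning plain
#' character data. Sequences are uppercased; `*` terminators are dropped.
#'
#' @param path Path to a FASTA file (plain or aligned; gaps `-` allowed).
#' @return Named character vector of sequences; names are the first
#'   whitespace-delimited token of each header, with the full header kept
#'   in attribute `descriptions`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  seqs <- toupper(gsub("\\*", "", as.character(set)))
  headers <- names(set)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
  names(seqs) <- ids
  attr(seqs, "descriptions") <- stats::setNames(headers, ids)
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector (gapped or ungapped).
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Construct an alignment object
#'
#' An alignment is the package's central sequence container: an ordered set
#' of equal-length gapped rows with one row designated as the reference
#' (the engineering target whose coordinates consensus calls are mapped
#' onto).
#'
#' @param seqs Named character vector of equal-length gapped sequences
#'   (uppercase amino acids, `X`, and `-`).
#' @param reference_id Name of the reference row.
#' @return An object of class `aa_alignment` with elements `ids`, `seqs`,
#'   `reference_id`.
#' @export
alignment <- function(seqs, reference_id) {
  stopifnot(is.character(seqs), length(seqs) >= 1L, !is.null(names(seqs)))
  if (anyDuplicated(names(seqs)))
    stop("alignment row ids must be unique")
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L)
    stop("all alignment rows must have equal length")
  seqs <- toupper(seqs)
  bad <- grepl(paste0("[^", paste(AA20, collapse = ""), "X-]"), seqs)
  if (any(bad))
    stop("invalid characters in rows: ", paste(names(seqs)[bad], collapse = ", "))
  if (!reference_id %in% names(seqs))
    stop("reference_id '", reference_id, "' not found among alignment rows")
  structure(
    list(ids = names(seqs), seqs = as.vector(unname(seqs)),
         reference_id = reference_id),
    class = "aa_alignment"
  )
}

#' Read an aligned FASTA file into an alignment object
#'
#' @inheritParams read_fasta
#' @param reference_id Id of the reference (target) row; must be present.
#' @export
read_alignment <- function(path, reference_id) {
  alignment(read_fasta(path), reference_id)
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat("Amino-acid alignment:", length(x$ids), "rows x",
      nchar(x$seqs[1]), "columns; reference:", x$reference_id, "\n")
  invisible(x)
}

#' Remove gap characters from a sequence
#'
#' @param x Character vector of gapped sequences.
#' @return Ungapped sequences.
#' @export
ungap <- function(x) gsub("-", "", x, fixed = TRUE)

alignment_row <- function(aln, id) {
  i <- match(id, aln$ids)
  if (is.na(i)) stop("row '", id, "' not in alignment")
  aln$seqs[i]
}

alignment_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seqs, ""))
  rownames(m) <- aln$ids
  m
}

subset_alignment <- function(aln, ids) {
  keep <- match(ids, aln$ids)
  alignment(stats::setNames(aln$seqs[keep], aln$ids[keep]), aln$reference_id)
}
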