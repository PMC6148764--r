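#' Detect hydrogen bonds and salt bridges
#'
#' Geometric criteria on heavy atoms: a hydrogen bond is any
#' nitrogen/oxygen pair from different residues within `hbond_cutoff`
#' (default 3.5 Angstrom), excluding covalently bonded and 1-3 pairs
#' (in practice, the backbone `O(i)`–`N(i+1)` pair across a peptide
#' bond); a salt bridge is a side-chain nitrogen of Lys/Arg/His within
#' `salt_cutoff` (default 4.0) of a side-chain carboxylate oxygen of
#' Asp/Glu. Each interaction is listed once with its distance; a salt
#' bridge pair is not additionally reported as a hydrogen bond.
#'
#' @param model A `structure_model`.
#' @param hbond_cutoff,salt_cutoff Distance cutoffs in Angstrom.
#' @return Data frame: `type` (`"hbond"`/`"salt_bridge"`), `chain1`,
#'   `resno1`, `resid1`, `atom1`, `sidechain1`, same for partner 2,
#'   `distance`.
#' @export
detect_interactions <- function(model, hbond_cutoff = 3.5, salt_cutoff = 4.0) {
  stopifnot(inherits(model, "structure_model"))
  prot <- model[!model$het, , drop = FALSE]
  no <- which(prot$element %in% c("N", "O"))
  if (length(no) < 2L)
    return(data.frame(type = character(0), chain1 = character(0),
                      resno1 = integer(0), resid1 = character(0),
                      atom1 = character(0), sidechain1 = logical(0),
                      chain2 = character(0), resno2 = integer(0),
                      resid2 = character(0), atom2 = character(0),
                      sidechain2 = logical(0), distance = numeric(0)))
  sub <- prot[no, , drop = FALSE]
  xyz <- as.matrix(sub[, c("x", "y", "z")])
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * xyz %*% t(xyz)
  d2[d2 < 0] <- 0
  n <- nrow(sub)
  rows <- list()
  maxcut2 <- max(hbond_cutoff, salt_cutoff)^2
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      if (d2[i, j] > maxcut2) next
      a <- sub[i, ]; b <- sub[j, ]
      same_res <- a$chain == b$chain && a$resno == b$resno
      if (same_res) next
      dist <- sqrt(d2[i, j])
      # salt bridge check first (takes precedence over plain H-bond)
      sb <- function(p, q) {
        p$resid %in% AA_THREE[SIDECHAIN_POSITIVE] &&
          p$atom_name %in% SALT_BRIDGE_N &&
          q$resid %in% AA_THREE[SIDECHAIN_NEGATIVE] &&
          q$atom_name %in% SALT_BRIDGE_O
      }
      type <- NULL
      if (dist <= salt_cutoff && (sb(a, b) || sb(b, a))) {
        type <- "salt_bridge"
      } else if (dist <= hbond_cutoff) {
        # exclude the peptide-bond 1-3 pair O(i)-N(i+1)
        adjacent <- a$chain == b$chain && abs(a$resno - b$resno) == 1L
        lower <- if (a$resno < b$resno) a else b
        upper <- if (a$resno < b$resno) b else a
        peptide13 <- adjacent && lower$atom_name == "O" && upper$atom_name == "N"
        if (!peptide13) type <- "hbond"
      }
      if (is.null(type)) next
      rows[[length(rows) + 1L]] <- data.frame(
        type = type,
        chain1 = a$chain, resno1 = a$resno, resid1 = a$resid,
        atom1 = a$atom_name, sidechain1 = !(a$atom_name %in% BACKBONE_ATOMS),
        chain2 = b$chain, resno2 = b$resno, resid2 = b$resid,
        atom2 = b$atom_name, sidechain2 = !(b$atom_name %in% BACKBONE_ATOMS),
        distance = dist, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) return(detect_interactions(model[0, , drop = FALSE]))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## Interactions in which residue `resno` participates through a
## side-chain atom.
sidechain_interactions_of <- function(interactions, resno, chain = NULL) {
  on1 <- interactions$resno1 == resno & interactions$sidechain1
  on2 <- interactions$resno2 == resno & interactions$sidechain2
  if (!is.null(chain)) {
    on1 <- on1 & interactions$chain1 == chain
    on2 <- on2 & interactions$chain2 == chain
  }
  interactions[on1 | on2, , drop = FALSE]
}
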