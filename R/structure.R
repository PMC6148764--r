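#' Read a structural model from PDB
#'
#' Parses ATOM/HETATM records via \pkg{bio3d} with a defined policy on
#' top: only the first MODEL is kept; where alternate locations exist,
#' the highest-occupancy altloc wins (ties go to altloc `A`); HETATM
#' records (metal cofactors in particular) are retained. Coordinate
#' fields are validated before parsing so malformed lines are reported
#' with their line number.
#'
#' @param path Path to a PDB file (ignored when `text` is given).
#' @param text Optional character vector of PDB lines instead of a file.
#' @return A `structure_model`: data frame with columns `serial`,
#'   `atom_name`, `altloc`, `resid`, `chain`, `resno`, `x`, `y`, `z`,
#'   `occupancy`, `element`, `het`.
#' @export
read_structure <- function(path = NULL, text = NULL) {
  if (is.null(text)) text <- readLines(path, warn = FALSE)
  endmdl <- grep("^ENDMDL", text)
  if (length(endmdl)) text <- text[seq_len(endmdl[1] - 1L)]
  rec <- grep("^(ATOM  |HETATM)", text)
  if (!length(rec)) stop("no ATOM/HETATM records found")
  for (i in rec) {
    coords <- substr(text[i], 31, 54)
    vals <- suppressWarnings(as.numeric(c(substr(coords, 1, 8),
                                          substr(coords, 9, 16),
                                          substr(coords, 17, 24))))
    if (anyNA(vals) || any(!is.finite(vals)))
      stop("malformed coordinate fields at line ", i)
  }
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(text, tmp)
  pdb <- bio3d::read.pdb(tmp, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  a <- pdb$atom
  elem <- toupper(trimws(a$elesy))
  guess <- toupper(substr(trimws(a$elety), 1, 1))
  elem[is.na(elem) | elem == ""] <- guess[is.na(elem) | elem == ""]
  m <- data.frame(
    serial = a$eleno, atom_name = trimws(a$elety),
    altloc = ifelse(is.na(a$alt) | a$alt == "", "", a$alt),
    resid = trimws(a$resid), chain = ifelse(is.na(a$chain), "A", a$chain),
    resno = a$resno, x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o), element = elem,
    het = a$type == "HETATM", stringsAsFactors = FALSE
  )
  # altloc resolution: highest occupancy, ties to alphabetically first altloc
  key <- paste(m$chain, m$resno, m$resid, m$atom_name, sep = "|")
  ord <- order(key, -m$occupancy, m$altloc)
  m <- m[ord, , drop = FALSE]
  m <- m[!duplicated(key[ord]), , drop = FALSE]
  m <- m[order(m$serial), , drop = FALSE]
  rownames(m) <- NULL
  class(m) <- c("structure_model", "data.frame")
  m
}

#' Write a structural model to PDB
#'
#' @param model A `structure_model`.
#' @param path Output path.
#' @export
write_structure <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  xyz <- as.vector(t(as.matrix(model[, c("x", "y", "z")])))
  bio3d::write.pdb(
    file = path, xyz = xyz, type = ifelse(model$het, "HETATM", "ATOM"),
    resno = model$resno, resid = model$resid, eleno = model$serial,
    elety = model$atom_name, chain = model$chain, o = model$occupancy,
    b = rep(0, nrow(model)), elesy = model$element
  )
  invisible(path)
}

#' Resolve an active-site specification to structure atoms
#'
#' The active site must be supplied by the user — typically the catalytic
#' metal plus its liganding residues. Selections are unioned.
#'
#' @param model A `structure_model`.
#' @param resno Residue numbers whose atoms belong to the site.
#' @param chain Optional chain restriction for `resno` selections.
#' @param elements Element symbols selecting atoms directly (e.g. `"FE"`
#'   for the catalytic iron).
#' @param serials Explicit atom serial numbers.
#' @return An `active_site` object: list with `atom_idx` (row indices
#'   into the model) and the original selections.
#' @export
active_site <- function(model, resno = NULL, chain = NULL,
                        elements = NULL, serials = NULL) {
  stopifnot(inherits(model, "structure_model"))
  idx <- integer(0)
  if (!is.null(resno)) {
    sel <- model$resno %in% resno
    if (!is.null(chain)) sel <- sel & model$chain %in% chain
    if (!any(sel)) stop("active-site residues ", paste(resno, collapse = ","),
                        " resolve to no atoms")
    idx <- c(idx, which(sel))
  }
  if (!is.null(elements)) {
    sel <- model$element %in% toupper(elements)
    if (!any(sel)) stop("active-site elements ", paste(elements, collapse = ","),
                        " resolve to no atoms")
    idx <- c(idx, which(sel))
  }
  if (!is.null(serials)) {
    sel <- match(serials, model$serial)
    if (anyNA(sel)) stop("active-site serials not found: ",
                         paste(serials[is.na(sel)], collapse = ","))
    idx <- c(idx, sel)
  }
  idx <- sort(unique(idx))
  if (!length(idx)) stop("active-site specification resolves to no atoms")
  structure(list(atom_idx = idx,
                 spec = list(resno = resno, chain = chain,
                             elements = elements, serials = serials)),
            class = "active_site")
}

#' Minimum distance from a residue to the active site
#'
#' Minimum Euclidean distance over all (residue atom, site atom) pairs;
#' the residue's own atoms are excluded from the site if the selections
#' overlap. `mode = "ca"` restricts the residue side to its C-alpha.
#'
#' @param model A `structure_model`.
#' @param resno Residue number of the query residue.
#' @param site An [active_site()] object.
#' @param chain Optional chain of the query residue.
#' @param mode `"atom"` (all atoms, default) or `"ca"`.
#' @return Distance in Angstrom.
#' @export
min_distance_to_active_site <- function(model, resno, site, chain = NULL,
                                        mode = c("atom", "ca")) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "structure_model"), inherits(site, "active_site"))
  res_sel <- model$resno == resno & !model$het
  if (!is.null(chain)) res_sel <- res_sel & model$chain == chain
  if (mode == "ca") res_sel <- res_sel & model$atom_name == "CA"
  res_idx <- which(res_sel)
  if (!length(res_idx)) stop("residue ", resno, " has no atoms in the model")
  site_idx <- setdiff(site$atom_idx, res_idx)
  if (!length(site_idx)) stop("active site is empty after excluding the residue's own atoms")
  A <- as.matrix(model[res_idx, c("x", "y", "z")])
  B <- as.matrix(model[site_idx, c("x", "y", "z")])
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(max(0, min(d2)))
}

atom_radii <- function(model, radii) {
  r <- radii[model$element]
  if (anyNA(r)) {
    bad <- which(is.na(r))[1]
    stop("no van der Waals radius for element '", model$element[bad],
         "' (atom serial ", model$serial[bad], ")")
  }
  unname(r)
}

golden_spiral <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake–Rupley solvent-accessible surface area
#'
#' Rolls a probe sphere over the structure using a deterministic
#' golden-spiral point set on each expanded atom sphere: a point is
#' solvent-accessible if it lies outside every neighboring atom's
#' expanded sphere. Per-atom SASA is the exposed point fraction times
#' the expanded sphere area `4*pi*(r + probe)^2`.
#'
#' @param model A `structure_model`.
#' @param probe_radius Solvent probe radius in Angstrom (water: 1.4).
#' @param n_points Test points per atom; 960 gives ~1-2% accuracy.
#' @param radii Named vector of van der Waals radii by element; defaults
#'   to a Bondi-style table.
#' @return List: `atom_sasa` (numeric vector, Angstrom^2), `residue_sasa`
#'   (data frame `chain`, `resno`, `resid`, `sasa`), `total`.
#' @export
shrake_rupley_sasa <- function(model, probe_radius = 1.4, n_points = 960L,
                               radii = VDW_RADII) {
  stopifnot(inherits(model, "structure_model"))
  n <- nrow(model)
  rad <- atom_radii(model, radii) + probe_radius
  xyz <- as.matrix(model[, c("x", "y", "z")])
  pts <- golden_spiral(n_points)
  atom_sasa <- numeric(n)
  for (i in seq_len(n)) {
    dc <- sqrt(rowSums((xyz - matrix(xyz[i, ], n, 3, byrow = TRUE))^2))
    nb <- which(dc < rad[i] + rad & seq_len(n) != i)
    if (!length(nb)) {
      exposed <- n_points
    } else {
      P <- pts * rad[i]
      P <- sweep(P, 2, xyz[i, ], "+")
      buried <- rep(FALSE, n_points)
      for (j in nb) {
        dj2 <- (P[, 1] - xyz[j, 1])^2 + (P[, 2] - xyz[j, 2])^2 +
               (P[, 3] - xyz[j, 3])^2
        buried <- buried | dj2 < rad[j]^2
        if (all(buried)) break
      }
      exposed <- sum(!buried)
    }
    atom_sasa[i] <- exposed / n_points * 4 * pi * rad[i]^2
  }
  key <- paste(model$chain, model$resno, sep = "|")
  agg <- stats::aggregate(atom_sasa, by = list(key = key), FUN = sum)
  first <- !duplicated(key)
  res <- data.frame(chain = model$chain[first], resno = model$resno[first],
                    resid = model$resid[first],
                    key = key[first], stringsAsFactors = FALSE)
  res$sasa <- agg$x[match(res$key, agg$key)]
  res$key <- NULL
  list(atom_sasa = atom_sasa, residue_sasa = res, total = sum(atom_sasa))
}

#' Classify a residue as surface, core, or intermediate
#'
#' Relative SASA is the residue's SASA divided by its theoretical maximum
#' in an extended Gly-X-Gly tripeptide. Classification thresholds follow
#' common convention: surface at relative SASA >= 0.25, core at <= 0.10
#' (boundary inclusive), intermediate otherwise.
#'
#' @param residue_sasa Residue SASA in Angstrom^2.
#' @param resid Residue type (1- or 3-letter code).
#' @param max_sasa_table Named max-SASA table (1-letter names).
#' @param surface_threshold,core_threshold Relative-SASA cutoffs.
#' @return List with `relative_sasa` and `location_class`.
#' @export
classify_location <- function(residue_sasa, resid,
                              max_sasa_table = MAX_SASA_GXG,
                              surface_threshold = 0.25,
                              core_threshold = 0.10) {
  aa <- if (nchar(resid) == 3) unname(AA_ONE[toupper(resid)]) else toupper(resid)
  if (is.na(aa) || !aa %in% names(max_sasa_table))
    stop("no max-SASA table entry for residue type '", resid, "'")
  rel <- residue_sasa / max_sasa_table[[aa]]
  cls <- if (rel >= surface_threshold) "surface"
         else if (rel <= core_threshold) "core"
         else "intermediate"
  list(relative_sasa = unname(rel), location_class = cls)
}
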