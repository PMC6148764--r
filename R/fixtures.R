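## Run code with a temporarily seeded RNG, restoring global RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(code)
}

#' Simulate a gapless homolog family at fixed identities
#'
#' For each requested identity, exactly `round((1 - id/100) * L)`
#' positions of the reference are substituted (chosen uniformly without
#' replacement; replacement residue uniform over the other 19 amino
#' acids). No indels are introduced, so the family is its own exact
#' alignment. A designated column can be forced to a chosen consensus
#' fraction: `round(fraction * n_rows)` homologs receive `aa` there and
#' the remaining homologs a fixed different residue, letting consensus
#' tests construct exact frequencies.
#'
#' @param reference Ungapped reference sequence (string).
#' @param identities Percent identities in (0, 100], one per homolog.
#' @param seed RNG seed; identical inputs give identical families.
#' @param ref_id Reference row id.
#' @param forced_column Optional `list(column =, aa =, fraction =)`.
#' @return An [alignment()] with the reference as first row and homologs
#'   `HOM001`, `HOM002`, ...
#' @export
simulate_homolog_family <- function(reference, identities, seed = 1L,
                                    ref_id = "TARGET", forced_column = NULL) {
  reference <- toupper(reference)
  L <- nchar(reference)
  refv <- strsplit(reference, "")[[1]]
  if (any(identities <= 0 | identities > 100))
    stop("identities must lie in (0, 100]")
  n_sub <- round((1 - identities / 100) * L)
  if (any(n_sub > L)) stop("substitution count exceeds sequence length")
  with_seed(seed, {
    seqs <- vapply(seq_along(identities), function(i) {
      v <- refv
      if (n_sub[i] > 0) {
        pos <- sample.int(L, n_sub[i])
        v[pos] <- vapply(v[pos], function(aa) sample(setdiff(AA20, aa), 1L),
                         character(1))
      }
      paste(v, collapse = "")
    }, character(1))
    names(seqs) <- sprintf("HOM%03d", seq_along(seqs))
    rows <- c(stats::setNames(reference, ref_id), seqs)
    if (!is.null(forced_column)) {
      fc <- forced_column
      if (fc$column < 1 || fc$column > L) stop("forced column out of range")
      n_rows <- length(rows)
      n_force <- round(fc$fraction * n_rows)
      if (n_force > length(seqs))
        stop("forced fraction requires more homolog rows than available")
      other <- setdiff(AA20, c(fc$aa, refv[fc$column]))[1]
      for (i in seq_along(seqs)) {
        substr(rows[i + 1L], fc$column, fc$column) <-
          if (i <= n_force) fc$aa else other
      }
    }
    alignment(rows, ref_id)
  })
}

#' Simulate assay series
#'
#' Model values with multiplicative Gaussian noise,
#' `y = model * (1 + N(0, noise_sd))`, clamped positive; `noise_sd = 0`
#' returns exact model values so every generator is inverted by its
#' fitter.
#'
#' @param kd First-order inactivation rate, 1/min.
#' @param times Sampling times, minutes.
#' @param noise_sd Multiplicative noise standard deviation.
#' @param seed RNG seed (`NULL` uses the current RNG state).
#' @return `simulate_decay`: data frame `time`, `residual_activity`.
#' @export
simulate_decay <- function(kd, times, noise_sd = 0, seed = NULL) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  with_seed(seed, {
    y <- exp(-kd * times)
    if (noise_sd > 0) y <- y * (1 + stats::rnorm(length(y), 0, noise_sd))
    data.frame(time = times, residual_activity = pmax(y, 1e-9))
  })
}

#' @rdname simulate_decay
#' @param tm Melting midpoint, degrees C.
#' @param steepness Transition width parameter, degrees C.
#' @param baselines List with `native` and `denatured`, each
#'   `c(intercept, slope)` of the linear baseline.
#' @param temperatures Scan temperatures, degrees C.
#' @return `simulate_melt`: data frame `temperature`, `signal`.
#' @export
simulate_melt <- function(tm, steepness = 2,
                          baselines = list(native = c(-20, 0.02),
                                           denatured = c(-4, 0.01)),
                          temperatures = seq(20, 90, by = 1),
                          noise_sd = 0, seed = NULL) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (steepness <= 0) stop("steepness must be positive")
  with_seed(seed, {
    y <- melt_model(temperatures, tm, steepness,
                    baselines$native[1], baselines$native[2],
                    baselines$denatured[1], baselines$denatured[2])
    if (noise_sd > 0) y <- y * (1 + stats::rnorm(length(y), 0, noise_sd))
    data.frame(temperature = temperatures, signal = y)
  })
}

#' @rdname simulate_decay
#' @param km Michaelis constant, umol/L.
#' @param vmax Limiting rate (any rate unit).
#' @param substrate Substrate grid, umol/L.
#' @return `simulate_rates`: data frame `substrate`, `rate`.
#' @export
simulate_rates <- function(km, vmax, substrate, noise_sd = 0, seed = NULL) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (km <= 0 || vmax <= 0) stop("km and vmax must be positive")
  with_seed(seed, {
    v <- vmax * substrate / (km + substrate)
    if (noise_sd > 0) v <- v * (1 + stats::rnorm(length(v), 0, noise_sd))
    data.frame(substrate = substrate, rate = pmax(v, 1e-12))
  })
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## Natural-extension (NeRF) placement: atom D bonded to C, with bond
## length r, bond angle theta at C (B-C-D) and dihedral phi (A-B-C-D),
## angles in degrees.
place_atom <- function(a, b, c, r, theta, phi) {
  theta <- theta * pi / 180; phi <- phi * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  n <- cross3(b - a, bc); n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d2 <- c(-r * cos(theta), r * cos(phi) * sin(theta), r * sin(phi) * sin(theta))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Build an ideal alpha-helix toy structure
#'
#' Extends a backbone by internal coordinates at phi = -57, psi = -47,
#' omega = 180 with standard bond lengths and angles, adding C-beta
#' pseudo-side-chains (except glycine). Optionally places a metal ion
#' (HETATM `FE`) at a stated distance from a chosen residue's outermost
#' atom, to exercise active-site proximity rules. Coordinates are
#' rounded to 3 decimals so written PDB files round-trip exactly.
#'
#' @param n_residues Helix length (>= 4).
#' @param sequence Optional 1-letter sequence (defaults to poly-Ala).
#' @param with_metal_site Place the metal ion?
#' @param metal_distance Distance (Angstrom) from the anchor residue's
#'   C-beta (C-alpha for Gly) to the metal.
#' @param metal_residue Anchor residue number (default: middle residue).
#' @return A `structure_model`.
#' @export
make_toy_structure <- function(n_residues, sequence = NULL,
                               with_metal_site = FALSE,
                               metal_distance = 4.2, metal_residue = NULL) {
  if (n_residues < 4L) stop("need at least 4 residues")
  if (is.null(sequence)) sequence <- strrep("A", n_residues)
  seqv <- strsplit(toupper(sequence), "")[[1]]
  if (length(seqv) != n_residues) stop("sequence length must equal n_residues")
  if (!all(seqv %in% AA20)) stop("sequence must use the 20 standard residues")

  phi <- -57; psi <- -47; omega <- 180
  N <- list(); CA <- list(); C <- list(); O <- list(); CB <- list()
  N[[1]] <- c(0, 0, 0)
  CA[[1]] <- c(1.458, 0, 0)
  ang <- 111.2 * pi / 180
  C[[1]] <- CA[[1]] + 1.525 * c(-cos(ang), sin(ang), 0)
  for (i in 2:n_residues) {
    N[[i]] <- place_atom(N[[i - 1]], CA[[i - 1]], C[[i - 1]], 1.329, 116.2, psi)
    CA[[i]] <- place_atom(CA[[i - 1]], C[[i - 1]], N[[i]], 1.458, 121.7, omega)
    C[[i]] <- place_atom(C[[i - 1]], N[[i]], CA[[i]], 1.525, 111.2, phi)
  }
  for (i in seq_len(n_residues)) {
    O[[i]] <- if (i < n_residues)
      place_atom(N[[i + 1]], CA[[i]], C[[i]], 1.231, 120.8, 180)
    else place_atom(N[[i]], CA[[i]], C[[i]], 1.231, 120.8, psi + 180)
    CB[[i]] <- if (seqv[i] == "G") NULL
      else place_atom(C[[i]], N[[i]], CA[[i]], 1.53, 110.5, 122.6)
  }

  rows <- list()
  serial <- 0L
  add <- function(name, elem, resno, xyz) {
    serial <<- serial + 1L
    rows[[length(rows) + 1L]] <<- data.frame(
      serial = serial, atom_name = name, altloc = "",
      resid = unname(AA_THREE[seqv[resno]]), chain = "A", resno = resno,
      x = round(xyz[1], 3), y = round(xyz[2], 3), z = round(xyz[3], 3),
      occupancy = 1, element = elem, het = FALSE, stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_residues)) {
    add("N", "N", i, N[[i]])
    add("CA", "C", i, CA[[i]])
    add("C", "C", i, C[[i]])
    add("O", "O", i, O[[i]])
    if (!is.null(CB[[i]])) add("CB", "C", i, CB[[i]])
  }
  model <- do.call(rbind, rows)
  if (with_metal_site) {
    if (is.null(metal_residue)) metal_residue <- n_residues %/% 2L
    anchor <- if (seqv[metal_residue] == "G") CA[[metal_residue]]
              else CB[[metal_residue]]
    base <- CA[[metal_residue]]
    dir <- anchor - base; dir <- dir / sqrt(sum(dir^2))
    pos <- anchor + metal_distance * dir
    model <- rbind(model, data.frame(
      serial = serial + 1L, atom_name = "FE", altloc = "", resid = "FE",
      chain = "A", resno = n_residues + 1L,
      x = round(pos[1], 3), y = round(pos[2], 3), z = round(pos[3], 3),
      occupancy = 1, element = "FE", het = TRUE, stringsAsFactors = FALSE))
  }
  rownames(model) <- NULL
  class(model) <- c("structure_model", "data.frame")
  model
}

#' Append atoms to a structure model
#'
#' Convenience for constructing synthetic interaction geometries (e.g.
#' placing a Lys `NZ` near a Glu `OE1` to create a salt bridge).
#'
#' @param model A `structure_model`.
#' @param atoms Data frame with `atom_name`, `resno`, `x`, `y`, `z`,
#'   `element`; `resid`/`chain` default to the residue's existing values.
#' @return The extended `structure_model`.
#' @export
add_atoms <- function(model, atoms) {
  stopifnot(inherits(model, "structure_model"))
  for (i in seq_len(nrow(atoms))) {
    a <- atoms[i, ]
    existing <- model[!model$het & model$resno == a$resno, ]
    resid <- if (!is.null(atoms$resid) && !is.na(a$resid)) a$resid
             else existing$resid[1]
    chain <- if (!is.null(atoms$chain) && !is.na(a$chain)) a$chain
             else if (nrow(existing)) existing$chain[1] else "A"
    model <- rbind(model, data.frame(
      serial = max(model$serial) + 1L, atom_name = a$atom_name, altloc = "",
      resid = resid, chain = chain, resno = a$resno,
      x = round(a$x, 3), y = round(a$y, 3), z = round(a$z, 3),
      occupancy = 1, element = a$element, het = FALSE,
      stringsAsFactors = FALSE))
  }
  rownames(model) <- NULL
  class(model) <- c("structure_model", "data.frame")
  model
}

#' Engineered candidate set for exercising the full filter pipeline
#'
#' Builds a 20-residue helix with a metal ion 4.2 Angstrom from residue
#' 10, a synthetic Lys3–Glu7 salt bridge (side-chain `NZ`/`OE1` atoms
#' placed between their C-betas), and 14 consensus candidates of which
#' exactly four violate one structural rule each: residue 10 sits inside
#' the 5 Angstrom active-site shell (rule 1), two candidates propose
#' hydrophobic residues at surface positions (rule 2), and the Lys3
#' candidate proposes glycine, which cannot keep the salt bridge
#' (rule 3). The remaining ten candidates pass every rule.
#'
#' @return List: `model` (a `structure_model`), `site` (an
#'   [active_site()]), `candidates` (data frame for
#'   [apply_design_filters()]).
#' @export
make_filter_demo <- function() {
  seqv <- c("N", "A", "K", "S", "N", "Q", "E", "T", "A", "N",
            "A", "S", "N", "T", "Q", "T", "N", "S", "Q", "A")
  model <- make_toy_structure(20, sequence = paste(seqv, collapse = ""),
                              with_metal_site = TRUE, metal_distance = 4.2,
                              metal_residue = 10)
  cb <- function(r) as.numeric(model[model$resno == r & model$atom_name == "CB",
                                     c("x", "y", "z")])
  u <- cb(7) - cb(3); u <- u / sqrt(sum(u^2))
  nz <- cb(3) + 1.7 * u
  oe1 <- cb(7) - 1.6 * u
  model <- add_atoms(model, data.frame(
    atom_name = c("NZ", "OE1"), resno = c(3L, 7L),
    x = c(nz[1], oe1[1]), y = c(nz[2], oe1[2]), z = c(nz[3], oe1[3]),
    element = c("N", "O"), stringsAsFactors = FALSE))
  site <- active_site(model, elements = "FE")
  candidates <- data.frame(
    target_position = c(10L, 4L, 16L, 3L,
                        1L, 5L, 6L, 8L, 12L, 13L, 14L, 15L, 17L, 18L),
    target_aa  = c("N", "S", "T", "K",
                   "N", "N", "Q", "T", "S", "N", "T", "Q", "N", "S"),
    consensus_aa = c("D", "I", "L", "G",
                     "D", "D", "E", "S", "T", "D", "S", "N", "D", "T"),
    frequency = c(0.90, 0.80, 0.80, 0.70,
                  0.65, 0.64, 0.63, 0.62, 0.61, 0.60, 0.59, 0.58, 0.57, 0.56),
    stringsAsFactors = FALSE)
  candidates$mutation <- paste0(candidates$target_aa,
                                candidates$target_position,
                                candidates$consensus_aa)
  list(model = model, site = site, candidates = candidates)
}

#' Emit a fixture bundle from a specification list
#'
#' Writes the inputs the other modules consume — an aligned homolog
#' FASTA, a toy PDB, and decay/melt/rate CSVs — into a directory.
#' Identical specifications produce byte-identical files.
#'
#' @param spec List with `seed` and optional components `family`
#'   (`reference`, `identities`), `structure` (`n_residues`, ...),
#'   `decay` (`kd`, `times`, `noise_sd`), `melt` (`tm`, ...),
#'   `rates` (`km`, `vmax`, `substrate`, ...).
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths.
#' @export
generate_fixture_bundle <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(spec$seed)) 1L else spec$seed
  written <- character(0)
  out <- function(p) { written <<- c(written, p); p }
  if (!is.null(spec$family)) {
    aln <- simulate_homolog_family(spec$family$reference,
                                   spec$family$identities, seed = seed)
    write_fasta(stats::setNames(aln$seqs, aln$ids),
                out(file.path(dir, "family.fasta")))
  }
  if (!is.null(spec$structure)) {
    s <- spec$structure
    model <- make_toy_structure(s$n_residues, sequence = s$sequence,
                                with_metal_site = isTRUE(s$with_metal_site))
    write_structure(model, out(file.path(dir, "structure.pdb")))
  }
  if (!is.null(spec$decay)) {
    d <- spec$decay
    utils::write.csv(simulate_decay(d$kd, d$times, d$noise_sd %||% 0, seed),
                     out(file.path(dir, "decay.csv")), row.names = FALSE)
  }
  if (!is.null(spec$melt)) {
    m <- spec$melt
    utils::write.csv(simulate_melt(m$tm, m$steepness %||% 2,
                                   noise_sd = m$noise_sd %||% 0, seed = seed),
                     out(file.path(dir, "melt.csv")), row.names = FALSE)
  }
  if (!is.null(spec$rates)) {
    r <- spec$rates
    utils::write.csv(simulate_rates(r$km, r$vmax, r$substrate,
                                    r$noise_sd %||% 0, seed),
                     out(file.path(dir, "rates.csv")), row.names = FALSE)
  }
  written
}

`%||%` <- function(a, b) if (is.null(a)) b else a
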