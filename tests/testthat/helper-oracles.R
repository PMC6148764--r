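# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# Random additive distance matrix: draw a random unrooted topology with
# n leaves, random branch lengths, and return its exact path distances.
random_additive_matrix <- function(n, seed) {
  set.seed(seed)
  topos <- ape::unroot(phangorn::allTrees(n, rooted = FALSE))
  tr <- topos[[sample.int(length(topos), 1)]]
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 1.5)
  d <- ape::cophenetic.phylo(tr)
  ord <- sort(rownames(d))
  list(tree = tr, d = d[ord, ord])
}

# Edge incidence of leaf-pair paths: rows = unordered tip pairs (in
# rownames(d) order), cols = tree edges; entry 1 if the edge lies on the
# path between the pair.
path_incidence <- function(tree, ids) {
  tips <- match(ids, tree$tip.label)
  pairs <- utils::combn(seq_along(ids), 2)
  A <- matrix(0, ncol(pairs), nrow(tree$edge))
  for (p in seq_len(ncol(pairs))) {
    np <- ape::nodepath(tree, tips[pairs[1, p]], tips[pairs[2, p]])
    for (s in seq_len(length(np) - 1)) {
      e <- which((tree$edge[, 1] == np[s] & tree$edge[, 2] == np[s + 1]) |
                 (tree$edge[, 1] == np[s + 1] & tree$edge[, 2] == np[s]))
      A[p, e] <- 1
    }
  }
  A
}

# Exhaustive least-squares topology search: fit branch lengths of every
# unrooted topology to d by linear least squares; return the topology
# with the smallest residual sum of squares.
brute_force_ls_topology <- function(d) {
  ids <- rownames(d)
  topos <- ape::unroot(phangorn::allTrees(length(ids), rooted = FALSE))
  best <- NULL; best_rss <- Inf
  for (ti in seq_along(topos)) {
    tr <- topos[[ti]]  # [[ restores tip labels from compressed multiPhylo
    tr$tip.label <- ids[as.integer(sub("t", "", tr$tip.label))]
    A <- path_incidence(tr, ids)
    fit <- stats::lm.fit(A, pair_vector(d))
    rss <- sum(fit$residuals^2)
    if (rss < best_rss) { best_rss <- rss; best <- tr }
  }
  list(tree = best, rss = best_rss)
}

# Distances as a vector in combn(ids, 2) order.
pair_vector <- function(d) {
  pairs <- utils::combn(seq_len(nrow(d)), 2)
  d[cbind(pairs[1, ], pairs[2, ])]
}

same_topology <- function(t1, t2) {
  phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2)) == 0
}

# Analytic solvent-accessible area of two overlapping expanded spheres
# (radii R1, R2, center distance dd): each sphere loses the spherical
# cap buried inside the other.
two_sphere_area <- function(R1, R2, dd) {
  if (dd >= R1 + R2) return(4 * pi * (R1^2 + R2^2))
  h1 <- R1 - (dd^2 + R1^2 - R2^2) / (2 * dd)
  h2 <- R2 - (dd^2 + R2^2 - R1^2) / (2 * dd)
  (4 * pi * R1^2 - 2 * pi * R1 * h1) + (4 * pi * R2^2 - 2 * pi * R2 * h2)
}

# Monte-Carlo full-coverage probability for the NNK scheme.
mc_coverage_nnk <- function(n_colonies, n_rep, seed) {
  set.seed(seed)
  exp_nnk <- expand_degenerate("NNK")
  aa <- Biostrings::GENETIC_CODE[exp_nnk$codons]
  aa_idx <- match(aa, c(consenz:::AA20, "*"))  # 21 = stop
  hits <- vapply(seq_len(n_rep), function(r) {
    draws <- aa_idx[sample.int(length(aa_idx), n_colonies, replace = TRUE)]
    length(unique(draws[draws <= 20])) == 20
  }, logical(1))
  mean(hits)
}

# Minimal single/double-atom structure models for SASA tests.
atom_model <- function(x, y, z, element = "C") {
  structure(data.frame(
    serial = seq_along(x), atom_name = element, altloc = "",
    resid = "UNK", chain = "A", resno = seq_along(x),
    x = x, y = y, z = z, occupancy = 1, element = element, het = FALSE,
    stringsAsFactors = FALSE), class = c("structure_model", "data.frame"))
}
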