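#' Identity-based distance matrix from an alignment
#'
#' @param aln An [alignment()] object with at least 3 rows.
#' @param correction `"identity"` (default): `d = 1 - identity/100`;
#'   `"poisson"`: `d = -ln(identity/100)`, a Poisson multiple-hit
#'   correction.
#' @param policy Identity denominator policy, see [pairwise_identity()].
#' @return Symmetric numeric matrix with zero diagonal, dimnames = row ids.
#' @export
distance_matrix <- function(aln, correction = c("identity", "poisson"),
                            policy = "shared") {
  correction <- match.arg(correction)
  stopifnot(inherits(aln, "aa_alignment"))
  n <- length(aln$ids)
  if (n < 3L) stop("need at least 3 rows for a distance matrix")
  d <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      pid <- pairwise_identity(aln$seqs[i], aln$seqs[j], policy)
      d[i, j] <- d[j, i] <- switch(correction,
        identity = 1 - pid / 100,
        poisson  = -log(max(pid, 1e-8) / 100)
      )
    }
  }
  d
}

check_distance_matrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("distance matrix must be square")
  if (is.null(rownames(d))) stop("distance matrix must have dimnames (ids)")
  if (any(d < 0)) stop("negative distances are not allowed")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be zero")
  invisible(TRUE)
}

quote_label <- function(x) {
  ifelse(grepl("[ ()\\[\\]:;,']", x), paste0("'", gsub("'", "''", x), "'"), x)
}

#' Neighbor-joining tree
#'
#' Classical Saitou–Nei neighbor joining: at each step the pair minimizing
#' the Q-criterion `Q(i,j) = (n-2) d(i,j) - r_i - r_j` is joined, with the
#' standard branch-length and distance-reduction formulas. Two
#' determinism rules make results reproducible: Q ties are broken by the
#' smallest (row, column) index pair in the current matrix order, and
#' negative branch lengths are clamped to zero with the pre-clamp value
#' recorded in attribute `negative_branch_lengths`.
#'
#' @param d Symmetric distance matrix with zero diagonal and ids as
#'   dimnames (e.g. from [distance_matrix()]).
#' @return Unrooted `phylo` tree (class from \pkg{ape}). Attribute
#'   `negative_branch_lengths` is a data frame (`label`, `original`) of
#'   any clamped branches, empty when none occurred.
#' @export
neighbor_joining <- function(d) {
  check_distance_matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  labels <- quote_label(rownames(d))
  active <- as.list(labels)   # newick fragments for current clusters
  D <- unname(d)
  clamped <- data.frame(label = character(0), original = numeric(0),
                        stringsAsFactors = FALSE)
  clamp <- function(x, lab) {
    if (x < 0) {
      clamped[nrow(clamped) + 1L, ] <<- list(lab, x)
      0
    } else x
  }

  while (length(active) > 3L) {
    m <- length(active)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    # smallest index pair (i < j), row-major scan, wins ties
    best <- c(NA_integer_, NA_integer_)
    qmin <- Inf
    for (i in seq_len(m - 1L)) for (j in seq(i + 1L, m)) {
      if (Q[i, j] < qmin) { qmin <- Q[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    bi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- D[i, j] - bi
    bi <- clamp(bi, sprintf("join(%d)", m))
    bj <- clamp(bj, sprintf("join(%d)", m))
    newdist <- (D[i, ] + D[j, ] - D[i, j]) / 2
    merged <- sprintf("(%s:%.12g,%s:%.12g)", active[[i]], bi, active[[j]], bj)
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newdist[keep]),
               c(newdist[keep], 0))
    active <- c(active[keep], merged)
  }

  b1 <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2, "terminal")
  b2 <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2, "terminal")
  b3 <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2, "terminal")
  nwk <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                 active[[1]], b1, active[[2]], b2, active[[3]], b3)
  tree <- ape::read.tree(text = nwk)
  attr(tree, "negative_branch_lengths") <- clamped
  tree
}

## Leaf sets of each connected component after removing `cut` edge rows.
leaf_components <- function(tree, cut_rows) {
  n_nodes <- ape::Ntip(tree) + tree$Nnode
  keep <- setdiff(seq_len(nrow(tree$edge)), cut_rows)
  parent <- seq_len(n_nodes)
  findr <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (e in keep) {
    a <- findr(tree$edge[e, 1]); b <- findr(tree$edge[e, 2])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_len(ape::Ntip(tree)), findr, integer(1))
  split(tree$tip.label, roots)
}

#' Partition a tree's leaves into k groups by cutting long edges
#'
#' Operationalizes "the main branches of the tree": edges are ranked —
#' internal edges first, by decreasing length, then pendant edges by
#' decreasing length, ties by child node index — and cut one at a time,
#' skipping cuts that do not increase the number of leaf-bearing
#' components, until `k` leaf groups exist. With
#' `k <= n_leaves - 2` only internal edges are ever cut (the k-1 longest);
#' larger `k` additionally severs pendant edges so that `k = n` yields
#' singletons.
#'
#' @param tree A `phylo` tree.
#' @param k Number of groups, `1 <= k <= Ntip(tree)`.
#' @return Named list of `k` character vectors of leaf labels (groups
#'   ordered by their first leaf's position in `tip.label`).
#' @export
partition_tree <- function(tree, k) {
  stopifnot(inherits(tree, "phylo"))
  n <- ape::Ntip(tree)
  if (k < 1 || k > n) stop("k must be between 1 and the number of leaves")
  is_internal <- tree$edge[, 2] > n
  len <- tree$edge.length
  ord <- order(!is_internal, -len, tree$edge[, 2])

  cut_rows <- integer(0)
  groups <- leaf_components(tree, cut_rows)
  for (e in ord) {
    if (length(groups) >= k) break
    trial <- c(cut_rows, e)
    trial_groups <- leaf_components(tree, trial)
    if (length(trial_groups) > length(groups)) {
      cut_rows <- trial
      groups <- trial_groups
    }
  }
  if (length(groups) != k)
    stop("could not partition tree into ", k, " leaf groups")
  first_pos <- vapply(groups, function(g) min(match(g, tree$tip.label)), numeric(1))
  groups <- groups[order(first_pos)]
  names(groups) <- paste0("group", seq_along(groups))
  groups
}

#' Select one representative sequence per tree branch group
#'
#' Representatives are group medoids: the leaf minimizing the summed
#' distance to all other members of its group (ties broken by
#' lexicographic id), a deterministic stand-in for "the most relevant
#' sequence" of each main branch.
#'
#' @param tree A `phylo` tree over the ids of `d`.
#' @param d Distance matrix (same ids as tree leaves).
#' @param k Number of groups.
#' @return List with `groups` (from [partition_tree()]) and
#'   `representatives` (named character vector, one id per group).
#' @export
select_representatives <- function(tree, d, k) {
  check_distance_matrix(d)
  if (!setequal(tree$tip.label, rownames(d)))
    stop("tree leaves and distance-matrix ids differ")
  groups <- partition_tree(tree, k)
  reps <- vapply(groups, function(g) {
    g <- sort(g)  # lexicographic tie-break
    sums <- vapply(g, function(id) sum(d[id, g]), numeric(1))
    g[which.min(sums)]
  }, character(1))
  list(groups = groups, representatives = reps)
}

#' Path-length (patristic) distances between tree leaves
#'
#' @param tree A `phylo` tree.
#' @return Symmetric matrix of summed branch lengths between leaf pairs.
#' @export
tree_path_distances <- function(tree) {
  m <- ape::cophenetic.phylo(tree)
  m[tree$tip.label, tree$tip.label]
}
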