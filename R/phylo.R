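#' Kimura two-parameter distance between two aligned DNA sequences
#'
#' `d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)` from the observed transition
#' proportion `P` and transversion proportion `Q` over counted sites.
#' Sites where either sequence has a gap or an ambiguous base are dropped
#' (pairwise deletion at the pair level; for complete deletion drop the
#' columns across the whole alignment first, as [k2p_matrix()] does).
#'
#' @param a,b aligned DNA strings of equal length (`A C G T N -`).
#' @return the distance `d`.
#' @export
k2p_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("sequences must be aligned (equal length)")
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  ok <- av %in% c("A", "C", "G", "T") & bv %in% c("A", "C", "G", "T")
  av <- av[ok]; bv <- bv[ok]
  L <- length(av)
  if (L == 0L) stop("no counted sites after deletion")
  diff <- av != bv
  purine <- c("A", "G")
  transition <- diff & ((av %in% purine) == (bv %in% purine))
  P <- sum(transition) / L
  Q <- sum(diff & !transition) / L
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    stop("K2P distance undefined (saturation): 1-2P-Q = ", signif(w1, 4),
         ", 1-2Q = ", signif(w2, 4))
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' K2P distance matrix for an alignment
#'
#' @param seqs named character vector of aligned DNA sequences.
#' @param deletion `"pairwise"` (drop incomparable sites per pair) or
#'   `"complete"` (drop every column in which any sequence has a gap or
#'   ambiguous base, then compute pairwise).
#' @return symmetric numeric matrix with zero diagonal.
#' @export
k2p_matrix <- function(seqs, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  if (length(unique(nchar(seqs))) != 1L)
    stop("sequences must be aligned (equal length)")
  if (deletion == "complete") {
    m <- do.call(rbind, strsplit(toupper(seqs), ""))
    keep <- colSums(matrix(m %in% c("A", "C", "G", "T"), nrow(m))) == nrow(m)
    if (!any(keep)) stop("no counted sites after complete deletion")
    seqs <- setNames(apply(m[, keep, drop = FALSE], 1, paste,
                           collapse = ""), names(seqs))
  }
  n <- length(seqs)
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    D[i, j] <- D[j, i] <- k2p_distance(seqs[[i]], seqs[[j]])
  }
  D
}

#' Neighbor-joining tree
#'
#' Standard agglomerative neighbor joining: at each step join the pair
#' minimizing `Q(i,j) = (n-2) d(i,j) - r_i - r_j`; branch lengths from the
#' usual three-point formulas; new-node distances by the reduction
#' formula. Ties in the joining criterion are broken by the
#' lexicographically smallest (sorted) pair of cluster labels, a cluster
#' being labelled by its smallest leaf name. Negative branch-length
#' estimates are clamped to zero with the deficit transferred to the
#' sibling edge.
#'
#' @param D symmetric distance matrix with row/col names (>= 3 taxa).
#' @return an unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  labels <- rownames(D)
  if (is.null(labels)) stop("distance matrix must have taxon names")
  n <- nrow(D)
  if (n < 3L) stop("need at least 3 taxa")
  if (any(abs(D - t(D)) > 1e-9)) stop("distance matrix must be symmetric")
  if (any(!is.finite(D))) stop("non-finite distance")
  clamp2 <- function(bi, bj) {
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- max(bi + bj, 0); bj <- 0 }
    c(bi, bj)
  }
  fmt <- function(x) sprintf("%.12g", x)
  nwk <- setNames(labels, labels)          # growing newick fragment
  key <- setNames(labels, labels)          # smallest leaf name per cluster
  act <- labels
  while (length(act) > 3L) {
    m <- length(act)
    d <- D[act, act]
    r <- rowSums(d)
    Qm <- (m - 2) * d - outer(r, r, `+`)
    diag(Qm) <- Inf
    qmin <- min(Qm)
    cand <- which(Qm - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pairs <- apply(cand, 1, function(ij)
      paste(sort(c(key[[act[ij[1]]]], key[[act[ij[2]]]])), collapse = "\r"))
    pick <- cand[order(pairs)[1], ]
    i <- act[pick[1]]; j <- act[pick[2]]
    dij <- D[i, j]
    bi <- dij / 2 + (r[[i]] - r[[j]]) / (2 * (m - 2))
    bj <- dij - bi
    bb <- clamp2(bi, bj)
    new_id <- paste0("(", nwk[[i]], ":", fmt(bb[1]), ",",
                     nwk[[j]], ":", fmt(bb[2]), ")")
    others <- setdiff(act, c(i, j))
    du <- (D[i, others] + D[j, others] - dij) / 2
    D <- rbind(cbind(D, 0), 0)
    rownames(D)[nrow(D)] <- colnames(D)[ncol(D)] <- new_id
    D[new_id, others] <- du
    D[others, new_id] <- du
    nwk[[new_id]] <- new_id
    key[[new_id]] <- min(key[[i]], key[[j]])
    act <- c(others, new_id)
  }
  a <- act[order(c(key[act[1]], key[act[2]], key[act[3]]))]
  ba <- (D[a[1], a[2]] + D[a[1], a[3]] - D[a[2], a[3]]) / 2
  bb <- D[a[1], a[2]] - ba
  bc <- D[a[1], a[3]] - ba
  ba <- max(ba, 0); bb <- max(bb, 0); bc <- max(bc, 0)
  txt <- paste0("(", nwk[[a[1]]], ":", fmt(ba), ",",
                nwk[[a[2]]], ":", fmt(bb), ",",
                nwk[[a[3]]], ":", fmt(bc), ");")
  ape::read.tree(text = txt)
}

#' Bootstrap support for a K2P + NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds the K2P distance
#' matrix and NJ tree for each replicate, and reports for each internal
#' edge of the original tree the fraction of replicates containing the
#' same bipartition. Deterministic for a fixed seed. Replicates whose
#' resampled columns saturate the K2P distance are redrawn (counted and
#' reported).
#'
#' @param seqs named aligned DNA sequences.
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed RNG seed.
#' @param deletion `"pairwise"` or `"complete"` (see [k2p_matrix()]).
#' @return list: `tree` (the original-tree `phylo` with `node.label` set
#'   to support fractions), `support` (numeric per internal node) and
#'   `n_reps`.
#' @export
bootstrap_support <- function(seqs, n_reps = 100, seed = 1,
                              deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  if (n_reps < 1) stop("n_reps must be >= 1")
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("sequences must be aligned")
  if (L < 2L) stop("alignment must have at least 2 columns")
  cols <- do.call(rbind, strsplit(toupper(seqs), ""))
  tree0 <- neighbor_joining(k2p_matrix(seqs, deletion))
  set.seed(seed)
  boot <- vector("list", n_reps)
  failed <- 0L
  for (b in seq_len(n_reps)) {
    repeat {
      idx <- sample.int(L, L, replace = TRUE)
      rs <- setNames(apply(cols[, idx, drop = FALSE], 1, paste,
                           collapse = ""), names(seqs))
      tr <- tryCatch(neighbor_joining(k2p_matrix(rs, deletion)),
                     error = function(e) NULL)
      if (!is.null(tr)) { boot[[b]] <- tr; break }
      failed <- failed + 1L
      if (failed > 100 * n_reps) stop("bootstrap replicates keep failing")
    }
  }
  counts <- ape::prop.clades(tree0, boot, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- counts / n_reps
  tree0$node.label <- sprintf("%g", support)
  list(tree = tree0, support = support, n_reps = n_reps,
       redrawn = failed)
}

#' Write a tree in newick format with integer-percent supports
#'
#' @param tree a `phylo`, or the list returned by [bootstrap_support()].
#' @param path output path.
#' @export
write_tree_newick <- function(tree, path) {
  if (is.list(tree) && !inherits(tree, "phylo") && !is.null(tree$tree)) {
    tr <- tree$tree
    tr$node.label <- sprintf("%d", as.integer(round(100 * tree$support)))
  } else tr <- tree
  ape::write.tree(tr, file = path)
  invisible(path)
}
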