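# Saitou-Nei neighbor joining with the Studier-Keppler Q criterion. NJ is
# exact on additive distance matrices: it returns the generating topology and
# branch lengths. Ties in Q are broken by the lexicographically smallest
# label pair so the result is deterministic without any seed.

#' Build a neighbor-joining tree from a distance matrix
#'
#' Agglomerates with the Studier-Keppler selection criterion
#' `Q(i,j) = (n-2) d(i,j) - R_i - R_j`; branch lengths come from the standard
#' two-point formulas and negative estimates are clamped to zero. The result
#' is the unrooted tree (internal nodes of degree 3, basal trifurcation).
#'
#' @param d an `sts_dist` or a symmetric labeled numeric matrix
#' @return an [ape::phylo] tree (unrooted)
#' @export
#' @examples
#' D <- matrix(c(0,3,5,6, 3,0,6,7, 5,6,0,7, 6,7,7,0), 4, 4,
#'             dimnames = list(c("A","B","C","D"), c("A","B","C","D")))
#' tr <- nj_tree(D)   # recovers split AB|CD with internal edge length 1
nj_tree <- function(d) {
  D <- if (inherits(d, "sts_dist")) d$d else as.matrix(d)
  labels <- rownames(D)
  if (is.null(labels) || !identical(labels, colnames(D)))
    stop("distance matrix must have matching row/column labels")
  if (nrow(D) < 3L) stop("at least 3 taxa are required")
  if (anyNA(D)) {
    bad <- which(is.na(D) & upper.tri(D), arr.ind = TRUE)
    stop("undefined distances for pair(s): ",
         paste(sprintf("%s-%s", labels[bad[, 1]], labels[bad[, 2]]),
               collapse = ", "))
  }
  if (max(abs(D - t(D))) > 1e-12) stop("distance matrix is not symmetric")

  # each active node carries a Newick fragment
  frag <- setNames(labels, labels)
  active <- labels
  merge_count <- 0L
  while (length(active) > 3L) {
    n <- length(active)
    Dm <- D[active, active]
    R <- rowSums(Dm)
    Q <- (n - 2) * Dm - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pairs <- cbind(active[cand[, 1]], active[cand[, 2]])
    pairs <- t(apply(pairs, 1L, sort))
    ord <- order(pairs[, 1], pairs[, 2])
    i <- pairs[ord[1L], 1L]; j <- pairs[ord[1L], 2L]

    dij <- D[i, j]
    bi <- dij / 2 + (R[i] - R[j]) / (2 * (n - 2))
    bj <- dij - bi
    bi <- max(bi, 0); bj <- max(bj, 0)

    merge_count <- merge_count + 1L
    u <- paste0("\x01u", merge_count)   # internal label, cannot clash with taxa
    others <- setdiff(active, c(i, j))
    du <- (D[i, others] + D[j, others] - dij) / 2
    D <- rbind(cbind(D, 0), 0)
    rownames(D)[nrow(D)] <- colnames(D)[ncol(D)] <- u
    D[u, others] <- D[others, u] <- du

    frag[u] <- sprintf("(%s:%.12g,%s:%.12g)", frag[[i]], bi, frag[[j]], bj)
    active <- c(others, u)
  }

  a <- active[1L]; b <- active[2L]; c_ <- active[3L]
  ba <- max((D[a, b] + D[a, c_] - D[b, c_]) / 2, 0)
  bb <- max((D[a, b] + D[b, c_] - D[a, c_]) / 2, 0)
  bc <- max((D[a, c_] + D[b, c_] - D[a, b]) / 2, 0)
  nwk <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                 frag[[a]], ba, frag[[b]], bb, frag[[c_]], bc)
  ape::read.tree(text = nwk)
}

# canonical unrooted bipartitions of a tree: for every internal edge, the
# sorted leaf set on the side not containing the alphabetically first leaf,
# serialized as a single string; trivial splits are dropped
tree_splits <- function(tree) {
  tips <- sort(tree$tip.label)
  ref <- tips[1L]
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  out <- character()
  for (p in parts) {
    side <- labs[p]
    if (ref %in% side) side <- setdiff(tips, side)
    if (length(side) < 2L || length(side) > length(tips) - 2L) next
    out <- c(out, paste(sort(side), collapse = "|"))
  }
  unique(out)
}
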