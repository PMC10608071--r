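# Column bootstrap for distance/NJ trees: resample alignment columns with
# replacement, rebuild the tree per replicate, and report for each internal
# edge of the full-data tree the fraction of replicate trees containing the
# same bipartition. Replicate r draws its RNG state from substream_seed(seed,
# r), so supports are reproducible and independent of replicate order.

#' Bootstrap bipartition supports for a distance/NJ tree
#'
#' @param aln named character vector of equal-length gapped sequences
#' @param n_reps number of bootstrap replicates (>= 1)
#' @param seed master integer seed
#' @param model distance model, as in [dist_matrix()]
#' @param jtt optional preloaded [jtt_model()] (loaded on demand)
#' @return list with `tree` (the full-data NJ tree, supports attached as
#'   internal node labels), `supports` (data.frame `split`, `support`),
#'   `n_reps`, `n_completed` (replicates with a defined distance matrix)
#' @export
bootstrap_support <- function(aln, n_reps, seed = 1,
                              model = c("p", "poisson", "jtt-ml"), jtt = NULL) {
  model <- match.arg(model)
  stopifnot(n_reps >= 1)
  if (model == "jtt-ml" && is.null(jtt)) jtt <- jtt_model()
  L <- unique(nchar(aln))
  stopifnot(length(L) == 1L)
  full_tree <- nj_tree(dist_matrix(aln, model, jtt))
  splits <- tree_splits(full_tree)
  hits <- setNames(numeric(length(splits)), splits)
  completed <- 0L
  chars <- strsplit(aln, "")
  for (r in seq_len(n_reps)) {
    set.seed(substream_seed(seed, r))
    cols <- sample.int(L, L, replace = TRUE)
    rep_aln <- vapply(chars, function(x) paste(x[cols], collapse = ""), "")
    D <- dist_matrix(rep_aln, model, jtt)
    if (anyNA(D$d)) {
      message("bootstrap replicate ", r, " skipped: undefined pair")
      next
    }
    completed <- completed + 1L
    rs <- tree_splits(nj_tree(D))
    found <- splits %in% rs
    hits[found] <- hits[found] + 1
  }
  if (completed == 0L) stop("no bootstrap replicate completed")
  supports <- hits / completed

  # attach supports as internal node labels of the full-data tree
  ntip <- length(full_tree$tip.label)
  parts <- ape::prop.part(full_tree)
  labs <- attr(parts, "labels")
  tips <- sort(full_tree$tip.label)
  ref <- tips[1L]
  node_lab <- character(full_tree$Nnode)
  for (k in seq_along(parts)) {
    side <- labs[parts[[k]]]
    if (ref %in% side) side <- setdiff(tips, side)
    if (length(side) < 2L || length(side) > ntip - 2L) { node_lab[k] <- ""; next }
    key <- paste(sort(side), collapse = "|")
    node_lab[k] <- formatC(supports[[key]], digits = 3, format = "f")
  }
  full_tree$node.label <- node_lab

  list(tree = full_tree,
       supports = data.frame(split = names(supports),
                             support = unname(supports),
                             stringsAsFactors = FALSE),
       n_reps = n_reps, n_completed = completed)
}
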