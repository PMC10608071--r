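# Clade assignment of query STS sequences against the reference alignment,
# plus product-profile prediction from nearest reference enzymes. A query may
# arrive pre-aligned (same width as the reference alignment) or unaligned, in
# which case it is threaded into the reference coordinate frame by pairwise
# alignment against the reference consensus.

# majority consensus of the reference alignment, gap columns excluded,
# with the mapping from consensus positions back to alignment columns
reference_consensus <- function(ref_aln) {
  mat <- do.call(rbind, strsplit(unname(ref_aln), ""))
  cons <- apply(mat, 2L, function(col) {
    col <- col[!col %in% c("-", ".", "X")]
    if (!length(col)) return(NA_character_)
    names(sort(table(col), decreasing = TRUE))[1L]
  })
  keep <- which(!is.na(cons))
  list(seq = paste(cons[keep], collapse = ""), columns = keep)
}

#' Thread an unaligned query into the reference alignment frame
#'
#' Globally aligns the query against the majority consensus of the reference
#' alignment (BLOSUM62, affine gaps) and writes the query residues into the
#' consensus's alignment columns. Query residues inserted relative to the
#' consensus are dropped; deleted consensus positions become gaps. A query
#' whose length already equals the alignment width is assumed pre-aligned and
#' returned unchanged.
#'
#' @param query single (named) protein sequence
#' @param ref_aln named character vector, the reference alignment
#' @return gapped query row of the reference alignment width
#' @export
map_query_to_alignment <- function(query, ref_aln) {
  width <- unique(nchar(ref_aln))
  stopifnot(length(width) == 1L)
  q <- toupper(query[[1L]])
  if (nchar(q) == width) return(q)   # assume pre-aligned
  cons <- reference_consensus(ref_aln)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(q), Biostrings::AAString(cons$seq),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global")
  pq <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  ps <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  out <- rep("-", width)
  cpos <- 0L
  for (k in seq_along(ps)) {
    if (ps[k] != "-") {
      cpos <- cpos + 1L
      if (pq[k] != "-") out[cons$columns[cpos]] <- pq[k]
    }
  }
  paste(out, collapse = "")
}

#' Assign a query sequence to an STS clade
#'
#' Distance-based placement of a query against the clade-labeled reference
#' alignment. `"nn"` takes the clade of the single nearest reference
#' (confidence `1 - d1/d2`, clamped to `[0, 1]`); `"knn"` (default) takes the
#' majority clade of the `k` nearest (ties broken by smallest mean distance,
#' then lexicographic clade label; confidence is the vote share);
#' `"placement"` inserts the query into a neighbor-joining tree of the
#' references and takes the majority clade of the query's sister group, with
#' confidence the share of bootstrap replicates agreeing (requires
#' `n_boot > 0`, otherwise `NA`).
#'
#' @param query single (named) protein sequence, aligned or not
#' @param ref_aln named character vector: reference alignment rows keyed by
#'   reference gene name
#' @param clades named character vector mapping reference gene names to
#'   clade labels `"I"`..`"IV"`
#' @param method `"knn"`, `"nn"`, or `"placement"`
#' @param k neighborhood size for knn
#' @param model distance model (see [dist_matrix()])
#' @param jtt optional preloaded JTT model
#' @param n_boot bootstrap replicates for placement confidence
#' @param seed seed for the placement bootstrap
#' @return an `sts_clade_assignment`: list with `query_id`, `clade`,
#'   `method`, `neighbors` (data.frame `gene_name`, `distance`, `clade`,
#'   ascending), `confidence`
#' @export
assign_clade <- function(query, ref_aln, clades,
                         method = c("knn", "nn", "placement"), k = 5,
                         model = c("p", "poisson", "jtt-ml"), jtt = NULL,
                         n_boot = 0, seed = 1) {
  method <- match.arg(method)
  model <- match.arg(model)
  stopifnot(is.character(query), length(query) == 1L,
            all(names(ref_aln) %in% names(clades)))
  qid <- names(query) %||% "query"
  if (model == "jtt-ml" && is.null(jtt)) jtt <- jtt_model()
  qrow <- map_query_to_alignment(query, ref_aln)

  fun <- switch(model, p = p_distance, poisson = poisson_distance,
                `jtt-ml` = function(a, b) jtt_ml_distance(a, b, jtt))
  dvec <- vapply(ref_aln, function(r) fun(qrow, r), numeric(1))
  if (all(is.na(dvec)))
    stop("query has zero comparable sites against every reference")
  nb <- data.frame(gene_name = names(ref_aln), distance = unname(dvec),
                   clade = unname(clades[names(ref_aln)]),
                   stringsAsFactors = FALSE)
  nb <- nb[!is.na(nb$distance), , drop = FALSE]
  nb <- nb[order(nb$distance, nb$gene_name), , drop = FALSE]
  row.names(nb) <- NULL

  if (method == "nn") {
    clade <- nb$clade[1L]
    conf <- if (nrow(nb) >= 2L && nb$distance[2L] > 0)
      min(max(1 - nb$distance[1L] / nb$distance[2L], 0), 1) else 1
  } else if (method == "knn") {
    top <- head(nb, k)
    votes <- table(top$clade)
    best <- names(votes)[votes == max(votes)]
    if (length(best) > 1L) {
      means <- vapply(best, function(cl)
        mean(top$distance[top$clade == cl]), numeric(1))
      best <- best[means == min(means)]
      best <- sort(best)
    }
    clade <- best[1L]
    conf <- max(votes) / sum(votes)
  } else {
    res <- placement_clade(qid, qrow, ref_aln, clades, model, jtt)
    clade <- res
    conf <- NA_real_
    if (n_boot > 0) {
      agree <- 0L; done <- 0L
      L <- nchar(qrow)
      qchars <- strsplit(qrow, "")[[1]]
      rchars <- strsplit(ref_aln, "")
      for (r in seq_len(n_boot)) {
        set.seed(substream_seed(seed, r))
        cols <- sample.int(L, L, replace = TRUE)
        qa <- paste(qchars[cols], collapse = "")
        ra <- vapply(rchars, function(x) paste(x[cols], collapse = ""), "")
        cl_r <- tryCatch(placement_clade(qid, qa, ra, clades, model, jtt),
                         error = function(e) NA_character_)
        if (is.na(cl_r)) next
        done <- done + 1L
        if (cl_r == clade) agree <- agree + 1L
      }
      conf <- if (done > 0L) agree / done else NA_real_
    }
  }
  structure(list(query_id = qid, clade = clade, method = method,
                 neighbors = nb, confidence = conf),
            class = "sts_clade_assignment")
}

# NJ placement: build the tree of references + query, find the query tip's
# attachment node, and vote over the smaller adjacent leaf set (the query's
# sister group); ties by lexicographic clade label
placement_clade <- function(qid, qrow, ref_aln, clades, model, jtt) {
  aln <- c(ref_aln, setNames(qrow, qid))
  D <- dist_matrix(aln, model, jtt)
  tr <- nj_tree(D)
  tip <- which(tr$tip.label == qid)
  parent <- tr$edge[tr$edge[, 2] == tip, 1]
  # leaf sets of the two non-query subtrees around the attachment node
  kids <- tr$edge[tr$edge[, 1] == parent, 2]
  kids <- setdiff(kids, tip)
  up <- tr$edge[tr$edge[, 2] == parent, 1]   # may be empty at basal node
  groups <- lapply(kids, function(nd) tip_labels_below(tr, nd))
  all_tips <- setdiff(tr$tip.label, qid)
  covered <- unlist(groups)
  rest <- setdiff(all_tips, covered)
  if (length(rest)) groups <- c(groups, list(rest))
  sizes <- vapply(groups, length, 1L)
  sister <- groups[[order(sizes, vapply(groups, function(g) sort(g)[1], ""))[1L]]]
  votes <- table(clades[sister])
  sort(names(votes)[votes == max(votes)])[1L]
}

# tips in the subtree below a node (tree treated as rooted at its base)
tip_labels_below <- function(tr, node) {
  ntip <- length(tr$tip.label)
  if (node <= ntip) return(tr$tip.label[node])
  acc <- character()
  stack <- node
  while (length(stack)) {
    nd <- stack[[1L]]; stack <- stack[-1L]
    kids <- tr$edge[tr$edge[, 1] == nd, 2]
    tips <- kids[kids <= ntip]
    acc <- c(acc, tr$tip.label[tips])
    stack <- c(stack, kids[kids > ntip])
  }
  acc
}

#' @export
print.sts_clade_assignment <- function(x, ...) {
  cat("query", x$query_id, "-> clade", x$clade,
      sprintf("(%s, confidence %.2f)\n", x$method,
              if (is.na(x$confidence)) NA else x$confidence))
  cat("nearest references:\n")
  print(head(x$neighbors, 5), row.names = FALSE)
  invisible(x)
}

#' Predict candidate products from nearest reference enzymes
#'
#' Collects the major (first-listed) products of the `k` nearest reference
#' enzymes that have a usable product list (entries with no detected product
#' or an unknown-sesquiterpene major product are skipped) and ranks
#' candidates by supporting-neighbor count, ties alphabetically. The
#' assignment's clade mechanism annotation is attached.
#'
#' @param assignment an `sts_clade_assignment`
#' @param db an `sts_refdb`
#' @param k how many nearest neighbors to consult
#' @param include_minor also collect rank >= 2 products
#' @return an `sts_prediction`: list with `query_id`, `clade`, `mechanism`,
#'   `candidates` (data.frame `product`, `n_support`), `neighbors_used`,
#'   `empty` flag
#' @export
predict_products <- function(assignment, db, k = 5, include_minor = FALSE) {
  stopifnot(inherits(assignment, "sts_clade_assignment"), inherits(db, "sts_refdb"))
  if (!nrow(assignment$neighbors)) stop("assignment has no neighbors")
  nb <- head(assignment$neighbors, k)
  e <- db$entries
  picked <- character()
  used <- character()
  for (g in nb$gene_name) {
    i <- match(g, e$gene_name)
    if (is.na(i)) next
    p <- e$products_parsed[[i]]
    p <- p[p$flag != "unknown", , drop = FALSE]
    if (!nrow(p)) next
    take <- if (include_minor) p$name else p$name[p$rank == min(p$rank)]
    picked <- c(picked, unique(take))
    used <- c(used, g)
  }
  if (!length(picked)) {
    cand <- data.frame(product = character(), n_support = integer(),
                       stringsAsFactors = FALSE)
    warn <- TRUE
  } else {
    tab <- table(picked)
    cand <- data.frame(product = names(tab), n_support = as.integer(tab),
                       stringsAsFactors = FALSE)
    cand <- cand[order(-cand$n_support, cand$product), , drop = FALSE]
    row.names(cand) <- NULL
    warn <- FALSE
  }
  structure(list(query_id = assignment$query_id, clade = assignment$clade,
                 mechanism = mechanism_for_clade(assignment$clade),
                 candidates = cand, neighbors_used = used, empty = warn),
            class = "sts_prediction")
}

#' @export
print.sts_prediction <- function(x, ...) {
  cat("product prediction for", x$query_id, "- clade", x$clade, "\n")
  cat(sprintf("  mechanism: %s, %s-ring closure via %s\n",
              x$mechanism$substrate, x$mechanism$ring_closure,
              x$mechanism$intermediate))
  if (x$empty) cat("  (no productive neighbor: empty report)\n")
  else print(x$candidates, row.names = FALSE)
  invisible(x)
}
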