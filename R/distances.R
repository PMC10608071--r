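# Pairwise-deletion protein distances. For each sequence pair only alignment
# columns where neither row has a gap (or an ambiguity X) are compared, as in
# the standard "pairwise deletion" treatment of incomplete alignments.

#' Columns comparable between two gapped rows (pairwise deletion)
#'
#' @param a,b equal-length gapped sequences (strings over amino acids, `-`,
#'   `X`)
#' @return strictly increasing 0-based column indices where neither row has a
#'   gap or an `X`
#' @export
pairwise_sites <- function(a, b) {
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  if (length(ca) != length(cb))
    stop("length mismatch: ", length(ca), " vs ", length(cb))
  drop <- c("-", "X", ".")
  which(!(ca %in% drop | cb %in% drop)) - 1L
}

# shared site bookkeeping: comparable-site count and mismatch count
pair_counts <- function(a, b) {
  idx <- pairwise_sites(a, b) + 1L
  ca <- strsplit(toupper(a), "")[[1]][idx]
  cb <- strsplit(toupper(b), "")[[1]][idx]
  list(n = length(idx), mismatches = sum(ca != cb), a = ca, b = cb)
}

#' Proportion of differing residues over pairwise-deleted sites
#'
#' @param a,b equal-length gapped sequences
#' @return p-distance in `[0, 1]`; `NA` when the pair has no comparable site
#' @export
p_distance <- function(a, b) {
  pc <- pair_counts(a, b)
  if (pc$n == 0L) return(NA_real_)
  pc$mismatches / pc$n
}

#' Poisson-corrected distance
#'
#' `d = -log(1 - p)` over pairwise-deleted sites; saturated pairs (`p = 1`)
#' return `Inf`.
#'
#' @inheritParams p_distance
#' @return distance in substitutions per site; `NA` when no comparable site
#' @export
poisson_distance <- function(a, b) {
  p <- p_distance(a, b)
  if (is.na(p)) return(NA_real_)
  if (p >= 1) return(Inf)
  -log(1 - p)
}

#' Maximum-likelihood pairwise distance under the JTT model
#'
#' Maximizes the pairwise log-likelihood
#' `sum over sites of log(pi_i * P_ij(t))` over `t >= 0`, with `P(t)` from
#' the eigendecomposition of the packaged JTT rate matrix, using bracketed
#' scalar optimization (golden section with parabolic interpolation) on
#' `[1e-8, t_max]` at tolerance `1e-6`. Identical sequences return 0.
#'
#' @param a,b equal-length gapped sequences
#' @param model an `sts_model` from [jtt_model()]
#' @param t_max upper bracket for the optimization, default 10
#' @return distance in substitutions per site; `NA` when no comparable site
#' @export
jtt_ml_distance <- function(a, b, model, t_max = 10) {
  stopifnot(inherits(model, "sts_model"))
  pc <- pair_counts(a, b)
  if (pc$n == 0L) return(NA_real_)
  if (pc$mismatches == 0L) return(0)
  ia <- match(pc$a, model$alphabet)
  ib <- match(pc$b, model$alphabet)
  if (anyNA(ia) || anyNA(ib))
    stop("sequence contains letters outside the model alphabet")
  # site-pattern counts: likelihood depends only on the 20x20 pair tally
  counts <- table(factor(ia, levels = 1:20), factor(ib, levels = 1:20))
  counts <- as.matrix(counts)
  nz <- which(counts > 0, arr.ind = TRUE)
  cnt <- counts[nz]
  logpi <- log(model$pi[nz[, 1]])
  negll <- function(t) {
    P <- transition_prob(model, t)
    -sum(cnt * (logpi + log(pmax(P[nz], 1e-300))))
  }
  opt <- stats::optimize(negll, interval = c(1e-8, t_max), tol = 1e-6)
  if (opt$minimum > t_max * (1 - 1e-3))
    stop("jtt_ml_distance did not converge: likelihood still increasing at ",
         "bracket end [1e-8, ", t_max, "], last iterate t = ",
         format(opt$minimum))
  opt$minimum
}

#' Pairwise distance matrix for an alignment
#'
#' @param aln named character vector of equal-length gapped sequences
#' @param model `"p"`, `"poisson"`, or `"jtt-ml"`
#' @param jtt an `sts_model`, loaded on demand when `model = "jtt-ml"`
#' @return an `sts_dist`: list with `labels`, `d` (symmetric matrix,
#'   zero diagonal, `NA` for pairs with no comparable site), `n_sites`
#'   (comparable-site counts), `model`
#' @export
dist_matrix <- function(aln, model = c("p", "poisson", "jtt-ml"), jtt = NULL) {
  model <- match.arg(model)
  stopifnot(is.character(aln), !is.null(names(aln)), !anyDuplicated(names(aln)))
  if (length(unique(nchar(aln))) != 1L) stop("alignment rows differ in length")
  n <- length(aln)
  labels <- names(aln)
  if (model == "jtt-ml" && is.null(jtt)) jtt <- jtt_model()
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  ns <- matrix(nchar(aln[1]), n, n, dimnames = list(labels, labels))
  fun <- switch(model,
                p = p_distance,
                poisson = poisson_distance,
                `jtt-ml` = function(a, b) jtt_ml_distance(a, b, jtt))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d[i, j] <- d[j, i] <- fun(aln[[i]], aln[[j]])
    ns[i, j] <- ns[j, i] <- length(pairwise_sites(aln[[i]], aln[[j]]))
  }
  structure(list(labels = labels, d = d, n_sites = ns, model = model),
            class = "sts_dist")
}

#' @export
print.sts_dist <- function(x, ...) {
  cat("pairwise distance matrix (", x$model, "): ", length(x$labels),
      " sequences", sep = "")
  if (anyNA(x$d)) cat(", ", sum(is.na(x$d[upper.tri(x$d)])), " undefined pairs", sep = "")
  cat("\n")
  invisible(x)
}

#' Write / read a distance matrix as square TSV
#'
#' The layout is PHYLIP-like: a header row of labels, then one row per
#' sequence with its label and distances at 6 decimals.
#'
#' @param x an `sts_dist` (or square labeled matrix for writing)
#' @param path file path
#' @export
write_dist_tsv <- function(x, path) {
  d <- if (inherits(x, "sts_dist")) x$d else x
  m <- cbind(label = rownames(d), format(round(d, 6), trim = TRUE, nsmall = 6))
  write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dist_tsv
#' @export
read_dist_tsv <- function(path) {
  m <- read.delim(path, check.names = FALSE)
  d <- as.matrix(m[, -1, drop = FALSE])
  rownames(d) <- m[[1]]
  storage.mode(d) <- "double"
  if (!identical(rownames(d), colnames(d))) stop("row/column labels differ")
  structure(list(labels = rownames(d), d = d,
                 n_sites = NULL, model = "file"),
            class = "sts_dist")
}
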