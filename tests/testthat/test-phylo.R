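test_that("pairwise deletion drops gap and ambiguity columns", {
  expect_equal(pairwise_sites("AC-D", "A-CD"), c(0L, 3L))
  expect_equal(pairwise_sites("ACDE", "ACDE"), 0:3)
  expect_equal(length(pairwise_sites("----", "AAAA")), 0L)
  # X carries no information: removed alongside gaps
  expect_equal(pairwise_sites("AXCD", "AACD"), c(0L, 2L, 3L))
  expect_error(pairwise_sites("AC", "ACD"), "length mismatch")
})

test_that("p and Poisson distances match their definitions", {
  expect_equal(p_distance("ACDE", "ACDE"), 0)
  expect_equal(p_distance("AC", "AD"), 0.5)
  expect_true(is.na(p_distance("--", "AA")))
  expect_equal(poisson_distance("AC", "AD"), -log(0.5))
  # oracle: direct column count on random gapped pairs
  set.seed(5)
  for (i in 1:20) {
    n <- 80
    a <- strsplit(random_protein(n, c("A", "C", "D", "-")), "")[[1]]
    b <- strsplit(random_protein(n, c("A", "C", "D", "-")), "")[[1]]
    keep <- a != "-" & b != "-"
    exp_p <- if (!any(keep)) NA_real_ else mean(a[keep] != b[keep])
    expect_equal(p_distance(paste(a, collapse = ""), paste(b, collapse = "")),
                 exp_p)
  }
})

test_that("the packaged JTT model satisfies the substitution-model invariants", {
  expect_equal(sum(jtt$pi), 1, tolerance = 1e-9)
  expect_equal(max(abs(rowSums(jtt$Q))), 0, tolerance = 1e-9)
  # unit mean rate at stationarity (distances in substitutions/site)
  expect_equal(-sum(jtt$pi * diag(jtt$Q)), 1, tolerance = 1e-9)
  # detailed balance: pi_i Q_ij = pi_j Q_ji
  F <- diag(jtt$pi) %*% jtt$Q
  expect_lt(max(abs(F - t(F))), 1e-9)
  # P(t) rows are probability distributions; P(0) = I
  P <- transition_prob(jtt, 0.37)
  expect_equal(rowSums(P), rep(1, 20), ignore_attr = TRUE, tolerance = 1e-9)
  expect_true(all(P >= 0))
  expect_equal(transition_prob(jtt, 0), diag(20), ignore_attr = TRUE,
               tolerance = 1e-9)
})

test_that("packaged JTT values agree with an independent encoding of the model", {
  m <- phangorn:::.JTT
  aa <- toupper(names(m$bf))
  S <- matrix(0, 20, 20, dimnames = list(aa, aa))
  S[lower.tri(S)] <- m$Q
  S <- S + t(S)
  raw <- read.delim(sts_extdata("jtt_model.tsv"), row.names = 1, check.names = FALSE)
  expect_equal(as.matrix(raw[1:20, ]), S, ignore_attr = TRUE)
  expect_equal(as.numeric(raw[21, ]) / sum(as.numeric(raw[21, ])),
               unname(m$bf / sum(m$bf)), tolerance = 1e-9)
})

test_that("JTT ML distance recovers simulated divergence and matches phangorn", {
  expect_equal(jtt_ml_distance(strrep("ACDEFGHIKL", 10),
                               strrep("ACDEFGHIKL", 10), jtt), 0,
               tolerance = 1e-6)
  tr <- ape::read.tree(text = "(a:0.15,b:0.15);")
  set.seed(900)
  root <- paste(sample(jtt$alphabet, 2000, TRUE, jtt$pi), collapse = "")
  seqs <- evolve_sequences(tr, root, jtt, seed = 901)
  est <- jtt_ml_distance(seqs[["a"]], seqs[["b"]], jtt)
  expect_equal(est, 0.3, tolerance = 0.1)
  # independent oracle: phangorn's ML distance under the same published model
  pd <- phangorn::phyDat(do.call(rbind, strsplit(seqs, "")), type = "AA")
  oracle <- as.matrix(phangorn::dist.ml(pd, model = "JTT"))[1, 2]
  expect_equal(est, oracle, tolerance = 1e-3)
  # all-gap overlap is undefined, not an error
  expect_true(is.na(jtt_ml_distance("AA--", "--AA", jtt)))
})

test_that("JTT ML distance is monotone in mismatches and linear for small t", {
  base <- strrep("A", 200)
  d_prev <- -1
  for (k in c(1, 4, 8, 16)) {
    other <- paste0(strrep("S", k), strrep("A", 200 - k))
    d <- jtt_ml_distance(base, other, jtt)
    expect_gt(d, d_prev)
    d_prev <- d
  }
  # small-t limit: d approx p for p <= 0.02 (the model's mean rate is 1 at
  # stationarity, so on stationary-composition sequences the correction
  # vanishes as t -> 0)
  tr <- ape::read.tree(text = "(a:0,b:0.015);")
  set.seed(660)
  root <- paste(sample(jtt$alphabet, 10000, TRUE, jtt$pi), collapse = "")
  s <- evolve_sequences(tr, root, jtt, seed = 661)
  p <- p_distance(s[["a"]], s[["b"]])
  expect_lte(p, 0.02)
  d <- jtt_ml_distance(s[["a"]], s[["b"]], jtt)
  expect_equal(d, p, tolerance = 0.05)
})

test_that("neighbor joining solves the worked 4-taxon additive case", {
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- nj_tree(D)
  expect_equal(mushSTS:::tree_splits(tr), "C|D")  # the AB|CD bipartition
  # internal edge length 1; leaf edges 1,2,3,4
  internal <- tr$edge.length[tr$edge[, 2] > length(tr$tip.label)]
  expect_equal(internal, 1)
  expect_equal(sort(tr$edge.length), c(1, 1, 2, 3, 4))
})

test_that("neighbor joining is exact for 3 taxa", {
  D <- matrix(c(0, 2, 3, 2, 0, 5, 3, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D)
  d <- ape::cophenetic.phylo(tr)[c("a", "b", "c"), c("a", "b", "c")]
  expect_equal(d, D, ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("neighbor joining recovers random additive trees exactly", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(4:8, 1)
    t0 <- ape::rtopology(n, rooted = FALSE, br = function(k) runif(k, 0.05, 1))
    D <- additive_matrix(t0)
    tr <- nj_tree(D)
    expect_setequal(mushSTS:::tree_splits(tr), mushSTS:::tree_splits(t0))
    # branch lengths via the path metric
    expect_equal(ape::cophenetic.phylo(tr)[rownames(D), colnames(D)], D,
                 ignore_attr = TRUE, tolerance = 1e-8)
  }
})

test_that("undefined pairs abort tree building with the offending pair named", {
  aln <- c(a = "AAAA", b = "AA--", c = "--AA", d = "ACAA")
  D <- dist_matrix(aln, "p")
  expect_true(is.na(D$d["b", "c"]))
  expect_error(nj_tree(D), "b-c")
})

test_that("trees round-trip through Newick with supports preserved", {
  txt <- "(A:1,B:2,(C:3,D:4)0.87:1);"
  tr <- ape::read.tree(text = txt)
  back <- ape::read.tree(text = ape::write.tree(tr))
  expect_equal(ape::write.tree(back), ape::write.tree(tr))
  expect_true("0.87" %in% back$node.label)
  expect_error(ape::read.tree(text = "(A:1,(B:2;"), "")
})
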