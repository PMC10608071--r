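test_that("random model trees are deterministic and honor the branch mean", {
  t1 <- make_model_tree(8, 0.1, seed = 4)
  t2 <- make_model_tree(8, 0.1, seed = 4)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_setequal(t1$tip.label, paste0("t", 1:8))

  # n = 2: a single leaf-to-leaf path, two exponential draws
  t3 <- make_model_tree(2, 0.1, seed = 1)
  expect_equal(length(t3$tip.label), 2L)
  expect_equal(length(t3$edge.length), 2L)

  expect_error(make_model_tree(1, 0.1), "n_leaves")

  # law of large numbers over many seeded draws
  lens <- unlist(lapply(1:150, function(s)
    make_model_tree(8, 0.1, seed = s)$edge.length))
  expect_equal(mean(lens), 0.1, tolerance = 0.05)
})

test_that("sequence evolution is a faithful CTMC simulation", {
  set.seed(101)
  root <- paste(sample(jtt$alphabet, 500, TRUE, jtt$pi), collapse = "")

  # zero-length branches copy the root
  tr0 <- ape::read.tree(text = "(a:0,b:0);")
  s0 <- evolve_sequences(tr0, root, jtt, seed = 8)
  expect_identical(unname(s0), c(root, root))

  # observed substitution fraction at t = 0.1 matches the closed form
  # p(t) = 1 - sum_i pi_i P_ii(t)
  tr <- ape::read.tree(text = "(a:0,b:0.1);")
  big_root <- paste(sample(jtt$alphabet, 10000, TRUE, jtt$pi), collapse = "")
  s <- evolve_sequences(tr, big_root, jtt, seed = 88)
  p_exp <- 1 - sum(jtt$pi * diag(transition_prob(jtt, 0.1)))
  expect_equal(p_distance(s[["a"]], s[["b"]]), p_exp, tolerance = 0.1)

  # long branches approach stationary pairwise identity
  tr5 <- ape::read.tree(text = "(a:0,b:5);")
  s5 <- evolve_sequences(tr5, big_root, jtt, seed = 89)
  id_exp <- sum(jtt$pi * diag(transition_prob(jtt, 5)))
  expect_equal(1 - p_distance(s5[["a"]], s5[["b"]]), id_exp,
               tolerance = 0.1)

  # invariant sites never change
  si <- evolve_sequences(tr5, big_root, jtt, seed = 90,
                         invariant_sites = 1:50)
  expect_identical(substr(si[["b"]], 1, 50), substr(big_root, 1, 50))
})

test_that("the benchmark is byte-identical under (config, seed)", {
  cfg <- benchmark_config(n_per_clade = 4, n_decoys = 5)
  b1 <- make_clade_benchmark(cfg, seed = 7, db = ref_db, jtt = jtt)
  b2 <- make_clade_benchmark(cfg, seed = 7, db = ref_db, jtt = jtt)
  expect_identical(b1$alignment, b2$alignment)
  expect_identical(b1$truth, b2$truth)
  expect_identical(lapply(b1$trees, ape::write.tree),
                   lapply(b2$trees, ape::write.tree))
  b3 <- make_clade_benchmark(cfg, seed = 8, db = ref_db, jtt = jtt)
  expect_false(identical(b1$alignment, b3$alignment))
})

test_that("truth labels partition the output and motifs are verifiable", {
  b <- make_clade_benchmark(benchmark_config(n_per_clade = 5, n_decoys = 6),
                            seed = 13, db = ref_db, jtt = jtt)
  expect_setequal(b$truth$id, names(b$alignment))
  expect_false(anyDuplicated(b$truth$id) > 0)
  expect_equal(sum(b$truth$clade != "decoy"), 20L)

  # planted motifs recoverable by the scanner in every non-decoy (no indels)
  planted <- b$truth$id[b$truth$clade != "decoy"]
  tab <- motif_table(b$sequences[planted])
  expect_gte(mean(!is.na(tab$motif2)), 0.99)
  # planted strings sit at the planned offsets
  for (cl in c("I", "II", "III", "IV")) {
    plan <- b$motif_plan[[cl]]
    ids <- b$truth$id[b$truth$clade == cl]
    for (id in ids) {
      expect_equal(substr(b$sequences[[id]], plan$asp_start + 1,
                          plan$asp_start + nchar(plan$motif1)), plan$motif1)
      expect_equal(substr(b$sequences[[id]], plan$nse_start + 1,
                          plan$nse_start + nchar(plan$motif2)), plan$motif2)
    }
    # planted strings are verbatim reference motif strings of that clade
    rows <- ref_db$entries[ref_db$entries$clade == cl, ]
    expect_true(plan$motif1 %in% rows$motif1)
    expect_true(plan$motif2 %in% rows$motif2)
  }
})

test_that("intra-clade distances are smaller than inter-clade distances", {
  b <- make_clade_benchmark(benchmark_config(n_per_clade = 4, n_decoys = 0),
                            seed = 23, db = ref_db, jtt = jtt)
  D <- dist_matrix(b$alignment, "jtt-ml", jtt)$d
  cl <- setNames(b$truth$clade, b$truth$id)
  same <- outer(cl[rownames(D)], cl[colnames(D)], "==") & upper.tri(D)
  diff <- !outer(cl[rownames(D)], cl[colnames(D)], "==") & upper.tri(D)
  expect_lt(mean(D[same]), mean(D[diff]))
})

test_that("indel planting respects motif windows and the gap dialect", {
  b <- make_clade_benchmark(
    benchmark_config(n_per_clade = 3, n_decoys = 0, indel_rate = 0.05),
    seed = 29, db = ref_db, jtt = jtt)
  expect_true(any(grepl("-", b$alignment, fixed = TRUE)))
  expect_false(any(grepl("-", b$sequences, fixed = TRUE)))
  # motifs intact despite deletions
  planted <- b$truth$id
  tab <- motif_table(b$sequences[planted])
  expect_gte(mean(!is.na(tab$motif2)), 0.99)
  # alignment width unchanged; pairwise deletion sees fewer sites across clades
  expect_equal(unique(nchar(b$alignment)), 350L)
})

test_that("benchmark artifacts are written as plain text", {
  b <- make_clade_benchmark(benchmark_config(n_per_clade = 3, n_decoys = 2),
                            seed = 3, db = ref_db, jtt = jtt)
  out <- withr::local_tempdir()
  write_benchmark(b, out)
  expect_true(all(file.exists(file.path(out,
    c("sequences.fasta", "alignment.fasta", "truth.tsv", "trees.nwk",
      "config.json")))))
  back <- read_fasta(file.path(out, "sequences.fasta"))
  expect_identical(back, b$sequences)
  cfg <- jsonlite::read_json(file.path(out, "config.json"))
  expect_equal(cfg$seed, 3L)
})
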