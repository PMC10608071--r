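# Synthetic benchmark generator. Emulates the statistical structure the
# analysis assumes: four diverged enzyme families (one per clade) evolved on
# random trees under the packaged JTT model, with clade-appropriate
# aspartate-rich and NSE motif strings (sampled verbatim from the packaged
# motif table of that clade's members) planted at realistic offsets as
# invariant sites, plus unrelated decoy proteins drawn i.i.d. from the JTT
# stationary frequencies, and a truth table. Fully deterministic under
# (config, seed).

#' Random model tree for one clade family
#'
#' Topology uniform over labeled unrooted binary topologies; branch lengths
#' i.i.d. exponential with the given mean. Deterministic per seed.
#'
#' @param n_leaves number of leaves (>= 2)
#' @param branch_mean mean branch length (substitutions/site)
#' @param seed integer seed
#' @param labels optional leaf labels (default `t1..tn`)
#' @return an [ape::phylo] tree
#' @export
make_model_tree <- function(n_leaves, branch_mean, seed = 1,
                            labels = paste0("t", seq_len(n_leaves))) {
  if (n_leaves < 2L) stop("n_leaves must be >= 2")
  stopifnot(length(labels) == n_leaves, branch_mean > 0)
  set.seed(seed)
  if (n_leaves == 2L) {
    tr <- ape::read.tree(text = sprintf("(%s:%.12g,%s:%.12g);",
                                        labels[1], rexp(1, 1 / branch_mean),
                                        labels[2], rexp(1, 1 / branch_mean)))
    return(tr)
  }
  tr <- ape::rtopology(n_leaves, rooted = FALSE, tip.label = labels,
                       br = function(n) rexp(n, 1 / branch_mean))
  tr
}

#' Evolve a protein sequence along a tree under the JTT model
#'
#' Site-independent continuous-time Markov simulation: each branch of length
#' `t` applies `P(t) = exp(Qt)` to every site independently. Sites listed in
#' `invariant_sites` are copied unchanged (used to keep planted motifs
#' intact).
#'
#' @param tree an [ape::phylo] with branch lengths
#' @param root_seq root protein sequence (characters in the model alphabet)
#' @param model an `sts_model` from [jtt_model()]
#' @param seed integer seed
#' @param invariant_sites 1-based site positions excluded from substitution
#' @return named character vector of leaf sequences
#' @export
evolve_sequences <- function(tree, root_seq, model, seed = 1,
                             invariant_sites = integer()) {
  stopifnot(inherits(model, "sts_model"))
  set.seed(seed)
  idx <- match(strsplit(toupper(root_seq), "")[[1]], model$alphabet)
  if (anyNA(idx)) stop("root sequence contains letters outside the model alphabet")
  L <- length(idx)
  mutable <- setdiff(seq_len(L), invariant_sites)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  states <- vector("list", ntip + tree$Nnode)
  states[[root]] <- idx
  # preorder over edges (ape trees store edges parent-before-child when
  # traversed in cladewise order)
  tr <- stats::reorder(tree, "cladewise")
  for (k in seq_len(nrow(tr$edge))) {
    par <- tr$edge[k, 1]; child <- tr$edge[k, 2]
    t_br <- tr$edge.length[k]
    s <- states[[par]]
    if (t_br > 0 && length(mutable)) {
      P <- transition_prob(model, t_br)
      new <- s
      for (a in unique(s[mutable])) {
        sel <- mutable[s[mutable] == a]
        new[sel] <- sample.int(20L, length(sel), replace = TRUE, prob = P[a, ])
      }
      states[[child]] <- new
    } else {
      states[[child]] <- s
    }
  }
  out <- vapply(seq_len(ntip), function(i)
    paste(model$alphabet[states[[i]]], collapse = ""), "")
  setNames(out, tree$tip.label)
}

#' Benchmark generator configuration
#'
#' Defaults state the benchmark's world: 4 clades of 12 sequences of length
#' 350 (the scale of the curated reference set and of typical 300-600 aa STS
#' enzymes), inter-clade backbone divergence 1.0 substitutions/site,
#' intra-clade branch mean 0.08, 20 decoys, no indels. The motif plan plants,
#' per clade, one aspartate-rich and one NSE string sampled from the packaged
#' motif table rows of that clade's members, at offsets drawn inside the
#' stated windows (defaults keep the catalytic spacing inside 60-260).
#'
#' @param n_per_clade sequences per clade family
#' @param seq_length protein length (residues)
#' @param interclade_divergence expected substitutions/site separating any
#'   two clade ancestors on the backbone
#' @param intraclade_branch_mean mean branch length inside a family
#' @param n_decoys number of unrelated stationary-frequency decoys
#' @param indel_rate fraction of columns deleted per family (0 disables;
#'   deletions never touch planted motifs)
#' @param asp_offset_window,motif_spacing_window 0-based start window for the
#'   aspartate-rich motif and start-to-start spacing window to the NSE motif
#' @return an `sts_benchmark_config` list
#' @export
benchmark_config <- function(n_per_clade = 12, seq_length = 350,
                             interclade_divergence = 1.0,
                             intraclade_branch_mean = 0.08,
                             n_decoys = 20, indel_rate = 0,
                             asp_offset_window = c(80, 110),
                             motif_spacing_window = c(120, 160)) {
  stopifnot(n_per_clade >= 0, seq_length > 0, interclade_divergence > 0,
            intraclade_branch_mean > 0, n_decoys >= 0,
            indel_rate >= 0, indel_rate < 1)
  if (asp_offset_window[2] + motif_spacing_window[2] + 9 > seq_length)
    stop("motif plan does not fit within seq_length")
  structure(list(n_per_clade = n_per_clade, seq_length = seq_length,
                 interclade_divergence = interclade_divergence,
                 intraclade_branch_mean = intraclade_branch_mean,
                 n_decoys = n_decoys, indel_rate = indel_rate,
                 asp_offset_window = asp_offset_window,
                 motif_spacing_window = motif_spacing_window),
            class = "sts_benchmark_config")
}

# per-clade pools of printed motif strings from the packaged motif table
clade_motif_pool <- function(db) {
  e <- db$entries
  lapply(setNames(c("I", "II", "III", "IV"), c("I", "II", "III", "IV")),
         function(cl) {
           rows <- e[e$clade == cl & !is.na(e$motif1) & !is.na(e$motif2), ]
           m1 <- rows$motif1[nchar(rows$motif1) == 5 &
                               classify_motif1(rows$motif1) != "absent"]
           m2 <- rows$motif2[grepl("^ND..S...E$", rows$motif2)]
           list(motif1 = unique(m1), motif2 = unique(m2))
         })
}

#' Generate the four-clade synthetic benchmark
#'
#' One root sequence is drawn from the JTT stationary distribution; the four
#' clade ancestors evolve from it along backbone branches of length
#' `interclade_divergence / 2` (so any two ancestors are separated by the
#' configured divergence). Clade-specific motif strings are then planted in
#' each ancestor at clade-specific offsets and kept invariant while each
#' family evolves on its own random tree. Decoys are i.i.d. stationary
#' sequences without planted motifs.
#'
#' @param config an `sts_benchmark_config`
#' @param seed master integer seed
#' @param db reference database supplying the per-clade motif string pools
#' @param jtt optional preloaded JTT model
#' @return an `sts_benchmark`: list with `alignment` (gapped rows; identical
#'   to `sequences` when `indel_rate = 0`), `sequences` (ungapped), `truth`
#'   (data.frame `id`, `clade`, decoys labeled `"decoy"`), `trees` (named
#'   list of [ape::phylo]), `motif_plan`, `config`, `seed`
#' @export
make_clade_benchmark <- function(config = benchmark_config(), seed = 7,
                                 db = load_reference(), jtt = jtt_model()) {
  stopifnot(inherits(config, "sts_benchmark_config"))
  clades <- c("I", "II", "III", "IV")
  pools <- clade_motif_pool(db)
  L <- config$seq_length

  set.seed(substream_seed(seed, 0))
  root <- sample(jtt$alphabet, L, replace = TRUE, prob = jtt$pi)
  root <- paste(root, collapse = "")

  # backbone: star over the four clade ancestors
  half <- config$interclade_divergence / 2
  backbone <- ape::read.tree(text = sprintf(
    "(I:%.12g,II:%.12g,III:%.12g,IV:%.12g);", half, half, half, half))
  ancestors <- evolve_sequences(backbone, root, jtt,
                                seed = substream_seed(seed, 1))

  # motif plan: per clade, verbatim strings from that clade's members and
  # clade-specific offsets
  plan <- list()
  aln <- character(); truth <- list(); trees <- list(backbone = backbone)
  for (ci in seq_along(clades)) {
    cl <- clades[ci]
    set.seed(substream_seed(seed, 10 + ci))
    m1 <- sample(pools[[cl]]$motif1, 1)
    m2 <- sample(pools[[cl]]$motif2, 1)
    a0 <- sample(seq(config$asp_offset_window[1], config$asp_offset_window[2]), 1)
    spacing <- sample(seq(config$motif_spacing_window[1],
                          config$motif_spacing_window[2]), 1)
    n0 <- a0 + spacing
    if (n0 + nchar(m2) > L) stop("inconsistent motif plan: window exceeds length")
    if (a0 + nchar(m1) > n0) stop("inconsistent motif plan: overlapping windows")
    sites <- c(seq(a0 + 1, a0 + nchar(m1)), seq(n0 + 1, n0 + nchar(m2)))
    anc <- strsplit(ancestors[[cl]], "")[[1]]
    anc[seq(a0 + 1, a0 + nchar(m1))] <- strsplit(m1, "")[[1]]
    anc[seq(n0 + 1, n0 + nchar(m2))] <- strsplit(m2, "")[[1]]
    anc <- paste(anc, collapse = "")
    plan[[cl]] <- list(motif1 = m1, motif2 = m2, asp_start = a0,
                       nse_start = n0, invariant_sites = sites)

    if (config$n_per_clade > 0) {
      ids <- sprintf("c%s_%02d", cl, seq_len(config$n_per_clade))
      tr <- make_model_tree(config$n_per_clade, config$intraclade_branch_mean,
                            seed = substream_seed(seed, 20 + ci), labels = ids)
      trees[[paste0("clade_", cl)]] <- tr
      fam <- evolve_sequences(tr, anc, jtt,
                              seed = substream_seed(seed, 30 + ci),
                              invariant_sites = sites)
      aln <- c(aln, fam)
      truth[[cl]] <- data.frame(id = ids, clade = cl, stringsAsFactors = FALSE)
    }
  }

  if (config$n_decoys > 0) {
    set.seed(substream_seed(seed, 50))
    dec <- vapply(seq_len(config$n_decoys), function(i)
      paste(sample(jtt$alphabet, L, replace = TRUE, prob = jtt$pi),
            collapse = ""), "")
    names(dec) <- sprintf("decoy_%02d", seq_len(config$n_decoys))
    aln <- c(aln, dec)
    truth$decoy <- data.frame(id = names(dec), clade = "decoy",
                              stringsAsFactors = FALSE)
  }

  # optional indels: per family, delete columns (as gaps) outside motifs
  sequences <- aln
  if (config$indel_rate > 0) {
    n_del <- ceiling(config$indel_rate * L)
    for (ci in seq_along(clades)) {
      cl <- clades[ci]
      if (config$n_per_clade == 0) next
      set.seed(substream_seed(seed, 60 + ci))
      protected <- plan[[cl]]$invariant_sites
      cols <- sample(setdiff(seq_len(L), protected), n_del)
      ids <- truth[[cl]]$id
      for (id in ids) {
        ch <- strsplit(aln[[id]], "")[[1]]
        ch[cols] <- "-"
        aln[id] <- paste(ch, collapse = "")
        sequences[id] <- paste(ch[ch != "-"], collapse = "")
      }
    }
  }

  truth <- do.call(rbind, truth)
  row.names(truth) <- NULL
  stopifnot(!anyDuplicated(truth$id), identical(sort(truth$id), sort(names(aln))))
  structure(list(alignment = aln, sequences = sequences, truth = truth,
                 trees = trees, motif_plan = plan, config = config,
                 seed = seed),
            class = "sts_benchmark")
}

#' @export
print.sts_benchmark <- function(x, ...) {
  cat("synthetic STS benchmark:",
      sum(x$truth$clade != "decoy"), "clade sequences +",
      sum(x$truth$clade == "decoy"), "decoys, length",
      x$config$seq_length, "\n")
  invisible(x)
}

#' Write benchmark artifacts to a directory
#'
#' Writes ungapped FASTA, aligned FASTA, the truth TSV, the generating trees
#' (Newick) and a JSON echo of the configuration and seed.
#'
#' @param bench an `sts_benchmark`
#' @param outdir output directory (created if missing)
#' @return `outdir`, invisibly
#' @export
write_benchmark <- function(bench, outdir) {
  stopifnot(inherits(bench, "sts_benchmark"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(bench$sequences, file.path(outdir, "sequences.fasta"))
  write_fasta(bench$alignment, file.path(outdir, "alignment.fasta"))
  write.table(bench$truth, file.path(outdir, "truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  ape::write.tree(do.call(c, unname(bench$trees)),
                  file.path(outdir, "trees.nwk"))
  cfg <- c(unclass(bench$config), list(seed = bench$seed))
  jsonlite::write_json(cfg, file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
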