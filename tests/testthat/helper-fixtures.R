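# Shared fixtures, loaded once per test run.

ref_db <- load_reference()
jtt <- jtt_model()

# naive sliding-window motif matcher: the independent oracle for scan_motif
naive_scan <- function(seq, pattern) {
  s <- strsplit(toupper(seq), "")[[1]]
  L <- pattern$length
  starts <- integer()
  if (length(s) >= L) {
    for (st in seq_len(length(s) - L + 1L)) {
      ok <- TRUE
      for (p in seq_len(L)) {
        allowed <- pattern$positions[[p]]
        if (!is.null(allowed) && !(s[st + p - 1L] %in% allowed)) { ok <- FALSE; break }
      }
      if (ok) starts <- c(starts, st - 1L)
    }
  }
  starts
}

random_protein <- function(n, alphabet = c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# additive distance matrix from a tree via path lengths (the NJ oracle)
additive_matrix <- function(tree) {
  D <- ape::cophenetic.phylo(tree)
  D[sort(rownames(D)), sort(colnames(D))]
}
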