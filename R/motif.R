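# Consensus-grammar motif engine for the two catalytic metal-binding motifs
# of sesquiterpene synthases: the N-terminal-side aspartate-rich region
# (canonical DExxD / DD(N)xxD, generalized D(D/E/N)xx(D/E)) and the NSE triad
# (NDxxSxxxE), which together coordinate the Mg2+ cluster that ionizes
# FPP/NPP. The notation: an uppercase letter fixes a residue, "x" matches any
# residue (including the ambiguity letter X), "(A/B/C)" allows alternatives
# at one position.

.aa_letters <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Compile a motif consensus string into a matcher
#'
#' @param consensus notation string, e.g. `"NDxxSxxxE"` or `"D(D/E/N)xx(D/E)"`
#' @param name optional display name; defaults to the consensus itself
#' @return an `sts_motif`: list with `name`, `consensus`, `length`, and
#'   `positions` (per-position character vectors of allowed residues, `NULL`
#'   meaning any)
#' @export
#' @examples
#' p <- compile_pattern("DExxD")
#' scan_motif(c(seq1 = "AADELSDAA"), p)
compile_pattern <- function(consensus, name = consensus) {
  stopifnot(is.character(consensus), length(consensus) == 1L, nzchar(consensus))
  chars <- strsplit(consensus, "")[[1]]
  positions <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "x") {
      positions <- c(positions, list(NULL))   # NULL = any residue
      i <- i + 1L
    } else if (ch == "(") {
      j <- i + 1L
      alt <- character()
      expecting <- "residue"
      repeat {
        if (j > length(chars))
          stop("unbalanced parenthesis in consensus at offset ", i - 1L)
        cj <- chars[j]
        if (cj == ")") {
          if (expecting == "residue")
            stop("empty alternative in consensus at offset ", j - 1L)
          break
        }
        if (expecting == "residue") {
          if (!cj %in% .aa_letters)
            stop("illegal character '", cj, "' in consensus at offset ", j - 1L)
          alt <- c(alt, cj)
          expecting <- "sep"
        } else {
          if (cj != "/")
            stop("expected '/' or ')' in consensus at offset ", j - 1L)
          expecting <- "residue"
        }
        j <- j + 1L
      }
      positions[[length(positions) + 1L]] <- alt
      i <- j + 1L
    } else if (ch %in% .aa_letters) {
      positions[[length(positions) + 1L]] <- ch
      i <- i + 1L
    } else {
      stop("illegal character '", ch, "' in consensus at offset ", i - 1L)
    }
  }
  structure(list(name = name, consensus = consensus,
                 length = length(positions), positions = positions),
            class = "sts_motif")
}

#' @export
print.sts_motif <- function(x, ...) {
  cat("motif pattern ", x$name, " (", x$length, " positions)\n", sep = "")
  invisible(x)
}

#' Builtin motif patterns
#'
#' The catalytic-motif consensus set used throughout the package, in the
#' field's display notation: `NSE` (`NDxxSxxxE`), the generalized
#' aspartate-rich pattern `D(D/E/N)xx(D/E)`, its canonical sub-forms `DExxD`
#' and `DD(N)xxD` (read as `D(D/N)xxD`: second position D or N), and the
#' additional fungal motifs `DxDTT`, `DDxDTT`, `QDxxDxxxD`.
#'
#' @return named list of compiled `sts_motif` objects
#' @export
sts_patterns <- function() {
  list(
    nse          = compile_pattern("NDxxSxxxE", "NDxxSxxxE"),
    aspartate    = compile_pattern("D(D/E/N)xx(D/E)", "D(D/E/N)xx(D/E)"),
    dexxd        = compile_pattern("DExxD", "DExxD"),
    ddnxxd       = compile_pattern("D(D/N)xxD", "DD(N)xxD"),
    dxdtt        = compile_pattern("DxDTT", "DxDTT"),
    ddxdtt       = compile_pattern("DDxDTT", "DDxDTT"),
    qdxxdxxxd    = compile_pattern("QDxxDxxxD", "QDxxDxxxD")
  )
}

#' Scan a protein sequence for all matches of a motif pattern
#'
#' Reports every match, including overlapping ones, ordered by start. Offsets
#' are 0-based on the unaligned protein. `"x"` positions match any residue
#' including the ambiguity letter `X`; fixed positions match only the stated
#' residue(s).
#'
#' @param seq a single protein sequence (character scalar, optionally named)
#'   or a named character vector of length 1
#' @param pattern a compiled `sts_motif`
#' @return data.frame with columns `sequence_id`, `pattern_name`, `start`
#'   (0-based), `matched`
#' @export
scan_motif <- function(seq, pattern) {
  stopifnot(inherits(pattern, "sts_motif"), is.character(seq), length(seq) == 1L)
  id <- names(seq) %||% NA_character_
  s <- toupper(seq[[1L]])
  L <- pattern$length
  n <- nchar(s)
  empty <- data.frame(sequence_id = character(), pattern_name = character(),
                      start = integer(), matched = character(),
                      stringsAsFactors = FALSE)
  if (n < L) return(empty)
  chars <- strsplit(s, "")[[1]]
  n_windows <- n - L + 1L
  ok <- rep(TRUE, n_windows)
  for (p in seq_len(L)) {
    allowed <- pattern$positions[[p]]
    if (is.null(allowed)) next
    ok <- ok & chars[seq_len(n_windows) + p - 1L] %in% allowed
  }
  starts <- which(ok)
  if (!length(starts)) return(empty)
  data.frame(sequence_id = id, pattern_name = pattern$name,
             start = starts - 1L,
             matched = substring(s, starts, starts + L - 1L),
             stringsAsFactors = FALSE)
}

#' Locate the catalytic aspartate-rich / NSE motif pair
#'
#' Selects an aspartate-rich hit upstream of an NSE hit with inter-motif
#' spacing (difference of 0-based starts) inside the configured window; among
#' valid pairs the one with spacing closest to the window midpoint wins (ties
#' broken by smaller aspartate start, then smaller NSE start). When no
#' validly ordered pair exists, single-motif hits are still reported alone,
#' but an NSE hit strictly upstream of every aspartate hit reports both
#' components absent (the ordering is part of the motif architecture).
#'
#' @param seq single (named) protein sequence
#' @param spacing_window allowed residue spacing between motif starts,
#'   default `c(60, 260)`
#' @param asp_pattern,nse_pattern compiled patterns; default the builtin
#'   generalized aspartate-rich and NSE patterns
#' @return an `sts_catalytic_pair`: list with `aspartate_hit`, `nse_hit`
#'   (one-row data.frames or `NULL`) and `spacing` (NA unless both present)
#' @export
locate_catalytic_pair <- function(seq, spacing_window = c(60, 260),
                                  asp_pattern = sts_patterns()$aspartate,
                                  nse_pattern = sts_patterns()$nse) {
  asp <- scan_motif(seq, asp_pattern)
  nse <- scan_motif(seq, nse_pattern)
  res <- function(a, n, spacing = NA_integer_)
    structure(list(aspartate_hit = a, nse_hit = n, spacing = spacing),
              class = "sts_catalytic_pair")
  if (nrow(asp) && nrow(nse)) {
    grid <- expand.grid(a = seq_len(nrow(asp)), n = seq_len(nrow(nse)))
    grid$spacing <- nse$start[grid$n] - asp$start[grid$a]
    valid <- grid[grid$spacing >= spacing_window[1] &
                  grid$spacing <= spacing_window[2], , drop = FALSE]
    if (nrow(valid)) {
      mid <- mean(spacing_window)
      valid <- valid[order(abs(valid$spacing - mid),
                           asp$start[valid$a], nse$start[valid$n]), , drop = FALSE]
      pick <- valid[1L, ]
      return(res(asp[pick$a, , drop = FALSE], nse[pick$n, , drop = FALSE],
                 as.integer(pick$spacing)))
    }
    # hits exist but no pair in order and in window: architecture absent
    return(res(NULL, NULL))
  }
  if (nrow(asp)) return(res(asp[1L, , drop = FALSE], NULL))
  if (nrow(nse)) return(res(NULL, nse[1L, , drop = FALSE]))
  res(NULL, NULL)
}

#' Classify an aspartate-rich motif string
#'
#' Tests sub-patterns in the fixed order `DExxD`, `DD(N)xxD`, generalized
#' `D(D/E/N)xx(D/E)` (label `"other-variant"`); strings matching none are
#' `"absent"`. Exactly one label results for every input.
#'
#' @param x character vector of motif-region strings (NA allowed)
#' @return character vector of labels in
#'   `c("DExxD", "DD(N)xxD", "other-variant", "absent")`
#' @export
classify_motif1 <- function(x) {
  pats <- sts_patterns()
  vapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) return("absent")
    s <- unname(s)
    if (nrow(scan_motif(s, pats$dexxd))) return("DExxD")
    if (nrow(scan_motif(s, pats$ddnxxd))) return("DD(N)xxD")
    if (nrow(scan_motif(s, pats$aspartate))) return("other-variant")
    "absent"
  }, character(1), USE.NAMES = !is.null(names(x)))
}

#' Per-sequence motif table
#'
#' Mirrors the reference motif table's layout: one row per sequence with the
#' matched aspartate-rich string, the matched NSE string, and the
#' aspartate-rich classification (see [classify_motif1()]).
#'
#' @param seqs named character vector of protein sequences
#' @param spacing_window passed to [locate_catalytic_pair()]
#' @return data.frame with columns `id`, `motif1`, `motif2`, `classification`
#' @export
motif_table <- function(seqs, spacing_window = c(60, 260)) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  rows <- lapply(names(seqs), function(id) {
    pair <- locate_catalytic_pair(seqs[id], spacing_window = spacing_window)
    m1 <- if (is.null(pair$aspartate_hit)) NA_character_ else pair$aspartate_hit$matched
    m2 <- if (is.null(pair$nse_hit)) NA_character_ else pair$nse_hit$matched
    data.frame(id = id, motif1 = m1, motif2 = m2,
               classification = unname(classify_motif1(m1)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Screen a proteome for STS-like candidate sequences
#'
#' Keeps sequences whose length falls inside the window and which carry an
#' NSE hit or an aspartate-rich hit. This replaces a similarity search with
#' explicit, parameter-free motif evidence; results are returned in
#' deterministic id order.
#'
#' @param seqs named character vector of protein sequences
#' @param length_window allowed protein length, default `c(250, 700)`
#'   residues (the size range of the reference enzymes)
#' @param asp_pattern,nse_pattern compiled patterns
#' @return character vector of passing sequence ids, sorted
#' @export
screen_candidates <- function(seqs, length_window = c(250, 700),
                              asp_pattern = sts_patterns()$aspartate,
                              nse_pattern = sts_patterns()$nse) {
  if (!length(seqs)) return(character())
  stopifnot(!is.null(names(seqs)))
  keep <- vapply(names(seqs), function(id) {
    n <- nchar(seqs[[id]])
    if (n < length_window[1] || n > length_window[2]) return(FALSE)
    nrow(scan_motif(seqs[id], nse_pattern)) > 0L ||
      nrow(scan_motif(seqs[id], asp_pattern)) > 0L
  }, logical(1))
  sort(names(seqs)[keep])
}
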