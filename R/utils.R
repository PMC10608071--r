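#' Derived random substream seed
#'
#' Deterministic per-replicate seeds so that bootstrap replicates and
#' simulation components are order-independent: replicate `r` under master
#' seed `s` always sees the same RNG state regardless of how many replicates
#' run before it. The derivation is `(s * 48271 + 1664525 * r) mod (2^31 - 1)`,
#' kept strictly below 2^31 so it is a valid R integer seed.
#'
#' @param seed master integer seed
#' @param r replicate / component index (>= 0)
#' @return an integer seed
#' @export
substream_seed <- function(seed, r) {
  s <- (as.double(seed) %% 2147483647) * 48271 + 1664525 * as.double(r)
  as.integer(s %% 2147483647)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file (protein; may be aligned, gaps "-")
#' @return named character vector of uppercase sequences
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write protein sequences to FASTA
#'
#' @param seqs named character vector
#' @param path output path
#' @param width line width
#' @export
write_fasta <- function(seqs, path, width = 70) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

# strict TSV reader used for the packaged tables: returns rows as character
# matrix and errors with the offending 1-based line number on ragged rows
read_strict_tsv <- function(path, n_fields) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("no data rows in ", path)
  # sentinel keeps trailing empty fields that strsplit would drop
  parts <- strsplit(paste0(lines, "\t\x01"), "\t", fixed = TRUE)
  parts <- lapply(parts, function(p) p[-length(p)])
  bad <- which(vapply(parts, length, 1L) != n_fields)
  if (length(bad))
    stop("malformed row in ", basename(path), " at line ", bad[1L],
         ": expected ", n_fields, " tab-separated fields")
  list(header = parts[[1L]],
       rows = do.call(rbind, parts[-1L]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
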