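# Product-name handling for the curated reference table.
#
# The printed product column mixes Greek letters, superscripts and a few
# spelling variants; normalization maps every printed form to a stable ASCII
# key ("alpha-muurolene", "delta6-protoilludene", ...) while the raw string is
# always kept alongside so the transcription stays reversible.

# printed variants -> canonical spelling
.product_aliases <- c(
  "virifloridol" = "viridiflorol"
)

#' Normalize a printed product name
#'
#' Lowercases, spells out Greek letters (alpha/beta/gamma/delta/tau), inlines
#' superscript markers (`Delta^6^` -> `delta6`), collapses whitespace and runs
#' of hyphens to single hyphens, and applies a small alias table for printed
#' spelling variants.
#'
#' @param x character vector of printed product names
#' @return character vector of normalized names
#' @export
#' @examples
#' normalize_product("α-muurolene")      # "alpha-muurolene"
#' normalize_product("germacrene A")          # "germacrene-a"
normalize_product <- function(x) {
  y <- x
  y <- gsub("\\*", "", y)
  greek <- c("α" = "alpha", "β" = "beta", "γ" = "gamma",
             "Δ" = "delta", "δ" = "delta", "Ʈ" = "tau",
             "τ" = "tau")
  for (g in names(greek)) y <- gsub(g, greek[[g]], y, fixed = TRUE)
  y <- gsub("\\^([^^]*)\\^", "\\1", y)   # inline superscripts
  y <- tolower(trimws(y))
  y <- gsub("\\s+", "-", y)
  y <- gsub("-+", "-", y)
  hit <- y %in% names(.product_aliases)
  y[hit] <- .product_aliases[y[hit]]
  y
}

#' Parse a printed product field into ordered product records
#'
#' Splits the printed cell on `";"`, trims, drops a trailing `"etc."`, assigns
#' 1-based ranks left to right, and flags `"unknown sesquiterpene"` /
#' `"unknown sesquiterpenol"` entries. `"ND"` (no product detected) and empty
#' cells yield zero records; the `"nd"` attribute distinguishes the two.
#'
#' @param raw the printed product cell (single string)
#' @return data.frame with columns `name` (normalized), `raw` (as printed),
#'   `rank`, `flag` (one of `"normal"`, `"unknown"`); attribute `nd` is TRUE
#'   when the cell printed `"ND"`
#' @export
parse_products <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  empty <- data.frame(name = character(), raw = character(),
                      rank = integer(), flag = character(),
                      stringsAsFactors = FALSE)
  raw <- trimws(raw)
  if (identical(raw, "ND")) {
    attr(empty, "nd") <- TRUE
    return(empty)
  }
  attr(empty, "nd") <- FALSE
  if (!nzchar(raw)) return(empty)
  parts <- trimws(strsplit(raw, ";", fixed = TRUE)[[1L]])
  parts <- parts[nzchar(parts)]
  parts <- parts[parts != "etc."]
  if (!length(parts)) return(empty)
  name <- normalize_product(parts)
  flag <- ifelse(name %in% c("unknown-sesquiterpene", "unknown-sesquiterpenol"),
                 "unknown", "normal")
  out <- data.frame(name = name, raw = parts,
                    rank = seq_along(parts), flag = flag,
                    stringsAsFactors = FALSE)
  attr(out, "nd") <- FALSE
  out
}
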