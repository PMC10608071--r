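# Curated reference knowledge base: 174 experimentally characterized
# sesquiterpene synthases from 35 mushroom-forming fungi, packaged as two
# plain-text transcriptions of the published summary tables (one with gene,
# species, accession, ordered products and clade; one with the printed
# aspartate-rich and NSE motif strings and Pfam domain labels).

#' Path to a packaged reference data file
#'
#' @param file file name under the package's `extdata` directory; the two
#'   reference tables are `"table1_reference.tsv"` and `"table2_motifs.tsv"`
#' @return absolute path
#' @export
sts_extdata <- function(file) {
  p <- system.file("extdata", file, package = "mushSTS", mustWork = FALSE)
  if (!nzchar(p)) stop("packaged data file not found: ", file)
  p
}

#' Load the curated STS reference database
#'
#' Reads and joins the two packaged reference tables on gene name. Rows
#' present in only one table are kept with the other table's fields absent
#' (the motif table omits the two entries without sequence data). The clade
#' column's printed `"\\"` (not analyzed) becomes `"unassigned"`; the `"na"`
#' literal in motif/domain fields becomes `NA`.
#'
#' @param path_table1 TSV with columns gene_name, species, accession,
#'   products, clade, citation; defaults to the packaged transcription
#' @param path_table2 TSV with columns gene_name, motif1, motif2, domains
#' @return an object of class `sts_refdb`: a list with `entries` (data.frame,
#'   one row per enzyme, with a `products` list-column of parsed product
#'   records) and `provenance`
#' @export
load_reference <- function(path_table1 = sts_extdata("table1_reference.tsv"),
                           path_table2 = sts_extdata("table2_motifs.tsv")) {
  t1 <- read_strict_tsv(path_table1, 6L)
  if (!identical(t1$header,
                 c("gene_name", "species", "accession", "products", "clade", "citation")))
    stop("unexpected header in ", basename(path_table1))
  t2 <- read_strict_tsv(path_table2, 4L)
  if (!identical(t2$header, c("gene_name", "motif1", "motif2", "domains")))
    stop("unexpected header in ", basename(path_table2))

  e <- as.data.frame(t1$rows, stringsAsFactors = FALSE)
  names(e) <- t1$header
  if (anyDuplicated(e$gene_name))
    stop("duplicate gene_name in table 1: ",
         paste(unique(e$gene_name[duplicated(e$gene_name)]), collapse = ", "))
  m <- as.data.frame(t2$rows, stringsAsFactors = FALSE)
  names(m) <- t2$header
  if (anyDuplicated(m$gene_name))
    stop("duplicate gene_name in table 2: ",
         paste(unique(m$gene_name[duplicated(m$gene_name)]), collapse = ", "))

  e$clade[e$clade == "\\"] <- "unassigned"
  bad <- setdiff(unique(e$clade), c("I", "II", "III", "IV", "unassigned"))
  if (length(bad)) stop("unknown clade label(s): ", paste(bad, collapse = ", "))

  idx <- match(e$gene_name, m$gene_name)
  e$motif1 <- ifelse(is.na(idx), NA_character_, m$motif1[idx])
  e$motif2 <- ifelse(is.na(idx), NA_character_, m$motif2[idx])
  e$domains <- ifelse(is.na(idx), NA_character_, m$domains[idx])
  for (f in c("motif1", "motif2", "domains"))
    e[[f]][!is.na(e[[f]]) & e[[f]] == "na"] <- NA_character_

  orphans <- setdiff(m$gene_name, e$gene_name)
  if (length(orphans))
    message("motif-table rows without a reference partner (kept aside): ",
            paste(orphans, collapse = ", "))

  dom <- e$domains[!is.na(e$domains)]
  dom_ids <- trimws(unlist(strsplit(dom, ";", fixed = TRUE)))
  bad_dom <- dom_ids[!grepl("^PF\\d{5}$", dom_ids)]
  if (length(bad_dom)) stop("malformed Pfam accession: ", paste(bad_dom, collapse = ", "))

  e$products_parsed <- lapply(e$products, parse_products)
  row.names(e) <- NULL
  structure(list(entries = e,
                 orphan_motif_rows = m[is.na(match(m$gene_name, e$gene_name)), ,
                                       drop = FALSE],
                 provenance = "packaged transcription v1"),
            class = "sts_refdb")
}

#' @export
print.sts_refdb <- function(x, ...) {
  e <- x$entries
  cat("STS reference database:", nrow(e), "enzymes,",
      length(unique(e$species)), "species\n")
  tab <- table(factor(e$clade, levels = c("I", "II", "III", "IV", "unassigned")))
  cat("  clades:", paste(sprintf("%s=%d", names(tab), tab), collapse = "  "), "\n")
  invisible(x)
}

#' Per-clade entry and species counts
#'
#' Counts are over the clade-assigned entries only; the two entries printed
#' as not analyzed are excluded. Species are counted by exact binomial string.
#'
#' @param db an `sts_refdb`
#' @return data.frame with columns clade, n_entries, n_species
#' @export
summarize_clades <- function(db) {
  stopifnot(inherits(db, "sts_refdb"))
  clades <- c("I", "II", "III", "IV")
  e <- db$entries[db$entries$clade %in% clades, , drop = FALSE]
  data.frame(
    clade = clades,
    n_entries = vapply(clades, function(cl) sum(e$clade == cl), 1L),
    n_species = vapply(clades, function(cl)
      length(unique(e$species[e$clade == cl])), 1L),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Count enzymes of a clade producing a given product in a given role
#'
#' Roles follow the reference table's printed ordering: `"major"` means the
#' first-listed (rank-1) product, `"minor"` means listed at rank 2 or later,
#' `"sole"` means the entry's only product.
#'
#' @param db an `sts_refdb`
#' @param product normalized product name (see [normalize_product()])
#' @param clade one of `"I"`, `"II"`, `"III"`, `"IV"`
#' @param role one of `"major"`, `"minor"`, `"sole"`
#' @return integer count
#' @export
count_product_role <- function(db, product, clade, role = c("major", "minor", "sole")) {
  stopifnot(inherits(db, "sts_refdb"))
  role <- match.arg(role)
  if (!clade %in% c("I", "II", "III", "IV"))
    stop("unknown clade label: ", clade)
  e <- db$entries[db$entries$clade == clade, , drop = FALSE]
  hit <- vapply(e$products_parsed, function(p) {
    if (!nrow(p)) return(FALSE)
    switch(role,
           major = p$name[p$rank == 1L] == product,
           minor = product %in% p$name[p$rank >= 2L],
           sole  = nrow(p) == 1L && p$name[1L] == product)
  }, logical(1))
  sum(hit)
}

#' Count reference entries whose printed motif string matches a pattern
#'
#' An entry counts when its printed motif string contains at least one match
#' of the compiled consensus pattern; absent (`NA`) fields never match.
#'
#' @param db an `sts_refdb`
#' @param pattern a compiled `sts_motif` (see [compile_pattern()])
#' @param field `"motif1"` (aspartate-rich region) or `"motif2"` (NSE region)
#' @return integer count
#' @export
count_motif_matches <- function(db, pattern, field = c("motif1", "motif2")) {
  stopifnot(inherits(db, "sts_refdb"), inherits(pattern, "sts_motif"))
  field <- match.arg(field)
  s <- db$entries[[field]]
  s <- s[!is.na(s)]
  sum(vapply(s, function(x) nrow(scan_motif(x, pattern)) > 0L, logical(1)))
}
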