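# Clade -> cyclization mechanism map. Each of the four basidiomycete STS
# clades is tied to one initial ring-closure chemistry on farnesyl
# pyrophosphate (FPP) or its isomer (3R)-nerolidyl diphosphate (NPP) and a
# characteristic first carbocation intermediate.

.mechanism_map <- data.frame(
  clade = c("I", "II", "III", "IV"),
  substrate = c("(2E,6E)-FPP", "(3R)-NPP", "(2E,6E)-FPP", "(3R)-NPP"),
  ring_closure = c("1,10", "1,10", "1,11", "1,6"),
  intermediate = c("(E,E)-germacradienyl cation",
                   "(Z,E)-germacradienyl cation",
                   "trans-humulyl cation",
                   "(6R)-beta-bisabolol cation"),
  stringsAsFactors = FALSE
)

#' Cyclization mechanism annotation for a clade
#'
#' @param clade one of `"I"`, `"II"`, `"III"`, `"IV"`
#' @return one-row data.frame with `clade`, `substrate`, `ring_closure`,
#'   `intermediate`
#' @export
#' @examples
#' mechanism_for_clade("III")  # 1,11-closure of (2E,6E)-FPP, trans-humulyl cation
mechanism_for_clade <- function(clade) {
  i <- match(clade, .mechanism_map$clade)
  if (is.na(i)) stop("no mechanism for clade label: ", clade)
  .mechanism_map[i, , drop = FALSE]
}
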