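## Shared constants and small helpers.

#' The six V-gene locus labels
#'
#' Variable-gene exons are classified into six classes: the three
#' immunoglobulin loci (heavy, kappa, lambda) and three T-cell receptor
#' classes.  TRAV and TRDV share a chromosomal location and are treated as
#' one combined class, `TRAV_D`.
#'
#' @return Character vector of the six locus labels, in the fixed order used
#'   for tie-breaking.
#' @export
#' @examples
#' lociLabels()
lociLabels <- function() {
  c("IGHV", "IGKV", "IGLV", "TRAV_D", "TRBV", "TRGV")
}

## 20 standard amino acids, fixed alphabetical one-letter order; pair index
## = 20 * idx(first residue) + idx(second) relies on this order being frozen.
.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## Deterministic seed derivation: one master seed expands to per-stage seeds.
## Strings are folded to integers; the LCG keeps everything < 2^31 - 1.
.deriveSeed <- function(master, ...) {
  parts <- list(...)
  acc <- as.numeric(master) %% 2147483647
  for (p in parts) {
    v <- if (is.character(p)) sum(utf8ToInt(paste(p, collapse = ""))) else as.numeric(p)
    acc <- (acc * 69069 + v + 12345) %% 2147483647
  }
  as.integer(acc)
}

.splitChars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

## Node naming for the multiresolution tree: "<level>.<index>".
.nodeName <- function(i, j) paste0(i, ".", j)

.nodeNames <- function(depth) {
  unlist(lapply(0:depth, function(i) .nodeName(i, seq_len(2^i) - 1L)))
}

.nodeLevel <- function(name) as.integer(sub("\\..*$", "", name))
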