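#' The standard genetic code and its synonymous-codon structure
#'
#' Builds the lookup tables used throughout the package: the 64-codon to
#' amino-acid map, the 61 sense codons, the 59 synonymous codons (SCs; the
#' sense codons minus the non-degenerate ATG and TGG), the per-amino-acid
#' synonymous families (Ser is one six-codon family: TCT/TCC/TCA/TCG/AGT/AGC),
#' and the 18 degenerate amino acids those 59 SCs encode.
#'
#' @return A list of class `scub_genetic_code` with elements:
#'   \describe{
#'     \item{codon_to_aa}{named character vector over all 64 codons; stops are
#'       `"*"`.}
#'     \item{sense_codons}{the 61 amino-acid-encoding codons.}
#'     \item{sc_set}{the 59 synonymous codons.}
#'     \item{families}{named list, one character vector of codons per amino
#'       acid (Met and Trp are singleton families).}
#'     \item{degenerate_aas}{the 18 amino acids with two or more codons.}
#'     \item{stops}{TAA, TAG, TGA.}
#'     \item{third_base, second_base, first_base}{named character vectors over
#'       the 64 codons.}
#'   }
#' @examples
#' gc <- scub_genetic_code()
#' length(gc$sc_set)          # 59
#' length(gc$degenerate_aas)  # 18
#' @export
scub_genetic_code <- function() {
  code <- Biostrings::GENETIC_CODE
  codon_to_aa <- stats::setNames(as.character(code), names(code))
  stops <- names(codon_to_aa)[codon_to_aa == "*"]
  sense <- names(codon_to_aa)[codon_to_aa != "*"]
  fam <- split(sense, codon_to_aa[sense])
  fam <- lapply(fam, sort)
  degenerate <- names(fam)[lengths(fam) >= 2L]
  sc <- sort(unlist(fam[degenerate], use.names = FALSE))
  structure(list(
    codon_to_aa    = codon_to_aa,
    sense_codons   = sense,
    sc_set         = sc,
    families       = fam,
    degenerate_aas = degenerate,
    stops          = stops,
    first_base     = stats::setNames(substr(names(codon_to_aa), 1L, 1L), names(codon_to_aa)),
    second_base    = stats::setNames(substr(names(codon_to_aa), 2L, 2L), names(codon_to_aa)),
    third_base     = stats::setNames(substr(names(codon_to_aa), 3L, 3L), names(codon_to_aa))
  ), class = "scub_genetic_code")
}

# Memoised copy: the code is immutable, recomputing it per call is waste.
.gc_cache <- new.env(parent = emptyenv())

.genetic_code <- function() {
  if (is.null(.gc_cache$gc)) .gc_cache$gc <- scub_genetic_code()
  .gc_cache$gc
}

#' @export
print.scub_genetic_code <- function(x, ...) {
  cat("Standard genetic code:",
      length(x$sense_codons), "sense codons,",
      length(x$sc_set), "synonymous codons over",
      length(x$degenerate_aas), "amino acids\n")
  invisible(x)
}

# A/G/C/T third-base class helpers
.AT_BASES <- c("A", "T")
.CG_BASES <- c("C", "G")
.BASES <- c("A", "C", "G", "T")
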