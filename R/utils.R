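`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a table as TSV
#'
#' Thin wrapper around [data.table::fwrite()] fixing the conventions used for
#' every tabular output of the package (tab separator, no quoting, `NA` for
#' missing values).
#'
#' @param x a data.frame / data.table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

# reverse-complement of plain character vectors (delegates to Biostrings)
.revcomp <- function(x) {
  out <- character(length(x))
  nz <- nchar(x) > 0L
  if (any(nz)) {
    out[nz] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[nz])))
  }
  out
}

# suppress R CMD check notes for data.table NSE symbols
utils::globalVariables(c(
  ".", ".N", ".SD", "gene_id", "transcript_id", "chromosome", "strand",
  "type", "ID", "Parent", "start", "end", "seqnames", "codon", "amino_acid",
  "ordinal", "exon_ordinal", "exon_count", "intron_count", "next_first_base",
  "is_stop", "is_start", "cds_sequence", "outcome", "reason", "tid", "mid",
  "piece", "gene", "m", "k_codons", "exon_idx", "aa", "prefix", "n_codons",
  "second_base", "third_base", "count", "frequency", "value", "stratum",
  "species", "N", "J", "first_base", "block_len", "gene_start", "e_off",
  "s_off", "cum_end", "intron_class", "n_sc"
))
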