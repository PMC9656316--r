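# Hand-built FASTA/GFF3 fixtures written to tempfiles, and in-memory
# transcript/record builders used by the statistics tests.

library(data.table)

write_fixture_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(c(paste0(">", nm), seqs[[nm]]), con)
  }
  path
}

write_fixture_gff3 <- function(lines, path = tempfile(fileext = ".gff3")) {
  writeLines(c("##gff-version 3", lines), path)
  path
}

gff_line <- function(seqid, type, start, end, strand, attrs, phase = ".") {
  paste(seqid, "test", type, start, end, ".", strand, phase, attrs,
        sep = "\t")
}

# a single-gene annotation block: gene + mRNA + one CDS row per exon interval
gene_block <- function(seqid, gid, strand, exons) {
  s <- min(vapply(exons, `[[`, 0, 1)); e <- max(vapply(exons, `[[`, 0, 2))
  c(gff_line(seqid, "gene", s, e, strand, paste0("ID=", gid)),
    gff_line(seqid, "mRNA", s, e, strand,
             paste0("ID=", gid, ".t1;Parent=", gid)),
    vapply(exons, function(ex) {
      gff_line(seqid, "CDS", ex[1], ex[2], strand,
               paste0("ID=CDS:", gid, ".t1;Parent=", gid, ".t1"))
    }, character(1)))
}

# build a scub_transcripts table directly from CDS strings (single- or
# multi-exon via exon_widths); bypasses file I/O for statistics tests
tx_from_cds <- function(cds, exon_widths = NULL, species = "fixture") {
  n <- length(cds)
  if (is.null(exon_widths)) exon_widths <- lapply(nchar(cds), identity)
  tx <- data.table::data.table(
    gene_id = paste0("g", seq_len(n)),
    transcript_id = paste0("g", seq_len(n), ".t1"),
    chromosome = "chr1", strand = "+",
    exon_count = lengths(exon_widths),
    intron_count = lengths(exon_widths) - 1L,
    cds_sequence = cds,
    exon_start0 = lapply(exon_widths, function(w) cumsum(c(0L, w[-length(w)]))),
    exon_end0 = lapply(exon_widths, cumsum),
    exon_width = exon_widths)
  data.table::setattr(tx, "species_label", species)
  data.table::setattr(tx, "class",
                      c("scub_transcripts", class(data.table::data.table())))
  tx[]
}

records_from_cds <- function(cds, exon_widths = NULL, species = "fixture") {
  suppressMessages(assign_codons(tx_from_cds(cds, exon_widths, species)))
}

# counts object built from an explicit codon -> count mapping
counts_from_map <- function(map, scope = "fixture") {
  count_codons(rep(names(map), times = unlist(map)), scope_label = scope)
}
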