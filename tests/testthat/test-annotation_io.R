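# a 60-nt chromosome used by several fixtures (alphabet A/C/G/T)
fix_chr <- paste0("AAAAAAAAAA", "ATGGCTTAAG", "CCCCCCCCCC",
                  "ATGAAAGGGT", "AATTTTTTTT", "GGGGGGGGGG")

test_that("GFF3 1-based inclusive coordinates map to 0-based half-open", {
  # CDS spanning bases 11..19 -> characters 11..19 of the chromosome string
  fa <- write_fixture_fasta(c(chr1 = fix_chr))
  gf <- write_fixture_gff3(gene_block("chr1", "gA", "+", list(c(11, 19))))
  tx <- load_transcripts(fa, gf)
  expect_identical(tx$cds_sequence, substr(fix_chr, 11, 19))
  expect_identical(tx$cds_sequence, "ATGGCTTAA")
  expect_identical(tx$exon_start0[[1]], 10L)
  expect_identical(tx$exon_end0[[1]], 19L)
})

test_that("minus-strand multi-exon CDS is stitched in descending order and reverse-complemented", {
  set.seed(42)
  chr <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
               collapse = "")
  fa <- write_fixture_fasta(c(chrM = chr))
  gf <- write_fixture_gff3(gene_block("chrM", "gM", "-",
                                      list(c(3, 11), c(18, 26))))
  tx <- load_transcripts(fa, gf)
  # brute-force expectation: revcomp of concatenated genomic exons taken in
  # descending coordinate order
  expected <- paste0(oracle_revcomp(substr(chr, 18, 26)),
                     oracle_revcomp(substr(chr, 3, 11)))
  expect_identical(tx$cds_sequence, expected)
  # transcript-order intervals descend along the genome
  expect_identical(tx$exon_start0[[1]], c(17L, 2L))
  expect_identical(tx$exon_end0[[1]], c(26L, 11L))
})

test_that("the first mRNA in document order is chosen; zero-CDS genes are skipped", {
  fa <- write_fixture_fasta(c(chr1 = fix_chr))
  lines <- c(
    gff_line("chr1", "gene", 11, 50, "+", "ID=gA"),
    gff_line("chr1", "mRNA", 11, 19, "+", "ID=gA.t1;Parent=gA"),
    gff_line("chr1", "mRNA", 31, 45, "+", "ID=gA.t2;Parent=gA"),
    gff_line("chr1", "CDS", 11, 19, "+", "ID=c1;Parent=gA.t1"),
    gff_line("chr1", "CDS", 31, 45, "+", "ID=c2;Parent=gA.t2"),
    gff_line("chr1", "gene", 51, 60, "+", "ID=gEmpty"),
    gff_line("chr1", "mRNA", 51, 60, "+", "ID=gEmpty.t1;Parent=gEmpty"))
  gf <- write_fixture_gff3(lines)
  expect_warning(tx <- load_transcripts(fa, gf), "zero CDS")
  expect_identical(nrow(tx), 1L)
  expect_identical(tx$transcript_id, "gA.t1")
  expect_identical(tx$cds_sequence, "ATGGCTTAA")
})

test_that("malformed GFF3 and missing sequence regions are hard errors", {
  fa <- write_fixture_fasta(c(chr1 = fix_chr))
  bad <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", "chr1\tonly\tthree"), bad)
  expect_error(load_transcripts(fa, bad), "line 2")
  gf <- write_fixture_gff3(gene_block("chrZ", "gA", "+", list(c(11, 19))))
  expect_error(load_transcripts(fa, gf), "chrZ")
})

test_that("CDS filters reject with the first matching reason in fixed order", {
  rep_ <- filter_cds(c("GTGAAATAA",    # bad start
                       "ATGAAATAA",    # retained
                       "ATGAANTAA",    # contains N
                       "ATGAAATAAC",   # not multiple of three
                       "ATGAAACCC",    # bad stop
                       "",             # empty -> not multiple of three
                       "GTGANTAACC"))  # bad length + N + bad start: length wins
  expect_identical(rep_$outcome,
                   c("rejected", "retained", "rejected", "rejected",
                     "rejected", "rejected", "rejected"))
  expect_identical(rep_$reason,
                   c("bad_start", "none", "contains_N",
                     "not_multiple_of_three", "bad_stop",
                     "not_multiple_of_three", "not_multiple_of_three"))
  # N outranks bad start when length is fine
  expect_identical(filter_cds("GTGAANTAA")$reason, "contains_N")
})

test_that("codons split by introns follow the upstream/downstream phase rule", {
  # exon widths 7 + 8: boundary after nt 7 = between codon 3's 1st and 2nd
  # nucleotide (phase-1 break) -> codon 3 belongs to the downstream exon
  rec <- records_from_cds("ATGGCTAAAGCTTAA", list(c(7L, 8L)))
  expect_identical(rec$exon_ordinal, c(1L, 1L, 2L, 2L, 2L))
  # exon widths 8 + 7: boundary between codon 3's 2nd and 3rd nucleotide
  # (phase-2 break) -> codon 3 stays with the upstream exon
  rec2 <- records_from_cds("ATGGCTAAAGCTTAA", list(c(8L, 7L)))
  expect_identical(rec2$exon_ordinal, c(1L, 1L, 1L, 2L, 2L))
  # clean boundary (phase 0) after codon 2
  rec0 <- records_from_cds("ATGGCTAAAGCTTAA", list(c(6L, 9L)))
  expect_identical(rec0$exon_ordinal, c(1L, 1L, 2L, 2L, 2L))
  # single-exon gene: every codon in exon 1
  rec1 <- records_from_cds("ATGGCTAAAGCTTAA")
  expect_identical(rec1$exon_ordinal, rep(1L, 5L))
})

test_that("cumulative-length oracle agrees on arbitrary split positions", {
  cds <- "ATGGCTAAAGCTGGGAAATTTCCCTAA"  # 9 codons
  for (w1 in 4:23) {
    widths <- c(w1, nchar(cds) - w1)
    rec <- records_from_cds(cds, list(as.integer(widths)))
    cum <- cumsum(widths)
    expected <- vapply(seq_len(9L), function(i) which(cum >= 3L * i - 1L)[1L],
                       integer(1))
    expect_identical(rec$exon_ordinal, expected, info = paste("w1 =", w1))
  }
})

test_that("next_first_base walks the spliced CDS, stop codon donating context", {
  rec <- records_from_cds("ATGGCTAAATAA")
  expect_identical(rec$codon, c("ATG", "GCT", "AAA", "TAA"))
  expect_identical(rec$next_first_base, c("G", "A", "T", NA))
  expect_identical(rec$is_stop, c(FALSE, FALSE, FALSE, TRUE))
  expect_identical(rec$next_is_stop, c(FALSE, FALSE, TRUE, FALSE))
  expect_identical(rec$amino_acid, c("M", "A", "K", "*"))
})

test_that("round-trip invariants hold on a synthetic genome", {
  spec <- generator_spec(seed = 5, n_genes = 60, species_label = "inv")
  g <- generate_genome(spec, file.path(tempdir(), "inv_genome"))
  tx <- load_transcripts(g$fasta, g$gff3, species_label = "inv")
  rep_ <- filter_cds(tx)
  expect_true(all(rep_$outcome == "retained"))
  rec <- suppressMessages(assign_codons(tx))
  # no internal stops
  expect_true(all(rec$amino_acid[!rec$is_stop] != "*"))
  # codons per exon sum to CDS length / 3, per transcript
  per_tx <- rec[, .N, by = gene_id]
  expect_identical(per_tx$N, as.integer(nchar(tx$cds_sequence) / 3))
  # exon ordinals within bounds
  expect_true(all(rec$exon_ordinal >= 1L & rec$exon_ordinal <= rec$exon_count))
})
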