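#' Load one transcript model per protein-coding gene from FASTA + GFF3
#'
#' Reads a genome FASTA and its GFF3 annotation, picks one transcript per gene
#' (by default the first mRNA child in GFF3 document order), stitches its CDS
#' features into a spliced coding sequence in transcript orientation (minus
#' strand reverse-complemented), and records the ordered coding-exon intervals.
#' GFF3 1-based inclusive coordinates are converted to the internal 0-based
#' half-open convention.
#'
#' The CDS is expected to include the stop codon (EnsemblPlants convention);
#' transcripts whose stitched CDS lacks a terminal stop are later rejected by
#' [filter_cds()]. Exon and intron counts refer to *coding* exons only.
#'
#' @param fasta_path path to the genome FASTA (optionally gzipped). Lowercase
#'   (soft-masked) bases are folded to uppercase; the alphabet must be
#'   A/C/G/T/N.
#' @param gff3_path path to the GFF3 annotation with gene / mRNA / CDS
#'   features.
#' @param species_label free-text label attached to all downstream records.
#' @param transcript_choice `"document"` (default) selects the first mRNA of
#'   each gene in file order; `"id"` selects the lexicographically first
#'   transcript ID.
#' @return A `data.table` of class `scub_transcripts`, one row per retained
#'   gene, with columns `gene_id`, `transcript_id`, `chromosome`, `strand`,
#'   `exon_count`, `intron_count`, `cds_sequence`, and list columns
#'   `exon_start0` / `exon_end0` (0-based half-open genomic intervals in
#'   5'→3' transcript order; descending genomic coordinate on the minus
#'   strand) and `exon_width`.
#' @seealso [filter_cds()], [assign_codons()]
#' @export
load_transcripts <- function(fasta_path, gff3_path,
                             species_label = "species",
                             transcript_choice = c("document", "id")) {
  transcript_choice <- match.arg(transcript_choice)
  if (!file.exists(fasta_path)) stop("FASTA not found: ", fasta_path)
  if (!file.exists(gff3_path)) stop("GFF3 not found: ", gff3_path)

  .validate_gff3_lines(gff3_path)

  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  chr_seq <- toupper(as.character(genome))
  bad <- vapply(chr_seq, function(s) grepl("[^ACGTN]", s), logical(1))
  if (any(bad)) {
    stop("sequence region(s) with alphabet outside A/C/G/T/N: ",
         paste(names(chr_seq)[bad], collapse = ", "))
  }

  gff <- rtracklayer::import(gff3_path, format = "gff3")
  df <- data.table::as.data.table(as.data.frame(gff))
  if (!nrow(df)) {
    return(.empty_transcripts(species_label))
  }
  df[, Parent := vapply(Parent, function(p) if (length(p)) p[[1]] else NA_character_,
                        character(1))]
  df[, row := .I]

  genes <- df[type == "gene"]
  mrnas <- df[type %in% c("mRNA", "transcript") & Parent %chin% genes$ID]
  if (transcript_choice == "document") {
    data.table::setorder(mrnas, row)
  } else {
    data.table::setorder(mrnas, ID)
  }
  chosen <- mrnas[, .SD[1L], by = Parent]
  data.table::setnames(chosen, "Parent", "gene_id")

  cds <- df[type == "CDS" & Parent %chin% chosen$ID]
  no_cds <- setdiff(chosen$ID, unique(cds$Parent))
  if (length(no_cds)) {
    warning(length(no_cds), " gene(s) with zero CDS features skipped",
            call. = FALSE)
    chosen <- chosen[!ID %chin% no_cds]
  }
  if (!nrow(chosen)) return(.empty_transcripts(species_label))

  cds[, chromosome := as.character(seqnames)]
  missing_chr <- setdiff(unique(cds$chromosome), names(chr_seq))
  if (length(missing_chr)) {
    stop("CDS feature references missing sequence region: ",
         paste(missing_chr, collapse = ", "))
  }

  # stitch in ascending genomic order, then reverse-complement whole minus CDS
  data.table::setorder(cds, Parent, start)
  cds[, piece := substring(chr_seq[chromosome], start, end)]
  asm <- cds[, .(
    chromosome = chromosome[1L],
    strand = as.character(strand[1L]),
    cds_plus = paste(piece, collapse = ""),
    starts = list(start), ends = list(end)
  ), by = .(transcript_id = Parent)]
  minus <- asm$strand == "-"
  asm[, cds_sequence := cds_plus]
  asm[minus, cds_sequence := .revcomp(cds_plus)]
  asm[, exon_start0 := lapply(starts, function(s) s - 1L)]
  asm[, exon_end0 := ends]
  # transcript order: descending genomic coordinate on the minus strand
  asm[minus, `:=`(exon_start0 = lapply(exon_start0, rev),
                  exon_end0 = lapply(exon_end0, rev))]
  asm[, exon_width := Map(function(s, e) e - s, exon_start0, exon_end0)]
  asm[, exon_count := lengths(exon_start0)]
  asm[, intron_count := exon_count - 1L]

  out <- merge(chosen[, .(gene_id, transcript_id = ID, gene_row = row)],
               asm[, .(transcript_id, chromosome, strand, exon_count,
                       intron_count, cds_sequence, exon_start0, exon_end0,
                       exon_width)],
               by = "transcript_id")
  data.table::setorder(out, gene_row)
  out[, gene_row := NULL]
  data.table::setcolorder(out, c("gene_id", "transcript_id", "chromosome",
                                 "strand"))
  data.table::setattr(out, "species_label", species_label)
  data.table::setattr(out, "class",
                      c("scub_transcripts", class(data.table::data.table())))
  out[]
}

.empty_transcripts <- function(species_label) {
  out <- data.table::data.table(
    gene_id = character(), transcript_id = character(),
    chromosome = character(), strand = character(),
    exon_count = integer(), intron_count = integer(),
    cds_sequence = character(),
    exon_start0 = list(), exon_end0 = list(), exon_width = list())
  data.table::setattr(out, "species_label", species_label)
  data.table::setattr(out, "class",
                      c("scub_transcripts", class(data.table::data.table())))
  out[]
}

# every non-comment GFF3 line must carry 9 tab-separated fields
.validate_gff3_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(lines)
  ntab <- lengths(regmatches(lines, gregexpr("\t", lines, fixed = TRUE)))
  bad <- which(body & ntab != 8L)
  if (length(bad)) {
    stop("malformed GFF3 line ", bad[1L], " in ", path,
         " (expected 9 tab-separated fields)")
  }
  invisible(TRUE)
}

#' Classify assembled CDS sequences against the retention filters
#'
#' A CDS is rejected with the *first* matching reason in the fixed order:
#' length not a multiple of three (an empty CDS also fails here), contains N,
#' start codon not ATG, final codon not one of TAA/TAG/TGA. Retained
#' otherwise.
#'
#' @param x a `scub_transcripts` table (from [load_transcripts()]) or a plain
#'   character vector of CDS sequences.
#' @return A `data.table` (the per-gene filter report) with columns `gene_id`,
#'   `transcript_id`, `outcome` (`retained` / `rejected`) and `reason`
#'   (`not_multiple_of_three`, `contains_N`, `bad_start`, `bad_stop`, `none`).
#'   For character input, `gene_id` is the element index.
#' @export
filter_cds <- function(x) {
  if (is.character(x)) {
    dt <- data.table::data.table(
      gene_id = as.character(seq_along(x)),
      transcript_id = as.character(seq_along(x)),
      cds = x)
  } else {
    dt <- data.table::data.table(
      gene_id = x$gene_id, transcript_id = x$transcript_id,
      cds = x$cds_sequence)
  }
  n <- nchar(dt$cds)
  last_codon <- substring(dt$cds, pmax(n - 2L, 1L), n)
  reason <- rep("none", nrow(dt))
  reason[!(substring(dt$cds, 1L, 3L) == "ATG")] <- "bad_start"
  reason[grepl("N", dt$cds, fixed = TRUE)] <- "contains_N"
  reason[n == 0L | n %% 3L != 0L] <- "not_multiple_of_three"
  # bad_stop ranks last: only genes passing the three rules above get it
  bs <- reason == "none" & !(last_codon %in% c("TAA", "TAG", "TGA"))
  reason[bs] <- "bad_stop"
  dt[, `:=`(outcome = ifelse(reason == "none", "retained", "rejected"),
            reason = reason, cds = NULL)]
  dt[]
}

#' Assign every codon of the retained CDSs to a coding exon
#'
#' Produces one record per codon, including the stop codon (flagged
#' `is_stop`, for downstream exclusion). A codon split by an intron between
#' its 1st and 2nd nucleotide belongs to the downstream exon; split between
#' the 2nd and 3rd nucleotide, to the upstream exon; unsplit codons to the
#' exon containing them. Equivalently, a codon belongs to the exon containing
#' its middle nucleotide. `next_first_base` of codon *i* is the first base of
#' codon *i + 1* on the spliced CDS (the stop codon donates context to the
#' final sense codon and itself has `NA`).
#'
#' @param transcripts a `scub_transcripts` table. Transcripts failing
#'   [filter_cds()] are dropped with a message.
#' @param code a genetic code from [scub_genetic_code()].
#' @return A `data.table` of codon records: `species`, `gene_id`,
#'   `transcript_id`, `chromosome`, `codon`, `amino_acid` (stop = `"*"`),
#'   `ordinal`, `exon_ordinal`, `exon_count`, `intron_count`,
#'   `next_first_base`, `is_start`, `is_stop`.
#' @export
assign_codons <- function(transcripts, code = .genetic_code()) {
  rep_ <- filter_cds(transcripts)
  keep <- rep_$outcome == "retained"
  if (any(!keep)) {
    message(sum(!keep), " transcript(s) rejected by CDS filters; ",
            sum(keep), " retained")
  }
  tx <- transcripts[keep]
  if (!nrow(tx)) {
    return(data.table::data.table(
      species = character(), gene_id = character(),
      transcript_id = character(), chromosome = character(),
      codon = character(), amino_acid = character(), ordinal = integer(),
      exon_ordinal = integer(), exon_count = integer(),
      intron_count = integer(), next_first_base = character(),
      next_is_stop = logical(), is_start = logical(), is_stop = logical()))
  }
  n_cod <- nchar(tx$cds_sequence) %/% 3L
  rec <- data.table::data.table(
    tid = rep.int(seq_len(nrow(tx)), n_cod),
    ordinal = sequence(n_cod))
  rec[, codon := substring(tx$cds_sequence[tid], 3L * ordinal - 2L,
                           3L * ordinal)]
  rec[, mid := 3L * ordinal - 1L]
  cum_ends <- lapply(tx$exon_width, cumsum)
  rec[, exon_ordinal := findInterval(mid - 0.5, cum_ends[[tid[1L]]]) + 1L,
      by = tid]
  rec[, next_first_base := data.table::shift(substring(codon, 1L, 1L),
                                             type = "lead"), by = tid]
  rec[, next_is_stop := ordinal == n_cod[tid] - 1L]
  rec[, `:=`(
    species = attr(transcripts, "species_label") %||% "species",
    gene_id = tx$gene_id[tid],
    transcript_id = tx$transcript_id[tid],
    chromosome = tx$chromosome[tid],
    amino_acid = unname(code$codon_to_aa[codon]),
    exon_count = tx$exon_count[tid],
    intron_count = tx$intron_count[tid],
    is_start = ordinal == 1L,
    is_stop = ordinal == n_cod[tid][1L]), by = tid]
  rec[, c("tid", "mid") := NULL]
  data.table::setcolorder(rec, c("species", "gene_id", "transcript_id",
                                 "chromosome", "codon", "amino_acid",
                                 "ordinal", "exon_ordinal", "exon_count",
                                 "intron_count", "next_first_base",
                                 "next_is_stop", "is_start", "is_stop"))
  rec[]
}

#' Write the per-gene filter report as TSV
#'
#' @param report output of [filter_cds()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  write_tsv(report[, c("gene_id", "transcript_id", "outcome", "reason")],
            path)
}
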