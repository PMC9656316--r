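# Independent splice-and-scan oracle: a deliberately naive, loop-based
# re-implementation of CDS extraction and codon/exon assignment using only
# base R. It shares no code with the package internals.

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCATGCA", x), "")[[1]]),
        collapse = "")
}

oracle_read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (!length(hdr)) return(character(0))
  nm <- sub("^>(\\S+).*$", "\\1", lines[hdr])
  starts <- hdr + 1L
  ends <- c(hdr[-1L] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i) {
    toupper(paste(lines[seq(starts[i], ends[i])], collapse = ""))
  }, character(1))
  stats::setNames(seqs, nm)
}

oracle_read_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(seqid = character(), type = character(),
                      start = integer(), end = integer(),
                      strand = character(), attr = character()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(
    seqid = vapply(f, `[[`, "", 1L),
    type = vapply(f, `[[`, "", 3L),
    start = as.integer(vapply(f, `[[`, "", 4L)),
    end = as.integer(vapply(f, `[[`, "", 5L)),
    strand = vapply(f, `[[`, "", 7L),
    attr = vapply(f, `[[`, "", 9L),
    stringsAsFactors = FALSE)
}

oracle_attr <- function(attr, key) {
  m <- regmatches(attr, regexpr(paste0("(^|;)", key, "=[^;]+"), attr))
  ifelse(lengths(regmatches(attr, regexpr(paste0("(^|;)", key, "=[^;]+"),
                                          attr))) > 0,
         sub(paste0("^;?", key, "="), "", m), NA_character_)
}

# one row per codon (stop included), genes in GFF document order
oracle_codon_records <- function(fasta_path, gff3_path) {
  genome <- oracle_read_fasta(fasta_path)
  gff <- oracle_read_gff3(gff3_path)
  out <- list()
  gene_rows <- which(gff$type == "gene")
  for (gi in gene_rows) {
    gid <- sub("^.*ID=([^;]+).*$", "\\1", gff$attr[gi])
    mr <- which(gff$type %in% c("mRNA", "transcript") &
                  grepl(paste0("Parent=", gid, "($|;)"), gff$attr))
    if (!length(mr)) next
    tid <- sub("^.*ID=([^;]+).*$", "\\1", gff$attr[mr[1L]])
    cr <- which(gff$type == "CDS" &
                  grepl(paste0("Parent=", tid, "($|;)"), gff$attr))
    if (!length(cr)) next
    cr <- cr[order(gff$start[cr])]
    pieces <- vapply(cr, function(i) {
      substr(genome[[gff$seqid[i]]], gff$start[i], gff$end[i])
    }, character(1))
    strand <- gff$strand[cr[1L]]
    if (strand == "-") {
      # transcript order = descending coordinate, each piece revcomped
      pieces <- vapply(rev(pieces), oracle_revcomp, character(1))
      widths <- rev(gff$end[cr] - gff$start[cr] + 1L)
    } else {
      widths <- gff$end[cr] - gff$start[cr] + 1L
    }
    cds <- paste(pieces, collapse = "")
    # retention filters
    n <- nchar(cds)
    if (n == 0L || n %% 3L != 0L) next
    if (grepl("N", cds, fixed = TRUE)) next
    if (substr(cds, 1L, 3L) != "ATG") next
    if (!(substr(cds, n - 2L, n) %in% c("TAA", "TAG", "TGA"))) next
    cum <- cumsum(widths)
    nc <- n %/% 3L
    codons <- character(nc); exon <- integer(nc)
    for (i in seq_len(nc)) {
      codons[i] <- substr(cds, 3L * i - 2L, 3L * i)
      midpos <- 3L * i - 1L
      exon[i] <- which(cum >= midpos)[1L]  # exon owning the middle base
    }
    out[[length(out) + 1L]] <- data.frame(
      gene_id = gid, ordinal = seq_len(nc), codon = codons,
      exon_ordinal = exon,
      next_first_base = c(substr(codons[-1L], 1L, 1L), NA_character_),
      is_stop = seq_len(nc) == nc, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# naive context tally over the oracle records
oracle_context_tally <- function(rec) {
  code <- scub_genetic_code()
  bases <- c("A", "C", "G", "T")
  zero <- stats::setNames(numeric(4), bases)
  nxa <- nxg <- ntx <- ncx <- zero
  for (i in seq_len(nrow(rec))) {
    cdn <- rec$codon[i]
    if (!(cdn %in% code$sc_set)) next
    t3 <- substr(cdn, 3, 3); s2 <- substr(cdn, 2, 2)
    if (t3 == "A") nxa[s2] <- nxa[s2] + 1
    if (t3 == "G") nxg[s2] <- nxg[s2] + 1
    nb <- rec$next_first_base[i]
    if (!is.na(nb)) {
      if (t3 == "T") ntx[nb] <- ntx[nb] + 1
      if (t3 == "C") ncx[nb] <- ncx[nb] + 1
    }
  }
  list(nxa = nxa, nxg = nxg, ntx = ntx, ncx = ncx)
}
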