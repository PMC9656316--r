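#' Specification for a synthetic annotated genome
#'
#' Describes a seed-deterministic genome with known codon-usage structure.
#' Each gene is `ATG + sampled sense codons + one stop codon`, split into 1-10
#' coding exons by introns inserted at random codon-phase positions. Codon
#' sampling is two-pass: amino acids and the first two codon bases are drawn
#' first; third bases are then drawn with a C/G-versus-A/T log-odds
#'
#' `eta = beta0 + beta_first * [first exon] - beta1 * introns - beta2 * w`
#'
#' where `w(ordinal, m)` is a triangular centrality weight, zero at ordinals
#' 1, 2 and m, peaking midway between the second and last exon (and zero for
#' genes with fewer than four exons). The third base is C/G with probability
#' `plogis(eta)` (uniform within the available C/G endings of the codon's
#' family prefix group, likewise for A/T), after a CpG-context re-weighting:
#' the weight of an A ending is multiplied by `gamma` when the second base is
#' C, and the weight of a T ending by `gamma` when the (already drawn) next
#' codon starts with G.
#'
#' Defaults portray a plant-like genome: a baseline preference for C/G-ending
#' synonymous codons (`beta0 = 1.1`; after the intron, positional and CpG
#' context effects this puts the genome-wide NNA/T : NNC/G ratio near
#' 0.6-0.7, the band observed in rice genomes), a per-intron shift toward
#' A/T endings (`beta1 = 0.1`, so nine-intron genes approach parity), a
#' convex internal-exon A/T boost (`beta2 = 0.3`), extra C/G bias in first
#' exons (`beta_first = 0.15`) and a CpG-context inflation `gamma = 1.5`.
#'
#' @param seed integer RNG seed; the whole genome is a deterministic function
#'   of the spec.
#' @param n_genes,n_chromosomes genome size; genes are placed on chromosomes
#'   in contiguous blocks with single-base intergenic spacers.
#' @param exon_count_probs probability weights over 1-10 coding exons.
#' @param exon_len_mean,exon_len_min codons per exon: `exon_len_min +
#'   Poisson(exon_len_mean - exon_len_min)`, minimum 2.
#' @param aa_probs optional named weights over the 18 degenerate amino acids
#'   (uniform by default).
#' @param met_trp_rate probability that a body codon is Met or Trp (split
#'   equally), the non-degenerate background.
#' @param beta0,beta1,beta2,beta_first,gamma third-base sampling parameters,
#'   see above; `gamma > 0`.
#' @param intron_len_range integer range of intron lengths (`GT...AG` filler,
#'   minimum 6 nt).
#' @param species_label label used for records and file names.
#' @return A list of class `scub_generator_spec`.
#' @export
generator_spec <- function(seed = 1L, n_genes = 500L, n_chromosomes = 2L,
                           exon_count_probs = c(0.26, 0.16, 0.12, 0.10, 0.08,
                                                0.07, 0.06, 0.05, 0.05, 0.05),
                           exon_len_mean = 20, exon_len_min = 2L,
                           aa_probs = NULL, met_trp_rate = 0.05,
                           beta0 = 1.1, beta1 = 0.1, beta2 = 0.3,
                           beta_first = 0.15, gamma = 1.5,
                           intron_len_range = c(12L, 40L),
                           species_label = "synthetic") {
  stopifnot(length(exon_count_probs) == 10L, all(exon_count_probs >= 0),
            sum(exon_count_probs) > 0, exon_len_min >= 2L,
            exon_len_mean >= exon_len_min, gamma > 0,
            met_trp_rate >= 0, met_trp_rate < 1,
            length(intron_len_range) == 2L, intron_len_range[1] >= 6L,
            intron_len_range[2] >= intron_len_range[1],
            n_genes >= 0L, n_chromosomes >= 1L)
  code <- .genetic_code()
  if (is.null(aa_probs)) {
    aa_probs <- stats::setNames(rep(1 / 18, 18L), code$degenerate_aas)
  }
  stopifnot(setequal(names(aa_probs), code$degenerate_aas),
            all(aa_probs >= 0), sum(aa_probs) > 0)
  structure(list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    n_chromosomes = as.integer(n_chromosomes),
    exon_count_probs = exon_count_probs / sum(exon_count_probs),
    exon_len_mean = exon_len_mean, exon_len_min = as.integer(exon_len_min),
    aa_probs = aa_probs[code$degenerate_aas] / sum(aa_probs),
    met_trp_rate = met_trp_rate,
    beta0 = beta0, beta1 = beta1, beta2 = beta2, beta_first = beta_first,
    gamma = gamma, intron_len_range = as.integer(intron_len_range),
    species_label = species_label), class = "scub_generator_spec")
}

# family prefix groups: for each degenerate amino acid, the sets of codons
# sharing their first two bases, with third-base availability
.codon_groups <- function(code = .genetic_code()) {
  rows <- lapply(code$degenerate_aas, function(a) {
    fam <- code$families[[a]]
    pre <- substr(fam, 1L, 2L)
    data.table::rbindlist(lapply(unique(pre), function(p) {
      ends <- substr(fam[pre == p], 3L, 3L)
      data.table::data.table(
        aa = a, prefix = p,
        availA = "A" %in% ends, availC = "C" %in% ends,
        availG = "G" %in% ends, availT = "T" %in% ends,
        n_at = sum(ends %in% .AT_BASES), n_cg = sum(ends %in% .CG_BASES),
        gsize = length(ends))
    }))
  })
  data.table::rbindlist(rows)
}

# centrality weight: 0 at ordinals 1, 2 and m, triangular peak at the middle
# of [2, m]; identically 0 for m < 4
.centrality_w <- function(ordinal, m) {
  ctr <- (2 + m) / 2
  w <- pmax(0, 1 - abs(ordinal - ctr) / (ctr - 2))
  w[m < 4L | ordinal == 1L] <- 0
  w
}

# pass 1: gene architecture, amino acids, prefixes, introns, placement
.gen_structure <- function(spec) {
  code <- .genetic_code()
  set.seed(spec$seed)
  n <- spec$n_genes
  if (n == 0L) {
    return(list(spec = spec, genes = NULL, exons = NULL, codons = NULL))
  }
  m <- sample.int(10L, n, replace = TRUE, prob = spec$exon_count_probs)
  exons <- data.table::data.table(gene = rep.int(seq_len(n), m),
                                  exon_idx = sequence(m))
  exons[, k_codons := spec$exon_len_min +
          stats::rpois(.N, spec$exon_len_mean - spec$exon_len_min)]
  exons[, m := m[gene]]
  genes <- exons[, .(m = m[1L], N = sum(k_codons)), by = gene]
  # intron break phase: 0 = between codons, 1 = after 1st nt (downstream
  # exon owns the codon), 2 = after 2nd nt (upstream exon owns it)
  exons[, phase_break := 0L]
  exons[exon_idx < m, phase_break := sample(0:2, sum(exon_idx < m),
                                            replace = TRUE)]
  exons[, cum_end := cumsum(k_codons) * 3L, by = gene]
  exons[, B := cum_end - phase_break]
  exons[exon_idx == m, B := cum_end]
  exons[, phase := {
    prevB <- data.table::shift(B, fill = 0L)
    as.integer((3L - prevB %% 3L) %% 3L)
  }, by = gene]

  # intron filler: GT ... AG, arbitrary but seed-deterministic interior
  n_intron <- nrow(exons) - n
  exons[, intron_len := NA_integer_]
  exons[, intron_seq := NA_character_]
  if (n_intron > 0L) {
    ilen <- sample(seq(spec$intron_len_range[1], spec$intron_len_range[2]),
                   n_intron, replace = TRUE)
    interior <- paste(sample(.BASES, sum(ilen - 4L), replace = TRUE),
                      collapse = "")
    offs <- cumsum(ilen - 4L)
    iseq <- paste0("GT", substring(interior, c(1L, utils::head(offs, -1L) + 1L),
                                   offs), "AG")
    exons[exon_idx < m, `:=`(intron_len = ilen, intron_seq = iseq)]
  }

  genes[, intron_count := m - 1L]
  genes[, chromosome := paste0("chr", ceiling(seq_len(n) * spec$n_chromosomes / n))]
  genes[, strand := sample(c("+", "-"), n, replace = TRUE)]
  genes[, stop_codon := sample(code$stops, n, replace = TRUE)]
  genes[, spacer := sample(.BASES, n, replace = TRUE)]
  genes[, gene_id := sprintf("g%06d", gene)]

  codons <- data.table::data.table(gene = rep.int(seq_len(n), genes$N),
                                   ordinal = sequence(genes$N))
  codons[, N := genes$N[gene]]
  codons[, m := genes$m[gene]]
  codons[, intron_count := genes$intron_count[gene]]
  codons[, is_start := ordinal == 1L]
  codons[, is_stop := ordinal == N]
  Bl <- exons[, .(Bl = list(B)), by = gene]$Bl
  codons[, exon_ordinal := findInterval(3 * ordinal - 1.5, Bl[[gene[1L]]]) + 1L,
         by = gene]

  # amino acids and prefixes for body codons
  body <- which(!codons$is_start & !codons$is_stop)
  nb <- length(body)
  aa_v <- character(nb)
  mt <- stats::runif(nb) < spec$met_trp_rate
  if (any(mt)) aa_v[mt] <- sample(c("M", "W"), sum(mt), replace = TRUE)
  if (any(!mt)) aa_v[!mt] <- sample(names(spec$aa_probs), sum(!mt),
                                    replace = TRUE, prob = spec$aa_probs)
  groups <- .codon_groups(code)
  prefix_v <- character(nb)
  fixed_v <- character(nb)  # full codon when non-degenerate
  fixed_v[aa_v == "M"] <- "ATG"
  fixed_v[aa_v == "W"] <- "TGG"
  for (a in setdiff(unique(aa_v), c("M", "W"))) {
    idx <- which(aa_v == a)
    g <- groups[aa == a]
    if (nrow(g) == 1L) {
      prefix_v[idx] <- g$prefix
    } else {
      gi <- sample.int(nrow(g), length(idx), replace = TRUE,
                       prob = g$gsize)
      prefix_v[idx] <- g$prefix[gi]
    }
  }
  codons[, `:=`(aa = NA_character_, prefix = NA_character_,
                fixed_codon = NA_character_)]
  codons[body, `:=`(aa = aa_v, prefix = prefix_v,
                    fixed_codon = data.table::fifelse(fixed_v == "",
                                                      NA_character_,
                                                      fixed_v))]
  codons[is_start == TRUE, `:=`(aa = "M", fixed_codon = "ATG")]
  codons[is_stop == TRUE, `:=`(aa = "*", fixed_codon = genes$stop_codon[gene])]
  codons[, first_base := ifelse(is.na(fixed_codon),
                                substring(prefix, 1L, 1L),
                                substring(fixed_codon, 1L, 1L))]
  codons[, next_first := data.table::shift(first_base, type = "lead"),
         by = gene]

  list(spec = spec, genes = genes, exons = exons, codons = codons,
       groups = groups)
}

# pass 2: third bases under a parameter set; independent RNG stream
.gen_third <- function(structure_, spec, stream_seed) {
  codons <- data.table::copy(structure_$codons)
  if (is.null(codons)) return(codons)
  set.seed(stream_seed)
  codons[, codon := fixed_codon]
  free <- which(is.na(codons$codon))
  if (length(free)) {
    sub <- codons[free]
    g <- structure_$groups[sub[, .(aa, prefix)], on = c("aa", "prefix")]
    w <- .centrality_w(sub$exon_ordinal, sub$m)
    eta <- spec$beta0 + spec$beta_first * (sub$exon_ordinal == 1L & sub$m >= 2L) -
      spec$beta1 * sub$intron_count - spec$beta2 * w
    pcg <- stats::plogis(eta)
    wA <- g$availA * (1 - pcg) / g$n_at
    wT <- g$availT * (1 - pcg) / g$n_at
    wC <- g$availC * pcg / g$n_cg
    wG <- g$availG * pcg / g$n_cg
    second <- substring(sub$prefix, 2L, 2L)
    wA <- wA * ifelse(second == "C", spec$gamma, 1)
    wT <- wT * ifelse(!is.na(sub$next_first) & sub$next_first == "G",
                      spec$gamma, 1)
    tot <- wA + wC + wG + wT
    u <- stats::runif(length(free)) * tot
    third <- .BASES[1L + (u > wA) + (u > wA + wC) + (u > wA + wC + wG)]
    codons[free, codon := paste0(prefix, third)]
  }
  codons[]
}

#' Generate a synthetic annotated genome
#'
#' Emits a FASTA + GFF3 pair (standard gene/mRNA/CDS features, 1-based
#' inclusive coordinates, phase column populated) together with a truth
#' manifest sufficient to recompute every expected statistic. Byte-identical
#' under the same spec.
#'
#' @param spec a [generator_spec()].
#' @param dir output directory (created if needed).
#' @param write_codon_manifest also write the per-codon truth table as TSV
#'   (can be large; the manifest is always returned in memory).
#' @return A list of class `scub_genome`: `fasta`, `gff3`, `genes_tsv`,
#'   `params_json` (paths) and `manifest` (list with `genes`, `exons`,
#'   `codons` tables and the spec echo).
#' @export
generate_genome <- function(spec, dir, write_codon_manifest = FALSE) {
  structure_ <- .gen_structure(spec)
  codons <- .gen_third(structure_, spec, stream_seed = spec$seed + 101L)
  .emit_genome(structure_, codons, spec, dir, write_codon_manifest)
}

#' Generate a wild-like / cultivated-like species pair
#'
#' Both genomes share the gene architecture, amino-acid sequences and intron
#' content drawn from the shared structural seed; third bases are drawn
#' independently under each spec's `beta`/`gamma` parameters. All structural
#' fields (seed, gene counts, exon distributions, amino-acid composition)
#' must match between the two specs. The first genome is identical to
#' `generate_genome(spec_wild, dir)`.
#'
#' @param spec_wild,spec_cultivated [generator_spec()]s differing only in
#'   `beta0`, `beta1`, `beta2`, `beta_first`, `gamma` and `species_label`.
#' @param dir output directory.
#' @param write_codon_manifest see [generate_genome()].
#' @return A list with elements `wild` and `cultivated`, each a
#'   `scub_genome`.
#' @export
paired_species <- function(spec_wild, spec_cultivated, dir,
                           write_codon_manifest = FALSE) {
  structural <- c("seed", "n_genes", "n_chromosomes", "exon_count_probs",
                  "exon_len_mean", "exon_len_min", "aa_probs", "met_trp_rate",
                  "intron_len_range")
  for (f in structural) {
    if (!isTRUE(all.equal(spec_wild[[f]], spec_cultivated[[f]]))) {
      stop("paired species must share structural field: ", f)
    }
  }
  if (spec_wild$species_label == spec_cultivated$species_label) {
    stop("paired species need distinct species labels")
  }
  structure_ <- .gen_structure(spec_wild)
  cw <- .gen_third(structure_, spec_wild, stream_seed = spec_wild$seed + 101L)
  cc <- .gen_third(structure_, spec_cultivated,
                   stream_seed = spec_cultivated$seed + 202L)
  list(wild = .emit_genome(structure_, cw, spec_wild, dir,
                           write_codon_manifest),
       cultivated = .emit_genome(structure_, cc, spec_cultivated, dir,
                                 write_codon_manifest))
}

.emit_genome <- function(structure_, codons, spec, dir,
                         write_codon_manifest = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, paste0(spec$species_label, ".fa"))
  gff3 <- file.path(dir, paste0(spec$species_label, ".gff3"))
  genes_tsv <- file.path(dir, paste0(spec$species_label, "_genes.tsv"))
  params_json <- file.path(dir, paste0(spec$species_label, "_params.json"))

  genes <- structure_$genes
  if (is.null(genes)) {
    writeLines(character(0), fasta)
    writeLines("##gff-version 3", gff3)
    write_tsv(data.table::data.table(gene_id = character()), genes_tsv)
    jsonlite::write_json(unclass(spec), params_json, auto_unbox = TRUE,
                         digits = NA)
    return(structure(list(fasta = fasta, gff3 = gff3, genes_tsv = genes_tsv,
                          params_json = params_json,
                          manifest = list(genes = NULL, exons = NULL,
                                          codons = NULL, spec = spec)),
                     class = "scub_genome"))
  }
  exons <- data.table::copy(structure_$exons)
  cds_vec <- codons[, .(cds = paste(codon, collapse = "")), by = gene]$cds

  exons[, prevB := data.table::shift(B, fill = 0L), by = gene]
  exons[, seq := substring(cds_vec[gene], prevB + 1L, B)]

  # transcript-orientation gene block: exon1 intron1 exon2 ... exonM
  pieces <- data.table::rbindlist(list(
    exons[, .(gene, ord = 2L * exon_idx - 1L, seq, exon_idx)],
    exons[!is.na(intron_seq),
          .(gene, ord = 2L * exon_idx, seq = intron_seq,
            exon_idx = NA_integer_)]), use.names = TRUE)
  data.table::setorder(pieces, gene, ord)
  pieces[, e_off := cumsum(nchar(seq)), by = gene]
  pieces[, s_off := e_off - nchar(seq) + 1L]
  blocks <- pieces[, .(block = paste(seq, collapse = ""),
                       block_len = e_off[.N]), by = gene]
  minus <- genes$strand == "-"
  blocks[minus, block := .revcomp(block)]

  # chromosome layout: [spacer][gene][spacer][gene]...
  genes[, block_len := blocks$block_len]
  genes[, gene_start := {
    off <- cumsum(c(0L, utils::head(block_len + 1L, -1L)))
    off + 2L
  }, by = chromosome]
  chrom_seqs <- genes[, .(seq = paste(spacer, blocks$block[gene],
                                      sep = "", collapse = "")),
                      by = chromosome]

  # CDS genomic coordinates (1-based inclusive)
  cds_rows <- pieces[!is.na(exon_idx)]
  cds_rows <- merge(cds_rows,
                    genes[, .(gene, gene_id, chromosome, strand, gene_start,
                              block_len)],
                    by = "gene")
  cds_rows[, `:=`(
    start = ifelse(strand == "+", gene_start + s_off - 1L,
                   gene_start + (block_len - e_off + 1L) - 1L),
    end = ifelse(strand == "+", gene_start + e_off - 1L,
                 gene_start + (block_len - s_off + 1L) - 1L))]
  cds_rows <- merge(cds_rows, exons[, .(gene, exon_idx, phase)],
                    by = c("gene", "exon_idx"))

  gene_rows <- genes[, .(gene_id, chromosome, strand, start = gene_start,
                         end = gene_start + block_len - 1L)]

  fmt <- function(chr, src, type, s, e, strand, phase, attr) {
    paste(chr, src, type, s, e, ".", strand, phase, attr, sep = "\t")
  }
  lines <- c(
    "##gff-version 3",
    sprintf("##sequence-region %s 1 %d", chrom_seqs$chromosome,
            nchar(chrom_seqs$seq)))
  per_gene <- vector("list", nrow(genes))
  data.table::setorder(cds_rows, gene, start)
  cds_split <- split(cds_rows, by = "gene", sorted = TRUE)
  for (i in seq_len(nrow(genes))) {
    gr <- gene_rows[i]
    gid <- gr$gene_id
    tid <- paste0(gid, ".t1")
    cg <- cds_split[[as.character(genes$gene[i])]]
    per_gene[[i]] <- c(
      fmt(gr$chromosome, "scubr", "gene", gr$start, gr$end, gr$strand, ".",
          paste0("ID=", gid, ";biotype=protein_coding")),
      fmt(gr$chromosome, "scubr", "mRNA", gr$start, gr$end, gr$strand, ".",
          paste0("ID=", tid, ";Parent=", gid)),
      fmt(cg$chromosome, "scubr", "CDS", cg$start, cg$end, cg$strand,
          cg$phase, paste0("ID=CDS:", tid, ";Parent=", tid)))
  }
  lines <- c(lines, unlist(per_gene))
  writeLines(lines, gff3)

  seqs <- Biostrings::DNAStringSet(chrom_seqs$seq)
  names(seqs) <- chrom_seqs$chromosome
  Biostrings::writeXStringSet(seqs, fasta, width = 80L)

  genes_out <- genes[, .(gene_id, chromosome, strand, start = gene_start,
                         exon_count = m, intron_count, n_codons = N,
                         stop_codon)]
  write_tsv(genes_out, genes_tsv)
  jsonlite::write_json(unclass(spec), params_json, auto_unbox = TRUE,
                       digits = NA)
  if (write_codon_manifest) {
    write_tsv(codons[, .(gene_id = genes$gene_id[gene], ordinal, codon, aa,
                         exon_ordinal, is_start, is_stop)],
              file.path(dir, paste0(spec$species_label, "_codons.tsv")))
  }
  structure(list(fasta = fasta, gff3 = gff3, genes_tsv = genes_tsv,
                 params_json = params_json,
                 manifest = list(genes = genes_out,
                                 exons = structure_$exons,
                                 codons = codons, spec = spec)),
            class = "scub_genome")
}

utils::globalVariables(c(
  "phase_break", "B", "phase", "intron_len", "intron_seq", "stop_codon",
  "spacer", "fixed_codon", "next_first", "..aa", "..prefix", "..fixed",
  "availA", "availC", "availG", "availT", "n_at", "n_cg", "gsize", "prevB",
  "seq", "ord", "block", "gene_rows", "availT", "codon_a", "codon_g", "row"))
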