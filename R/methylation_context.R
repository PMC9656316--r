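#' Tally CpG-deamination sequence contexts over the 59 SCs
#'
#' Methylated cytosine deaminates to thymine, converting CpG to TpG on the
#' strand carrying the C and to CpA on the opposite strand. Two codon-level
#' proxies follow: (i) A- versus G-ending SCs keyed by their *second* base
#' (the NCA/NCG contrast reads the antisense-strand CpG→CpA conversion), and
#' (ii) T- versus C-ending SCs keyed by the *first base of the following
#' codon* (the NT|G/NC|G contrast reads the sense-strand CpG→TpG conversion).
#'
#' Tallies are restricted to the 59-SC set (ATG, TGG and stops never enter).
#' Records lacking next-codon context (the final codon of a CDS, i.e. the
#' stop, is never an SC record; `NA` context can still arise if the stop
#' donor is disabled) are excluded from the `ntx` / `ncx` tallies only.
#'
#' @param records codon records from [assign_codons()].
#' @param drop_final_context if `TRUE`, the final sense codon's next-first-base
#'   context (donated by the stop codon) is ignored.
#' @return A list of class `scub_context_tally`: `nxa`, `nxg` (counts of A-
#'   resp. G-ending SCs by second base), `ntx`, `ncx` (counts of T- resp.
#'   C-ending SCs by next codon's first base), `sc_counts` (per-codon counts
#'   over the 59 SCs), `n_sc`, `n_no_context`.
#' @export
context_tally <- function(records, drop_final_context = FALSE) {
  code <- .genetic_code()
  sc <- records[codon %chin% code$sc_set]
  t3 <- substring(sc$codon, 3L, 3L)
  s2 <- substring(sc$codon, 2L, 2L)
  tb <- function(sel, key) {
    v <- vapply(.BASES, function(b) sum(sel & key == b, na.rm = TRUE),
                numeric(1))
    stats::setNames(as.numeric(v), .BASES)
  }
  has_ctx <- !is.na(sc$next_first_base)
  if (drop_final_context && "next_is_stop" %in% names(sc)) {
    has_ctx <- has_ctx & !sc$next_is_stop
  }
  structure(list(
    nxa = tb(t3 == "A", s2),
    nxg = tb(t3 == "G", s2),
    ntx = tb(t3 == "T" & has_ctx, sc$next_first_base),
    ncx = tb(t3 == "C" & has_ctx, sc$next_first_base),
    sc_counts = count_codons(sc, scope_label = "sc"),
    n_sc = nrow(sc),
    n_no_context = sum(!has_ctx)), class = "scub_context_tally")
}

#' @export
print.scub_context_tally <- function(x, ...) {
  cat("context tally over", x$n_sc, "SCs\n")
  print(rbind(nxa = x$nxa, nxg = x$nxg, ntx = x$ntx, ncx = x$ncx))
  invisible(x)
}

# amino acids with NNA/NNG sibling pairs sharing the first two bases
.aa_pair_table <- function(code = .genetic_code()) {
  rows <- list()
  for (a in code$degenerate_aas) {
    fam <- code$families[[a]]
    pre <- substr(fam, 1L, 2L)
    t3 <- substr(fam, 3L, 3L)
    for (p in unique(pre)) {
      ca <- fam[pre == p & t3 == "A"]
      cg <- fam[pre == p & t3 == "G"]
      if (length(ca) && length(cg)) {
        rows[[length(rows) + 1L]] <- data.table::data.table(
          amino_acid = a, codon_a = ca, codon_g = cg)
      }
    }
  }
  data.table::rbindlist(rows)
}

#' Context ratios: NXA/NXG, NT|X/NC|X and amino-acid pair ratios
#'
#' Computes the four NXA/NXG ratios (by second base X), the four NT|X/NC|X
#' ratios (by next codon's first base X), and per-amino-acid A-ending over
#' G-ending ratios restricted to synonymous sibling pairs sharing their first
#' two bases (Ala GCA/GCG, Pro CCA/CCG, Ser TCA/TCG, Thr ACA/ACG, plus Arg,
#' Gln, Glu, Gly, Leu, Lys, Val). Zero denominators yield `NA`.
#'
#' @param x a `scub_context_tally`, or codon records (tallied internally).
#' @param ... passed to [context_tally()] when `x` is a record table.
#' @return A list of class `scub_context_ratios`: `r_xa_xg`, `r_tx_cx`
#'   (named over A/C/G/T), `aa_pair_ratios` (named over the 11 amino acids),
#'   and the underlying `tally`.
#' @export
context_ratios <- function(x, ...) {
  tally <- if (inherits(x, "scub_context_tally")) x else context_tally(x, ...)
  safe_div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  pairs <- .aa_pair_table()
  cnt <- unclass(tally$sc_counts)
  aa_ratios <- vapply(unique(pairs$amino_acid), function(a) {
    pp <- pairs[amino_acid == a]
    den <- sum(cnt[pp$codon_g])
    if (den == 0) NA_real_ else sum(cnt[pp$codon_a]) / den
  }, numeric(1))
  structure(list(
    r_xa_xg = stats::setNames(safe_div(tally$nxa, tally$nxg), .BASES),
    r_tx_cx = stats::setNames(safe_div(tally$ntx, tally$ncx), .BASES),
    aa_pair_ratios = aa_ratios,
    tally = tally), class = "scub_context_ratios")
}

#' @export
print.scub_context_ratios <- function(x, ...) {
  cat("NXA/NXG:", sprintf("%s=%.3f", .BASES, x$r_xa_xg), "\n")
  cat("NT|X/NC|X:", sprintf("%s=%.3f", .BASES, x$r_tx_cx), "\n")
  invisible(x)
}

#' Stratified context ratios by intron class or exon position
#'
#' Applies [context_ratios()] within the same strata as the SCUB profiles:
#' intron classes 0-9, or exon ordinals within exon-count classes 2-10.
#'
#' @param records codon records from [assign_codons()].
#' @param by `"intron"` or `"exon_position"`.
#' @param max_introns,m_range stratum ranges (defaults 9 and 2:10).
#' @return A `data.table`, one row per stratum, with columns
#'   `r_AA_AG` ... `r_TA_TG` (NXA/NXG by second base) and
#'   `r_TA_CA` ... `r_TT_CT` (NT|X/NC|X by next first base).
#' @export
stratified_context <- function(records, by = c("intron", "exon_position"),
                               max_introns = 9L, m_range = 2:10) {
  by <- match.arg(by)
  ratio_row <- function(sub, ...) {
    base <- data.table::data.table(...)
    if (!nrow(sub)) {
      vals <- rep(NA_real_, 8L)
    } else {
      cr <- context_ratios(sub)
      vals <- c(cr$r_xa_xg, cr$r_tx_cx)
    }
    nm <- c(paste0("r_", .BASES, "A_", .BASES, "G"),
            paste0("r_T", .BASES, "_C", .BASES))
    base[, (nm) := as.list(vals)]
    base
  }
  if (by == "intron") {
    data.table::rbindlist(lapply(0:max_introns, function(i)
      ratio_row(records[intron_count == i], intron_class = i)), fill = TRUE)
  } else {
    data.table::rbindlist(lapply(m_range, function(m) {
      sub_m <- records[exon_count == m]
      data.table::rbindlist(lapply(seq_len(m), function(o)
        ratio_row(sub_m[exon_ordinal == o], m = m, exon_ordinal = o)),
        fill = TRUE)
    }), fill = TRUE)
  }
}
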