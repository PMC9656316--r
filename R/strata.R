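#' Pool codon counts by intron class
#'
#' Genes with 0 to `max_introns` introns are pooled per class; genes with more
#' introns are excluded from the class tables (they remain part of genome-wide
#' totals) and returned in the `"excluded"` attribute.
#'
#' @param records codon records from [assign_codons()].
#' @param max_introns upper class bound (default 9, i.e. classes 0-9).
#' @return A named list (`"0"` ... `"9"`) of `scub_counts`, with attribute
#'   `excluded` holding the pooled counts of genes above the bound.
#' @export
stratify_by_introns <- function(records, max_introns = 9L) {
  classes <- as.character(0:max_introns)
  out <- lapply(0:max_introns, function(i)
    count_codons(records[intron_count == i],
                 scope_label = paste0("introns_", i)))
  names(out) <- classes
  attr(out, "excluded") <- count_codons(records[intron_count > max_introns],
                                        scope_label = "introns_excluded")
  out
}

#' SCUB summaries per intron class
#'
#' @inheritParams stratify_by_introns
#' @return A `data.table`, one row per intron class with the [scub_summary()]
#'   fractions and ratios (classes with no SCs yield NA rows).
#' @export
intron_profiles <- function(records, max_introns = 9L) {
  strata <- stratify_by_introns(records, max_introns)
  data.table::rbindlist(lapply(names(strata), function(cls) {
    .summary_row(strata[[cls]], intron_class = as.integer(cls))
  }), fill = TRUE)
}

.summary_row <- function(counts, ...) {
  s <- tryCatch(scub_summary(counts), error = function(e) NULL)
  base <- data.table::data.table(...)
  if (is.null(s)) {
    base[, `:=`(n_sc = 0L, f_NNA = NA_real_, f_NNT = NA_real_,
                f_NNC = NA_real_, f_NNG = NA_real_, f_NNAT = NA_real_,
                f_NNCG = NA_real_, ratio_AT_over_CG = NA_real_,
                ratio_CG_over_AT = NA_real_)]
  } else {
    base[, `:=`(n_sc = s$n_sc, f_NNA = s$f_NNA, f_NNT = s$f_NNT,
                f_NNC = s$f_NNC, f_NNG = s$f_NNG, f_NNAT = s$f_NNAT,
                f_NNCG = s$f_NNCG, ratio_AT_over_CG = s$ratio_AT_over_CG,
                ratio_CG_over_AT = s$ratio_CG_over_AT)]
  }
  base
}

#' Exon-position SCUB profiles for genes with m coding exons
#'
#' For each exon-count class `m` in `m_range`, pools the codons of all genes
#' with exactly `m` coding exons by exon ordinal and summarises each ordinal.
#' The terminal exons are the first, second and last; internal exons are the
#' third to the last-but-one (empty for `m <= 3`). Statistics are pooled-count
#' ratios, not per-gene averages.
#'
#' @param records codon records from [assign_codons()].
#' @param m_range exon-count classes to profile (default 2:10).
#' @return A named list over `m` of `scub_position_profile` objects: lists
#'   with fields `m`, `summaries` (per-ordinal [scub_summary()] results),
#'   `terminal`, `internal`.
#' @export
exon_position_profiles <- function(records, m_range = 2:10) {
  out <- lapply(m_range, function(m) {
    sub <- records[exon_count == m]
    summaries <- lapply(seq_len(m), function(o) {
      cnt <- count_codons(sub[exon_ordinal == o],
                          scope_label = sprintf("m%d_exon%d", m, o))
      tryCatch(scub_summary(cnt), error = function(e) NULL)
    })
    structure(list(
      m = m, summaries = summaries,
      terminal = unique(c(1L, 2L, m)),
      internal = if (m > 3L) 3:(m - 1L) else integer(0)),
      class = "scub_position_profile")
  })
  names(out) <- as.character(m_range)
  out
}

#' Tidy exon-position profile table
#'
#' @inheritParams exon_position_profiles
#' @return A `data.table` with one row per (m, exon ordinal): SCUB fractions,
#'   ratios and the terminal/internal classification.
#' @export
position_profile_table <- function(records, m_range = 2:10) {
  data.table::rbindlist(lapply(m_range, function(m) {
    sub <- records[exon_count == m]
    data.table::rbindlist(lapply(seq_len(m), function(o) {
      row <- .summary_row(count_codons(sub[exon_ordinal == o]),
                          m = m, exon_ordinal = o)
      row[, position_class := if (o %in% c(1L, 2L, m)) "terminal"
          else "internal"]
      row
    }), fill = TRUE)
  }), fill = TRUE)
}

#' SCUB summaries per chromosome
#'
#' @param records codon records from [assign_codons()].
#' @return A `data.table` with one row per chromosome plus a `genome` row
#'   (the exact pool of all chromosomes).
#' @export
chromosome_profiles <- function(records) {
  chroms <- sort(unique(records$chromosome))
  rows <- lapply(chroms, function(ch)
    .summary_row(count_codons(records[chromosome == ch], scope_label = ch),
                 scope = ch))
  rows <- c(rows, list(.summary_row(count_codons(records), scope = "genome")))
  data.table::rbindlist(rows, fill = TRUE)
}

utils::globalVariables(c("position_class", "scope"))
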