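#' Tally codon occurrences
#'
#' Counts every codon occurrence in a set of codon records, including stop
#' codons. Stop codons are stored (marked by the genetic code), never removed;
#' all synonymous-codon statistics downstream restrict themselves to the
#' 59-codon SC set, which excludes stops, ATG and TGG by construction.
#'
#' @param records codon records from [assign_codons()], or a character vector
#'   of codons.
#' @param scope_label free-text label for the counting scope (genome,
#'   chromosome, stratum, ...).
#' @return A named integer vector of class `scub_counts` over all 64 codons.
#' @export
count_codons <- function(records, scope_label = "genome") {
  codons <- if (is.character(records)) records else records$codon
  code <- .genetic_code()
  lev <- names(code$codon_to_aa)
  counts <- tabulate(factor(codons, levels = lev), nbins = length(lev))
  structure(stats::setNames(as.integer(counts), lev),
            scope_label = scope_label, class = "scub_counts")
}

#' @export
print.scub_counts <- function(x, ...) {
  cat("codon counts [", attr(x, "scope_label"), "]: ",
      sum(x), " codons, ", sum(x > 0), " distinct\n", sep = "")
  invisible(x)
}

#' Add two codon-count tallies
#'
#' @param a,b `scub_counts` objects.
#' @param scope_label label for the pooled scope.
#' @return A pooled `scub_counts` object.
#' @export
add_counts <- function(a, b, scope_label = "pooled") {
  structure(stats::setNames(as.integer(unclass(a) + unclass(b)[names(a)]),
                            names(a)),
            scope_label = scope_label, class = "scub_counts")
}

#' Per-codon frequencies over the 61 sense codons
#'
#' The frequency of each sense codon is its count divided by the total
#' sense-codon count; the 61 frequencies sum to one.
#'
#' @param counts a `scub_counts` object.
#' @return Named numeric vector over the 61 sense codons.
#' @export
codon_frequencies <- function(counts) {
  code <- .genetic_code()
  sense <- unclass(counts)[code$sense_codons]
  tot <- sum(sense)
  if (tot == 0L) stop("empty scope: no sense codons counted")
  sense / tot
}

#' Synonymous codon usage bias (SCUB) summary
#'
#' Computes the third-base composition of the 59 synonymous codons (SCs):
#' the fractions `f_NNA`, `f_NNT`, `f_NNC`, `f_NNG` of SC occurrences ending
#' in each base (denominator: all 59-SC occurrences, i.e. every sense codon
#' except ATG and TGG), the pooled `f_NNAT` / `f_NNCG`, the A/T:C/G ratios,
#' and the per-amino-acid SCUB frequency — for each of the 18 degenerate
#' amino acids, the count of its C/G-ending SCs over the count of its
#' A/T-ending SCs. Ratios with zero denominators are `NA` (undefined), never
#' infinite.
#'
#' @param counts a `scub_counts` object.
#' @return A list of class `scub_summary` with fields `f_NNA`, `f_NNT`,
#'   `f_NNC`, `f_NNG`, `f_NNAT`, `f_NNCG`, `ratio_AT_over_CG`,
#'   `ratio_CG_over_AT`, `per_aa_scub` (named over the 18 amino acids) and
#'   `n_sc` (total SC occurrences).
#' @export
scub_summary <- function(counts) {
  code <- .genetic_code()
  sc <- unclass(counts)[code$sc_set]
  n_sc <- sum(sc)
  if (n_sc == 0L) stop("empty scope: no synonymous codons counted")
  tb <- code$third_base[code$sc_set]
  by_base <- vapply(.BASES, function(b) sum(sc[tb == b]), numeric(1))
  f <- by_base / n_sc
  f_at <- f[["A"]] + f[["T"]]
  f_cg <- f[["C"]] + f[["G"]]
  per_aa <- vapply(code$degenerate_aas, function(a) {
    fam <- code$families[[a]]
    tb_f <- code$third_base[fam]
    cg <- sum(unclass(counts)[fam[tb_f %in% .CG_BASES]])
    at <- sum(unclass(counts)[fam[tb_f %in% .AT_BASES]])
    if (at == 0L) NA_real_ else cg / at
  }, numeric(1))
  structure(list(
    f_NNA = f[["A"]], f_NNT = f[["T"]], f_NNC = f[["C"]], f_NNG = f[["G"]],
    f_NNAT = f_at, f_NNCG = f_cg,
    ratio_AT_over_CG = if (f_cg == 0) NA_real_ else f_at / f_cg,
    ratio_CG_over_AT = if (f_at == 0) NA_real_ else f_cg / f_at,
    per_aa_scub = per_aa, n_sc = n_sc), class = "scub_summary")
}

#' @export
print.scub_summary <- function(x, ...) {
  cat(sprintf(
    "SCUB summary (%d SCs): f_NNA=%.4f f_NNT=%.4f f_NNC=%.4f f_NNG=%.4f  NNA/T:NNC/G=%.3f\n",
    x$n_sc, x$f_NNA, x$f_NNT, x$f_NNC, x$f_NNG, x$ratio_AT_over_CG))
  invisible(x)
}

#' Relative synonymous codon usage
#'
#' For codon *j* in a synonymous family of size *k* with family total *n*,
#' `RSCU_j = count_j * k / n`; values within each non-empty family average to
#' exactly one. Singleton families (Met, Trp) trivially have RSCU 1 when
#' observed. Families with zero total yield `NA`.
#'
#' @param counts a `scub_counts` object.
#' @return Named numeric vector over the 61 sense codons.
#' @export
rscu <- function(counts) {
  code <- .genetic_code()
  out <- stats::setNames(rep(NA_real_, length(code$sense_codons)),
                         code$sense_codons)
  for (fam in code$families) {
    n <- sum(unclass(counts)[fam])
    if (n > 0L) out[fam] <- unclass(counts)[fam] * length(fam) / n
  }
  out
}

#' Classic codon-bias indices: RSCU, CAI, CBI, Nc, GC3
#'
#' * CAI: geometric mean over SC occurrences of relative adaptiveness
#'   `w_j = RSCU_j / max(family RSCU)`. By default the reference is the
#'   scope's own usage (self-referential); an external weight table may be
#'   supplied. Weights of zero or missing are floored at 0.01 as in classic
#'   implementations.
#' * CBI (Bennetzen-Hall): `(N_pref - N_rand) / (N_tot - N_rand)`, with one
#'   preferred codon per degenerate family (the most frequent; ties broken
#'   alphabetically) and `N_rand` the uniform-usage expectation
#'   `sum(n_fam / k_fam)`.
#' * Nc (Wright's effective number of codons):
#'   `Nc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`, where `Fk` is the mean codon
#'   homozygosity `F = (n * sum(p^2) - 1) / (n - 1)` over k-fold degenerate
#'   families with at least two counted codons; non-positive family F values
#'   are treated as missing. A missing 3-fold mean is replaced by
#'   `(F2 + F4)/2` (Wright's recommendation). Nc is clamped to `[20, 61]`.
#' * GC3: fraction of SC occurrences with third base G or C.
#'
#' @param counts a `scub_counts` object.
#' @param reference_weights optional named numeric vector of relative
#'   adaptiveness values per codon (rescaled within each family so the best
#'   codon has weight 1).
#' @return A list of class `scub_bias_indices` with fields `rscu`, `cai`,
#'   `cbi`, `enc`, `gc3`.
#' @export
bias_indices <- function(counts, reference_weights = NULL) {
  code <- .genetic_code()
  cnt <- unclass(counts)
  r <- rscu(counts)

  # relative adaptiveness per codon
  w <- stats::setNames(rep(NA_real_, length(code$sense_codons)),
                       code$sense_codons)
  for (fam in code$families) {
    if (!is.null(reference_weights)) {
      wf <- reference_weights[fam]
      mx <- max(wf, na.rm = TRUE)
      if (is.finite(mx) && mx > 0) w[fam] <- wf / mx
    } else if (sum(cnt[fam]) > 0L) {
      w[fam] <- r[fam] / max(r[fam])
    }
  }
  w[is.na(w) | w <= 0] <- 0.01

  sc <- code$sc_set
  occ <- cnt[sc]
  tot_sc <- sum(occ)
  cai <- if (tot_sc == 0L) NA_real_ else
    exp(sum(occ * log(w[sc])) / tot_sc)

  # CBI over degenerate families
  deg_fams <- code$families[code$degenerate_aas]
  n_pref <- n_rand <- 0
  for (fam in deg_fams) {
    cf <- cnt[fam]
    nf <- sum(cf)
    pref <- fam[order(-cf, fam)][1L]
    n_pref <- n_pref + cf[[pref]]
    n_rand <- n_rand + nf / length(fam)
  }
  cbi <- if (tot_sc == n_rand) NA_real_ else
    (n_pref - n_rand) / (tot_sc - n_rand)

  enc <- .wright_enc(cnt, deg_fams)
  gc3 <- if (tot_sc == 0L) NA_real_ else {
    tb <- code$third_base[sc]
    sum(occ[tb %in% .CG_BASES]) / tot_sc
  }
  structure(list(rscu = r, cai = cai, cbi = cbi, enc = enc, gc3 = gc3),
            class = "scub_bias_indices")
}

.wright_enc <- function(cnt, deg_fams) {
  sizes <- lengths(deg_fams)
  f_by_class <- list()
  for (k in sort(unique(sizes))) {
    fs <- vapply(deg_fams[sizes == k], function(fam) {
      cf <- cnt[fam]
      n <- sum(cf)
      if (n < 2L) return(NA_real_)
      p <- cf / n
      (n * sum(p^2) - 1) / (n - 1)
    }, numeric(1))
    fs <- fs[!is.na(fs) & fs > 0]
    f_by_class[[as.character(k)]] <- if (length(fs)) mean(fs) else NA_real_
  }
  f2 <- f_by_class[["2"]]; f3 <- f_by_class[["3"]]
  f4 <- f_by_class[["4"]]; f6 <- f_by_class[["6"]]
  if (is.na(f3)) f3 <- mean(c(f2, f4))  # Wright's substitution
  if (anyNA(c(f2, f3, f4, f6))) return(NA_real_)
  enc <- 2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6
  min(max(enc, 20), 61)
}

#' @export
print.scub_bias_indices <- function(x, ...) {
  cat(sprintf("codon-bias indices: CAI=%.4f CBI=%.4f Nc=%.2f GC3=%.4f\n",
              x$cai, x$cbi, x$enc, x$gc3))
  invisible(x)
}

#' Per-scope codon usage table
#'
#' Convenience long table combining counts, sense-codon frequencies and RSCU
#' for TSV export.
#'
#' @param counts a `scub_counts` object.
#' @return A `data.table` with columns `codon`, `amino_acid`, `count`,
#'   `frequency` (NA for stops), `rscu` (NA for stops / empty families).
#' @export
codon_usage_table <- function(counts) {
  code <- .genetic_code()
  freq <- tryCatch(codon_frequencies(counts), error = function(e) NULL)
  r <- rscu(counts)
  dt <- data.table::data.table(
    codon = names(code$codon_to_aa),
    amino_acid = unname(code$codon_to_aa),
    count = as.integer(unclass(counts)))
  dt[, frequency := NA_real_]
  if (!is.null(freq)) dt[codon %in% names(freq),
                         frequency := freq[codon]]
  dt[, rscu := r[codon]]
  dt[]
}
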