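#' Build a pipeline run configuration
#'
#' @param species list of species sources, each a list with `label`, `fasta`,
#'   `gff3`.
#' @param out_dir output directory for all tables.
#' @param pairs list of ordered 2-vectors `c(wild_label, cultivated_label)`
#'   naming the species contrasts to compute.
#' @param max_introns,m_range stratification ranges (defaults 9 and 2:10).
#' @param var_equal use pooled-variance t-tests instead of Welch.
#' @param pca_standardize standardize features before PCA.
#' @param drop_final_codon_context drop the stop-codon-donated next-base
#'   context (see [context_tally()]).
#' @param include_chromosome_profiles emit per-chromosome tables.
#' @param seed seed for any resampling (none is performed by the standard
#'   stages; recorded in the run manifest).
#' @return A list of class `scub_run_config`.
#' @export
scub_config <- function(species, out_dir, pairs = list(),
                        max_introns = 9L, m_range = 2:10,
                        var_equal = FALSE, pca_standardize = FALSE,
                        drop_final_codon_context = FALSE,
                        include_chromosome_profiles = TRUE, seed = 1L) {
  stopifnot(length(species) >= 1L)
  for (sp in species) {
    stopifnot(!is.null(sp$label), !is.null(sp$fasta), !is.null(sp$gff3))
  }
  labels <- vapply(species, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("duplicate species labels")
  for (p in pairs) {
    if (!all(unlist(p) %in% labels)) {
      stop("pair references unknown species: ", paste(unlist(p), collapse = ","))
    }
  }
  structure(list(species = species, out_dir = out_dir, pairs = pairs,
                 max_introns = as.integer(max_introns),
                 m_range = as.integer(m_range), var_equal = var_equal,
                 pca_standardize = pca_standardize,
                 drop_final_codon_context = drop_final_codon_context,
                 include_chromosome_profiles = include_chromosome_profiles,
                 seed = as.integer(seed)),
            class = "scub_run_config")
}

.species_stage_tables <- function(rec, config) {
  sense <- rec[!(is_stop)]
  counts <- count_codons(rec)
  idx <- bias_indices(counts)
  s <- scub_summary(counts)
  list(
    codon_usage = codon_usage_table(counts),
    indices = data.table::data.table(
      scope = "genome", n_sc = s$n_sc,
      f_NNA = s$f_NNA, f_NNT = s$f_NNT, f_NNC = s$f_NNC, f_NNG = s$f_NNG,
      f_NNAT = s$f_NNAT, f_NNCG = s$f_NNCG,
      ratio_AT_over_CG = s$ratio_AT_over_CG,
      ratio_CG_over_AT = s$ratio_CG_over_AT,
      cai = idx$cai, cbi = idx$cbi, enc = idx$enc, gc3 = idx$gc3),
    per_aa_scub = data.table::data.table(
      amino_acid = names(s$per_aa_scub),
      scub_frequency = unname(s$per_aa_scub)),
    chromosome = if (config$include_chromosome_profiles)
      chromosome_profiles(rec) else NULL,
    introns = intron_profiles(rec, config$max_introns),
    exon_position = position_profile_table(rec, config$m_range),
    context = {
      cr <- context_ratios(rec,
                           drop_final_context = config$drop_final_codon_context)
      data.table::data.table(
        combination = c(paste0("N", .BASES, "A/N", .BASES, "G"),
                        paste0("NT|", .BASES, "/NC|", .BASES),
                        paste0(names(cr$aa_pair_ratios), "_A/G")),
        ratio = c(cr$r_xa_xg, cr$r_tx_cx, cr$aa_pair_ratios))
    },
    context_by_intron = stratified_context(rec, "intron",
                                           max_introns = config$max_introns),
    context_by_exon = stratified_context(rec, "exon_position",
                                         m_range = config$m_range),
    summary = s, counts = counts)
}

# per-species dispersion table: AT-vs-CG t-test over intron classes, and
# first-exon coefficient of variation across exon-count classes
.strata_tests <- function(tabs, config) {
  ip <- tabs$introns[stats::complete.cases(tabs$introns)]
  rows <- list()
  if (nrow(ip) >= 2L) {
    tt <- two_sample_t(ip$f_NNCG, ip$f_NNAT, var_equal = config$var_equal)
    rows[[1L]] <- data.table::data.table(
      metric = "t_NNCG_vs_NNAT_by_intron_class",
      statistic = tt$t, df = tt$df, p_value = tt$p.value)
  }
  first_exon <- tabs$exon_position[exon_ordinal == 1L]
  for (col in c("f_NNA", "f_NNT", "f_NNC", "f_NNG", "f_NNAT", "f_NNCG")) {
    v <- first_exon[[col]]
    v <- v[!is.na(v)]
    if (length(v) >= 2L && mean(v) != 0) {
      rows[[length(rows) + 1L]] <- data.table::data.table(
        metric = paste0("cv_first_exon_", col),
        statistic = coefficient_of_variation(v),
        df = NA_real_, p_value = NA_real_)
    }
  }
  data.table::rbindlist(rows)
}

.sc_class_counts <- function(counts) {
  code <- .genetic_code()
  sc <- unclass(counts)[code$sc_set]
  tb <- code$third_base[code$sc_set]
  vapply(.BASES, function(b) sum(sc[tb == b]), numeric(1))
}

.pair_contrasts <- function(res_by_species, pairs) {
  rows <- list()
  for (p in pairs) {
    w <- p[[1]]; cu <- p[[2]]
    cw <- .sc_class_counts(res_by_species[[w]]$counts)
    cc <- .sc_class_counts(res_by_species[[cu]]$counts)
    t4 <- rbind(cw, cc)
    t2 <- cbind(AT = rowSums(t4[, c("A", "T")]),
                CG = rowSums(t4[, c("C", "G")]))
    x4 <- chisq_crosstable(t4)
    x2 <- chisq_crosstable(t2)
    rows[[length(rows) + 1L]] <- data.table::data.table(
      comparison = paste0(w, "_vs_", cu,
                          c("_NNA.NNT.NNC.NNG", "_NNAT.NNCG")),
      statistic = c(x4$statistic, x2$statistic),
      df = c(x4$df, x2$df),
      p_value = c(x4$p.value, x2$p.value),
      low_expected = c(x4$low_expected, x2$low_expected))
  }
  data.table::rbindlist(rows)
}

.feature_matrices <- function(res_by_species, config) {
  labels <- names(res_by_species)
  code <- .genetic_code()
  sc_freq <- t(vapply(labels, function(l) {
    codon_frequencies(res_by_species[[l]]$counts)[code$sc_set]
  }, numeric(length(code$sc_set))))
  rscu_m <- t(vapply(labels, function(l) {
    rscu(res_by_species[[l]]$counts)[code$sc_set]
  }, numeric(length(code$sc_set))))
  exon_f <- t(vapply(labels, function(l) {
    ep <- res_by_species[[l]]$tables$exon_position
    stats::setNames(c(ep$f_NNAT, ep$f_NNCG),
                    c(paste0("AT_m", ep$m, "e", ep$exon_ordinal),
                      paste0("CG_m", ep$m, "e", ep$exon_ordinal)))
  }, numeric(2L * nrow(res_by_species[[labels[1]]]$tables$exon_position))))
  ctx <- t(vapply(labels, function(l) {
    tb <- res_by_species[[l]]$tables$context
    stats::setNames(tb$ratio, tb$combination)
  }, numeric(nrow(res_by_species[[labels[1]]]$tables$context))))
  list(sc_freq = sc_freq, rscu = rscu_m, exon_position = exon_f,
       methylation_context = ctx)
}

#' Run the full SCUB pipeline over one or more species
#'
#' Per species: loads transcripts, writes the filter report, and emits codon
#' usage / index tables, SCUB summaries (genome, chromosome, intron class,
#' exon position) and methylation-context ratio tables. Across species:
#' chi-square contrast tables for each configured (wild, cultivated) pair,
#' feature matrices, average-linkage dendrograms (Newick) and PCA scores,
#' plus a machine-readable run manifest. All outputs are TSV/JSON under
#' `config$out_dir`.
#'
#' @param config a [scub_config()].
#' @param stages subset of pipeline stages to run (`"extract"`,
#'   `"summarize"`, `"stratify"`, `"context"`, `"compare"`, `"cluster"`);
#'   default all.
#' @return Invisibly, a list with per-species results and cross-species
#'   objects.
#' @export
run_all <- function(config,
                    stages = c("extract", "summarize", "stratify", "context",
                               "compare", "cluster")) {
  stages <- match.arg(stages, several.ok = TRUE)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  created <- character(0)
  emit <- function(x, name) {
    if (is.null(x)) return(invisible(NULL))
    path <- file.path(out, name)
    write_tsv(x, path)
    created <<- c(created, path)
    invisible(path)
  }
  res_by_species <- list()
  on_fail <- function(e, label) {
    unlink(created)
    stop("species '", label, "' failed: ", conditionMessage(e), call. = FALSE)
  }
  for (sp in config$species) {
    lab <- sp$label
    message("[", lab, "] loading transcripts")
    tx <- tryCatch(load_transcripts(sp$fasta, sp$gff3, species_label = lab),
                   error = function(e) on_fail(e, lab))
    rep_ <- filter_cds(tx)
    emit(rep_, paste0(lab, "_filter_report.tsv"))
    rec <- suppressMessages(assign_codons(tx))
    message("[", lab, "] ", nrow(tx), " transcripts, ",
            sum(rep_$outcome == "retained"), " retained, ",
            nrow(rec), " codon records")
    if (!nrow(rec)) on_fail(simpleError("no retained transcripts"), lab)
    tabs <- .species_stage_tables(rec, config)
    if ("summarize" %in% stages) {
      emit(tabs$codon_usage, paste0(lab, "_codon_usage.tsv"))
      emit(tabs$indices, paste0(lab, "_indices.tsv"))
      emit(tabs$per_aa_scub, paste0(lab, "_per_aa_scub.tsv"))
    }
    if ("stratify" %in% stages) {
      emit(tabs$chromosome, paste0(lab, "_chromosome_profiles.tsv"))
      emit(tabs$introns, paste0(lab, "_intron_profiles.tsv"))
      emit(tabs$exon_position, paste0(lab, "_exon_position_profiles.tsv"))
      emit(.strata_tests(tabs, config), paste0(lab, "_strata_tests.tsv"))
    }
    if ("context" %in% stages) {
      emit(tabs$context, paste0(lab, "_context_ratios.tsv"))
      emit(tabs$context_by_intron, paste0(lab, "_context_by_intron.tsv"))
      emit(tabs$context_by_exon, paste0(lab, "_context_by_exon.tsv"))
    }
    res_by_species[[lab]] <- list(records = rec, tables = tabs,
                                  counts = tabs$counts)
  }

  cross <- list()
  if ("compare" %in% stages && length(config$pairs)) {
    cross$contrasts <- .pair_contrasts(res_by_species, config$pairs)
    emit(cross$contrasts, "pair_contrasts.tsv")
  }
  if ("cluster" %in% stages && length(res_by_species) >= 2L) {
    fm <- .feature_matrices(res_by_species, config)
    cross$features <- fm
    for (nm in names(fm)) {
      dend <- tryCatch(cluster_profiles(fm[[nm]]), error = function(e) NULL)
      if (!is.null(dend)) {
        path <- file.path(out, paste0("dendrogram_", nm, ".nwk"))
        writeLines(dend$newick, path)
        created <- c(created, path)
        cross[[paste0("dendrogram_", nm)]] <- dend
      }
      if (nrow(fm[[nm]]) >= 3L) {
        pca <- tryCatch(
          suppressMessages(pca_scores(fm[[nm]],
                                      standardize = config$pca_standardize)),
          error = function(e) NULL)
        if (!is.null(pca)) {
          emit(data.table::data.table(
            species = rownames(pca$scores),
            PC1 = pca$scores[, 1L],
            PC2 = if (pca$n_components >= 2L) pca$scores[, 2L] else NA_real_),
            paste0("pca_scores_", nm, ".tsv"))
          cross[[paste0("pca_", nm)]] <- pca
        }
      }
    }
  }

  manifest <- list(
    package = "scubr",
    version = as.character(utils::packageVersion("scubr")),
    seed = config$seed,
    species = vapply(config$species, `[[`, character(1), "label"),
    pairs = config$pairs,
    options = config[c("max_introns", "m_range", "var_equal",
                       "pca_standardize", "drop_final_codon_context",
                       "include_chromosome_profiles")],
    outputs = basename(created))
  jsonlite::write_json(manifest, file.path(out, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(species = res_by_species, cross = cross,
                 manifest = manifest))
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `extract`, `summarize`,
#' `stratify`, `context`, `compare`, `cluster` and `all` against a JSON
#' configuration file. The configuration mirrors [scub_config()]:
#' ```json
#' {"out_dir": "results",
#'  "species": [{"label": "wild", "fasta": "w.fa", "gff3": "w.gff3"}],
#'  "pairs": [["wild", "cultivated"]],
#'  "simulate": [{"species_label": "wild", "seed": 1, "n_genes": 500}]}
#' ```
#' `simulate` generates the genomes listed under `"simulate"` (fields are
#' [generator_spec()] arguments) into `out_dir`; the analysis subcommands run
#' the corresponding pipeline stages via [run_all()].
#'
#' @param args character vector, e.g. `commandArgs(trailingOnly = TRUE)`;
#'   `args[1]` is the subcommand, `args[2]` the config path.
#' @return Invisibly, the value of the dispatched stage.
#' @export
scub_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  cmds <- c("simulate", "extract", "summarize", "stratify", "context",
            "compare", "cluster", "all")
  if (length(args) < 2L || !(args[1] %in% cmds)) {
    stop("usage: scub <", paste(cmds, collapse = "|"), "> <config.json>")
  }
  cmd <- args[1]
  cfg <- jsonlite::read_json(args[2])
  out_dir <- cfg$out_dir %||% "scub_results"
  if (cmd == "simulate") {
    stopifnot(!is.null(cfg$simulate))
    res <- lapply(cfg$simulate, function(s) {
      spec <- do.call(generator_spec, s)
      generate_genome(spec, out_dir)
    })
    return(invisible(res))
  }
  config <- scub_config(
    species = lapply(cfg$species, function(s)
      list(label = s$label, fasta = s$fasta, gff3 = s$gff3)),
    out_dir = out_dir,
    pairs = lapply(cfg$pairs %||% list(), unlist),
    max_introns = cfg$options$max_introns %||% 9L,
    m_range = unlist(cfg$options$m_range %||% 2:10),
    var_equal = isTRUE(cfg$options$var_equal),
    pca_standardize = isTRUE(cfg$options$pca_standardize),
    drop_final_codon_context = isTRUE(cfg$options$drop_final_codon_context),
    include_chromosome_profiles =
      !isFALSE(cfg$options$include_chromosome_profiles),
    seed = cfg$options$seed %||% 1L)
  stages <- if (cmd == "all") {
    c("extract", "summarize", "stratify", "context", "compare", "cluster")
  } else cmd
  invisible(run_all(config, stages = stages))
}

utils::globalVariables(c("p_value", "combination", "ratio", "scub_frequency"))
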