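test_that("context tallies follow the hand walk-throughs", {
  # ATG CCA TAA: CCA is an SC ending in A with second base C -> nxa[C] = 1;
  # CCA ends in A so the T/C-ending tallies stay empty
  t1 <- context_tally(records_from_cds("ATGCCATAA"))
  expect_equal(t1$nxa, c(A = 0, C = 1, G = 0, T = 0))
  expect_equal(sum(t1$nxg) + sum(t1$ntx) + sum(t1$ncx), 0)
  # ATG GCC GAA TAA: GCC ends in C, next codon starts G -> ncx[G] = 1;
  # GAA ends in A with second base A -> nxa[A] = 1
  t2 <- context_tally(records_from_cds("ATGGCCGAATAA"))
  expect_equal(t2$ncx, c(A = 0, C = 0, G = 1, T = 0))
  expect_equal(t2$nxa, c(A = 1, C = 0, G = 0, T = 0))
  # the final sense codon takes its context from the stop codon
  t3 <- context_tally(records_from_cds("ATGGCTTAA"))  # GCT next base T
  expect_equal(t3$ntx, c(A = 0, C = 0, G = 0, T = 1))
  # ... unless the stop donor is disabled
  t3b <- context_tally(records_from_cds("ATGGCTTAA"), drop_final_context = TRUE)
  expect_equal(sum(t3b$ntx), 0)
  expect_identical(t3b$n_no_context, 1L)
})

test_that("context tallies exclude non-SC codons and match the naive oracle", {
  spec <- generator_spec(seed = 17, n_genes = 80, species_label = "ctx")
  g <- generate_genome(spec, file.path(tempdir(), "ctx_genome"))
  tx <- load_transcripts(g$fasta, g$gff3)
  rec <- suppressMessages(assign_codons(tx))
  tal <- context_tally(rec)
  orc <- oracle_context_tally(oracle_codon_records(g$fasta, g$gff3))
  expect_equal(tal$nxa, orc$nxa)
  expect_equal(tal$nxg, orc$nxg)
  expect_equal(tal$ntx, orc$ntx)
  expect_equal(tal$ncx, orc$ncx)
  # conservation: every tally is bounded by the total SC count
  expect_lte(sum(tal$nxa) + sum(tal$nxg), tal$n_sc)
  expect_lte(sum(tal$ntx) + sum(tal$ncx), tal$n_sc)
})

test_that("context ratios divide tallies and flag zero denominators", {
  rec <- records_from_cds("ATGCCATAA")
  cr <- context_ratios(rec)
  expect_true(is.na(cr$r_xa_xg[["C"]]))  # nxg[C] = 0
  # direct division on a larger fixture: NCA=10, NCG=5 -> 2.0
  cds <- paste0("ATG", strrep("CCA", 10), strrep("CCG", 5), "TAA")
  cr2 <- context_ratios(records_from_cds(cds))
  expect_equal(cr2$r_xa_xg[["C"]], 2.0)
  # amino-acid pair ratios pool sibling pairs sharing the first two bases
  cds3 <- paste0("ATG", strrep("GCA", 4), strrep("GCG", 2),
                 strrep("TTA", 3), strrep("CTA", 3), strrep("TTG", 2),
                 strrep("CTG", 1), "TAA")
  cr3 <- context_ratios(records_from_cds(cds3))
  expect_equal(cr3$aa_pair_ratios[["A"]], 2)      # Ala GCA/GCG = 4/2
  expect_equal(cr3$aa_pair_ratios[["L"]], 2)      # Leu (TTA+CTA)/(TTG+CTG)
  expect_setequal(names(cr3$aa_pair_ratios),
                  c("A", "P", "S", "T", "R", "Q", "E", "G", "L", "K", "V"))
  # genome with zero A-ending SCs: observed-G contexts give 0, the rest NA
  cr4 <- context_ratios(records_from_cds("ATGGCCGCGTAA"))
  expect_equal(cr4$r_xa_xg[["C"]], 0)  # GCG counted, no NCA partner
  expect_true(all(is.na(cr4$r_xa_xg[c("A", "G", "T")])))
})

test_that("stratified context reduces to the unstratified ratios on one stratum", {
  rec <- records_from_cds(c("ATGGCACCATTAGGTTGCTAA", "ATGCCGGCGTCATAA"))
  tab <- stratified_context(rec, by = "intron")
  cr <- context_ratios(rec)
  expect_equal(unlist(tab[1, paste0("r_", c("A", "C", "G", "T"), "A_",
                                    c("A", "C", "G", "T"), "G"),
                          with = FALSE]),
               setNames(cr$r_xa_xg,
                        paste0("r_", c("A", "C", "G", "T"), "A_",
                               c("A", "C", "G", "T"), "G")))
  # all other intron classes empty
  expect_true(all(is.na(unlist(tab[-1, -1]))))
})

test_that("stratified tallies pool back to the genome tally", {
  spec <- generator_spec(seed = 19, n_genes = 100, species_label = "pool")
  g <- generate_genome(spec, file.path(tempdir(), "pool_genome"))
  rec <- g$manifest$codons
  rec[, next_first_base := next_first]
  total <- context_tally(rec)
  parts <- lapply(0:9, function(i) context_tally(rec[intron_count == i]))
  expect_equal(Reduce(`+`, lapply(parts, `[[`, "nxa")), total$nxa)
  expect_equal(Reduce(`+`, lapply(parts, `[[`, "ntx")), total$ntx)
})

test_that("a gamma-free generator leaves NXA/NXG flat and NT|X/NC|X flat", {
  aa_p <- setNames(rep(1 / 17, 18), scub_genetic_code()$degenerate_aas)
  aa_p[["I"]] <- 0  # Ile has an A-ending SC but no G-ending sibling
  aa_p <- aa_p / sum(aa_p)
  spec <- generator_spec(seed = 23, n_genes = 600, beta0 = 0.4, beta1 = 0,
                         beta2 = 0, beta_first = 0, gamma = 1,
                         aa_probs = aa_p, species_label = "null")
  g <- generate_genome(spec, file.path(tempdir(), "null_genome"))
  rec <- g$manifest$codons
  rec[, next_first_base := next_first]
  cr <- context_ratios(context_tally(rec))
  tal <- cr$tally
  # 3-standard-error band on the log ratio differences
  for (x in c("A", "G", "T")) {
    se <- sqrt(1 / tal$nxa[["C"]] + 1 / tal$nxg[["C"]] +
                 1 / tal$nxa[[x]] + 1 / tal$nxg[[x]])
    expect_lt(abs(log(cr$r_xa_xg[["C"]]) - log(cr$r_xa_xg[[x]])), 3 * se)
  }
  for (x in c("A", "C", "T")) {
    se <- sqrt(1 / tal$ntx[["G"]] + 1 / tal$ncx[["G"]] +
                 1 / tal$ntx[[x]] + 1 / tal$ncx[[x]])
    expect_lt(abs(log(cr$r_tx_cx[["G"]]) - log(cr$r_tx_cx[[x]])), 3 * se)
  }
})

test_that("increasing gamma strictly increases NCA/NCG and NT|G/NC|G", {
  base <- function(gam, seed) {
    spec <- generator_spec(seed = seed, n_genes = 600, beta1 = 0, beta2 = 0,
                           beta_first = 0, gamma = gam,
                           species_label = paste0("g", gam * 10))
    g <- generate_genome(spec, file.path(tempdir(), paste0("gam", gam * 10)))
    rec <- g$manifest$codons
    rec[, next_first_base := next_first]
    context_ratios(context_tally(rec))
  }
  lo <- base(1.0, 31); mid <- base(1.5, 31); hi <- base(2.2, 31)
  expect_lt(lo$r_xa_xg[["C"]], mid$r_xa_xg[["C"]])
  expect_lt(mid$r_xa_xg[["C"]], hi$r_xa_xg[["C"]])
  expect_lt(lo$r_tx_cx[["G"]], mid$r_tx_cx[["G"]])
  expect_lt(mid$r_tx_cx[["G"]], hi$r_tx_cx[["G"]])
})
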