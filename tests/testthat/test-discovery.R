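# Discovery funnel stages, prioritization, cross-HLA and MS1 screens.

test_that("the binding filter is boundary-inclusive at the threshold", {
  rec <- data.frame(peptide = c("AAAAAAAAK", "CCCCCCCCK", "DDDDDDDDK"),
                    ic50 = c(100, 500, 501))
  expect_identical(nrow(filter_binding(rec, 500)), 2L)
  expect_identical(nrow(filter_binding(rec, Inf)), 3L)
  rec$ic50[2] <- NA
  expect_error(filter_binding(rec, 500), "missing ic50 in rows: 2")
  # widening the threshold never loses survivors
  set.seed(8)
  rec2 <- data.frame(peptide = "AAAAAAAAK", ic50 = runif(200, 1, 2000))
  for (t in c(100, 500, 1500)) {
    expect_true(all(filter_binding(rec2, t)$ic50 %in%
                    filter_binding(rec2, t + 200)$ic50))
  }
})

test_that("a fully tumour-restricted gene passes DE against every tissue", {
  genes <- c("hot", "flat")
  samples <- c(paste0("T", 1:10), paste0("A", 1:10), paste0("B", 1:10))
  expr <- rbind(hot = c(rep(8, 10), rep(0, 20)),
                flat = c(rep(4, 10), rep(4, 10), rep(0, 10)))
  colnames(expr) <- samples
  sm <- data.frame(sample = samples,
                   tissue = rep(c("tumour", "tissueA", "tissueB"), each = 10),
                   cohort = rep(c("tumour", "normal", "normal"), each = 10))
  de <- differential_expression(expr, sm)
  hot <- de$per_tissue[de$per_tissue$gene == "hot"]
  expect_equal(hot$lfc, rep(log2(9), 2), tolerance = 1e-12)
  expect_true(all(hot$p < 0.01))
  expect_true(de$summary$passes[de$summary$gene == "hot"])
  # identical in even one tissue fails the conjunction regardless of others
  expect_false(de$summary$passes[de$summary$gene == "flat"])
  flat <- de$per_tissue[de$per_tissue$gene == "flat"]
  expect_true(flat$lfc[flat$tissue == "tissueB"] >= 1)  # passes vs B alone
})

test_that("DE is invariant to sample column order and warns on tiny tissues", {
  ex <- synth_expression(sprintf("g%02d", 1:8), n_tumour = 6,
                         n_normal_tissues = 2, samples_per_tissue = 6,
                         planted_genes = "g01", effect_log2 = 4, seed = 14)
  de1 <- differential_expression(ex$expr, ex$sample_map)
  perm <- sample(ncol(ex$expr))
  de2 <- differential_expression(ex$expr[, perm], ex$sample_map)
  expect_equal(de1$summary, de2$summary)
  # a one-sample tissue is excluded with a warning, not an error
  expr2 <- cbind(ex$expr, lonely_01 = ex$expr[, 1])
  sm2 <- rbind(ex$sample_map,
               data.frame(sample = "lonely_01", tissue = "lonely", cohort = "normal"))
  expect_warning(de3 <- differential_expression(expr2, sm2), "lonely")
  expect_false("lonely" %in% de3$per_tissue$tissue)
})

test_that("benign-ligandome exclusion is gene-level, not peptide-level", {
  rec <- data.frame(peptide = c("AAAAAAAAK", "CCCCCCCCK"),
                    gene = c("g1", "g2"))
  # ligandome holds a DIFFERENT peptide of g1: the g1 record still drops
  lig <- data.frame(peptide = "DDDDDDDDK", gene = "g1", tissue = "liver")
  out <- filter_normal_ligandome(rec, lig)
  expect_identical(out$gene, "g2")
  expect_identical(nrow(filter_normal_ligandome(rec, lig[0, ])), 2L)
  unrelated <- data.frame(peptide = "EEEEEEEEK", gene = "g9")
  expect_identical(nrow(filter_normal_ligandome(rec, unrelated)), 2L)
})

test_that("the funnel reproduces generator stage labels and keeps the subset chain", {
  for (seed in c(2, 17, 31)) {
    fx <- make_funnel_fixture(seed)
    fr <- run_funnel(fx$records, fx$expr, fx$sample_map, fx$ligandome)
    tr <- fx$truth
    expect_setequal(fr$stages$binding$peptide, tr$peptide[tr$pass_binding])
    expect_setequal(fr$stages$differential_expression$peptide,
                    tr$peptide[tr$pass_binding & tr$pass_de])
    expect_setequal(fr$stages$ligandome$peptide,
                    tr$peptide[tr$pass_binding & tr$pass_de & tr$pass_ligandome])
    expect_true(all(diff(fr$counts$n_records) <= 0))
    expect_true(all(fr$stages$ligandome$peptide %in% fr$stages$binding$peptide))
  }
})

test_that("an all-failing input empties the funnel with monotone counts", {
  fx <- make_funnel_fixture(5)
  fx$records$ic50 <- 10000  # nothing binds
  fr <- run_funnel(fx$records, fx$expr, fx$sample_map, fx$ligandome)
  expect_identical(nrow(fr$stages$ligandome), 0L)
  expect_true(all(diff(fr$counts$n_records) <= 0))
})

test_that("prioritization ranks recurrence up and is deterministic", {
  one <- data.frame(sample = "S1", peptide = "AAAAAAAAK", gene = "g1",
                    allele = "HLA-A24:02", ic50 = 50, rank_pct = 0.5)
  expect_identical(prioritize(one)$priority_rank, 1L)
  # identical except recurrence 8 vs 1
  rec <- data.frame(
    sample = c(paste0("S", 1:8), "S1"),
    peptide = c(rep("AAAAAAAAK", 8), "CCCCCCCCK"),
    gene = "g1", allele = "HLA-A24:02", ic50 = 50, rank_pct = 0.5)
  ranked <- prioritize(rec)
  expect_identical(ranked$peptide[1], "AAAAAAAAK")
  expect_identical(ranked$recurrence, c(8L, 1L))
  expect_equal(prioritize(rec), ranked)  # rerun identical
  # missing factors are imputed and flagged, not fatal
  expect_true(all(grepl("lfc", ranked$imputed_factors)))
})

test_that("cross-HLA scan thresholds on rank, excludes the discovery allele, lists unscored", {
  alleles <- paste0("HLA-X", sprintf("%02d", 1:10))
  tab <- data.frame(peptide = "QYNPIRTTF", allele = alleles,
                    ic50 = 10^seq(0.5, 4, length.out = 10),
                    rank = c(0.2, 0.8, 1.5, 3, 5, 10, 20, 40, 70, 95))
  pred <- table_predictor(tab)
  res <- cross_hla_scan("QYNPIRTTF", alleles, pred, rank_threshold_pct = 2)
  expect_setequal(res$presented$allele, alleles[1:3])
  expect_identical(res$presented$allele, alleles[order(tab$rank)][1:3])
  # discovery allele reported separately, excluded from the additional set
  res2 <- cross_hla_scan("QYNPIRTTF", alleles, pred, rank_threshold_pct = 2,
                         discovery_allele = alleles[1])
  expect_false(alleles[1] %in% res2$presented$allele)
  expect_identical(res2$discovery$allele, alleles[1])
  expect_identical(nrow(cross_hla_scan("QYNPIRTTF", alleles, pred, 0)$presented), 0L)
  expect_identical(nrow(cross_hla_scan("QYNPIRTTF", alleles, pred, 100)$presented), 10L)
  # an allele missing from the table is listed, not dropped silently
  res3 <- cross_hla_scan("QYNPIRTTF", c(alleles, "HLA-NEW"), pred, 100)
  expect_identical(res3$unscored, "HLA-NEW")
  expect_identical(nrow(res3$presented), 10L)
})

test_that("MS1 matching honours the ppm and retention-time windows", {
  q <- "QYNPIRTTF"
  feats <- data.frame(sample = "S1", mz = peptide_mz(q, 2), rt = 30.5, charge = 2)
  m <- match_ms1_features(q, feats, reference_rt = 30)
  expect_identical(nrow(m), 1L)
  expect_identical(m$matched_charge, 2L)
  expect_lt(abs(m$ppm_error), 1e-6)
  # RT offset 1.5 min with a 1 min window: no match
  feats$rt <- 31.5
  expect_identical(nrow(match_ms1_features(q, feats, reference_rt = 30)), 0L)
  # m/z off by 50 ppm at 10 ppm tolerance: no match
  feats2 <- data.frame(sample = "S1", mz = peptide_mz(q, 2) * (1 + 50e-6),
                       rt = 30, charge = 2)
  expect_identical(nrow(match_ms1_features(q, feats2, reference_rt = 30)), 0L)
  expect_identical(nrow(match_ms1_features(q, feats2, ppm_tol = 60,
                                           reference_rt = 30)), 1L)
  # charge-free features try every allowed charge
  feats3 <- data.frame(sample = "S1", mz = peptide_mz(q, 3), rt = 30)
  expect_identical(match_ms1_features(q, feats3, reference_rt = 30)$matched_charge, 3L)
  expect_error(match_ms1_features(q, feats3), "reference_rt")
})
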