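# Proteome windowing, expression annotation, and index construction.

toy_proteome <- function() {
  data.table::data.table(
    protein_id = c("P1", "P2", "P3"),
    gene = c("GA", "GB", "GC"),
    sequence = c("ACDEFGHIKL", "MNPQRSTVWY", "ACDEFGHIK"))
}

test_that("windowing enumerates every fixed-length substring with gene sets", {
  prot <- data.table::data.table(protein_id = "P1", gene = "GA",
                                 sequence = "ACDEFGHIKL")
  win <- window_peptides(prot, 9)
  expect_setequal(win$peptide, c("ACDEFGHIK", "CDEFGHIKL"))
  expect_identical(unique(win$genes), "GA")
  # protein shorter than window contributes nothing
  short <- data.table::data.table(protein_id = "P2", gene = "GB",
                                  sequence = "ACDEFG")
  expect_identical(nrow(window_peptides(short, 9)), 0L)
  # two genes sharing a 9-mer: union of parents
  dup <- data.table::data.table(protein_id = c("P1", "P2"),
                                gene = c("GA", "GB"),
                                sequence = c("ACDEFGHIK", "ACDEFGHIKL"))
  win2 <- window_peptides(dup, 9)
  expect_identical(win2[win2$peptide == "ACDEFGHIK"]$genes, "GA;GB")
  expect_error(window_peptides(prot, 7), "8-14")
  expect_identical(nrow(window_peptides(prot[0], 9)), 0L)
})

test_that("window counts are conserved and non-canonical windows are skip-logged", {
  prot <- synth_proteome(15, seed = 5)
  win <- window_peptides(prot, 9)
  expected_windows <- sum(pmax(0L, nchar(prot$sequence) - 9L + 1L))
  expect_identical(attr(win, "n_windows") , expected_windows)
  expect_identical(attr(win, "n_skipped"), 0L)
  # plant an X residue: windows crossing it are skipped, not dropped silently
  protx <- data.table::copy(prot)
  protx$sequence[1] <- paste0(substr(protx$sequence[1], 1, 20), "X",
                              substr(protx$sequence[1], 21, nchar(protx$sequence[1])))
  winx <- window_peptides(protx, 9)
  expect_identical(attr(winx, "n_skipped"), 9L)  # 9 windows cross the X
  expect_identical(attr(winx, "n_windows"),
                   sum(pmax(0L, nchar(protx$sequence) - 9L + 1L)))
  expect_false(any(grepl("X", winx$peptide, fixed = TRUE)))
})

test_that("expression annotation takes the max over parent genes with a floor for missing", {
  pg <- data.table::data.table(peptide = c("AAAAAAAAK", "CCCCCCCCK", "DDDDDDDDK"),
                               genes = c("g1", "g1;g2", "gmissing"))
  emax <- c(g1 = 3, g2 = 10)
  ann <- annotate_expression(pg, emax, missing_value = 0.01)
  expect_equal(ann$E_max, c(3, 10, 0.01))
  expect_identical(attr(ann, "missing_genes"), "gmissing")
  # max over tissues: matrix input reduced per gene
  m <- matrix(c(2, 7), 1, 2, dimnames = list("g1", c("liver", "heart")))
  ann2 <- annotate_expression(pg[1], m)
  expect_equal(ann2$E_max, 7)
  # all-zero expression survives as 0 (floored downstream at score time)
  ann3 <- annotate_expression(pg[1], c(g1 = 0))
  expect_equal(ann3$E_max, 0)
  expect_error(annotate_expression(pg, c(g1 = -1)), ">= 0")
})

test_that("normal-tissue maximum summarizes per tissue then maximizes, tumour excluded", {
  expr <- matrix(c(1, 1, 9, 9, 2, 2,   # gene1: tumour 1, tissueA 9, tissueB 2
                   5, 5, 1, 1, 8, 8),  # gene2
                 nrow = 2, byrow = TRUE,
                 dimnames = list(c("gene1", "gene2"),
                                 c("t1", "t2", "a1", "a2", "b1", "b2")))
  sm <- data.frame(sample = colnames(expr),
                   tissue = c("tumour", "tumour", "A", "A", "B", "B"),
                   cohort = c("tumour", "tumour", rep("normal", 4)))
  em <- normal_tissue_max(expr, sm)
  expect_equal(unname(em), c(9, 8))
  # adding a tissue can only keep or raise E_max
  expr2 <- cbind(expr, c1 = c(20, 0), c2 = c(20, 0))
  sm2 <- rbind(sm, data.frame(sample = c("c1", "c2"), tissue = "C", cohort = "normal"))
  em2 <- normal_tissue_max(expr2, sm2)
  expect_true(all(em2 >= em))
})

test_that("index construction composes windowing, prediction and expression", {
  prot <- toy_proteome()
  pred <- toy_predictor(3)
  ex <- synth_expression(prot$gene, n_tumour = 4, n_normal_tissues = 2,
                         samples_per_tissue = 4, seed = 3)
  gene_emax <- normal_tissue_max(ex$expr, ex$sample_map)
  idx <- build_index(prot, 9, "HLA-A24:02", pred, gene_emax)
  # exactly the brute-force-enumerated unique 9-mers
  manual <- unique(unlist(lapply(prot$sequence, function(s) {
    if (nchar(s) < 9) return(character(0))
    sapply(seq_len(nchar(s) - 8), function(i) substr(s, i, i + 8))
  })))
  expect_setequal(idx$peptide, manual)
  expect_true(all(idx$b_nM > 0))
  expect_true(all(idx$rank >= 0 & idx$rank <= 100))
  expect_identical(attr(idx, "allele"), "HLA-A24:02")
  # deterministic and order-independent w.r.t. protein input order
  idx2 <- build_index(prot, 9, "HLA-A24:02", toy_predictor(3), gene_emax)
  expect_equal(as.data.frame(idx2), as.data.frame(idx))
  idx3 <- build_index(prot[c(3, 1, 2)], 9, "HLA-A24:02", toy_predictor(3), gene_emax)
  expect_equal(as.data.frame(idx3), as.data.frame(idx))
})

test_that("predictor failures drop rows with a count, never silently", {
  prot <- toy_proteome()
  flaky <- function(peptides, allele) {
    if (any(startsWith(peptides, "ACD"))) stop("engine refused peptide")
    data.frame(ic50 = rep(100, length(peptides)), rank = rep(1, length(peptides)))
  }
  idx <- build_index(prot, 9, "HLA-A24:02", flaky)
  expect_identical(attr(idx, "n_predictor_failures"), 1L)
  expect_false("ACDEFGHIK" %in% idx$peptide)
  expect_true("CDEFGHIKL" %in% idx$peptide)
})

test_that("the index round-trips through its TSV representation", {
  idx <- synth_index(50, seed = 9)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_index(idx, path)
  back <- read_index(path)
  expect_identical(attr(back, "allele"), attr(idx, "allele"))
  expect_identical(attr(back, "peptide_length"), attr(idx, "peptide_length"))
  expect_equal(as.data.frame(back), as.data.frame(idx), tolerance = 1e-12)
})

test_that("proteome FASTA round-trips with the ID|GENE header dialect", {
  prot <- synth_proteome(5, seed = 2)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_proteome(prot, path)
  back <- read_proteome(path)
  expect_equal(as.data.frame(back), as.data.frame(prot))
})

test_that("predictor contract is validated and cacheable to TSV", {
  pred <- toy_predictor(1)
  peps <- c("QYNPIRTTF", "EVDPIGHLY")
  out <- predict_binding(pred, peps, "HLA-A24:02")
  expect_identical(out$peptide, peps)
  expect_true(all(out$ic50 > 0 & out$ic50 <= 50000))
  bad <- function(peptides, allele) data.frame(ic50 = -1, rank = 5)
  expect_error(predict_binding(bad, "QYNPIRTTF", "X"), "one row per peptide|IC50")
  path <- withr::local_tempfile(fileext = ".tsv")
  cache_predictions(pred, peps, c("HLA-A24:02", "HLA-A02:01"), path)
  replay <- table_predictor(data.table::fread(path))
  expect_equal(predict_binding(replay, peps, "HLA-A24:02"),
               predict_binding(pred, peps, "HLA-A24:02"))
  expect_error(predict_binding(replay, "AAAAAAAAA", "HLA-A24:02"), "no prediction")
})
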