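# Deterministic synthetic-data generators with planted ground truth.
#
# Every input the scoring, indexing and funnel modules consume can be
# generated here as a pure function of (parameters, seed): a gene-annotated
# proteome, tumour-vs-normal expression with planted tumour-specific genes,
# predictor-consistent peptide tables, a benign ligandome, MS1 feature
# tables, and planted near-identical cross-reactive peptides whose expected
# positional score is computable arithmetically from the construction. Each
# generator derives its own RNG substream from the root seed, so fixtures
# are independently regenerable.

#' Generate a synthetic gene-annotated proteome
#'
#' Residues are drawn near-uniformly from the 20 canonical amino acids
#' (so every chemical class is exercised) rather than from human
#' composition. Identical (seed, parameters) give byte-identical output.
#'
#' @param n_genes number of proteins/genes (one protein per gene)
#' @param length_range protein length range, inclusive
#' @param seed integer seed
#' @return `data.table` with `protein_id`, `gene`, `sequence`
#' @export
synth_proteome <- function(n_genes, length_range = c(50L, 100L), seed = 1L) {
  stopifnot(n_genes >= 1)
  with_local_seed(derive_seed(seed, "proteome"), {
    lens <- sample(length_range[1]:length_range[2], n_genes, replace = TRUE)
    seqs <- vapply(lens, function(n) {
      paste(sample(CANONICAL_AA, n, replace = TRUE), collapse = "")
    }, character(1))
    data.table::data.table(
      protein_id = sprintf("P%04d", seq_len(n_genes)),
      gene = sprintf("G%04d", seq_len(n_genes)),
      sequence = seqs)
  })
}

#' Plant a near-identical cross-reactive peptide into a proteome
#'
#' Inserts, as a new protein, a variant of `query` differing at exactly the
#' stated positions. Substitutions are drawn from a different chemical
#' class (expected positional score -2) or the same class
#' (`substitution_class = "same"`, expected score 2); positions left
#' untouched score 5 at scored positions. The expected positional sum is
#' computed arithmetically from the construction, independent of the
#' scoring engine, and returned as ground truth together with the intended
#' predictor IC50 and expression level for the host gene.
#'
#' @param proteome proteome table to extend
#' @param query query peptide the plant imitates
#' @param n_substitutions number of substituted positions (ignored when
#'   `at_positions` given)
#' @param at_positions explicit 1-based substitution positions
#' @param substitution_class `"different"` or `"same"` chemical class
#' @param ic50 intended predictor IC50 for the planted peptide, nM
#' @param expression_level intended normal-tissue expression of the host
#'   gene (NA = leave the gene out of the matrix, i.e. floor)
#' @param host_gene gene symbol of the inserted protein
#' @param convention anchor-masking convention for the expected score
#' @param seed integer seed (substitution residue choice)
#' @return list with `proteome` (extended) and `truth` (`data.table`:
#'   peptide, host_gene, positions, expected_sum_p, ic50, expression_level)
#' @export
plant_cross_reactor <- function(proteome, query, n_substitutions = 0L,
                                at_positions = NULL,
                                substitution_class = c("different", "same"),
                                ic50 = 1, expression_level = NA_real_,
                                host_gene = "PLANTED1",
                                convention = "text", seed = 1L) {
  substitution_class <- match.arg(substitution_class)
  validate_peptide(query)
  n <- nchar(query)
  if (is.null(at_positions)) at_positions <- utils::head(scored_positions(n, convention),
                                                         n_substitutions)
  if (any(at_positions < 1 | at_positions > n))
    stop_scrapseek("substitution positions outside the peptide")
  tab <- default_aa_table()
  cls <- stats::setNames(tab$class, tab$residue)
  res <- strsplit(query, "", fixed = TRUE)[[1]]
  variant <- res
  with_local_seed(derive_seed(seed, paste0("plant:", query)), {
    for (p in at_positions) {
      pool <- if (substitution_class == "different")
        tab$residue[cls[tab$residue] != cls[res[p]]]
      else
        setdiff(tab$residue[cls[tab$residue] == cls[res[p]]], res[p])
      if (length(pool) == 0)
        stop_scrapseek("no residue satisfies the requested substitution at position ", p)
      variant[p] <- sample(pool, 1)
    }
  })
  variant <- paste(variant, collapse = "")
  sp <- scored_positions(n, convention)
  per_pos <- ifelse(sp %in% at_positions,
                    ifelse(substitution_class == "different", -2L, 2L), 5L)
  truth <- data.table::data.table(
    peptide = variant, host_gene = host_gene,
    positions = paste(at_positions, collapse = ";"),
    expected_sum_p = sum(per_pos), ic50 = ic50,
    expression_level = expression_level)
  planted <- data.table::data.table(
    protein_id = paste0("PLANT_", host_gene), gene = host_gene,
    sequence = variant)
  list(proteome = data.table::rbindlist(list(proteome, planted)),
       truth = truth)
}

#' Generate a tumour-vs-normal expression matrix with planted effects
#'
#' Each gene gets a log2-normal baseline; planted genes are shifted up by
#' `effect_log2` in tumour samples only. FPKM values are strictly positive
#' (2 to the power of the log2 signal).
#'
#' @param genes character vector of gene symbols
#' @param n_tumour tumour sample count
#' @param n_normal_tissues number of named normal tissues
#' @param samples_per_tissue samples per normal tissue
#' @param planted_genes genes made tumour-specific
#' @param effect_log2 tumour shift in log2 units
#' @param seed integer seed
#' @param baseline_mean_log2,baseline_sd_log2 per-gene baseline distribution
#' @param noise_sd_log2 per-sample log2 noise
#' @return list with `expr` (matrix genes x samples), `sample_map`
#'   (`data.table`: sample, tissue, cohort) and `truth` (planted genes)
#' @export
synth_expression <- function(genes, n_tumour = 20L, n_normal_tissues = 3L,
                             samples_per_tissue = 20L, planted_genes = NULL,
                             effect_log2 = 3, seed = 1L,
                             baseline_mean_log2 = 3, baseline_sd_log2 = 1,
                             noise_sd_log2 = 1) {
  stopifnot(effect_log2 >= 0)
  tissues <- sprintf("tissue%02d", seq_len(n_normal_tissues))
  tum_samples <- sprintf("TUM%03d", seq_len(n_tumour))
  norm_samples <- unlist(lapply(tissues, function(t)
    paste0(t, "_", sprintf("%03d", seq_len(samples_per_tissue)))))
  sample_map <- data.table::data.table(
    sample = c(tum_samples, norm_samples),
    tissue = c(rep("tumour", n_tumour),
               rep(tissues, each = samples_per_tissue)),
    cohort = c(rep("tumour", n_tumour),
               rep("normal", length(norm_samples))))
  with_local_seed(derive_seed(seed, "expression"), {
    base <- stats::rnorm(length(genes), baseline_mean_log2, baseline_sd_log2)
    m <- matrix(stats::rnorm(length(genes) * nrow(sample_map), 0, noise_sd_log2),
                nrow = length(genes))
    m <- m + base
    if (!is.null(planted_genes)) {
      idx <- match(planted_genes, genes)
      if (any(is.na(idx))) stop_scrapseek("planted gene not in gene list")
      m[idx, seq_len(n_tumour)] <- m[idx, seq_len(n_tumour)] + effect_log2
    }
    expr <- 2^m
    dimnames(expr) <- list(genes, sample_map$sample)
    list(expr = expr, sample_map = sample_map,
         truth = data.table::data.table(gene = genes,
                                        planted = genes %in% (planted_genes %||% character(0))))
  })
}

#' Deterministic toy binding predictor
#'
#' A position-weight scheme per allele: each allele (via a seed derived
#' from its name) draws a preferred residue and a weight per position, with
#' anchor positions (P2 and the C-terminus) weighted 5x so anchors dominate
#' binding, as in real class I presentation. Per position a peptide earns
#' the full weight for the preferred residue, half for a same-class
#' residue, none otherwise; the normalized score maps monotonically to IC50
#' in [1, 50000] nM and percentile rank in [0, 100] (rank a monotone
#' transform of IC50 within an allele). Deterministic for fixed
#' (seed, peptide, allele); `overrides` pins exact (peptide, allele) rows,
#' which is how planted cross-reactors get their intended affinity.
#'
#' @param seed integer seed
#' @param overrides optional data.frame (peptide, allele, ic50, rank)
#' @return predictor function, see [predict_binding()]
#' @export
toy_predictor <- function(seed = 1L, overrides = NULL) {
  tab <- default_aa_table()
  cls <- stats::setNames(tab$class, tab$residue)
  ov <- if (!is.null(overrides)) {
    o <- data.table::as.data.table(overrides)
    data.table::setkeyv(o, c("peptide", "allele"))
    o
  }
  params <- new.env(parent = emptyenv())
  allele_params <- function(allele) {
    if (!exists(allele, envir = params)) {
      par <- with_local_seed(derive_seed(seed, paste0("allele:", allele)), {
        list(preferred = sample(CANONICAL_AA, 14, replace = TRUE),
             w = stats::runif(14, 0.5, 1.5))
      })
      assign(allele, par, envir = params)
    }
    get(allele, envir = params)
  }
  function(peptides, allele) {
    par <- allele_params(allele)
    score_one <- function(p) {
      n <- nchar(p)
      res <- strsplit(p, "", fixed = TRUE)[[1]]
      w <- par$w[seq_len(n)]
      w[c(2L, n)] <- 5 * w[c(2L, n)]
      pref <- par$preferred[seq_len(n)]
      hit <- ifelse(res == pref, 1, ifelse(cls[res] == cls[pref], 0.5, 0))
      sum(w * hit) / sum(w)
    }
    u <- vapply(peptides, score_one, numeric(1), USE.NAMES = FALSE)
    ic50 <- 50000^(1 - u)
    rank <- 100 * log(ic50) / log(50000)
    if (!is.null(ov)) {
      want <- data.table::data.table(peptide = peptides, allele = allele)
      hit <- ov[want, on = c("peptide", "allele")]
      use <- !is.na(hit$ic50)
      ic50[use] <- hit$ic50[use]
      rank[use] <- hit$rank[use]
    }
    data.frame(ic50 = ic50, rank = rank)
  }
}

#' Generate a random normal-peptidome index directly
#'
#' Draws unique random peptides with log-uniform binding affinities and
#' log-normal expression values: the quickest route to a scan-ready
#' [build_index()]-shaped object for property tests and benchmarks.
#'
#' @param n_peptides index size
#' @param length peptide length
#' @param allele HLA allele name
#' @param seed integer seed
#' @return `proteome_index`
#' @export
synth_index <- function(n_peptides, length = 9L, allele = "HLA-A24:02",
                        seed = 1L) {
  with_local_seed(derive_seed(seed, "index"), {
    peptides <- character(0)
    while (length(peptides) < n_peptides) {
      more <- vapply(seq_len(n_peptides - length(peptides) + 10L), function(i)
        paste(sample(CANONICAL_AA, length, replace = TRUE), collapse = ""),
        character(1))
      peptides <- unique(c(peptides, more))
    }
    peptides <- peptides[seq_len(n_peptides)]
    b <- exp(stats::runif(n_peptides, log(1), log(50000)))
    idx <- data.table::data.table(
      peptide = peptides,
      genes = sprintf("G%05d", sample.int(max(1L, n_peptides %/% 3L),
                                          n_peptides, replace = TRUE)),
      b_nM = b,
      rank = 100 * log(b) / log(50000),
      E_max = exp(stats::rnorm(n_peptides, 1, 1)))
    data.table::setkeyv(idx, "peptide")
    data.table::setattr(idx, "allele", allele)
    data.table::setattr(idx, "peptide_length", as.integer(length))
    data.table::setattr(idx, "class", c("proteome_index", class(idx)))
    idx[]
  })
}

#' Sample a synthetic immunopeptidome from a proteome
#'
#' Windows the proteome, predicts binding on the stated allele, and samples
#' `n_records` unique peptides biased toward low IC50 (probability
#' proportional to 1/IC50), assigning each to a random sample. Errors when
#' `n_records` exceeds the available windows.
#'
#' @param proteome proteome table
#' @param predictor binding predictor
#' @param allele HLA allele
#' @param n_records number of peptide records
#' @param peptide_length window length
#' @param samples sample identifiers to assign records to
#' @param seed integer seed
#' @return `data.table` with `sample`, `peptide`, `gene`, `allele`, `ic50`,
#'   `rank_pct`
#' @export
synth_immunopeptidome <- function(proteome, predictor, allele,
                                  n_records = 100L, peptide_length = 9L,
                                  samples = paste0("S", 1:4), seed = 1L) {
  win <- window_peptides(proteome, peptide_length)
  if (n_records > nrow(win))
    stop_scrapseek("n_records (", n_records, ") exceeds available windows (",
                   nrow(win), ")")
  pred <- predict_binding(predictor, win$peptide, allele)
  with_local_seed(derive_seed(seed, "immunopeptidome"), {
    pick <- sample.int(nrow(win), n_records, prob = 1 / pred$ic50)
    data.table::data.table(
      sample = sample(samples, n_records, replace = TRUE),
      peptide = win$peptide[pick],
      gene = vapply(strsplit(win$genes[pick], ";", fixed = TRUE), `[`, character(1), 1),
      allele = allele,
      ic50 = pred$ic50[pick],
      rank_pct = pred$rank[pick])
  })
}

#' Sample a synthetic benign-tissue ligandome
#'
#' @param proteome proteome table
#' @param n_peptides ligandome size
#' @param tissues tissue names to assign
#' @param peptide_length window length
#' @param seed integer seed
#' @return `data.table` with `peptide`, `gene`, `tissue`
#' @export
synth_normal_ligandome <- function(proteome, n_peptides,
                                   tissues = c("liver", "heart", "lung"),
                                   peptide_length = 9L, seed = 1L) {
  win <- window_peptides(proteome, peptide_length)
  if (n_peptides > nrow(win))
    stop_scrapseek("n_peptides exceeds available windows")
  with_local_seed(derive_seed(seed, "ligandome"), {
    pick <- sample.int(nrow(win), n_peptides)
    data.table::data.table(
      peptide = win$peptide[pick],
      gene = vapply(strsplit(win$genes[pick], ";", fixed = TRUE), `[`, character(1), 1),
      tissue = sample(tissues, n_peptides, replace = TRUE))
  })
}

#' Emit MS1 features for a set of peptides, with controlled jitter
#'
#' Each peptide produces one feature per sample at its theoretical m/z
#' (given charge) perturbed by a uniform ppm offset in
#' `[-jitter_ppm, +jitter_ppm]`, and at `reference_rt` perturbed by a
#' uniform offset in `[-jitter_rt_min, +jitter_rt_min]`. Optional decoy
#' features are drawn far from any real m/z. The truth table records which
#' features derive from which peptide, so matcher recovery is scoreable.
#'
#' @param peptides character vector
#' @param reference_rt reference retention time, minutes
#' @param jitter_ppm half-width of the uniform m/z jitter, ppm
#' @param jitter_rt_min half-width of the uniform RT jitter, minutes
#' @param charge charge state of emitted features
#' @param samples sample identifiers
#' @param n_decoys unrelated decoy features per sample
#' @param seed integer seed
#' @return list with `features` (`data.table`: sample, mz, rt, charge) and
#'   `truth` (`data.table`: sample, peptide, mz, rt)
#' @export
synth_ms1_features <- function(peptides, reference_rt = 30,
                               jitter_ppm = 0, jitter_rt_min = 0,
                               charge = 2L, samples = "S1", n_decoys = 0L,
                               seed = 1L) {
  validate_peptide(peptides)
  theo <- peptide_mz(peptides, charge)
  with_local_seed(derive_seed(seed, "ms1"), {
    rows <- lapply(samples, function(s) {
      ppm_off <- stats::runif(length(peptides), -jitter_ppm, jitter_ppm)
      rt_off <- stats::runif(length(peptides), -jitter_rt_min, jitter_rt_min)
      data.table::data.table(
        sample = s, peptide = peptides,
        mz = theo * (1 + ppm_off * 1e-6),
        rt = reference_rt + rt_off, charge = as.integer(charge))
    })
    truth <- data.table::rbindlist(rows)
    features <- truth[, c("sample", "mz", "rt", "charge")]
    if (n_decoys > 0) {
      dec <- data.table::rbindlist(lapply(samples, function(s) {
        data.table::data.table(
          sample = s,
          mz = stats::runif(n_decoys, min(theo) * 0.7, max(theo) * 1.3),
          rt = stats::runif(n_decoys, 0, 2 * reference_rt),
          charge = as.integer(charge))
      }))
      # keep decoys > 100 ppm away from every true feature m/z
      ok <- vapply(dec$mz, function(m)
        all(abs(m - theo) / theo * 1e6 > 100), logical(1))
      features <- data.table::rbindlist(list(features, dec[ok]))
    }
    list(features = features[], truth = truth[, c("sample", "peptide", "mz", "rt")])
  })
}

#' Generate a funnel fixture with exact per-stage ground truth
#'
#' Builds an immunopeptidomics hit table, an expression matrix, and a
#' benign ligandome where each record's fate at every funnel stage is known
#' by construction: IC50s are sampled clear of the 500 nM boundary,
#' tumour-specific genes get fully separated expression (deterministic
#' rank-sum outcome), and ligandome membership is assigned at the gene
#' level. The truth table carries the three per-record stage labels.
#'
#' @param seed integer seed
#' @param n_records number of peptide records
#' @param n_genes gene universe size
#' @param n_tumour,n_normal_tissues,samples_per_tissue expression design
#' @return list with `records`, `expr`, `sample_map`, `ligandome`, `truth`
#'   (per-record `pass_binding`, `pass_de`, `pass_ligandome`) and
#'   `tumour_specific_genes`
#' @export
make_funnel_fixture <- function(seed = 1L, n_records = 40L, n_genes = 12L,
                                n_tumour = 10L, n_normal_tissues = 3L,
                                samples_per_tissue = 10L) {
  genes <- sprintf("FG%03d", seq_len(n_genes))
  with_local_seed(derive_seed(seed, "funnel-fixture"), {
    tumour_specific <- sort(sample(genes, max(2L, n_genes %/% 3L)))
    lig_genes <- sort(sample(genes, max(2L, n_genes %/% 4L)))
    peptides <- character(0)
    while (length(peptides) < n_records)
      peptides <- unique(c(peptides, vapply(seq_len(n_records), function(i)
        paste(sample(CANONICAL_AA, 9, replace = TRUE), collapse = ""),
        character(1))))
    peptides <- peptides[seq_len(n_records)]
    strong <- sample(c(TRUE, FALSE), n_records, replace = TRUE)
    ic50 <- ifelse(strong, stats::runif(n_records, 10, 400),
                   stats::runif(n_records, 600, 5000))
    rec_gene <- sample(genes, n_records, replace = TRUE)
    records <- data.table::data.table(
      sample = sample(paste0("S", 1:4), n_records, replace = TRUE),
      peptide = peptides, gene = rec_gene, allele = "HLA-A24:02",
      ic50 = ic50, rank_pct = 100 * log(ic50) / log(50000))
  })
  # deterministic, fully separated expression: outcome of the DE stage is
  # fixed by construction, not by noise
  tissues <- sprintf("tissue%02d", seq_len(n_normal_tissues))
  tum_samples <- sprintf("TUM%03d", seq_len(n_tumour))
  norm_samples <- unlist(lapply(tissues, function(t)
    paste0(t, "_", sprintf("%03d", seq_len(samples_per_tissue)))))
  sample_map <- data.table::data.table(
    sample = c(tum_samples, norm_samples),
    tissue = c(rep("tumour", n_tumour), rep(tissues, each = samples_per_tissue)),
    cohort = c(rep("tumour", n_tumour), rep("normal", length(norm_samples))))
  n_samp <- nrow(sample_map)
  expr <- matrix(0, length(genes), n_samp, dimnames = list(genes, sample_map$sample))
  jit_t <- seq_len(n_tumour) * 0.1
  jit_n <- seq_along(norm_samples) * 0.01
  for (g in genes) {
    if (g %in% tumour_specific) {
      expr[g, tum_samples] <- 200 + jit_t
      expr[g, norm_samples] <- 1 + jit_n
    } else {
      expr[g, tum_samples] <- 5 + jit_t
      expr[g, norm_samples] <- 5 + jit_n[seq_along(norm_samples)]
    }
  }
  truth <- data.table::data.table(
    peptide = records$peptide,
    pass_binding = records$ic50 <= 500,
    pass_de = records$gene %in% tumour_specific,
    pass_ligandome = !records$gene %in% lig_genes)
  lig_peptides <- with_local_seed(derive_seed(seed, "funnel-lig"), {
    vapply(seq_along(lig_genes), function(i)
      paste(sample(CANONICAL_AA, 9, replace = TRUE), collapse = ""),
      character(1))
  })
  ligandome <- data.table::data.table(peptide = lig_peptides,
                                      gene = lig_genes, tissue = "liver")
  list(records = records, expr = expr, sample_map = sample_map,
       ligandome = ligandome, truth = truth,
       tumour_specific_genes = tumour_specific)
}

#' Write a ready-made synthetic dataset to disk
#'
#' Presets bundle the generators into on-disk fixtures (FASTA + TSV +
#' `truth/` tables) for CLI use: `smoke` (small proteome, index inputs,
#' planted cross-reactor), `funnel` (hit table, expression, ligandome with
#' stage labels), `scan` (like smoke with a larger proteome) and `ms1`
#' (feature tables with planted peptides).
#'
#' @param preset one of `"smoke"`, `"funnel"`, `"scan"`, `"ms1"`
#' @param seed integer seed
#' @param out_dir output directory (created)
#' @return named character vector of written file paths, invisibly
#' @export
synth_preset <- function(preset = c("smoke", "funnel", "scan", "ms1"),
                         seed = 1L, out_dir) {
  preset <- match.arg(preset)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "truth"), showWarnings = FALSE)
  paths <- c()
  emit <- function(x, name) {
    p <- file.path(out_dir, name)
    dir.create(dirname(p), recursive = TRUE, showWarnings = FALSE)
    write_tsv(x, p)
    paths[name] <<- p
  }
  query <- "QYNPIRTTF"; allele <- "HLA-A24:02"
  if (preset %in% c("smoke", "scan")) {
    n_genes <- if (preset == "smoke") 12L else 60L
    prot <- synth_proteome(n_genes, seed = seed)
    planted <- plant_cross_reactor(prot, query, n_substitutions = 0L,
                                   ic50 = 1, seed = seed)
    prot <- planted$proteome
    fasta <- file.path(out_dir, "proteome.fasta")
    write_proteome(prot, fasta); paths["proteome.fasta"] <- fasta
    ex <- synth_expression(setdiff(prot$gene, planted$truth$host_gene),
                           seed = seed)
    emit(data.table::data.table(gene = rownames(ex$expr),
                                data.table::as.data.table(ex$expr)),
         "expression.tsv")
    emit(ex$sample_map, "sample_map.tsv")
    pred <- toy_predictor(seed, overrides = data.table::data.table(
      peptide = planted$truth$peptide, allele = allele,
      ic50 = planted$truth$ic50, rank = 0.01))
    idx <- build_index(prot, 9L, allele, pred,
                       normal_tissue_max(ex$expr, ex$sample_map))
    ipath <- file.path(out_dir, "index.tsv")
    write_index(idx, ipath); paths["index.tsv"] <- ipath
    lig <- synth_normal_ligandome(prot, min(20L, nrow(idx)), seed = seed)
    emit(lig, "ligandome.tsv")
    emit(planted$truth, "truth/planted_cross_reactor.tsv")
  } else if (preset == "funnel") {
    fx <- make_funnel_fixture(seed)
    emit(fx$records, "records.tsv")
    emit(data.table::data.table(gene = rownames(fx$expr),
                                data.table::as.data.table(fx$expr)),
         "expression.tsv")
    emit(fx$sample_map, "sample_map.tsv")
    emit(fx$ligandome, "ligandome.tsv")
    emit(fx$truth, "truth/stage_labels.tsv")
  } else if (preset == "ms1") {
    ms <- synth_ms1_features(c(query, "EVDPIGHLY"), reference_rt = 30,
                             jitter_ppm = 2, jitter_rt_min = 0.2,
                             samples = paste0("S", 1:3), n_decoys = 5L,
                             seed = seed)
    emit(ms$features, "features.tsv")
    emit(ms$truth, "truth/feature_origin.tsv")
  }
  invisible(paths)
}
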