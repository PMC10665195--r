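# The antigen-discovery funnel and companion screens.
#
# Immunopeptidomics hits are filtered in three stages -- predicted binding
# affinity, tumour-specific differential expression of the parent gene
# versus every normal tissue, and absence of the parent gene from the
# empirically observed benign-tissue immunopeptidome -- then survivors are
# prioritized for receptor development. Cross-HLA presentation scans and
# MS1 matched-peptide searches support follow-up of individual candidates.

#' Filter pMHC records by predicted binding affinity
#'
#' Keeps records whose predicted IC50 is at or below the threshold
#' (boundary inclusive). 500 nM is the conventional cut-off for a peptide
#' strong enough to act as a T cell epitope.
#'
#' @param records data.frame with at least `peptide` and `ic50` (nM); one
#'   row per (sample, peptide, allele)
#' @param threshold_nm inclusive IC50 threshold in nM
#' @return surviving records as `data.table`
#' @export
filter_binding <- function(records, threshold_nm = 500) {
  rec <- data.table::as.data.table(records)
  if (!"ic50" %in% names(rec)) stop_scrapseek("records need an ic50 column")
  if (any(is.na(rec$ic50)))
    stop_scrapseek("missing ic50 in rows: ",
                   paste(utils::head(which(is.na(rec$ic50)), 10), collapse = ", "))
  rec[rec$ic50 <= threshold_nm]
}

#' Per-tissue tumour-versus-normal differential expression
#'
#' For each gene and each normal tissue, computes the log2 fold change of
#' mean log2(FPKM + 1) in tumour versus that tissue and a two-group p-value
#' (Mann-Whitney rank-sum by default; Welch t available). A gene passes the
#' tumour-specificity rule only when the fold change meets `min_lfc` AND
#' p < `alpha` against EVERY normal tissue (a conjunction, not a pooled
#' test). Tissues with fewer than `min_n` samples are excluded with a
#' warning.
#'
#' @param expr numeric matrix, rows = genes (rownames), columns = samples
#' @param sample_map data.frame with `sample`, `tissue`, `cohort`; cohort
#'   `tumour_cohort` marks tumour samples
#' @param min_lfc required log fold change (log2 by default; `log_base`
#'   switches)
#' @param alpha per-tissue significance level (raw p-values; set
#'   `p_adjust = "BH"` for Benjamini-Hochberg within tissue)
#' @param test `"wilcoxon"` (rank-sum) or `"welch"`
#' @param log_base base of the "one log fold" rule
#' @param tumour_cohort cohort label of tumour samples
#' @param p_adjust `"none"` (default, raw p rule) or `"BH"`
#' @param min_n minimum samples per group
#' @return `de_result`: list with `per_tissue` (`data.table`: gene, tissue,
#'   lfc, p), `summary` (`data.table`: gene, min_lfc, max_p, passes) and
#'   `params`
#' @export
differential_expression <- function(expr, sample_map, min_lfc = 1.0,
                                    alpha = 0.01,
                                    test = c("wilcoxon", "welch"),
                                    log_base = 2, tumour_cohort = "tumour",
                                    p_adjust = c("none", "BH"), min_n = 2L) {
  test <- match.arg(test)
  p_adjust <- match.arg(p_adjust)
  sm <- data.table::as.data.table(sample_map)
  sm <- sm[sm$sample %in% colnames(expr)]
  tum <- sm$sample[sm$cohort == tumour_cohort]
  if (length(tum) < min_n)
    stop_scrapseek("need at least ", min_n, " tumour samples")
  norm <- sm[sm$cohort != tumour_cohort]
  tissues <- split(norm$sample, norm$tissue)
  small <- names(tissues)[vapply(tissues, length, integer(1)) < min_n]
  if (length(small)) {
    warning("excluding tissues with < ", min_n, " samples: ",
            paste(small, collapse = ", "), call. = FALSE)
    tissues <- tissues[setdiff(names(tissues), small)]
  }
  if (length(tissues) == 0) stop_scrapseek("no normal tissue has enough samples")
  lx <- log(expr + 1, base = log_base)
  tum_mean <- rowMeans(lx[, tum, drop = FALSE])
  rows <- lapply(names(tissues), function(ti) {
    cols <- tissues[[ti]]
    ti_mean <- rowMeans(lx[, cols, drop = FALSE])
    p <- vapply(rownames(expr), function(g) {
      x <- expr[g, tum]; y <- expr[g, cols]
      if (test == "wilcoxon")
        stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
      else
        stats::t.test(lx[g, tum], lx[g, cols])$p.value
    }, numeric(1))
    p[is.na(p)] <- 1  # constant-in-both-groups degenerate case
    data.table::data.table(gene = rownames(expr), tissue = ti,
                           lfc = tum_mean - ti_mean, p = unname(p))
  })
  per_tissue <- data.table::rbindlist(rows)
  if (p_adjust == "BH") {
    tissue <- p <- NULL
    per_tissue[, p := stats::p.adjust(p, "BH"), by = tissue]
  }
  gene <- lfc <- p <- NULL
  summary <- per_tissue[, .(min_lfc = min(lfc), max_p = max(p),
                            passes = all(lfc >= min_lfc & p < alpha)),
                        by = gene]
  structure(list(per_tissue = per_tissue, summary = summary,
                 params = list(min_lfc = min_lfc, alpha = alpha, test = test,
                               log_base = log_base, p_adjust = p_adjust,
                               n_tumour = length(tum),
                               tissues = names(tissues))),
            class = "de_result")
}

#' @export
print.de_result <- function(x, ...) {
  cat("differential expression:", nrow(x$summary), "genes vs",
      length(x$params$tissues), "normal tissues;",
      sum(x$summary$passes), "pass (lfc >=", x$params$min_lfc,
      "and p <", x$params$alpha, "in every tissue)\n")
  invisible(x)
}

#' Exclude peptides whose parent gene appears in the benign ligandome
#'
#' Gene-level exclusion: a record is dropped if its parent gene is
#' represented anywhere in the normal-tissue immunopeptidome, even by a
#' different peptide. This is deliberately conservative for receptor
#' safety and is flagged as gene-level in funnel reports.
#'
#' @param records data.frame with a `gene` column
#' @param normal_ligandome data.frame with a `gene` column (peptides
#'   observed on normal tissues with their parent genes)
#' @return surviving records as `data.table`
#' @export
filter_normal_ligandome <- function(records, normal_ligandome) {
  rec <- data.table::as.data.table(records)
  lig_genes <- if (is.null(normal_ligandome) || nrow(normal_ligandome) == 0)
    character(0) else unique(as.character(normal_ligandome$gene))
  rec[!rec$gene %in% lig_genes]
}

#' Run the full antigen-discovery funnel
#'
#' Applies the three stages in order -- binding affinity, per-tissue
#' differential expression of the parent gene, benign-ligandome exclusion --
#' and reports surviving records with per-stage counts (records, unique
#' peptides, unique genes). Counts are monotone non-increasing by
#' construction.
#'
#' @param records pMHC hit table: `sample`, `peptide`, `gene`, `allele`,
#'   `ic50`, `rank_pct`
#' @param expr,sample_map expression inputs, see [differential_expression()]
#' @param normal_ligandome benign immunopeptidome table with `gene`
#' @param binding_threshold_nm IC50 cut-off (nM, inclusive)
#' @param min_lfc,alpha,test,log_base DE-stage parameters
#' @return `funnel_report`: list with `stages` (named list of survivor
#'   `data.table`s, in order input/binding/differential_expression/
#'   ligandome), `counts` (`data.table`), `de` (the [differential_expression()]
#'   result) and `params`
#' @export
run_funnel <- function(records, expr, sample_map, normal_ligandome,
                       binding_threshold_nm = 500, min_lfc = 1.0,
                       alpha = 0.01, test = "wilcoxon", log_base = 2) {
  rec <- data.table::as.data.table(records)
  validate_peptide(rec$peptide)
  s0 <- rec
  s1 <- filter_binding(s0, binding_threshold_nm)
  de <- differential_expression(expr, sample_map, min_lfc = min_lfc,
                                alpha = alpha, test = test,
                                log_base = log_base)
  pass_genes <- de$summary$gene[de$summary$passes]
  s2 <- s1[s1$gene %in% pass_genes]
  s3 <- filter_normal_ligandome(s2, normal_ligandome)
  stages <- list(input = s0, binding = s1,
                 differential_expression = s2, ligandome = s3)
  counts <- data.table::rbindlist(lapply(names(stages), function(nm) {
    s <- stages[[nm]]
    data.table::data.table(stage = nm, n_records = nrow(s),
                           n_unique_peptides = length(unique(s$peptide)),
                           n_unique_genes = length(unique(s$gene)))
  }))
  structure(list(stages = stages, counts = counts, de = de,
                 params = list(binding_threshold_nm = binding_threshold_nm,
                               min_lfc = min_lfc, alpha = alpha, test = test,
                               log_base = log_base,
                               ligandome_exclusion = "gene-level")),
            class = "funnel_report")
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("antigen-discovery funnel (binding <=", x$params$binding_threshold_nm,
      "nM -> DE -> benign-ligandome exclusion)\n")
  print(x$counts)
  invisible(x)
}

#' Prioritize funnel survivors for receptor development
#'
#' Aggregates surviving records to unique peptides and ranks them by a
#' composite of per-factor z-scores: differential expression (minimum
#' tumour-vs-tissue log fold change), HLA allele population frequency,
#' relative peptide abundance (predictor percentile rank, lower is more
#' abundant), predicted binding affinity (lower IC50 is better) and
#' recurrence (number of distinct tumours presenting the identical
#' peptide). All factor columns are emitted so users can re-rank; the
#' composite is decision support, not a verdict.
#'
#' @param survivors records surviving the funnel (`sample`, `peptide`,
#'   `gene`, `allele`, `ic50`, `rank_pct`)
#' @param de optional [differential_expression()] result supplying min_lfc
#' @param allele_freq optional named vector, allele -> population frequency
#' @param weights named numeric weights over
#'   `c("lfc","allele_freq","abundance","binding","recurrence")`; default equal
#' @return ranked `data.table`, one row per unique peptide, with factor
#'   columns, `composite`, `priority_rank` and an `imputed_factors` note
#'   column
#' @export
prioritize <- function(survivors, de = NULL, allele_freq = NULL,
                       weights = NULL) {
  rec <- data.table::as.data.table(survivors)
  if (nrow(rec) == 0) return(rec)
  peptide <- gene <- allele <- ic50 <- rank_pct <- NULL
  agg <- rec[, .(gene = gene[1], allele = allele[1],
                 ic50 = min(ic50), rank_pct = min(rank_pct),
                 recurrence = length(unique(sample))),
             by = peptide]
  agg$lfc <- if (!is.null(de))
    de$summary$min_lfc[match(agg$gene, de$summary$gene)] else NA_real_
  agg$allele_freq <- if (!is.null(allele_freq))
    unname(allele_freq[agg$allele]) else NA_real_
  factors <- c(lfc = 1, allele_freq = 1, abundance = -1, binding = -1,
               recurrence = 1)  # sign: +1 higher-is-better
  raw <- data.table::data.table(
    lfc = agg$lfc, allele_freq = agg$allele_freq,
    abundance = agg$rank_pct, binding = log10(agg$ic50),
    recurrence = as.numeric(agg$recurrence))
  if (is.null(weights))
    weights <- stats::setNames(rep(1, length(factors)), names(factors))
  imputed <- character(nrow(agg))
  zmat <- matrix(0, nrow(agg), length(factors),
                 dimnames = list(NULL, names(factors)))
  for (f in names(factors)) {
    v <- raw[[f]]
    miss <- is.na(v)
    if (all(miss)) { imputed[] <- paste0(imputed, f, ";"); next }
    v[miss] <- stats::median(v, na.rm = TRUE)
    if (any(miss)) imputed[miss] <- paste0(imputed[miss], f, ";")
    s <- stats::sd(v)
    z <- if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
    zmat[, f] <- factors[f] * weights[f] * z
  }
  agg$composite <- rowSums(zmat)
  agg$imputed_factors <- sub(";$", "", imputed)
  data.table::setorderv(agg, c("composite", "peptide"), order = c(-1L, 1L))
  agg$priority_rank <- seq_len(nrow(agg))
  agg[]
}

#' Scan which HLA alleles are predicted to present a peptide
#'
#' Runs the binding predictor over a panel of alleles and returns those
#' with percentile rank at or below the threshold, sorted by rank. The
#' allele the peptide was discovered on is excluded from the "additional"
#' set but reported separately; alleles the predictor cannot score are
#' listed under `unscored`, never dropped silently.
#'
#' @param peptide query peptide
#' @param alleles character vector of HLA allele names
#' @param predictor binding predictor
#' @param rank_threshold_pct presentation call threshold on percentile rank
#' @param discovery_allele allele to exclude from the additional set
#' @return list with `presented` (`data.table`: allele, ic50, rank),
#'   `discovery` (row for the discovery allele, if scored) and `unscored`
#' @export
cross_hla_scan <- function(peptide, alleles, predictor,
                           rank_threshold_pct = 2, discovery_allele = NULL) {
  validate_peptide(peptide)
  rows <- list(); unscored <- character(0)
  for (a in alleles) {
    r <- tryCatch(predict_binding(predictor, peptide, a),
                  error = function(e) NULL)
    if (is.null(r)) unscored <- c(unscored, a) else rows[[a]] <- r
  }
  tab <- data.table::rbindlist(rows)
  disc <- if (!is.null(discovery_allele) && nrow(tab) > 0)
    tab[tab$allele == discovery_allele] else NULL
  if (nrow(tab) > 0 && !is.null(discovery_allele))
    tab <- tab[tab$allele != discovery_allele]
  hits <- if (nrow(tab) > 0) tab[tab$rank <= rank_threshold_pct] else tab
  if (nrow(hits) > 0)
    data.table::setorderv(hits, c("rank", "allele"))
  list(presented = hits, discovery = disc, unscored = unscored)
}

#' Match MS1 features to a peptide's theoretical m/z
#'
#' A feature matches when its m/z lies within `ppm_tol` of the theoretical
#' m/z of the peptide at some allowed charge AND its retention time is
#' within `rt_window_min` of the reference RT. When features carry a
#' `charge` column the observed charge is used (and must be in `charges`);
#' otherwise every allowed charge is tried. No RT prediction is attempted:
#' `reference_rt` is required.
#'
#' @param peptide peptide sequence
#' @param features data.frame with `sample`, `mz`, `rt` (minutes) and
#'   optionally `charge`
#' @param ppm_tol m/z tolerance, parts per million
#' @param rt_window_min retention-time window, minutes
#' @param charges allowed charge states
#' @param reference_rt reference retention time, minutes
#' @param table amino-acid table for the mass calculation
#' @return matched features as `data.table` with `matched_charge`,
#'   `theoretical_mz`, `ppm_error`, `rt_offset`, ordered by sample
#' @export
match_ms1_features <- function(peptide, features, ppm_tol = 10,
                               rt_window_min = 1.0, charges = c(1L, 2L, 3L),
                               reference_rt = NULL,
                               table = default_aa_table()) {
  if (is.null(reference_rt) || !is.finite(reference_rt))
    stop_scrapseek("reference_rt is required; retention time is not predicted")
  validate_peptide(peptide)
  feat <- data.table::as.data.table(features)
  theo <- stats::setNames(peptide_mz(peptide, charges, table), charges)
  has_charge <- "charge" %in% names(feat)
  out <- lapply(seq_len(nrow(feat)), function(i) {
    zs <- if (has_charge && !is.na(feat$charge[i])) {
      if (feat$charge[i] %in% charges) feat$charge[i] else return(NULL)
    } else charges
    rt_off <- feat$rt[i] - reference_rt
    if (abs(rt_off) > rt_window_min) return(NULL)
    for (z in zs) {
      t_mz <- theo[as.character(z)]
      ppm <- (feat$mz[i] - t_mz) / t_mz * 1e6
      if (abs(ppm) <= ppm_tol) {
        row <- feat[i]
        row$matched_charge <- as.integer(z)
        row$theoretical_mz <- unname(t_mz)
        row$ppm_error <- unname(ppm)
        row$rt_offset <- rt_off
        return(row)
      }
    }
    NULL
  })
  matched <- data.table::rbindlist(out)
  if (nrow(matched) > 0) data.table::setorderv(matched, "sample")
  matched
}
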