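# Proteome windowing and the searchable normal-peptidome index.
#
# The cross-reactivity scan compares a query against every same-length
# window of the normal proteome; this module builds that index and annotates
# each unique window with parent genes, predicted binding (b, nM) and
# maximum normal-tissue expression (E_max).

#' Read a gene-annotated proteome from FASTA
#'
#' Headers are expected in the dialect `ID|GENE description`; the gene field
#' is extracted with a configurable regex whose first capture group is the
#' gene symbol.
#'
#' @param path FASTA file
#' @param gene_pattern regex with one capture group extracting the gene from
#'   the header; records that do not match keep the full header as gene
#' @return `data.table` with columns `protein_id`, `gene`, `sequence`
#' @export
read_proteome <- function(path, gene_pattern = "^[^|]+\\|([^ |]+)") {
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  ids <- sub("[ |].*$", "", headers)
  m <- regmatches(headers, regexec(gene_pattern, headers))
  genes <- vapply(seq_along(m), function(i) {
    if (length(m[[i]]) >= 2) m[[i]][2] else headers[i]
  }, character(1))
  out <- data.table::data.table(protein_id = ids, gene = genes,
                                sequence = as.character(aa))
  if (anyDuplicated(out$protein_id))
    stop_scrapseek("duplicate protein_id in proteome FASTA")
  if (any(nchar(out$sequence) == 0))
    stop_scrapseek("empty sequence in proteome FASTA")
  out
}

#' Write a proteome table as FASTA
#'
#' @param proteome `data.table` with `protein_id`, `gene`, `sequence`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_proteome <- function(proteome, path) {
  aa <- Biostrings::AAStringSet(proteome$sequence)
  names(aa) <- paste0(proteome$protein_id, "|", proteome$gene)
  Biostrings::writeXStringSet(aa, path, width = 60)
  invisible(path)
}

#' Window a proteome into fixed-length peptides
#'
#' Enumerates every substring of the stated length from every protein;
#' identical peptides arising from several proteins are merged, carrying the
#' union of parent genes. Windows containing non-canonical residues are
#' skipped and counted, never silently dropped.
#'
#' @param proteome `data.table` with `protein_id`, `gene`, `sequence`
#' @param length window length, 8-14
#' @return `data.table` with columns `peptide`, `genes` (semicolon-joined,
#'   sorted) plus attributes `n_windows` (total windows before dedup,
#'   skipped included) and `n_skipped`
#' @export
window_peptides <- function(proteome, length) {
  if (length < 8 || length > 14)
    stop_scrapseek("window length must be 8-14 (got ", length, ")")
  k <- as.integer(length)
  if (nrow(proteome) == 0) {
    out <- data.table::data.table(peptide = character(), genes = character())
    data.table::setattr(out, "n_windows", 0L)
    data.table::setattr(out, "n_skipped", 0L)
    return(out)
  }
  pieces <- lapply(seq_len(nrow(proteome)), function(i) {
    s <- proteome$sequence[i]
    n <- nchar(s)
    if (n < k) return(NULL)
    starts <- seq_len(n - k + 1L)
    data.table::data.table(peptide = substring(s, starts, starts + k - 1L),
                           gene = proteome$gene[i])
  })
  win <- data.table::rbindlist(pieces)
  if (nrow(win) == 0) {
    out <- data.table::data.table(peptide = character(), genes = character())
    data.table::setattr(out, "n_windows", 0L)
    data.table::setattr(out, "n_skipped", 0L)
    return(out)
  }
  n_windows <- nrow(win)
  ok <- grepl(paste0("^[", paste(CANONICAL_AA, collapse = ""), "]+$"), win$peptide)
  n_skipped <- sum(!ok)
  win <- win[ok]
  gene <- peptide <- NULL  # NSE notes
  out <- win[, .(genes = paste(sort(unique(gene)), collapse = ";")), by = peptide]
  data.table::setkeyv(out, "peptide")
  data.table::setattr(out, "n_windows", n_windows)
  data.table::setattr(out, "n_skipped", n_skipped)
  out[]
}

#' Maximum normal-tissue expression per gene
#'
#' Summarizes a gene x sample FPKM/RPKM matrix to one value per gene: the
#' maximum over normal tissues of the per-tissue mean expression. Samples
#' are mapped to tissues and cohorts by `sample_map`; only cohorts other
#' than `tumour_cohort` count as normal.
#'
#' @param expr numeric matrix, rows = genes (rownames), columns = samples
#' @param sample_map data.frame with columns `sample`, `tissue`, `cohort`
#' @param tumour_cohort cohort label excluded from the normal-tissue maximum
#' @return named numeric vector, gene -> E_max
#' @export
normal_tissue_max <- function(expr, sample_map, tumour_cohort = "tumour") {
  sm <- data.table::as.data.table(sample_map)
  norm <- sm[sm$cohort != tumour_cohort]
  if (nrow(norm) == 0) stop_scrapseek("no normal-cohort samples in sample map")
  cols <- intersect(norm$sample, colnames(expr))
  if (length(cols) == 0) stop_scrapseek("no normal samples found in expression matrix")
  tissues <- split(cols, stats::setNames(norm$tissue, norm$sample)[cols])
  per_tissue <- vapply(tissues, function(smp) {
    rowMeans(expr[, smp, drop = FALSE])
  }, numeric(nrow(expr)))
  if (is.null(dim(per_tissue))) per_tissue <- matrix(per_tissue, ncol = 1)
  stats::setNames(apply(per_tissue, 1, max), rownames(expr))
}

#' Annotate peptides with maximum normal-tissue expression
#'
#' E_max of a peptide is the maximum over its parent genes of the gene-level
#' normal-tissue maximum. Genes absent from the expression summary receive a
#' configurable floor (default 0.01 RPKM) so downstream score divisions are
#' finite while unexpressed genes still rank as high-risk under the printed
#' score; missing genes are recorded in the `missing_genes` attribute.
#'
#' @param peptide_genes `data.table` from [window_peptides()]
#' @param gene_emax named vector from [normal_tissue_max()], or a gene x
#'   tissue matrix (summarized with per-gene max)
#' @param missing_value E_max assigned to genes absent from the summary
#' @return copy of `peptide_genes` with an `E_max` column; attribute
#'   `missing_genes` lists unresolved genes
#' @export
annotate_expression <- function(peptide_genes, gene_emax, missing_value = 0.01) {
  if (is.matrix(gene_emax))
    gene_emax <- stats::setNames(apply(gene_emax, 1, max), rownames(gene_emax))
  if (any(gene_emax < 0)) stop_scrapseek("expression values must be >= 0")
  out <- data.table::copy(peptide_genes)
  gene_sets <- strsplit(out$genes, ";", fixed = TRUE)
  missing <- character()
  out$E_max <- vapply(gene_sets, function(gs) {
    known <- gs %in% names(gene_emax)
    if (any(!known)) missing <<- c(missing, gs[!known])
    if (any(known)) max(gene_emax[gs[known]], if (all(known)) NULL else missing_value)
    else missing_value
  }, numeric(1))
  data.table::setattr(out, "missing_genes", sort(unique(missing)))
  out[]
}

#' Build the normal-peptidome index for one HLA allele
#'
#' Composition of [window_peptides()], the binding predictor, and
#' [annotate_expression()]: every unique window of the stated length gets
#' parent genes, predicted IC50 (`b_nM`) and percentile rank, and `E_max`.
#' Peptides the predictor fails on are dropped with a count in the
#' `n_predictor_failures` attribute.
#'
#' @param proteome `data.table` with `protein_id`, `gene`, `sequence`
#' @param length peptide length, 8-14
#' @param allele HLA allele name
#' @param predictor binding predictor (see [predict_binding()])
#' @param gene_emax named gene -> E_max vector (see [normal_tissue_max()]);
#'   NULL gives every peptide the floor value
#' @param missing_value expression floor for unresolved genes
#' @return `proteome_index` object: `data.table` with columns `peptide`,
#'   `genes`, `b_nM`, `rank`, `E_max` and attributes `allele`,
#'   `peptide_length`, `n_windows`, `n_skipped`, `n_predictor_failures`
#' @export
build_index <- function(proteome, length, allele, predictor,
                        gene_emax = NULL, missing_value = 0.01) {
  win <- window_peptides(proteome, length)
  if (is.null(gene_emax)) gene_emax <- stats::setNames(numeric(0), character(0))
  ann <- annotate_expression(win, gene_emax, missing_value)
  n_fail <- 0L
  if (nrow(ann) > 0) {
    pred <- tryCatch(predict_binding(predictor, ann$peptide, allele),
                     error = function(e) NULL)
    if (is.null(pred)) {
      # batch failed: retry row-wise so one bad peptide cannot sink the build
      rows <- lapply(ann$peptide, function(p) {
        tryCatch(predict_binding(predictor, p, allele), error = function(e) NULL)
      })
      n_fail <- sum(vapply(rows, is.null, logical(1)))
      keep <- !vapply(rows, is.null, logical(1))
      ann <- ann[keep]
      pred <- data.table::rbindlist(rows[keep])
    }
    ann$b_nM <- pred$ic50
    ann$rank <- pred$rank
  } else {
    ann$b_nM <- numeric(0)
    ann$rank <- numeric(0)
  }
  data.table::setcolorder(ann, c("peptide", "genes", "b_nM", "rank", "E_max"))
  data.table::setkeyv(ann, "peptide")
  data.table::setattr(ann, "allele", allele)
  data.table::setattr(ann, "peptide_length", as.integer(length))
  data.table::setattr(ann, "n_predictor_failures", n_fail)
  data.table::setattr(ann, "class", c("proteome_index", class(ann)))
  ann[]
}

#' @export
print.proteome_index <- function(x, ...) {
  cat("proteome_index:", nrow(x), "unique", attr(x, "peptide_length"),
      "-mers on", attr(x, "allele"), "\n")
  cat("  windows:", attr(x, "n_windows"), " skipped:", attr(x, "n_skipped"),
      " predictor failures:", attr(x, "n_predictor_failures"), "\n")
  print(data.table::as.data.table(x), topn = 3)
  invisible(x)
}

#' Persist / load a proteome index as TSV
#'
#' Metadata (allele, peptide length) is carried in `#`-prefixed header
#' lines so the file round-trips losslessly.
#' @param index `proteome_index`
#' @param path TSV path
#' @return `write_index`: `path` invisibly; `read_index`: `proteome_index`
#' @export
write_index <- function(index, path) {
  con <- file(path, "w")
  writeLines(c(paste0("# allele=", attr(index, "allele")),
               paste0("# peptide_length=", attr(index, "peptide_length"))), con)
  close(con)
  data.table::fwrite(data.table::as.data.table(index), path, sep = "\t",
                     quote = FALSE, append = TRUE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_index
#' @export
read_index <- function(path) {
  hdr <- readLines(path, n = 2L)
  meta <- sub("^# *", "", hdr[startsWith(hdr, "#")])
  kv <- strsplit(meta, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, character(1), 2),
                          vapply(kv, `[`, character(1), 1))
  tab <- data.table::fread(path, sep = "\t", skip = length(meta), header = TRUE)
  data.table::setkeyv(tab, "peptide")
  data.table::setattr(tab, "allele", unname(vals["allele"]))
  data.table::setattr(tab, "peptide_length", as.integer(vals["peptide_length"]))
  data.table::setattr(tab, "class", c("proteome_index", class(tab)))
  tab[]
}
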