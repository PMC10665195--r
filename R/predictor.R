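# Pluggable pMHC binding-predictor contract.
#
# A predictor is any function(peptides, allele) returning a data.frame with
# numeric columns ic50 (nM, > 0) and rank (percentile, 0-100), one row per
# peptide, deterministic for fixed inputs. External engines (NetMHC-class
# tools) satisfy the contract by being run once and replayed from a cached
# table; a deterministic toy predictor ships with the synthetic module.

#' Run a binding predictor with contract validation
#'
#' @param predictor function(peptides, allele) -> data.frame(ic50, rank)
#' @param peptides character vector of peptides
#' @param allele single HLA allele name
#' @return `data.table` with columns `peptide`, `allele`, `ic50`, `rank`
#' @export
predict_binding <- function(predictor, peptides, allele) {
  stopifnot(is.function(predictor), length(allele) == 1L)
  out <- predictor(peptides, allele)
  if (!all(c("ic50", "rank") %in% names(out)) || nrow(out) != length(peptides))
    stop_scrapseek("predictor must return one row per peptide with columns ic50, rank")
  if (any(!is.finite(out$ic50)) || any(out$ic50 <= 0))
    stop_scrapseek("predictor returned non-positive IC50")
  if (any(out$rank < 0 | out$rank > 100))
    stop_scrapseek("predictor returned percentile rank outside [0, 100]")
  data.table::data.table(peptide = peptides, allele = allele,
                         ic50 = as.numeric(out$ic50), rank = as.numeric(out$rank))
}

#' Predictor backed by a precomputed (peptide, allele) table
#'
#' Wraps a table of precomputed predictions (for example the replayed output
#' of an external engine) as a predictor function. Unknown (peptide, allele)
#' combinations raise an error so gaps are never silently imputed.
#'
#' @param table data.frame with columns peptide, allele, ic50, rank
#' @return predictor function
#' @export
table_predictor <- function(table) {
  tab <- data.table::as.data.table(table)
  need <- c("peptide", "allele", "ic50", "rank")
  if (!all(need %in% names(tab)))
    stop_scrapseek("prediction table needs columns: ", paste(need, collapse = ", "))
  data.table::setkeyv(tab, c("peptide", "allele"))
  function(peptides, allele) {
    want <- data.table::data.table(peptide = peptides, allele = allele)
    hit <- tab[want, on = c("peptide", "allele")]
    if (any(is.na(hit$ic50))) {
      miss <- hit$peptide[is.na(hit$ic50)]
      stop_scrapseek("no prediction for ", length(miss), " peptide(s) on ",
                     allele, " (first: ", miss[1], ")")
    }
    data.frame(ic50 = hit$ic50, rank = hit$rank)
  }
}

#' Cache predictor output to a TSV and replay it
#'
#' Runs `predictor` once over `peptides` x `alleles`, writes the results as
#' TSV, and returns the cached table. `table_predictor(read_tsv(path))`
#' replays it, so expensive external engines need only one pass.
#'
#' @param predictor predictor function
#' @param peptides character vector
#' @param alleles character vector of HLA allele names
#' @param path output TSV path
#' @return the cached `data.table`, invisibly
#' @export
cache_predictions <- function(predictor, peptides, alleles, path) {
  rows <- lapply(alleles, function(a) predict_binding(predictor, peptides, a))
  tab <- data.table::rbindlist(rows)
  write_tsv(tab, path)
  invisible(tab)
}
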