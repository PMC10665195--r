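# The cross-reactivity scoring engine.
#
# A query tumour pMHC is compared position-by-position against every
# same-length peptide in the normal-peptidome index. Per scored position the
# pair contributes 5 (identical), 2 (same chemical class) or -2 (otherwise);
# the positional sum is combined with the candidate's predicted binding
# affinity b (nM) and maximum normal-tissue expression E_max into the
# overall risk score, and candidates are reported ranked.

#' Positional similarity between a query and a candidate peptide
#'
#' Applies [classify_pair()] at each scored position and sums the outcomes.
#' No alignment or gapping is attempted: lengths must match.
#'
#' @param query,candidate equal-length peptides
#' @param table amino-acid table
#' @param positions 1-based positions to score, default the anchor-masked
#'   set from [scored_positions()]
#' @return list with `sum_p` (integer) and `scores` (integer vector named
#'   by position)
#' @export
#' @examples
#' similarity_score("QYNPIRTTF", "QYNPIRTTF")$sum_p  # 35
similarity_score <- function(query, candidate, table = default_aa_table(),
                             positions = scored_positions(nchar(query))) {
  validate_peptide(query)
  validate_residues(candidate)
  if (nchar(query) != nchar(candidate))
    stop_scrapseek("query and candidate lengths differ (",
                   nchar(query), " vs ", nchar(candidate), "); no alignment is attempted")
  if (any(positions < 1 | positions > nchar(query)))
    stop_scrapseek("scored positions outside the peptide")
  qa <- substring(query, positions, positions)
  ca <- substring(candidate, positions, positions)
  sc <- classify_pair(qa, ca, table)
  names(sc) <- positions
  list(sum_p = sum(sc), scores = sc)
}

# vectorized positional scoring of many candidates against one query
similarity_score_many <- function(query, candidates, table = default_aa_table(),
                                  positions = scored_positions(nchar(query))) {
  if (length(candidates) == 0) return(integer(0))
  cls <- stats::setNames(table$class, table$residue)
  qres <- substring(query, positions, positions)
  qcls <- cls[qres]
  total <- integer(length(candidates))
  for (j in seq_along(positions)) {
    p <- positions[j]
    cres <- substr(candidates, p, p)
    sc <- ifelse(cres == qres[j], 5L,
                 ifelse(cls[cres] == qcls[j], 2L, -2L))
    total <- total + as.integer(sc)
  }
  total
}

#' Overall cross-reactivity score
#'
#' Printed mode computes `sum_p / (b * E_max)` with `E_max` floored to avoid
#' division by zero; expression-weighted mode computes
#' `sum_p * E_max / b`, in which higher normal expression raises rather than
#' lowers the risk score. Both orientations ship because the two readings of
#' the expression term disagree; the mode used is always recorded in report
#' metadata.
#'
#' @param sum_p positional score sum
#' @param b predicted binding affinity of the normal peptide, nM IC50 (> 0)
#' @param e_max maximum normal-tissue expression, RPKM (>= 0)
#' @param mode `"printed"` (default) or `"expression_weighted"`
#' @param e_max_floor lower bound applied to `e_max`
#' @return numeric score
#' @export
#' @examples
#' overall_score(35, 1, 1)        # 35
#' overall_score(35, 500, 10)     # 0.007
overall_score <- function(sum_p, b, e_max,
                          mode = c("printed", "expression_weighted"),
                          e_max_floor = 0.01) {
  mode <- match.arg(mode)
  if (any(!is.finite(b)) || any(b <= 0))
    stop_scrapseek("binding affinity b must be positive (nM)")
  if (any(e_max < 0)) stop_scrapseek("E_max must be >= 0")
  e <- pmax(e_max, e_max_floor)
  if (mode == "printed") sum_p / (b * e) else sum_p * e / b
}

#' Scan a query pMHC against the normal-peptidome index
#'
#' Scores every index peptide against the query, combines the positional
#' sum with b and E_max, and returns the ranked report. Ordering is overall
#' score descending with deterministic tie-breaks (sum_p descending, b
#' ascending, peptide lexicographic in the C locale). Exact self-matches are
#' reported and flagged rather than removed, and each candidate carries a
#' T/F flag for presence in the normal-tissue immunopeptidome.
#'
#' @param query query peptide (8-14-mer)
#' @param allele query HLA allele; must match the index
#' @param index `proteome_index` from [build_index()]
#' @param normal_ligandome optional data.frame with a `peptide` column (and
#'   typically `gene`, `tissue`): the empirically observed normal
#'   immunopeptidome
#' @param top_k number of top candidates to return
#' @param mode overall-score orientation, see [overall_score()]
#' @param table amino-acid table
#' @param convention anchor-masking convention, see [scored_positions()]
#' @param e_max_floor expression floor shared with [overall_score()]
#' @return `scrap_report`: `data.table` with columns `rank`, `peptide`,
#'   `genes`, `sum_p`, `b_nM`, `E_max`, `overall_score`,
#'   `in_normal_ligandome`, `self`; attributes `query`, `allele`, `mode`,
#'   `convention`, `n_candidates`
#' @export
scrap_scan <- function(query, allele, index, normal_ligandome = NULL,
                       top_k = 100L, mode = c("printed", "expression_weighted"),
                       table = default_aa_table(),
                       convention = c("text", "equation"),
                       e_max_floor = 0.01) {
  mode <- match.arg(mode)
  convention <- match.arg(convention)
  validate_peptide(query)
  if (!identical(attr(index, "allele"), allele))
    stop_scrapseek("index allele (", attr(index, "allele"),
                   ") does not match query allele (", allele, ")")
  if (nchar(query) != attr(index, "peptide_length"))
    stop_scrapseek("index peptide length (", attr(index, "peptide_length"),
                   ") does not match query length (", nchar(query), ")")
  positions <- scored_positions(nchar(query), convention)
  cand <- data.table::as.data.table(index)
  for (a in c("allele", "peptide_length", "n_windows", "n_skipped",
              "n_predictor_failures", "missing_genes"))
    data.table::setattr(cand, a, NULL)
  n_total <- nrow(cand)
  if (n_total > 0) {
    cand$sum_p <- similarity_score_many(query, cand$peptide, table, positions)
    cand$overall_score <- overall_score(cand$sum_p, cand$b_nM, cand$E_max,
                                        mode, e_max_floor)
    lig <- if (is.null(normal_ligandome)) character(0) else
      unique(as.character(normal_ligandome$peptide))
    cand$in_normal_ligandome <- cand$peptide %in% lig
    cand$self <- cand$peptide == query
    data.table::setorderv(cand,
                          c("overall_score", "sum_p", "b_nM", "peptide"),
                          order = c(-1L, -1L, 1L, 1L))
    cand$rank <- seq_len(n_total)
    cand <- cand[seq_len(min(top_k, n_total))]
  } else {
    cand <- data.table::data.table(
      peptide = character(), genes = character(), b_nM = numeric(),
      rank = integer(), E_max = numeric(), sum_p = integer(),
      overall_score = numeric(), in_normal_ligandome = logical(),
      self = logical())
  }
  data.table::setcolorder(cand, c("rank", "peptide", "genes", "sum_p", "b_nM",
                                  "E_max", "overall_score",
                                  "in_normal_ligandome", "self"))
  data.table::setattr(cand, "query", query)
  data.table::setattr(cand, "allele", allele)
  data.table::setattr(cand, "mode", mode)
  data.table::setattr(cand, "convention", convention)
  data.table::setattr(cand, "n_candidates", n_total)
  data.table::setattr(cand, "class", c("scrap_report", class(cand)))
  cand[]
}

#' @export
print.scrap_report <- function(x, ...) {
  cat("sCRAP scan:", attr(x, "query"), "on", attr(x, "allele"),
      "| mode:", attr(x, "mode"),
      "|", attr(x, "n_candidates"), "candidates scored\n")
  print(data.table::as.data.table(x), topn = 5)
  invisible(x)
}

#' Write / read a cross-reactivity report
#'
#' Fixed column order `rank, peptide, genes, sum_p, b_nM, E_max,
#' overall_score, in_normal_ligandome, self`; the ligandome and self flags
#' render exactly as `"T"`/`"F"`. Scan metadata travels in `#`-prefixed
#' header lines so the report round-trips losslessly.
#'
#' @param report `scrap_report` from [scrap_scan()]
#' @param path TSV path
#' @return `write_scrap_report`: `path` invisibly; `read_scrap_report`: the
#'   report
#' @export
write_scrap_report <- function(report, path) {
  out <- data.table::as.data.table(report)
  out$in_normal_ligandome <- ifelse(out$in_normal_ligandome, "T", "F")
  out$self <- ifelse(out$self, "T", "F")
  meta <- c(query = attr(report, "query"), allele = attr(report, "allele"),
            mode = attr(report, "mode"), convention = attr(report, "convention"),
            n_candidates = attr(report, "n_candidates"))
  con <- file(path, "w")
  writeLines(paste0("# ", names(meta), "=", meta), con)
  close(con)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, append = TRUE,
                     col.names = TRUE)
  invisible(path)
}

#' @rdname write_scrap_report
#' @export
read_scrap_report <- function(path) {
  all_lines <- readLines(path)
  meta_lines <- all_lines[startsWith(all_lines, "# ")]
  kv <- strsplit(sub("^# ", "", meta_lines), "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, character(1), 2),
                          vapply(kv, `[`, character(1), 1))
  tab <- data.table::fread(path, sep = "\t", skip = length(meta_lines),
                           header = TRUE,
                           colClasses = list(character = c("in_normal_ligandome", "self")))
  tab$in_normal_ligandome <- tab$in_normal_ligandome == "T"
  tab$self <- tab$self == "T"
  data.table::setattr(tab, "query", unname(vals["query"]))
  data.table::setattr(tab, "allele", unname(vals["allele"]))
  data.table::setattr(tab, "mode", unname(vals["mode"]))
  data.table::setattr(tab, "convention", unname(vals["convention"]))
  data.table::setattr(tab, "n_candidates", as.integer(vals["n_candidates"]))
  data.table::setattr(tab, "class", c("scrap_report", class(tab)))
  tab[]
}
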