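# Alanine-scan contact-residue analysis.
#
# Single-position alanine substitution of the target peptide abrogates
# receptor binding at positions the receptor contacts; positions whose
# relative tetramer/dextramer signal falls below a threshold are called
# contact residues, after excluding MHC anchor positions (which face the
# groove, not the receptor).

#' Relative binding of a substituted peptide
#'
#' Background-subtracted fraction of the wild-type signal, clipped below at
#' zero: `(signal_mut - background) / (signal_wt - background)`.
#'
#' @param signal_mut mutant signal (e.g. MFI)
#' @param signal_wt wild-type signal; must exceed background
#' @param signal_background background signal
#' @return numeric fraction >= 0
#' @export
#' @examples
#' relative_binding(100, 1000)       # 0.1
#' relative_binding(50, 1050, 50)    # 0
relative_binding <- function(signal_mut, signal_wt, signal_background = 0) {
  if (any(signal_wt <= signal_background))
    stop_scrapseek("wild-type signal must exceed background")
  pmax(0, (signal_mut - signal_background) / (signal_wt - signal_background))
}

#' Read an alanine-scan table
#'
#' TSV with columns `position`, `substitution`, `mean_signal`, `background`.
#' The wild-type reference travels as a row with position 0 and
#' substitution `"WT"`.
#'
#' @param path TSV path
#' @return `data.table`
#' @export
read_alanine_scan <- function(path) {
  tab <- read_tsv(path)
  need <- c("position", "substitution", "mean_signal", "background")
  if (!all(need %in% names(tab)))
    stop_scrapseek("alanine-scan table needs columns: ", paste(need, collapse = ", "))
  tab
}

#' Compute per-position relative binding from an alanine-scan table
#'
#' @param scan table as from [read_alanine_scan()], including the WT row
#' @return `data.table` with `position`, `substituted_residue`,
#'   `relative_binding` for the substituted positions (WT row consumed as
#'   the reference)
#' @export
alanine_scan_relative <- function(scan) {
  tab <- data.table::as.data.table(scan)
  wt <- tab[tab$position == 0 | tab$substitution == "WT"]
  if (nrow(wt) != 1) stop_scrapseek("exactly one wild-type row (position 0, substitution WT) required")
  mut <- tab[!(tab$position == 0 | tab$substitution == "WT")]
  data.table::data.table(
    position = as.integer(mut$position),
    substituted_residue = mut$substitution,
    relative_binding = relative_binding(mut$mean_signal, wt$mean_signal,
                                        mut$background))
}

#' Call receptor contact residues from an alanine scan
#'
#' Positions whose relative binding falls below `threshold` are called
#' contacts; anchor positions are excluded and the result is sorted
#' ascending. "Significant abrogation" is quantified as relative binding
#' below 0.5 by default (reported alongside the call).
#'
#' @param scan `data.table` with `position` and `relative_binding` (as from
#'   [alanine_scan_relative()])
#' @param threshold relative-binding cut-off below which a position is a
#'   contact
#' @param anchors anchor positions to exclude (P2 and the C-terminus for
#'   9-mers)
#' @return increasing integer vector of contact positions
#' @export
#' @examples
#' scan <- data.frame(position = c(1, 3:8),
#'                    relative_binding = c(0.9, 0.1, 0.8, 0.2, 0.05, 0.3, 0.25))
#' contact_residues(scan)  # 3 5 6 7 8
contact_residues <- function(scan, threshold = 0.5, anchors = c(2L, 9L)) {
  tab <- data.table::as.data.table(scan)
  if (anyDuplicated(tab$position))
    stop_scrapseek("duplicate positions in alanine scan")
  hits <- tab$position[tab$relative_binding < threshold]
  sort(as.integer(setdiff(hits, anchors)))
}
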