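# Amino-acid chemistry tables and peptide primitives.
#
# Every similarity decision downstream is a lookup into this table, so it is
# kept on disk as a plain TSV and loadable, letting users swap in alternative
# classification schemes without touching code.

CANONICAL_AA <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
                  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Monoisotopic residue masses (Da), standard values; water and proton
# constants used for peptide mass and m/z arithmetic.
MONO_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)
MASS_WATER <- 18.0105646863
MASS_PROTON <- 1.00727646688

#' Default amino-acid classification table
#'
#' Five chemical classes drive the positional similarity score: residues in
#' the same class but not identical score 2; identity scores 5; everything
#' else scores -2. The polarity flag marks residues outside the hydrophobic
#' set, and monoisotopic masses support MS1 m/z arithmetic.
#'
#' @return `data.table` with columns `residue`, `class`, `polar` (0/1),
#'   `monoisotopic_mass` (Da), one row per canonical residue.
#' @export
#' @examples
#' tab <- default_aa_table()
#' tab[residue %in% c("L", "I")]  # both aliphatic-nonpolar
default_aa_table <- function() {
  classes <- c(
    G = "aliphatic-nonpolar", A = "aliphatic-nonpolar", V = "aliphatic-nonpolar",
    L = "aliphatic-nonpolar", I = "aliphatic-nonpolar", P = "aliphatic-nonpolar",
    M = "aliphatic-nonpolar",
    F = "aromatic", W = "aromatic", Y = "aromatic",
    S = "polar-uncharged", T = "polar-uncharged", C = "polar-uncharged",
    N = "polar-uncharged", Q = "polar-uncharged",
    K = "positive", R = "positive", H = "positive",
    D = "negative", E = "negative"
  )
  nonpolar <- c("G", "A", "V", "L", "I", "P", "M", "F", "W")
  data.table::data.table(
    residue = CANONICAL_AA,
    class = unname(classes[CANONICAL_AA]),
    polar = as.integer(!CANONICAL_AA %in% nonpolar),
    monoisotopic_mass = unname(MONO_MASS[CANONICAL_AA])
  )
}

#' Read / write an amino-acid table
#'
#' On-disk representation is TSV with columns residue, class, polar(0/1),
#' monoisotopic_mass; [default_aa_table()] round-trips exactly.
#' @param path file path
#' @return `read_aa_table`: validated `data.table`; `write_aa_table`: `path`,
#'   invisibly.
#' @export
read_aa_table <- function(path) {
  tab <- read_tsv(path)
  validate_aa_table(tab)
  tab
}

#' @rdname read_aa_table
#' @param table amino-acid table as from [default_aa_table()]
#' @export
write_aa_table <- function(table, path) {
  validate_aa_table(table)
  write_tsv(table, path)
}

validate_aa_table <- function(table) {
  need <- c("residue", "class", "polar", "monoisotopic_mass")
  if (!all(need %in% names(table)))
    stop_scrapseek("amino-acid table must have columns: ", paste(need, collapse = ", "))
  if (!setequal(table$residue, CANONICAL_AA) || anyDuplicated(table$residue))
    stop_scrapseek("amino-acid table must cover each of the 20 canonical residues exactly once")
  if (any(table$monoisotopic_mass <= 0))
    stop_scrapseek("residue masses must be positive")
  if (!all(table$polar %in% c(0L, 1L)))
    stop_scrapseek("polar flag must be 0 or 1")
  invisible(TRUE)
}

#' Validate peptide sequences
#'
#' `validate_residues()` checks that sequences use only the 20 canonical
#' amino acids (B/J/O/U/X/Z and anything else rejected, naming the offending
#' character). `validate_peptide()` additionally enforces the MHC class I
#' length window of 8-14 residues.
#'
#' @param x character vector of peptide sequences
#' @return `x` invisibly; errors on invalid input.
#' @export
#' @examples
#' validate_peptide("QYNPIRTTF")
validate_residues <- function(x) {
  if (!is.character(x) || any(is.na(x)) || any(nchar(x) == 0))
    stop_scrapseek("peptides must be non-empty character strings")
  for (p in unique(x)) {
    res <- strsplit(p, "", fixed = TRUE)[[1]]
    bad <- setdiff(res, CANONICAL_AA)
    if (length(bad))
      stop_scrapseek("invalid residue '", bad[1], "' in peptide '", p, "'")
  }
  invisible(x)
}

#' @rdname validate_residues
#' @export
validate_peptide <- function(x) {
  validate_residues(x)
  n <- nchar(x)
  if (any(n < 8 | n > 14))
    stop_scrapseek("peptide length must be 8-14 residues (got ",
                   paste(unique(n[n < 8 | n > 14]), collapse = ", "), ")")
  invisible(x)
}

#' Positional similarity score for a residue pair
#'
#' The three-outcome rule at one peptide position: identical residues score
#' 5, different residues of the same chemical class score 2, and every other
#' pair scores -2. Symmetric and vectorized over pairs.
#'
#' @param a,b character vectors of single residues (recycled)
#' @param table amino-acid table, default [default_aa_table()]
#' @return integer vector of scores in \{5, 2, -2\}
#' @export
#' @examples
#' classify_pair("Q", "Q")  # 5
#' classify_pair("L", "I")  # 2: both aliphatic-nonpolar
#' classify_pair("R", "D")  # -2: positive vs negative
classify_pair <- function(a, b, table = default_aa_table()) {
  validate_residues(a); validate_residues(b)
  if (any(nchar(c(a, b)) != 1))
    stop_scrapseek("classify_pair expects single residues")
  cls <- stats::setNames(table$class, table$residue)
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  out <- ifelse(a == b, 5L, ifelse(cls[a] == cls[b], 2L, -2L))
  as.integer(out)
}

#' Scored (receptor-facing) positions of a class I peptide
#'
#' MHC anchor residues are buried in the binding groove and do not face the
#' receptor, so they are excluded from similarity scoring. Two conventions
#' are provided: `"text"` (default) scores position 1 plus positions 3
#' through length-1, masking the P2 and C-terminal anchors; `"equation"`
#' scores positions 3 through length (the literal index range of the
#' displayed score sum).
#'
#' @param length peptide length, 8-14
#' @param convention `"text"` or `"equation"`
#' @return increasing integer vector of 1-based positions
#' @export
#' @examples
#' scored_positions(9)              # 1 3 4 5 6 7 8
#' scored_positions(9, "equation")  # 3 4 5 6 7 8 9
scored_positions <- function(length, convention = c("text", "equation")) {
  convention <- match.arg(convention)
  if (!is.numeric(length) || length < 8 || length > 14)
    stop_scrapseek("peptide length must be 8-14 (got ", length, ")")
  length <- as.integer(length)
  if (convention == "text") c(1L, 3:(length - 1L)) else 3:length
}

#' Peptide monoisotopic mass and m/z
#'
#' `peptide_mass()` sums residue monoisotopic masses plus one water;
#' `peptide_mz()` returns `(mass + z * proton) / z`.
#'
#' @param peptide character vector of peptide sequences (any length >= 1;
#'   residues must be canonical)
#' @param table amino-acid table supplying `monoisotopic_mass`
#' @return numeric vector, Da (mass) or Th (m/z)
#' @export
#' @examples
#' peptide_mass("GG")            # 132.0535
#' peptide_mz("QYNPIRTTF", 2)    # 570.296
peptide_mass <- function(peptide, table = default_aa_table()) {
  validate_residues(peptide)
  masses <- stats::setNames(table$monoisotopic_mass, table$residue)
  vapply(peptide, function(p) {
    sum(masses[strsplit(p, "", fixed = TRUE)[[1]]]) + MASS_WATER
  }, numeric(1), USE.NAMES = FALSE)
}

#' @rdname peptide_mass
#' @param charge positive integer charge state(s)
#' @export
peptide_mz <- function(peptide, charge, table = default_aa_table()) {
  if (any(charge < 1) || any(charge != floor(charge)))
    stop_scrapseek("charge must be a positive integer")
  (peptide_mass(peptide, table) + charge * MASS_PROTON) / charge
}
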