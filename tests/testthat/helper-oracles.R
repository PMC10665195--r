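# Independent oracles used across tests. Deliberately written against the
# raw classification table with plain loops, not via the package's scoring
# path, so equivalence checks have teeth.

oracle_pair_matrix <- function(tab = default_aa_table()) {
  cls <- setNames(tab$class, tab$residue)
  m <- matrix(-2L, 20, 20, dimnames = list(tab$residue, tab$residue))
  for (a in tab$residue) for (b in tab$residue) {
    m[a, b] <- if (a == b) 5L else if (cls[a] == cls[b]) 2L else -2L
  }
  m
}

# naive double-loop reference for scrap_scan: per-candidate, per-position
# table lookups, base-R ordering with radix (C locale) tie-breaks
naive_scan <- function(query, index, mode = "printed", convention = "text",
                       e_max_floor = 0.01) {
  m <- oracle_pair_matrix()
  positions <- scored_positions(nchar(query), convention)
  n <- nrow(index)
  sum_p <- integer(n)
  for (i in seq_len(n)) {
    s <- 0L
    for (p in positions) {
      s <- s + m[substr(query, p, p), substr(index$peptide[i], p, p)]
    }
    sum_p[i] <- s
  }
  e <- pmax(index$E_max, e_max_floor)
  overall <- if (mode == "printed") sum_p / (index$b_nM * e)
             else sum_p * e / index$b_nM
  ord <- order(-overall, -sum_p, index$b_nM, index$peptide, method = "radix")
  data.frame(peptide = index$peptide[ord], sum_p = sum_p[ord],
             overall_score = overall[ord], rank = seq_len(n),
             stringsAsFactors = FALSE)
}

random_peptide <- function(n = 9L) {
  paste(sample(scrapseek:::CANONICAL_AA, n, replace = TRUE), collapse = "")
}

with_seed_peptide <- function(seed, n = 9L) {
  set.seed(seed + 1000L)
  random_peptide(n)
}

# a 9-mer differing from `query` by a different-class residue at every
# scored position (expected positional sum: -2 per scored position)
all_mismatch_peptide <- function(query, convention = "text") {
  tab <- default_aa_table()
  cls <- setNames(tab$class, tab$residue)
  res <- strsplit(query, "")[[1]]
  for (p in scored_positions(nchar(query), convention)) {
    pool <- tab$residue[cls[tab$residue] != cls[res[p]]]
    res[p] <- pool[1]
  }
  paste(res, collapse = "")
}
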