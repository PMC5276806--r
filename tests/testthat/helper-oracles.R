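# Independent oracles used by the unit tests.

# Brute-force natural mass-shift distribution of a set of atoms: enumerate
# every per-atom isotope assignment and sum probabilities by total shift.
# Exponential in atom count; only usable for tiny formulas.
bf_shift_dist <- function(counts, isotopes) {
  atoms <- list()
  for (el in names(counts))
    atoms <- c(atoms, rep(list(isotopes[[el]]), counts[[el]]))
  if (!length(atoms)) return(1)
  grid <- expand.grid(lapply(atoms, function(d) seq_along(d) - 1L))
  probs <- apply(grid, 1, function(row)
    prod(mapply(function(d, s) d[s + 1], atoms, row)))
  tot <- rowSums(grid)
  out <- numeric(max(tot) + 1)
  for (i in seq_along(tot)) out[tot[i] + 1] <- out[tot[i] + 1] + probs[i]
  out
}

# Brute-force correction-matrix column: j tracer carbons labeled, the rest
# of the molecule at natural abundance, truncated to the measured window.
bf_correction_column <- function(counts, n_tracer, j, isotopes) {
  counts["C"] <- counts[["C"]] - j
  d <- bf_shift_dist(counts, isotopes)
  col <- numeric(n_tracer + 1)
  shifts <- j + seq_along(d) - 1L
  keep <- shifts <= n_tracer
  col[shifts[keep] + 1L] <- d[keep]
  col
}

# pure-light isotope table (no natural enrichment), for identity checks
pure_isotopes <- list(C = 1, H = 1, N = 1, O = 1, P = 1, S = 1, Si = 1)

# random normalized MID over n+1 shifts
random_mid <- function(n, analyte = "x") {
  f <- runif(n + 1)
  mid(f / sum(f), analyte = analyte)
}
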