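# Mass isotopomer distributions and natural-abundance correction.
#
# A MID stores fractional abundances of the M+0..M+n mass shifts of one
# analyte fragment, indexed by integer mass shift (the mapping from raw m/z
# to shift is the reader's job). Natural-abundance correction removes the
# contribution of naturally occurring heavy isotopes (13C, 2H, 17O/18O, ...)
# so the corrected MID reflects tracer incorporation only.

# Natural isotope abundance by mass shift (index 1 = shift 0).
# 13C 0.0107; 2H 0.000115; 17O/18O 0.00038/0.00205.
.acetrace_isotopes <- list(
  C  = c(0.9893, 0.0107),
  H  = c(0.999885, 0.000115),
  N  = c(0.99636, 0.00364),
  O  = c(0.99757, 0.00038, 0.00205),
  P  = 1,
  S  = c(0.9499, 0.0075, 0.0425, 0, 0.0001),
  Si = c(0.92223, 0.04685, 0.03092)
)

#' Construct a mass isotopomer distribution
#'
#' @param fractions Numeric vector of abundances for mass shifts M+0..M+n.
#'   Need not be normalized on input.
#' @param analyte Analyte identifier (e.g. `"palmitate"`).
#' @param n_carbons Number of tracer carbons; the vector must have
#'   `n_carbons + 1` entries.
#' @param normalize Normalize fractions to sum to 1 (default `TRUE`).
#' @return An object of class `"mid"`: a list with elements `analyte`,
#'   `n_carbons` and `fractions` (named `M+0`..`M+n`).
#' @examples
#' mid(c(0.5, 0.25, 0.25), analyte = "acetate")
#' @export
mid <- function(fractions, analyte = "analyte",
                n_carbons = length(fractions) - 1L, normalize = TRUE) {
  fractions <- as.numeric(fractions)
  if (length(fractions) != n_carbons + 1L)
    stop("'fractions' must have n_carbons + 1 = ", n_carbons + 1L, " entries")
  if (any(!is.finite(fractions)) || any(fractions < -1e-12))
    stop("MID fractions must be finite and non-negative")
  fractions <- pmax(fractions, 0)
  s <- sum(fractions)
  if (s <= 0) stop("MID fractions sum to zero")
  if (normalize) fractions <- fractions / s
  names(fractions) <- paste0("M+", seq_along(fractions) - 1L)
  structure(list(analyte = analyte, n_carbons = as.integer(n_carbons),
                 fractions = fractions),
            class = "mid")
}

#' @export
print.mid <- function(x, digits = 4, ...) {
  cat("Mass isotopomer distribution:", x$analyte,
      sprintf("(%d tracer carbons)\n", x$n_carbons))
  print(round(x$fractions, digits))
  invisible(x)
}

#' Extract MID fractions as a plain vector
#' @param x A `"mid"` object.
#' @return Named numeric vector of fractional abundances.
#' @export
mid_fractions <- function(x) {
  stopifnot(inherits(x, "mid"))
  x$fractions
}

#' Parse an elemental formula string
#'
#' Converts `"C17H34O2"` to a named atom-count vector for use with
#' [correction_matrix()]. Only element symbols present in the built-in
#' isotope table (C, H, N, O, P, S, Si) are accepted.
#'
#' @param formula A formula string such as `"C17H34O2"`, or an already-named
#'   numeric vector (returned unchanged after validation).
#' @return Named numeric vector of atom counts.
#' @examples
#' parse_formula("C17H34O2")
#' @export
parse_formula <- function(formula) {
  if (is.numeric(formula)) {
    counts <- formula
  } else {
    stopifnot(is.character(formula), length(formula) == 1L)
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
    parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
    if (sum(nchar(parts)) != nchar(formula))
      stop("cannot parse formula: ", formula)
    el <- sub("[0-9]*$", "", parts)
    nn <- as.numeric(ifelse(sub("^[A-Za-z]+", "", parts) == "", "1",
                            sub("^[A-Za-z]+", "", parts)))
    counts <- tapply(nn, el, sum)
    counts <- setNames(as.numeric(counts), names(counts))
  }
  if (is.null(names(counts)) || any(names(counts) == ""))
    stop("formula atom counts must be named by element symbol")
  unknown <- setdiff(names(counts), names(.acetrace_isotopes))
  if (length(unknown))
    stop("unknown element(s): ", paste(unknown, collapse = ", "))
  if (any(counts < 0)) stop("negative atom counts")
  counts
}

# polynomial (open) convolution of two probability vectors
.conv <- function(a, b) {
  if (length(a) == 1L) return(a * b)
  if (length(b) == 1L) return(a * b)
  convolve(a, rev(b), type = "open")
}

# k-fold self-convolution of a per-atom shift distribution
.conv_pow <- function(d, k) {
  out <- 1
  while (k > 0) {
    out <- .conv(out, d)
    k <- k - 1
  }
  out
}

#' Natural-abundance correction matrix
#'
#' Builds the square matrix `M` whose column `j` (0-based) is the natural
#' mass-shift distribution of a fragment molecule carrying exactly `j`
#' tracer-labeled carbons: the remaining carbons and every non-carbon atom of
#' the measured ion contribute heavy isotopes at natural abundance by
#' per-atom convolution. Shifts beyond the measured window
#' `0..n_tracer_carbons` are truncated, so columns sum to at most 1 and the
#' matrix is lower triangular in mass shift. A raw measured MID then relates
#' to the tracer-only MID `x` by `raw = M x` (up to normalization).
#'
#' @param formula Elemental formula of the measured ion/derivative, as a
#'   string or named count vector (see [parse_formula()]); e.g. palmitate
#'   methyl ester `"C17H34O2"`.
#' @param n_tracer_carbons Number of carbons that can carry tracer label;
#'   must not exceed the formula's carbon count.
#' @param isotopes Isotope abundance table; override for testing or for
#'   enriched reagents.
#' @return `(n+1) x (n+1)` matrix of conditional isotopologue probabilities.
#' @examples
#' M <- correction_matrix("C2H3O2", 2)
#' colSums(M) # sub-probability columns
#' @export
correction_matrix <- function(formula, n_tracer_carbons,
                              isotopes = .acetrace_isotopes) {
  counts <- parse_formula(formula)
  n <- as.integer(n_tracer_carbons)
  if (n < 0) stop("n_tracer_carbons must be >= 0")
  nC <- if ("C" %in% names(counts)) counts[["C"]] else 0
  if (nC < n)
    stop("formula carbon count (", nC, ") < n_tracer_carbons (", n, ")")
  M <- matrix(0, n + 1L, n + 1L)
  for (j in 0:n) {
    # j tracer carbons are already 13C; nC - j carbons remain at natural
    # abundance, plus all non-carbon atoms.
    d <- .conv_pow(isotopes[["C"]], nC - j)
    for (el in setdiff(names(counts), "C")) {
      if (counts[[el]] > 0)
        d <- .conv(d, .conv_pow(isotopes[[el]], counts[[el]]))
    }
    shifts <- j + seq_along(d) - 1L   # absolute mass shift of each entry
    keep <- shifts <= n
    M[shifts[keep] + 1L, j + 1L] <- d[keep]
  }
  dimnames(M) <- list(paste0("M+", 0:n), paste0("x", 0:n))
  M
}

#' Correct a raw MID for natural isotope abundance
#'
#' Solves the linear system `raw = M x` for the tracer-only MID `x`, where
#' `M` is the [correction_matrix()] of the measured fragment. Small negative
#' solution entries (noise artifacts) are clipped to zero and the result
#' renormalized; when the clipped mass exceeds `clip_warn` a warning is
#' emitted so the artifact stays visible.
#'
#' @param raw A `"mid"` object holding the measured (normalized) MID.
#' @param formula Elemental formula of the measured ion (string or counts).
#' @param cond_max Maximum acceptable condition number of the correction
#'   matrix; above it the correction fails explicitly rather than returning
#'   amplified noise.
#' @param clip_warn Clipped-mass threshold for the warning (default 1e-3).
#' @param isotopes Isotope abundance table override.
#' @return The corrected, renormalized `"mid"`.
#' @examples
#' M <- correction_matrix("C2H3O2", 2)
#' raw <- mid(as.vector(M %*% c(0.2, 0.3, 0.5)))
#' na_correct(raw, "C2H3O2")
#' @export
na_correct <- function(raw, formula, cond_max = 1e8, clip_warn = 1e-3,
                       isotopes = .acetrace_isotopes) {
  stopifnot(inherits(raw, "mid"))
  M <- correction_matrix(formula, raw$n_carbons, isotopes = isotopes)
  k <- kappa(M, exact = TRUE)
  if (!is.finite(k) || k > cond_max)
    stop("correction matrix is ill-conditioned (condition number ",
         format(k, digits = 3), " > ", cond_max, ")")
  x <- solve(M, as.numeric(raw$fractions))
  clipped <- sum(pmax(-x, 0))
  if (clipped > clip_warn)
    warning(sprintf(
      "na_correct: clipped negative mass %.4g in '%s' after correction",
      clipped, raw$analyte))
  x <- pmax(x, 0)
  mid(x, analyte = raw$analyte, n_carbons = raw$n_carbons)
}

#' Fraction of analyte carrying any tracer label
#'
#' For a natural-abundance corrected MID, returns `1 - f(M+0)`, the fraction
#' of molecules with at least one labeled carbon. Invariant under
#' renormalization of the input.
#'
#' @param x A corrected, normalized `"mid"`.
#' @return Fraction in \[0, 1\].
#' @seealso [mean_enrichment()] for the carbon-weighted alternative.
#' @examples
#' fraction_labeled(mid(c(0.5, 0.25, 0.25))) # 0.5
#' @export
fraction_labeled <- function(x) {
  stopifnot(inherits(x, "mid"))
  f <- x$fractions / sum(x$fractions)
  unname(1 - f[1])
}

#' Carbon-weighted (mean) tracer enrichment of a MID
#'
#' Returns `sum(k * f_k) / n`, the average fraction of labeled carbons per
#' molecule — distinct from [fraction_labeled()], which counts molecules with
#' any label.
#'
#' @inheritParams fraction_labeled
#' @return Fraction in \[0, 1\].
#' @examples
#' mean_enrichment(mid(c(0.5, 0.25, 0.25))) # 0.375
#' @export
mean_enrichment <- function(x) {
  stopifnot(inherits(x, "mid"))
  f <- x$fractions / sum(x$fractions)
  k <- seq_along(f) - 1L
  sum(k * f) / x$n_carbons
}
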