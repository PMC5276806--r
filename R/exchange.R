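# Growth-normalized acetate exchange fluxes.
#
# Cells simultaneously take up and release acetate. The net exchange rate e
# (release-positive, mmol/hr/L cell volume) is the change in total medium
# acetate divided by the growth-integrated cell volume. The uptake (u) and
# release (r) components follow from the balance equations for total and
# 12C acetate:
#     e  = r - u
#     xe = a r - b u
# where x is the 12C concentration change relative to the total change, a is
# the average intracellular 12C-acetate fraction and b the average medium
# 12C fraction. a is not measurable (the intracellular free acetate pool is
# too small to quantify), so (r, u) are scanned over all biologically
# relevant a and reported as one-sided quantile bounds.

#' Construct a cell growth curve
#'
#' @param times Measurement times (hr), strictly increasing, at least two.
#' @param pcv_ul Packed cell volume per well (uL) at each time; positive.
#' @param medium_volume_ml Medium volume per well (mL).
#' @return Object of class `"growth_curve"`.
#' @examples
#' growth_curve(c(0, 24), c(3, 3), medium_volume_ml = 3)
#' @export
growth_curve <- function(times, pcv_ul, medium_volume_ml) {
  times <- as.numeric(times); pcv_ul <- as.numeric(pcv_ul)
  if (length(times) < 2L) stop("growth curve needs at least 2 points")
  if (length(times) != length(pcv_ul)) stop("times and pcv lengths differ")
  if (any(diff(times) <= 0)) stop("growth-curve times must be strictly increasing")
  if (any(pcv_ul <= 0)) stop("packed cell volume must be > 0")
  if (medium_volume_ml <= 0) stop("medium volume must be > 0")
  structure(list(times = times, pcv_ul = pcv_ul,
                 medium_volume_ml = medium_volume_ml),
            class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf("Growth curve: %d points over %.3g-%.3g hr, PCV %.3g-%.3g uL, medium %.3g mL\n",
              length(x$times), min(x$times), max(x$times),
              min(x$pcv_ul), max(x$pcv_ul), x$medium_volume_ml))
  invisible(x)
}

#' Growth-integrated cell volume per medium volume
#'
#' Trapezoidal integral of `pcv(t) / medium_volume` over `[t0, t1]`, in
#' L cell volume x hr per L medium. This is the normalization `T` that turns
#' medium concentration changes into per-cell-volume fluxes.
#'
#' @param g A [growth_curve()].
#' @param t0,t1 Integration limits (hr), within the curve's span; defaults
#'   to the full span.
#' @return Integrated cell volume (L cell x hr / L medium).
#' @examples
#' g <- growth_curve(c(0, 24), c(3, 3), 3)
#' integrated_cell_volume(g) # 0.024
#' @export
integrated_cell_volume <- function(g, t0 = min(g$times), t1 = max(g$times)) {
  stopifnot(inherits(g, "growth_curve"))
  if (t1 < t0) stop("t1 must be >= t0")
  if (t1 == t0) return(0)
  if (t0 < min(g$times) - 1e-9 || t1 > max(g$times) + 1e-9)
    stop("[t0, t1] outside the growth curve's span")
  tt <- sort(unique(c(t0, t1, g$times[g$times > t0 & g$times < t1])))
  pcv <- approx(g$times, g$pcv_ul, xout = tt)$y
  # uL * hr / mL = 1e-6 L * hr / 1e-3 L
  pracma::trapz(tt, pcv) / g$medium_volume_ml * 1e-3
}

#' Net acetate exchange flux
#'
#' `e = delta(c_total) / T`, the change in total medium acetate between the
#' first and last quantified time points divided by the growth-integrated
#' cell volume, converted to mmol/hr/L cell volume. Positive = net release,
#' negative = net uptake.
#'
#' @param conc Data frame with columns `time_hr` and `c_total` (uM); at
#'   least two quantified time points.
#' @param g A [growth_curve()] spanning the concentration time points.
#' @return Net exchange flux (mmol/hr/L cell volume).
#' @export
net_exchange <- function(conc, g) {
  stopifnot(is.data.frame(conc), all(c("time_hr", "c_total") %in% names(conc)))
  conc <- conc[is.finite(conc$c_total), , drop = FALSE]
  conc <- conc[order(conc$time_hr), , drop = FALSE]
  if (nrow(conc) < 2L) stop("need at least two quantified time points")
  t0 <- conc$time_hr[1]; t1 <- conc$time_hr[nrow(conc)]
  T_int <- integrated_cell_volume(g, t0, t1)
  if (T_int <= 0) stop("growth-integrated cell volume is zero")
  # uM = umol/L medium; /T gives umol/hr/L cell; *1e-3 -> mmol/hr/L cell
  (conc$c_total[nrow(conc)] - conc$c_total[1]) * 1e-3 / T_int
}

#' Deconvolve net exchange into release and uptake fluxes
#'
#' Solves the 2x2 balance system from measured concentration changes:
#' `r - u = dC_total/T` and `a r - b u = dC12/T`, giving
#' `r = (dC12 - b dC_total) / (T (a - b))` and `u = r - dC_total/T`.
#' Working from delta-quantities keeps the zero-net-exchange case
#' well-defined.
#'
#' @param d_total_um Change in total medium acetate (uM, release-positive).
#' @param d_c12_um Change in medium 12C-acetate (uM).
#' @param T_int Growth-integrated cell volume (L cell x hr / L medium).
#' @param a Average intracellular 12C-acetate fraction, in \[0, 1\].
#' @param b Average medium 12C-acetate fraction, in \[0, 1\].
#' @param tol Singularity tolerance on `|a - b|`.
#' @return Named vector `c(r = , u = )` (mmol/hr/L cell volume).
#' @examples
#' deconvolve_fluxes(0, 2e3 * 0.01, 0.01, a = 1, b = 0.5) # r = u = 4
#' @export
deconvolve_fluxes <- function(d_total_um, d_c12_um, T_int, a, b, tol = 1e-6) {
  if (any(c(a, b) < 0) || any(c(a, b) > 1))
    stop("a and b must be fractions in [0, 1]")
  if (abs(a - b) < tol)
    stop("singular system: |a - b| = ", format(abs(a - b)), " < ", tol)
  if (T_int <= 0) stop("T_int must be > 0")
  qt <- d_total_um * 1e-3 / T_int   # mmol/hr/L cell
  q12 <- d_c12_um * 1e-3 / T_int
  r <- (q12 - b * qt) / (a - b)
  c(r = r, u = r - qt)
}

# mean medium 12C fraction: endpoint mean (default) or Vcell-weighted
# time integral over the sampled series.
.medium_b <- function(conc, g = NULL, method = c("endpoint", "integral")) {
  method <- match.arg(method)
  frac <- conc$c12 / conc$c_total
  if (method == "endpoint") return(mean(frac[c(1, length(frac))]))
  w <- approx(g$times, g$pcv_ul, xout = conc$time_hr)$y
  pracma::trapz(conc$time_hr, frac * w) / pracma::trapz(conc$time_hr, w)
}

#' Estimate exchange fluxes with uncertainty over the intracellular fraction
#'
#' Computes the net exchange flux and deconvolves it into simultaneous
#' release and uptake, scanning the unidentifiable intracellular 12C
#' fraction `a` over a grid of biologically relevant values. Because
#' endogenous acetate production is unlabeled, the intracellular 12C
#' fraction cannot fall below the medium's, so the default grid is 101
#' uniform points on `[b, 1]`. Grid values yielding a negative release or
#' uptake are physically impossible and are excluded (not clipped) from the
#' retained range. With three or more replicate wells, a seeded
#' nonparametric bootstrap over wells propagates measurement error into the
#' quantiles; with a single series the quantiles reflect the a-scan only.
#'
#' The reported `r_q05` and `u_q05` are 5% quantiles, i.e. one-sided lower
#' bounds: with 95% confidence the true release (uptake) flux is at least
#' that high.
#'
#' @param conc Data frame with columns `time_hr`, `c12`, `c13` (uM) and
#'   optionally `well` for replicates; `c_total` is computed if absent.
#' @param g A [growth_curve()].
#' @param a_grid Grid of intracellular 12C fractions; default 101 uniform
#'   points on `[b, 1]`.
#' @param b_method `"endpoint"` (mean of endpoint medium fractions, default)
#'   or `"integral"` (cell-volume-weighted time average).
#' @param n_boot Bootstrap draws over wells (default 1000); used only when
#'   >= 3 wells are present.
#' @param seed Optional integer seed for the bootstrap.
#' @return Object of class `"exchange_fit"` with elements `e_median`,
#'   `e_ci95`, `r_q05`, `u_q05`, `a_retained`, `b`, `T_int`, `scan`
#'   (per-a table), `n_boot`, `seed`.
#' @export
estimate_exchange <- function(conc, g, a_grid = NULL,
                              b_method = c("endpoint", "integral"),
                              n_boot = 1000, seed = NULL) {
  b_method <- match.arg(b_method)
  stopifnot(is.data.frame(conc), all(c("time_hr", "c12", "c13") %in% names(conc)))
  if (!"c_total" %in% names(conc)) conc$c_total <- conc$c12 + conc$c13
  conc <- conc[is.finite(conc$c_total), , drop = FALSE]
  wells <- if ("well" %in% names(conc)) unique(conc$well) else "w1"
  if (!"well" %in% names(conc)) conc$well <- "w1"

  mean_series <- function(d) {
    agg <- stats::aggregate(d[c("c12", "c13", "c_total")],
                            by = list(time_hr = d$time_hr), FUN = mean)
    agg[order(agg$time_hr), , drop = FALSE]
  }
  base <- mean_series(conc)
  if (nrow(base) < 2L) stop("need at least two quantified time points")
  t0 <- base$time_hr[1]; t1 <- base$time_hr[nrow(base)]
  T_int <- integrated_cell_volume(g, t0, t1)
  b_hat <- .medium_b(base, g, b_method)
  if (is.null(a_grid)) a_grid <- seq(b_hat, 1, length.out = 101)
  if (any(a_grid < 0 | a_grid > 1)) stop("a_grid must lie in [0, 1]")

  one_draw <- function(d) {
    s <- mean_series(d)
    n <- nrow(s)
    dt <- s$c_total[n] - s$c_total[1]
    d12 <- s$c12[n] - s$c12[1]
    b <- .medium_b(s, g, b_method)
    e <- dt * 1e-3 / T_int
    ok_a <- abs(a_grid - b) >= 1e-6
    ru <- vapply(a_grid[ok_a], function(a)
      deconvolve_fluxes(dt, d12, T_int, a, b), numeric(2))
    list(e = e, a = a_grid[ok_a], r = ru[1, ], u = ru[2, ], b = b)
  }

  use_boot <- length(wells) >= 3 && n_boot > 0
  if (use_boot) {
    if (!is.null(seed)) set.seed(seed)
    draws <- lapply(seq_len(n_boot), function(i) {
      w <- sample(wells, replace = TRUE)
      one_draw(do.call(rbind, lapply(w, function(x)
        conc[conc$well == x, , drop = FALSE])))
    })
  } else {
    draws <- list(one_draw(conc))
  }
  point <- one_draw(conc)

  a_all <- unlist(lapply(draws, `[[`, "a"))
  r_all <- unlist(lapply(draws, `[[`, "r"))
  u_all <- unlist(lapply(draws, `[[`, "u"))
  e_all <- vapply(draws, `[[`, numeric(1), "e")
  # physical constraint r, u >= 0; tolerate floating error around zero
  flux_tol <- 1e-9 * max(1, abs(e_all), abs(u_all))
  keep <- r_all >= -flux_tol & u_all >= -flux_tol
  r_all <- pmax(r_all, 0); u_all <- pmax(u_all, 0)
  if (!any(keep)) {
    stop("no a-value on the grid yields non-negative release and uptake; ",
         "constraint violated: r in [", format(min(r_all), digits = 3), ", ",
         format(max(r_all), digits = 3), "], u in [",
         format(min(u_all), digits = 3), ", ",
         format(max(u_all), digits = 3), "]")
  }
  structure(list(
    e_median = unname(median(e_all)),
    e_ci95 = unname(quantile(e_all, c(0.025, 0.975))),
    r_q05 = unname(quantile(r_all[keep], 0.05)),
    u_q05 = unname(quantile(u_all[keep], 0.05)),
    a_retained = range(a_all[keep]),
    a_excluded = sort(unique(a_all[!keep])),
    b = point$b,
    T_int = T_int,
    scan = data.frame(a = point$a, r = point$r, u = point$u),
    n_boot = if (use_boot) n_boot else 0L,
    n_wells = length(wells),
    seed = seed,
    window_hr = c(t0, t1)
  ), class = "exchange_fit")
}

#' @export
print.exchange_fit <- function(x, ...) {
  cat("Acetate exchange flux estimate (mmol/hr/L cell volume, release-positive)\n")
  cat(sprintf("  window: %.3g-%.3g hr;  T = %.4g L cell*hr/L medium;  b = %.3f\n",
              x$window_hr[1], x$window_hr[2], x$T_int, x$b))
  cat(sprintf("  net exchange e: median %.4g  (95%% CI %.4g to %.4g)\n",
              x$e_median, x$e_ci95[1], x$e_ci95[2]))
  cat(sprintf("  release  r >= %.4g  (5%% quantile)\n", x$r_q05))
  cat(sprintf("  uptake   u >= %.4g  (5%% quantile)\n", x$u_q05))
  cat(sprintf("  intracellular 12C fraction retained: [%.3f, %.3f]  (%d wells, %d bootstrap draws)\n",
              x$a_retained[1], x$a_retained[2], x$n_wells, x$n_boot))
  invisible(x)
}

#' @export
summary.exchange_fit <- function(object, ...) {
  data.frame(e_median = object$e_median,
             e_ci_lo = object$e_ci95[1], e_ci_hi = object$e_ci95[2],
             r_q05 = object$r_q05, u_q05 = object$u_q05,
             a_lo = object$a_retained[1], a_hi = object$a_retained[2],
             n_boot = object$n_boot,
             seed = if (is.null(object$seed)) NA_integer_ else object$seed)
}

#' Ratio of 12C-acetate released to 13C-acetate consumed
#'
#' `delta(c12) / (-delta(c13))` over a medium time course: the accumulated
#' unlabeled acetate divided by the consumed labeled acetate. Cell-number
#' independent by construction; a high ratio indicates poor recapture of
#' endogenously produced acetate.
#'
#' @param conc Data frame with columns `time_hr`, `c12`, `c13` (uM).
#' @return Dimensionless ratio.
#' @export
release_uptake_ratio <- function(conc) {
  stopifnot(is.data.frame(conc), all(c("time_hr", "c12", "c13") %in% names(conc)))
  conc <- conc[order(conc$time_hr), , drop = FALSE]
  n <- nrow(conc)
  d12 <- conc$c12[n] - conc$c12[1]
  d13 <- conc$c13[n] - conc$c13[1]
  if (d13 >= 0)
    stop("no net 13C-acetate consumption; release/consumption ratio undefined")
  d12 / (-d13)
}
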