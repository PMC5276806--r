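# Seeded scenario simulator.
#
# Generates every input table the pipeline consumes, with the statistical
# structure the analysis assumes: exponential cell growth, medium acetate
# dynamics under constant per-cell-volume uptake/release fluxes, binomial
# palmitate labeling from a two-pool AcCoA precursor, first-order label
# incorporation over time, and multiplicative lognormal measurement noise.
# Condition presets encode the experimental design values (90 uM 13C
# acetate, ~15 uM residual unlabeled acetate, 3 mL medium per well, ...).

#' Scenario configuration for the simulator
#'
#' Build a scenario from a named preset and/or explicit overrides. Fluxes
#' are constant per unit cell volume; a linear substrate-limited taper below
#' `taper_um` prevents negative concentrations when labeled acetate is
#' nearly exhausted.
#'
#' @param preset Optional preset name; see [scenario_presets()].
#' @param ... Named overrides of any configuration field.
#' @return Object of class `"scenario"`: a named list with fields
#'   `doubling_time` (hr), `pcv0` (uL), `medium_volume` (mL), `u`, `r`
#'   (mmol/hr/L cell), `a` (intracellular 12C fraction), `c13_0`, `c12_0`
#'   (uM), `D_acetate`, `D_glucose`, `D_glutamine`, `g_turnover_k` (1/hr),
#'   `palmitate_pool` (mmol/L cell), `histone_fractions` (percent per
#'   tracer), `noise_cv`, `taper_um`, `n_wells`, internal-standard fields,
#'   `fame_formula`, and default sampling schedules.
#' @examples
#' scenario("BT474_lowserum", noise_cv = 0)
#' @export
scenario <- function(preset = NULL, ...) {
  cfg <- list(
    condition = "custom",
    doubling_time = 36, pcv0 = 0.33, medium_volume = 3,
    u = 3.5, r = 3.5, a = 0.95,
    c13_0 = 90, c12_0 = 15,
    D_acetate = 0.10, D_glucose = 0.50, D_glutamine = 0.15,
    g_turnover_k = 0.0625, palmitate_pool = 20,
    histone_fractions = c(glucose = 50, glutamine = 10, acetate = 8),
    noise_cv = 0.02, taper_um = 5, n_wells = 3,
    is_volume_ml = 0.040, is_conc_um = 1000, sample_volume_ml = 0.200,
    i64_base = 1e5, fame_formula = "C17H34O2",
    medium_times = seq(0, 48, by = 12),
    growth_times = seq(0, 48, by = 2),
    kfp_times = c(0, 6, 12, 24, 48)
  )
  if (!is.null(preset)) {
    presets <- scenario_presets()
    if (!preset %in% names(presets))
      stop("unknown preset '", preset, "'; see scenario_presets()")
    cfg[names(presets[[preset]])] <- presets[[preset]]
    cfg$condition <- preset
  }
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown scenario field(s): ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  with(cfg, {
    stopifnot(doubling_time > 0, pcv0 > 0, medium_volume > 0,
              u >= 0, r >= 0, a >= 0, a <= 1,
              c13_0 >= 0, c12_0 >= 0, noise_cv >= 0,
              D_acetate >= 0, D_acetate <= 1, g_turnover_k >= 0,
              palmitate_pool > 0)
  })
  structure(cfg, class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("Scenario '%s': doubling %g hr, PCV0 %g uL, medium %g mL\n",
              x$condition, x$doubling_time, x$pcv0, x$medium_volume))
  cat(sprintf("  fluxes: u = %g, r = %g (e = %g) mmol/hr/L cell;  a = %g\n",
              x$u, x$r, x$r - x$u, x$a))
  cat(sprintf("  acetate: %g uM 13C + %g uM 12C;  D_acetate = %g;  k = %g /hr;  P = %g\n",
              x$c13_0, x$c12_0, x$D_acetate, x$g_turnover_k, x$palmitate_pool))
  cat(sprintf("  noise CV = %g over %d wells\n", x$noise_cv, x$n_wells))
  invisible(x)
}

#' Condition presets anchored to the study design
#'
#' Each preset encodes a culture condition of the experiments the pipeline
#' reproduces: MDA-MB-468 normoxia (uptake and release both ~3.5 mmol/hr/L
#' cell), MDA-MB-468 hypoxia (lipogenic AcCoA enrichment from acetate 30%,
#' near-complete 13C-acetate consumption over 72 hr), BT-474 in low serum
#' (net uptake 8 mmol/hr/L cell), its ACSS1-silenced counterpart (uptake
#' scaled by 0.7), a hypoxia/low-serum lipogenic-demand condition
#' (acetyl demand 2.5x net uptake), free-fatty-acid supplementation (halved
#' palmitate synthesis), and histone-labeling panels (acetate contribution
#' 8% normoxic, 15% in hypoxia/low serum).
#'
#' @return Named list of preset field overrides consumed by [scenario()].
#' @export
scenario_presets <- function() {
  list(
    MDA468_normoxia = list(
      doubling_time = 30, pcv0 = 0.33, u = 3.5, r = 3.5, a = 0.95,
      D_acetate = 0.10, D_glucose = 0.50, D_glutamine = 0.15,
      histone_fractions = c(glucose = 50, glutamine = 10, acetate = 8),
      medium_times = seq(0, 24, by = 6), growth_times = seq(0, 24, by = 2)),
    MDA468_hypoxia = list(
      doubling_time = 48, pcv0 = 2.5, u = 3.5, r = 3.5, a = 0.95,
      D_acetate = 0.30, D_glucose = 0.25, D_glutamine = 0.30,
      g_turnover_k = 0.04,
      histone_fractions = c(glucose = 25, glutamine = 20, acetate = 15),
      medium_times = seq(0, 72, by = 12), growth_times = seq(0, 72, by = 2)),
    BT474_lowserum = list(
      doubling_time = 48, pcv0 = 0.33, u = 8.3, r = 0.3, a = 0.95,
      D_acetate = 0.30, D_glucose = 0.25, D_glutamine = 0.30),
    BT474_siACSS1 = list(
      doubling_time = 48, pcv0 = 0.33, u = 8.3 * 0.7, r = 0.3, a = 0.95,
      D_acetate = 0.30, D_glucose = 0.25, D_glutamine = 0.30),
    hypoxia_lowserum_demand = list(
      doubling_time = 48, pcv0 = 0.33, u = 4.5, r = 0.5, a = 0.95,
      D_acetate = 0.30, g_turnover_k = 0.0625, palmitate_pool = 20),
    FFA_supplement = list(
      doubling_time = 48, pcv0 = 0.33, u = 4.5, r = 0.5, a = 0.95,
      D_acetate = 0.30, g_turnover_k = 0.0625 / 2, palmitate_pool = 20),
    histone_normoxia = list(
      doubling_time = 30, pcv0 = 0.33, u = 3.5, r = 3.5, a = 0.95,
      D_acetate = 0.10,
      histone_fractions = c(glucose = 50, glutamine = 10, acetate = 8)),
    histone_hypoxia_lowserum = list(
      doubling_time = 48, pcv0 = 0.33, u = 3.5, r = 3.5, a = 0.95,
      D_acetate = 0.30,
      histone_fractions = c(glucose = 25, glutamine = 20, acetate = 15))
  )
}

# mean-one multiplicative lognormal noise
.lognoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

# intensities from concentrations by inverting the quantification model
.sim_intensities <- function(c12, c13, cfg, cv) {
  c_is <- effective_is_concentration(cfg$is_volume_ml, cfg$is_conc_um,
                                     cfg$sample_volume_ml)
  n <- length(c12)
  data.frame(
    mz61 = cfg$i64_base * (c12 / c_is) * .lognoise(n, cv),
    mz63 = cfg$i64_base * (c13 / c_is) * .lognoise(n, cv),
    mz64 = cfg$i64_base * .lognoise(n, cv))
}

#' Simulate the cell growth curve
#'
#' Exponential growth `pcv(t) = pcv0 * 2^(t / doubling_time)`.
#'
#' @param cfg A [scenario()].
#' @param times Sampling times (hr).
#' @return A [growth_curve()].
#' @export
simulate_growth <- function(cfg, times = cfg$growth_times) {
  stopifnot(inherits(cfg, "scenario"))
  growth_curve(times, cfg$pcv0 * 2^(times / cfg$doubling_time),
               cfg$medium_volume)
}

#' Simulate medium acetate dynamics and SIM intensities
#'
#' Forward-integrates the medium balance (fixed-step RK4, 0.1 hr):
#' `d c_total/dt = (r - u_eff) pcv(t) / V_med` and
#' `d c12/dt = (a r - b(t) u_eff) pcv(t) / V_med` with `b(t) = c12/c_total`
#' the instantaneous medium 12C fraction, and
#' `u_eff = u * min(1, c_total / taper_um)` the substrate-limited uptake.
#' SIM intensities per replicate well are generated by inverting the
#' internal-standard quantification model with multiplicative lognormal
#' noise.
#'
#' @param cfg A [scenario()].
#' @param times Sampling times (hr).
#' @param noise_cv Measurement noise CV; defaults to the scenario's.
#' @param n_wells Replicate wells; defaults to the scenario's.
#' @param seed Optional integer seed.
#' @return List with `concentrations` (noise-free truth: `sample_id`,
#'   `time_hr`, `c12`, `c13`, `c_total`) and `sim` (per-well intensity
#'   table: `well`, `sample_id`, `time_hr`, `mz61`, `mz63`, `mz64`).
#' @export
simulate_medium_acetate <- function(cfg, times = cfg$medium_times,
                                    noise_cv = cfg$noise_cv,
                                    n_wells = cfg$n_wells, seed = NULL) {
  stopifnot(inherits(cfg, "scenario"))
  times <- sort(unique(as.numeric(times)))
  if (min(times) < 0) stop("times must be >= 0")
  grid <- sort(unique(c(seq(0, max(times), by = 0.1), times)))
  deriv <- function(t, y, p) {
    pcv <- cfg$pcv0 * 2^(t / cfg$doubling_time)
    scale <- pcv / cfg$medium_volume         # uM/hr per (mmol/hr/L cell)
    ct <- max(y[1], 0)
    u_eff <- cfg$u * min(1, ct / cfg$taper_um)
    b <- if (ct > 1e-12) min(max(y[2], 0) / ct, 1) else 0
    list(c((cfg$r - u_eff) * scale,
           (cfg$a * cfg$r - b * u_eff) * scale))
  }
  sol <- deSolve::ode(y = c(ct = cfg$c13_0 + cfg$c12_0, c12 = cfg$c12_0),
                      times = grid, func = deriv, parms = NULL,
                      method = "rk4")
  at <- match(times, sol[, "time"])
  conc <- data.frame(
    sample_id = sprintf("t%g", times), time_hr = times,
    c12 = pmax(sol[at, "c12"], 0),
    c13 = pmax(sol[at, "ct"] - sol[at, "c12"], 0))
  conc$c_total <- conc$c12 + conc$c13
  if (!is.null(seed)) set.seed(seed)
  sim <- do.call(rbind, lapply(seq_len(n_wells), function(w) {
    cbind(well = sprintf("w%d", w),
          conc[c("sample_id", "time_hr")],
          .sim_intensities(conc$c12, conc$c13, cfg, noise_cv))
  }))
  rownames(sim) <- NULL
  list(concentrations = conc, sim = sim)
}

#' Simulate a palmitate MID labeling time course
#'
#' Per time point, `g(t) = 1 - exp(-g_turnover_k * t)` and the tracer MID is
#' the two-pool binomial model [forward_palmitate_mid()] with the scenario's
#' AcCoA enrichment; the raw (measured) MID is obtained by convolving with
#' the natural-abundance matrix of the fatty-acid methyl ester formula and
#' applying multiplicative intensity noise.
#'
#' @inheritParams simulate_medium_acetate
#' @param tracer Which tracer's enrichment to use (`"acetate"`, `"glucose"`
#'   or `"glutamine"`).
#' @return Long-format data frame: `sample_id`, `time_hr`, `analyte`,
#'   `mass_shift`, `intensity`.
#' @export
simulate_palmitate_mids <- function(cfg, times = cfg$kfp_times,
                                    noise_cv = cfg$noise_cv, seed = NULL,
                                    tracer = "acetate") {
  stopifnot(inherits(cfg, "scenario"))
  D <- switch(tracer, acetate = cfg$D_acetate, glucose = cfg$D_glucose,
              glutamine = cfg$D_glutamine,
              stop("unknown tracer: ", tracer))
  M <- correction_matrix(cfg$fame_formula, 16L)
  if (!is.null(seed)) set.seed(seed)
  do.call(rbind, lapply(sort(times), function(t) {
    g <- 1 - exp(-cfg$g_turnover_k * t)
    true <- forward_palmitate_mid(D, g)
    raw <- as.vector(M %*% true$fractions)
    raw <- raw / sum(raw)
    data.frame(sample_id = sprintf("t%g", t), time_hr = t,
               analyte = "palmitate", mass_shift = 0:16,
               intensity = 1e6 * raw * .lognoise(17, noise_cv))
  }))
}

#' Simulate histone hydrolysate SIM intensities
#'
#' The hydrolysate's `c13 / (c12 + c13)` equals the scenario's per-tracer
#' histone-bound acetate labeled fraction; intensities are generated by
#' inverting the internal-standard quantification with noise. A nominal
#' hydrolysate acetate concentration of 40 uM is used (only ratios matter).
#'
#' @inheritParams simulate_medium_acetate
#' @param tracers Tracers to simulate; default all in the scenario panel.
#' @param total_um Nominal hydrolysate acetate concentration (uM).
#' @return Data frame: `sample_id`, `sample_type`, `tracer`, `mz61`,
#'   `mz63`, `mz64`.
#' @export
simulate_histone_hydrolysate <- function(cfg,
                                         tracers = names(cfg$histone_fractions),
                                         noise_cv = cfg$noise_cv,
                                         seed = NULL, total_um = 40) {
  stopifnot(inherits(cfg, "scenario"))
  if (!is.null(seed)) set.seed(seed)
  f <- cfg$histone_fractions[tracers] / 100
  if (any(is.na(f))) stop("tracer(s) missing from histone_fractions")
  cbind(data.frame(sample_id = paste0("hist_", tracers),
                   sample_type = "histone_hydrolysate", tracer = tracers),
        .sim_intensities((1 - f) * total_um, f * total_um, cfg, noise_cv))
}

#' Simulate a complete scenario bundle
#'
#' Runs all simulator stages with sub-seeds derived from `seed` and, when
#' `out_dir` is given, writes the CSV bundle (`growth.csv`,
#' `medium_sim.csv`, `palmitate_mids.csv`, `histone_sim.csv`) together with
#' a `manifest.json` recording the configuration and the true parameter
#' values for recovery tests. Each CSV starts with a `#`-prefixed units
#' comment row.
#'
#' @param cfg A [scenario()] (or preset name, passed to [scenario()]).
#' @param seed Optional integer seed; fixed seed gives identical tables.
#' @param out_dir Optional output directory for the CSV bundle.
#' @return Invisibly, a list with `config`, `growth`, `medium`, `palmitate`,
#'   `histone` and `manifest`.
#' @export
simulate_scenario <- function(cfg, seed = NULL, out_dir = NULL) {
  if (is.character(cfg)) cfg <- scenario(cfg)
  stopifnot(inherits(cfg, "scenario"))
  sub <- function(k) if (is.null(seed)) NULL else (seed + k) %% .Machine$integer.max
  growth <- simulate_growth(cfg)
  medium <- simulate_medium_acetate(cfg, seed = sub(1))
  palm <- simulate_palmitate_mids(cfg, seed = sub(2))
  hist <- simulate_histone_hydrolysate(cfg, seed = sub(3))
  manifest <- list(
    condition = cfg$condition,
    config = unclass(cfg),
    truth = list(e = cfg$r - cfg$u, u = cfg$u, r = cfg$r, a = cfg$a,
                 D_acetate = cfg$D_acetate, k = cfg$g_turnover_k,
                 J_syn = cfg$g_turnover_k * cfg$palmitate_pool,
                 acetyl_demand = 8 * cfg$g_turnover_k * cfg$palmitate_pool),
    seed = seed,
    generator = paste0("acetrace ", as.character(packageVersion("acetrace"))),
    files = c("growth.csv", "medium_sim.csv", "palmitate_mids.csv",
              "histone_sim.csv"))
  out <- list(config = cfg,
              growth = data.frame(time_hr = growth$times,
                                  pcv_ul = growth$pcv_ul),
              growth_curve = growth,
              medium = medium, palmitate = palm, histone = hist,
              manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    .write_units_csv(out$growth, file.path(out_dir, "growth.csv"),
                     "# units: time_hr = hours, pcv_ul = uL packed cell volume per well")
    .write_units_csv(medium$sim, file.path(out_dir, "medium_sim.csv"),
                     "# units: time_hr = hours, mz61/mz63/mz64 = ion intensities (arbitrary)")
    .write_units_csv(palm, file.path(out_dir, "palmitate_mids.csv"),
                     "# units: time_hr = hours, mass_shift = integer, intensity = arbitrary")
    .write_units_csv(hist, file.path(out_dir, "histone_sim.csv"),
                     "# units: mz61/mz63/mz64 = ion intensities (arbitrary)")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out)
}
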