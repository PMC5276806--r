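# Table schemas, validation and the end-to-end pipeline.
#
# All tables are long-format UTF-8 CSV with '.' decimal; times in hours,
# concentrations in uM, fluxes in mmol/hr/L cell volume. Each file written
# by the package starts with a '#'-prefixed units comment row, which the
# readers skip.

.write_units_csv <- function(df, path, units_comment) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(units_comment, con)
  suppressWarnings(utils::write.table(df, con, sep = ",", row.names = FALSE,
                                      quote = FALSE))
}

#' Read a package CSV table
#'
#' Reads a long-format CSV written by the simulator or pipeline, skipping
#' `#` comment rows.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_table_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Assemble MIDs from a long-format intensity table
#'
#' Converts rows of (`sample_id`, `analyte`, `mass_shift`, `intensity`) into
#' a named list of [mid()] objects, one per sample.
#'
#' @param df Data frame in the shared MID table format.
#' @return Named list of `"mid"` objects (names = sample ids, ordered by
#'   `time_hr` when present).
#' @export
mids_from_table <- function(df) {
  stopifnot(all(c("sample_id", "analyte", "mass_shift", "intensity") %in% names(df)))
  ids <- unique(df$sample_id)
  if ("time_hr" %in% names(df)) {
    tt <- vapply(ids, function(i) df$time_hr[df$sample_id == i][1], numeric(1))
    ids <- ids[order(tt)]
  }
  out <- lapply(ids, function(i) {
    d <- df[df$sample_id == i, , drop = FALSE]
    d <- d[order(d$mass_shift), , drop = FALSE]
    if (!identical(as.integer(d$mass_shift), seq(0L, max(d$mass_shift))))
      stop("sample ", i, ": mass shifts must be complete 0..n")
    mid(d$intensity, analyte = d$analyte[1])
  })
  names(out) <- ids
  out
}

.issue <- function(file, row, message)
  data.frame(file = file, row = row, message = message,
             stringsAsFactors = FALSE)

#' Validate a simulated or measured data bundle
#'
#' Schema, unit and invariant checks over a bundle directory
#' (`growth.csv`, `medium_sim.csv`, `palmitate_mids.csv`,
#' `histone_sim.csv`, `manifest.json`): required columns, non-negative
#' intensities, strictly increasing growth times, monotone per-well
#' sampling times, complete mass-shift windows. Fails loudly with row-level
#' diagnostics.
#'
#' @param dir Bundle directory.
#' @return Data frame of issues (`file`, `row`, `message`); zero rows means
#'   the bundle validates. Attribute `ok` carries the logical result.
#' @export
validate_bundle <- function(dir) {
  issues <- list()
  need <- c("growth.csv", "medium_sim.csv", "palmitate_mids.csv",
            "histone_sim.csv", "manifest.json")
  for (f in need)
    if (!file.exists(file.path(dir, f)))
      issues <- c(issues, list(.issue(f, NA, "missing file")))
  chk_cols <- function(df, cols, f) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      list(.issue(f, NA, paste("missing column(s):",
                               paste(miss, collapse = ", "))))
    else list()
  }
  chk_nonneg <- function(df, cols, f) {
    out <- list()
    for (cl in intersect(cols, names(df))) {
      bad <- which(!is.finite(df[[cl]]) | df[[cl]] < 0)
      for (i in bad)
        out <- c(out, list(.issue(f, i, paste0("negative or non-finite ",
                                               cl, " = ", df[[cl]][i]))))
    }
    out
  }
  if (file.exists(file.path(dir, "growth.csv"))) {
    g <- read_table_csv(file.path(dir, "growth.csv"))
    issues <- c(issues, chk_cols(g, c("time_hr", "pcv_ul"), "growth.csv"))
    if (all(c("time_hr", "pcv_ul") %in% names(g))) {
      if (any(diff(g$time_hr) <= 0))
        issues <- c(issues, list(.issue("growth.csv", NA,
                                        "time_hr not strictly increasing")))
      if (any(g$pcv_ul <= 0))
        issues <- c(issues, list(.issue("growth.csv", NA, "pcv_ul <= 0")))
    }
  }
  if (file.exists(file.path(dir, "medium_sim.csv"))) {
    m <- read_table_csv(file.path(dir, "medium_sim.csv"))
    issues <- c(issues,
                chk_cols(m, c("well", "sample_id", "time_hr",
                              "mz61", "mz63", "mz64"), "medium_sim.csv"),
                chk_nonneg(m, c("mz61", "mz63", "mz64"), "medium_sim.csv"))
    if (all(c("well", "time_hr") %in% names(m))) {
      for (w in unique(m$well)) {
        tw <- m$time_hr[m$well == w]
        if (any(diff(tw) < 0))
          issues <- c(issues, list(.issue("medium_sim.csv", NA,
            paste0("well ", w, ": time_hr not monotone"))))
      }
    }
  }
  if (file.exists(file.path(dir, "palmitate_mids.csv"))) {
    p <- read_table_csv(file.path(dir, "palmitate_mids.csv"))
    issues <- c(issues,
                chk_cols(p, c("sample_id", "time_hr", "analyte",
                              "mass_shift", "intensity"),
                         "palmitate_mids.csv"),
                chk_nonneg(p, "intensity", "palmitate_mids.csv"))
  }
  if (file.exists(file.path(dir, "histone_sim.csv"))) {
    h <- read_table_csv(file.path(dir, "histone_sim.csv"))
    issues <- c(issues,
                chk_cols(h, c("sample_id", "sample_type", "tracer",
                              "mz61", "mz63", "mz64"), "histone_sim.csv"),
                chk_nonneg(h, c("mz61", "mz63", "mz64"), "histone_sim.csv"))
  }
  out <- if (length(issues)) do.call(rbind, issues) else
    .issue(character(0), integer(0), character(0))
  attr(out, "ok") <- nrow(out) == 0L
  out
}

.log_stage <- function(stage, t0)
  message(sprintf("[acetrace] %-10s %.2fs", stage,
                  as.numeric(proc.time()[3]) - t0))

#' Run the full acetate-tracing analysis on a data bundle
#'
#' Validates the bundle, quantifies medium acetate, estimates exchange
#' fluxes with uncertainty, fits the lipogenic AcCoA enrichment (steady
#' state and joint time course), performs kinetic flux profiling, computes
#' the histone-bound acetate panel and the lipogenic/histone contrast, the
#' 12C-released/13C-consumed ratio, and (under net uptake) the acetyl
#' demand to uptake ratio. Deterministic given `seed`. When ACSS2
#' expression covariates are present in the manifest, a plain Pearson
#' correlation of expression with the release/consumption ratio is appended
#' as a descriptive summary.
#'
#' @param dir Bundle directory (from [simulate_scenario()] or equivalent).
#' @param seed Optional integer seed for the exchange bootstrap.
#' @param n_boot Bootstrap draws for [estimate_exchange()] (default 200).
#' @param out_dir Optional directory to write result CSVs and a
#'   `summary.json`.
#' @return List with `flux`, `isa`, `kfp`, `histone`, `contrast` tables and
#'   a `summary` list; also carries the fitted objects in `fits`.
#' @export
run_pipeline <- function(dir, seed = NULL, n_boot = 200, out_dir = NULL) {
  t0 <- as.numeric(proc.time()[3])
  v <- validate_bundle(dir)
  if (!attr(v, "ok")) {
    stop("bundle validation failed (stage: validate):\n",
         paste(sprintf("  %s [row %s]: %s", v$file, v$row, v$message),
               collapse = "\n"))
  }
  .log_stage("validate", t0)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  cfg <- manifest$config
  condition <- if (!is.null(manifest$condition)) manifest$condition else "condition"
  c_is <- effective_is_concentration(cfg$is_volume_ml, cfg$is_conc_um,
                                     cfg$sample_volume_ml)

  g <- read_table_csv(file.path(dir, "growth.csv"))
  gc <- growth_curve(g$time_hr, g$pcv_ul, cfg$medium_volume)

  t1 <- as.numeric(proc.time()[3])
  med <- quantify_acetate(read_table_csv(file.path(dir, "medium_sim.csv")),
                          c_is)
  ex <- estimate_exchange(med, gc, n_boot = n_boot, seed = seed)
  mean_conc <- stats::aggregate(med[c("c12", "c13")],
                                by = list(time_hr = med$time_hr), FUN = mean)
  rur <- tryCatch(release_uptake_ratio(mean_conc), error = function(e) NA_real_)
  .log_stage("exchange", t1)

  t2 <- as.numeric(proc.time()[3])
  palm <- read_table_csv(file.path(dir, "palmitate_mids.csv"))
  raw_mids <- mids_from_table(palm)
  corrected <- lapply(raw_mids, na_correct, formula = cfg$fame_formula)
  times <- vapply(names(corrected),
                  function(i) palm$time_hr[palm$sample_id == i][1], numeric(1))
  series <- newly_synthesized_series(corrected, times)
  isa_last <- fit_isa(corrected[[length(corrected)]])
  kfp <- fit_kfp(series$times, series$g, pool_size = cfg$palmitate_pool)
  .log_stage("isa/kfp", t2)

  t3 <- as.numeric(proc.time()[3])
  hist_raw <- quantify_acetate(read_table_csv(file.path(dir, "histone_sim.csv")),
                               c_is)
  hist_pct <- setNames(histone_fraction_labeled(hist_raw), hist_raw$tracer)
  contrast <- compartment_contrast(hist_pct["acetate"],
                                   c(acetate = 100 * isa_last$D))
  dvu <- if (ex$e_median < 0) demand_vs_uptake(kfp, ex) else
    list(ratio = NA_real_, note = "net release condition; ratio undefined")
  .log_stage("histone", t3)

  summary_list <- list(
    condition = condition,
    net_exchange = ex$e_median,
    release_uptake_ratio = rur,
    D_acetate_percent = 100 * isa_last$D,
    J_syn = kfp$J_syn,
    acetyl_demand = kfp$acetyl_demand,
    demand_vs_uptake = dvu$ratio,
    histone_percent = as.list(hist_pct),
    seed = seed)
  if (!is.null(manifest$acss2_expression)) {
    expr <- manifest$acss2_expression
    if (is.list(expr) && !is.null(expr$expression) && !is.null(expr$ratio) &&
        length(expr$expression) >= 3) {
      ct <- cor.test(as.numeric(expr$expression), as.numeric(expr$ratio))
      summary_list$acss2_ratio_correlation <-
        list(pearson_r = unname(ct$estimate), p_value = ct$p.value)
    }
  }
  res <- list(
    flux = cbind(condition = condition, summary(ex)),
    isa = data.frame(sample_id = names(corrected)[length(corrected)],
                     tracer = "acetate", D_percent = 100 * isa_last$D,
                     g = isa_last$g, ssr = isa_last$ssr),
    kfp = data.frame(condition = condition, k_per_hr = kfp$k,
                     J_syn = kfp$J_syn, acetyl_demand = kfp$acetyl_demand,
                     rss = kfp$rss),
    histone = data.frame(condition = condition, tracer = names(hist_pct),
                         percent = unname(hist_pct),
                         other = 100 - sum(hist_pct), row.names = NULL),
    contrast = contrast,
    summary = summary_list,
    fits = list(exchange = ex, isa = isa_last, isa_series = series$fit,
                kfp = kfp))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    .write_units_csv(res$flux, file.path(out_dir, "flux.csv"),
                     "# units: fluxes in mmol/hr/L cell volume, release-positive")
    .write_units_csv(res$isa, file.path(out_dir, "isa.csv"),
                     "# units: D_percent = percent lipogenic AcCoA enrichment")
    .write_units_csv(res$kfp, file.path(out_dir, "kfp.csv"),
                     "# units: k_per_hr = 1/hr, J_syn and acetyl_demand in mmol/hr/L cell volume")
    .write_units_csv(res$histone, file.path(out_dir, "histone.csv"),
                     "# units: percent of histone-bound acetate labeled")
    jsonlite::write_json(summary_list, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  .log_stage("total", t0)
  res
}
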