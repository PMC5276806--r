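# Internal-standard quantification of derivatized acetate from selected-ion
# GC-MS intensities. The propyl-ester acetate fragment is monitored at
# m/z 61 (12C-acetate), 63 (U-13C-acetate) and 64 (2H3-acetate internal
# standard). With equal response factors for the three esters,
# concentration = intensity ratio to the internal standard times the
# effective standard concentration in the sample.

# M+2 natural abundance of the light two-carbon fragment (would shift
# m/z 61 signal onto 63). Below 0.1%, i.e. below measurement noise; set to
# a nonzero value and subtract I61 * .mz61_to_63_crosstalk from I63 to
# enable the correction.
.mz61_to_63_crosstalk <- 0

#' Effective internal-standard concentration in a spiked sample
#'
#' A volume of internal standard added to a sample dilutes into it; the
#' standard's amount, expressed as a concentration in the original sample
#' volume, is `is_volume * is_concentration / sample_volume`. With the
#' protocol's 40 uL of 1 mM 2H3-acetate added to 200 uL of medium this is
#' 200 uM.
#'
#' @param is_volume_ml Volume of internal standard added (mL).
#' @param is_conc_um Concentration of the internal standard stock (uM).
#' @param sample_volume_ml Sample volume the standard is referenced to (mL).
#' @return Effective internal-standard concentration (uM).
#' @examples
#' effective_is_concentration(0.040, 1000, 0.200) # 200
#' @export
effective_is_concentration <- function(is_volume_ml, is_conc_um,
                                       sample_volume_ml) {
  if (any(sample_volume_ml <= 0)) stop("sample volume must be > 0")
  if (any(is_volume_ml < 0) || any(is_conc_um < 0))
    stop("internal-standard volume and concentration must be >= 0")
  is_volume_ml * is_conc_um / sample_volume_ml
}

#' Quantify 12C- and 13C-acetate from SIM intensities
#'
#' Single-point internal-standard quantification:
#' `c12 = (I61/I64) * C_IS` and `c13 = (I63/I64) * C_IS`, assuming equal MS
#' response factors for the 12C, 13C and 2H3 acetate esters. Rows with a
#' non-positive internal-standard intensity are flagged unquantifiable
#' (`quantifiable = FALSE`, concentrations `NA`) rather than silently
#' zeroed.
#'
#' @param sim Data frame with columns `mz61`, `mz63`, `mz64` (non-negative
#'   ion intensities, arbitrary units); any other columns (`sample_id`,
#'   `time_hr`, `well`, ...) are passed through.
#' @param c_is_um Effective internal-standard concentration in the sample
#'   (uM), from [effective_is_concentration()].
#' @return The input data frame with added columns `c12`, `c13`, `c_total`
#'   (uM) and logical `quantifiable`.
#' @examples
#' sim <- data.frame(sample_id = "s1", mz61 = 0.075, mz63 = 0.45, mz64 = 1)
#' quantify_acetate(sim, effective_is_concentration(0.040, 1000, 0.200))
#' @export
quantify_acetate <- function(sim, c_is_um) {
  stopifnot(is.data.frame(sim),
            all(c("mz61", "mz63", "mz64") %in% names(sim)))
  if (length(c_is_um) != 1L || !is.finite(c_is_um) || c_is_um <= 0)
    stop("'c_is_um' must be a single positive number")
  if (any(sim$mz61 < 0 | sim$mz63 < 0 | sim$mz64 < 0, na.rm = TRUE))
    stop("negative ion intensities")
  out <- sim
  ok <- is.finite(sim$mz64) & sim$mz64 > 0
  if (any(!ok))
    warning(sum(!ok), " sample(s) with I64 <= 0 flagged unquantifiable")
  i63 <- sim$mz63 - .mz61_to_63_crosstalk * sim$mz61
  out$c12 <- ifelse(ok, sim$mz61 / sim$mz64 * c_is_um, NA_real_)
  out$c13 <- ifelse(ok, pmax(i63, 0) / sim$mz64 * c_is_um, NA_real_)
  out$c_total <- out$c12 + out$c13
  out$quantifiable <- ok
  out
}
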