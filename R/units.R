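# Internal unit system: geometry is stored in micron; all solver arithmetic
# happens in {cm, s, mmHg}; quantities are converted at module boundaries.
# Flows are reported in nl/min (vascular) or ul/min (transvascular),
# velocities in um/s, shear stresses in dyn/cm2, perfusion in ml/min/100g.

#' Unit conversion constants
#'
#' Named constants used to move between the storage units (micron for
#' geometry), the internal solver system (cm, s, mmHg) and reporting units
#' (nl/min, dyn/cm2, um/s, ml/min/100g).
#'
#' @format A named list with elements:
#' \describe{
#'   \item{um_to_cm}{1e-4}
#'   \item{cp_to_mmhg_s}{centipoise to mmHg s (1e-3 Pa s / 133.322387415 Pa)}
#'   \item{mmhg_to_dyn_cm2}{mmHg to dyn/cm2 (1333.22387415)}
#'   \item{cm3s_to_nl_min}{cm3/s to nl/min (6e7)}
#'   \item{cm3s_to_ul_min}{cm3/s to ul/min (6e4)}
#'   \item{cm_s_to_um_s}{cm/s to um/s (1e4)}
#' }
#' @export
tf_units <- list(
  um_to_cm        = 1e-4,
  cp_to_mmhg_s    = 1e-3 / 133.322387415,
  mmhg_to_dyn_cm2 = 1333.22387415,
  cm3s_to_nl_min  = 6e7,
  cm3s_to_ul_min  = 6e4,
  cm_s_to_um_s    = 1e4
)
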