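#' Unit conversion helpers
#'
#' Internal pressure unit is Pa, volumes are mm^3 on the mesh and mL at
#' reporting boundaries (1 mL = 1000 mm^3). The mmHg conversion is fixed at
#' 1 mmHg = 133.322 Pa.
#'
#' @param x numeric vector of pressures.
#' @return converted numeric vector.
#' @export
mmHg_to_Pa <- function(x) x * 133.322

#' @rdname mmHg_to_Pa
#' @export
Pa_to_mmHg <- function(x) x / 133.322

# mm^3 -> mL
mm3_to_mL <- function(x) x / 1000
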