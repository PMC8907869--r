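#' Unit conversions between clinical and SI haemodynamic units
#'
#' The package works in clinical units internally (pressure in mmHg, flow in
#' ml/s, volume in ml, resistance in mmHg/(ml/s), compliance in ml/mmHg,
#' inductance in mmHg/(ml/s^2)) and converts to SI at the boundary.
#' 1 mmHg = 133.322 Pa, 1 ml = 1e-6 m^3.
#'
#' @param x numeric value(s) to convert.
#' @return converted numeric value(s).
#' @name units
NULL

#' @rdname units
#' @export
MMHG_PER_PA <- 1 / 133.322

#' @rdname units
#' @export
PA_PER_MMHG <- 133.322

#' @rdname units
#' @export
mmhg_to_pa <- function(x) x * PA_PER_MMHG

#' @rdname units
#' @export
pa_to_mmhg <- function(x) x / PA_PER_MMHG

#' Convert resistance between SI (Pa s/m^3) and clinical (mmHg/(ml/s))
#' @rdname units
#' @export
resistance_si_to_clinical <- function(x) x * 1e-6 / PA_PER_MMHG

#' @rdname units
#' @export
resistance_clinical_to_si <- function(x) x * PA_PER_MMHG / 1e-6

#' Convert inductance between SI (Pa s^2/m^3) and clinical (mmHg/(ml/s^2))
#' @rdname units
#' @export
inductance_si_to_clinical <- function(x) x * 1e-6 / PA_PER_MMHG

#' @rdname units
#' @export
inductance_clinical_to_si <- function(x) x * PA_PER_MMHG / 1e-6

#' Convert compliance between SI (m^3/Pa) and clinical (ml/mmHg)
#' @rdname units
#' @export
compliance_si_to_clinical <- function(x) x * 1e6 * PA_PER_MMHG

#' @rdname units
#' @export
compliance_clinical_to_si <- function(x) x / (1e6 * PA_PER_MMHG)

#' Convert distensibility between 1/Pa and 1/mmHg
#' @rdname units
#' @export
distensibility_pa_to_mmhg <- function(x) x * PA_PER_MMHG

#' @rdname units
#' @export
distensibility_mmhg_to_pa <- function(x) x / PA_PER_MMHG
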