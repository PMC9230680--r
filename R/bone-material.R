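# CT gray value -> apparent density -> elastic modulus mapping.
#
# Compact and cancellous bone follow different density-modulus power laws;
# the Poisson ratio is 0.3 for both. Density is mapped linearly from the CT
# gray value (HU) as rho = rho_max * HU / HU_max.

POISSON_BONE <- 0.3

#' CT gray value to apparent density
#'
#' Linear map `rho = rho_max * HU / HU_max`. The scaling constants are
#' scanner-calibration inputs; the defaults (`HU_max = 2000`,
#' `rho_max = 2 g/cm^3`) are common conventions, not measured values.
#' Gray values outside `[0, HU_max]` are rejected rather than clamped: the
#' linear law is only stated as a positive proportionality.
#'
#' @param HU gray value(s), dimensionless, in `[0, HU_max]`.
#' @param HU_max gray value mapped to `rho_max` (> 0).
#' @param rho_max maximum apparent density, g/cm^3 (> 0).
#' @return apparent density, g/cm^3.
#' @examples
#' hu_to_density(1000)           # 1 g/cm^3 at the default calibration
#' @export
hu_to_density <- function(HU, HU_max = 2000, rho_max = 2.0) {
  if (!is.finite(HU_max) || HU_max <= 0) stop("'HU_max' must be > 0")
  if (!is.finite(rho_max) || rho_max <= 0) stop("'rho_max' must be > 0")
  if (any(!is.finite(HU)) || any(HU < 0 | HU > HU_max))
    stop("'HU' must lie in [0, HU_max] = [0, ", HU_max, "]")
  rho_max * HU / HU_max
}

#' Apparent density to elastic modulus
#'
#' Power-law density-modulus relations for the two bone classes:
#' compact bone `E = 2065 * rho^3.09` MPa, cancellous bone
#' `E = 1904 * rho^1.64` MPa (`rho` in g/cm^3). The two laws cross near
#' `rho = 0.95 g/cm^3`; below it the cancellous law predicts the stiffer
#' tissue, above it the compact law does.
#'
#' @param rho apparent density, g/cm^3 (>= 0, vectorised).
#' @param bone_class `"compact"` or `"cancellous"`.
#' @return elastic modulus, MPa.
#' @examples
#' bone_modulus(1, "compact")     # 2065
#' bone_modulus(1, "cancellous")  # 1904
#' @export
bone_modulus <- function(rho, bone_class = c("compact", "cancellous")) {
  bone_class <- match.arg(bone_class)
  if (any(!is.finite(rho)) || any(rho < 0))
    stop("'rho' must be nonnegative and finite")
  switch(bone_class,
         compact    = 2065 * rho^3.09,
         cancellous = 1904 * rho^1.64)
}

#' Material table for a set of CT gray values
#'
#' Vectorised composition of [hu_to_density()] and [bone_modulus()]; one row
#' per gray value, with the Poisson ratio fixed at 0.3.
#'
#' @inheritParams hu_to_density
#' @inheritParams bone_modulus
#' @return a data frame with columns `HU`, `rho` (g/cm^3), `E` (MPa),
#'   `poisson`, `bone_class`.
#' @examples
#' material_table(c(0, 500, 1000, 2000), bone_class = "compact")
#' @export
material_table <- function(HU, HU_max = 2000, rho_max = 2.0,
                           bone_class = c("compact", "cancellous")) {
  bone_class <- match.arg(bone_class)
  if (length(HU) == 0)
    return(data.frame(HU = numeric(), rho = numeric(), E = numeric(),
                      poisson = numeric(), bone_class = character()))
  rho <- hu_to_density(HU, HU_max, rho_max)
  data.frame(HU = HU, rho = rho,
             E = bone_modulus(rho, bone_class),
             poisson = POISSON_BONE, bone_class = bone_class)
}
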