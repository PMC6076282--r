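# Allometric conversions: harvester lata counts to seed kilograms, and DBH
# to above-ground biomass via the diameter-only pantropical model.

#' Allometry parameters
#'
#' @param wood_density Species wood density in g cm^-3 (default 0.59, the
#'   accepted value for Bertholletia excelsa).
#' @param env_stress_E Dimensionless environmental stress term `E` of the
#'   pantropical diameter-only AGB model; 0 by default and configurable
#'   because tree inventories rarely include heights and `E` varies by
#'   site.
#' @param lata_kg Kilograms of fresh in-shell seed per lata (harvesters'
#'   tin-can unit); approximately 11.66 kg.
#' @param coef Numeric length-5 coefficient vector `(a, b, c, d, e)` of
#'   `ln(AGB) = a + b*E + c*ln(rho) + d*ln(D) + e*ln(D)^2`; replaceable so
#'   the statistics never depend on one specific allometric equation.
#' @return An object of class `allometry_params`.
#' @examples
#' allometry_params()
#' @export
allometry_params <- function(wood_density = 0.59, env_stress_E = 0,
                             lata_kg = 11.66,
                             coef = c(-1.803, -0.976, 0.976, 2.673, -0.0299)) {
  check_number(wood_density, "wood_density", 0, strict = TRUE)
  check_number(env_stress_E, "env_stress_E")
  check_number(lata_kg, "lata_kg", 0, strict = TRUE)
  if (!is.numeric(coef) || length(coef) != 5L) {
    stop_ddd("`coef` must be a numeric vector of length 5")
  }
  structure(
    list(wood_density = wood_density, env_stress_E = env_stress_E,
         lata_kg = lata_kg, coef = coef),
    class = "allometry_params"
  )
}

#' @export
print.allometry_params <- function(x, ...) {
  cat(sprintf(
    "Allometry: wood density %.2f g/cm3, E = %g, lata = %.2f kg\n",
    x$wood_density, x$env_stress_E, x$lata_kg
  ))
  invisible(x)
}

#' Convert lata counts to seed kilograms
#'
#' Harvesters express per-tree seed production in latas (tin cans) of fresh
#' in-shell seed; one lata holds approximately 11.66 kg.
#'
#' @param latas Numeric vector of lata counts, >= 0.
#' @param params [allometry_params()].
#' @return Seed production in kg.
#' @examples
#' latas_to_kg(1)    # 11.66
#' latas_to_kg(10)   # 116.6
#' @export
latas_to_kg <- function(latas, params = allometry_params()) {
  if (!is.numeric(latas) || any(is.na(latas)) || any(latas < 0)) {
    stop_ddd("`latas` must be non-negative numbers")
  }
  latas * params$lata_kg
}

#' Above-ground biomass from DBH
#'
#' Diameter-only pantropical allometric model:
#' `ln(AGB) = -1.803 - 0.976 E + 0.976 ln(rho) + 2.673 ln(D) - 0.0299 ln(D)^2`
#' with `D` the diameter at breast height in cm, `rho` the wood density in
#' g cm^-3 and `E` an environmental stress surrogate.  Output in kg.  The
#' model is strictly increasing in `D` over the inventory range.
#'
#' @param dbh_cm DBH in cm, >= 10 (the inventory threshold).
#' @param params [allometry_params()].
#' @return AGB in kg.
#' @examples
#' agb_from_dbh(100)  # about 11.6 tonnes at rho = 0.59, E = 0
#' @export
agb_from_dbh <- function(dbh_cm, params = allometry_params()) {
  if (!is.numeric(dbh_cm) || any(is.na(dbh_cm))) {
    stop_ddd("`dbh_cm` must be numeric without missing values")
  }
  if (any(dbh_cm < 10)) {
    stop_ddd("DBH below the 10 cm inventory threshold")
  }
  k <- params$coef
  lnD <- log(dbh_cm)
  exp(k[1L] + k[2L] * params$env_stress_E + k[3L] * log(params$wood_density) +
        k[4L] * lnD + k[5L] * lnD^2)
}
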