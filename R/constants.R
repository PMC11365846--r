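# Default tables: WHO standards, published integrated weights, equivalent
# weights, toxicity constants, exposure profiles, generator targets.
# All units mg/L unless stated (EC in uS/cm, pH unitless).

#' Ion names understood by the hydrochemical routines
#' @keywords internal
ION_NAMES <- c("Ca", "Mg", "Na", "K", "Cl", "SO4", "HCO3", "CO3", "NO3")

#' Cations and anions among [ION_NAMES]
#' @keywords internal
CATIONS <- c("Ca", "Mg", "Na", "K")
#' @rdname CATIONS
#' @keywords internal
ANIONS <- c("Cl", "SO4", "HCO3", "CO3", "NO3")

#' Potentially toxic elements carried by the package
#' @keywords internal
PTE_NAMES <- c("Fe", "Mn", "Cu", "Zn")

# Equivalent weights in g/eq (molar mass / charge), pinned so meq arithmetic
# is reproducible across platforms.
EQUIVALENT_WEIGHTS <- c(
  Ca = 20.04, Mg = 12.15, Na = 22.99, K = 39.10,
  Cl = 35.45, SO4 = 48.03, HCO3 = 61.02, CO3 = 30.00, NO3 = 62.00
)

# The 14 parameters entering the drinking water quality index by default.
WQI_PARAMETERS <- c(
  "TDS", "pH", "EC", "Na", "K", "Mg", "Ca", "Mn", "Fe",
  "Cl", "SO4", "HCO3", "NO3", "TH"
)

#' Default WHO-based standards table for the water quality index
#'
#' One row per evaluated parameter with the WHO guideline value `sj`
#' (mg/L, uS/cm for EC, unitless for pH), the ideal pure-water value `cjp`
#' (0 everywhere except pH where it is 7), and the published integrated
#' weight `wj` that the index assigns to the parameter.
#'
#' @return data.frame with columns `parameter`, `sj`, `cjp`, `wj`.
#' @export
#' @examples
#' std <- default_standards()
#' sum(std$wj)  # weights sum to 1
default_standards <- function() {
  data.frame(
    parameter = WQI_PARAMETERS,
    sj = c(1000, 7.5, 1500, 400, 12, 150, 200, 0.1, 0.3, 600, 400, 200, 45, 500),
    cjp = c(0, 7, rep(0, 12)),
    wj = c(0.042538, 0.085516, 0.038892, 0.038133, 0.090798, 0.04749,
           0.045792, 0.118172, 0.154696, 0.048279, 0.056017, 0.100238,
           0.059186, 0.074253),
    stringsAsFactors = FALSE
  )
}

#' Default toxicity table for Fe, Mn, Cu and Zn
#'
#' Constants used by the pollution indices and the exposure chain:
#' `si` is the drinking standard used by the heavy-metal pollution index,
#' `tr` the Hakanson toxic-response factor, `rfd_oral`/`rfd_dermal` the
#' USEPA reference doses (mg/kg/day, dermal = oral x `abs_gi`), `kp` the
#' dermal permeability coefficient (cm/h), and `c_bg` the site background
#' concentration. Backgrounds ship as `NA`: they are site-specific and must
#' be supplied by the user (see [load_config()]).
#'
#' @return data.frame keyed by `metal`.
#' @export
default_toxicity <- function() {
  tox <- data.frame(
    metal = c("Fe", "Mn", "Cu", "Zn"),
    si = c(0.3, 0.1, 2, 3),
    tr = c(1, 1, 5, 1),
    rfd_oral = c(0.7, 0.024, 0.04, 0.3),
    abs_gi = c(0.2, 0.04, 0.3, 0.2),
    kp = c(0.001, 0.001, 0.001, 6e-4),
    c_bg = rep(NA_real_, 4),
    stringsAsFactors = FALSE
  )
  tox$rfd_dermal <- rfd_dermal(tox$rfd_oral, tox$abs_gi)
  tox
}

#' Default exposure profiles for the adult and child cohorts
#'
#' Ingestion rate `ir` (L/day), exposure duration `ed` (years), exposure
#' frequency `ef` (days/year), exposure time `et` (h/day), skin surface area
#' `sa` (cm2), unit conversion factor `cf` (L/cm3), body weight `bw` (kg)
#' and averaging time `at` (days). The non-carcinogenic convention
#' `at = ed * 365` is applied.
#'
#' @param cohort `"adult"`, `"child"`, or both (default).
#' @return data.frame with one row per cohort.
#' @export
default_exposure <- function(cohort = c("adult", "child")) {
  cohort <- match.arg(cohort, several.ok = TRUE)
  prof <- data.frame(
    cohort = c("adult", "child"),
    ir = c(2.2, 1.8),
    ed = c(70, 6),
    ef = c(350, 350),
    et = c(0.58, 1),
    sa = c(18000, 6600),
    cf = c(1e-3, 1e-3),
    bw = c(70, 15),
    stringsAsFactors = FALSE
  )
  prof$at <- prof$ed * 365
  prof[prof$cohort %in% cohort, , drop = FALSE]
}

#' Published per-parameter summary statistics used as generator targets
#'
#' Min/max/mean/SD of the 16 measured attributes of the 69-well cohort the
#' synthetic generator emulates. Two source-table readings are ambiguous and
#' were resolved as the only internally consistent option (EC) or in favour
#' of the body text (Ca maximum); both are plain columns here and can be
#' overridden through the generator config.
#'
#' @return data.frame with columns `parameter`, `min`, `max`, `mean`, `sd`,
#'   `family` (sampling family used by the generator).
#' @export
cohort_targets <- function() {
  t <- data.frame(
    parameter = c("pH", "EC", "TDS", "TH", "Cl", "SO4", "Cu", "Fe",
                  "HCO3", "NO3", "Ca", "Mg", "Na", "K", "Mn", "Zn"),
    min = c(6.5, 296, 225, 50, 13, 0.05, 0.002, 2e-4,
            65, 0.001, 2, 8.06, 14, 1, 0.002, 0.003),
    max = c(8.39, 8504, 4930, 2288, 2799, 985, 0.16, 0.62,
            851, 158, 667, 133, 1600, 74, 1.71, 0.88),
    mean = c(7.71, 1755, 982, 345, 258, 141, 0.049, 0.152,
             387.5, 7.3, 98, 35, 209, 15, 0.422, 0.081),
    sd = c(0.3, 1458.4, 800.7, 397.2, 432.3, 156.9, 0.038, 0.160,
           183.6, 19.4, 101.5, 21.1, 220.3, 16.1, 0.421, 0.113),
    stringsAsFactors = FALSE
  )
  t$family <- ifelse(t$parameter == "pH", "truncnorm", "trunclnorm")
  t
}

# Parameters drawn jointly through the Gaussian copula (salinity block):
# the ions/bulk measures that co-load on the first principal component of
# the source cohort. HCO3 and NO3 stay independent (anthropogenic, spatially
# random); so do the trace metals.
SALINITY_BLOCK <- c("TDS", "EC", "TH", "Ca", "Mg", "Na", "K", "Cl", "SO4")
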