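# Deterministic USEPA non-carcinogenic exposure chain: chronic daily
# intake (oral ingestion and dermal absorption), hazard quotients against
# the route-specific reference dose, and hazard indices, for adult and
# child cohorts.

#' Chronic daily intake, oral route
#'
#' `CDI_oral = C * EF * IR * ED / (AT * BW)` in mg/kg/day, with the water
#' concentration `C` in mg/L and the exposure profile fields in their
#' stated units (see [default_exposure()]).
#'
#' @param c_mgl concentration(s) in mg/L (>= 0).
#' @param profile one-row exposure profile data.frame.
#' @return CDI in mg/kg/day.
#' @export
cdi_oral <- function(c_mgl, profile) {
  if (any(c_mgl < 0)) stop("negative concentration", call. = FALSE)
  c_mgl * profile$ef * profile$ir * profile$ed / (profile$at * profile$bw)
}

#' Chronic daily intake, dermal route
#'
#' `CDI_dermal = C * ET * EF * Kp * SA * CF * ED / (BW * AT)` in mg/kg/day;
#' `Kp` is the metal's dermal permeability coefficient in cm/h.
#'
#' @param c_mgl concentration(s) in mg/L (>= 0).
#' @param profile one-row exposure profile data.frame.
#' @param kp permeability coefficient (cm/h, > 0).
#' @return CDI in mg/kg/day.
#' @export
cdi_dermal <- function(c_mgl, profile, kp) {
  if (any(c_mgl < 0)) stop("negative concentration", call. = FALSE)
  if (is.na(kp) || kp <= 0) stop("missing or non-positive Kp", call. = FALSE)
  c_mgl * profile$et * profile$ef * kp * profile$sa * profile$cf *
    profile$ed / (profile$bw * profile$at)
}

#' Hazard quotient
#' @param cdi chronic daily intake (mg/kg/day).
#' @param rfd route-matched reference dose (mg/kg/day, > 0).
#' @return `cdi / rfd` (dimensionless; > 1 flags potential risk).
#' @export
hazard_quotient <- function(cdi, rfd) {
  if (any(!is.finite(rfd)) || any(rfd <= 0)) {
    stop("reference dose must be positive", call. = FALSE)
  }
  cdi / rfd
}

#' Dermal reference dose from the oral dose
#' @param rfd_oral oral reference dose (mg/kg/day).
#' @param abs_gi gastrointestinal absorption fraction in (0, 1].
#' @return `rfd_oral * abs_gi`.
#' @export
rfd_dermal <- function(rfd_oral, abs_gi) {
  if (any(abs_gi <= 0 | abs_gi > 1)) {
    stop("ABS fraction must be in (0, 1]", call. = FALSE)
  }
  rfd_oral * abs_gi
}

#' Hazard index
#'
#' Sums hazard quotients. Used in two ways: per route over metals (the
#' cohort-level `HI_oral` / `HI_dermal`) and per metal over routes
#' (`HQ_oral + HQ_dermal`).
#'
#' @param hq named numeric vector of hazard quotients (non-empty).
#' @return their sum.
#' @export
hazard_index <- function(hq) {
  if (!length(hq)) stop("empty hazard-quotient set", call. = FALSE)
  sum(hq)
}

#' Deterministic risk assessment of a cohort of samples
#'
#' Applies the CDI -> HQ chain to every sample, metal, route and exposure
#' cohort, and derives the per-sample hazard indices.
#'
#' @param tbl sample table.
#' @param toxicity toxicity table ([default_toxicity()]).
#' @param exposure exposure profiles ([default_exposure()]).
#' @param metals metals to assess.
#' @return list with `by_metal` (sample x metal x cohort rows: CDIs, HQs,
#'   per-metal oral+dermal HI, risk flags) and `by_sample` (route-wise HI
#'   per sample and cohort with flags).
#' @export
assess_health_risk <- function(tbl, toxicity = default_toxicity(),
                               exposure = default_exposure(),
                               metals = intersect(toxicity$metal, names(tbl))) {
  idx <- match(metals, toxicity$metal)
  if (any(is.na(idx))) stop("no toxicity entry for: ",
                            paste(metals[is.na(idx)], collapse = ", "),
                            call. = FALSE)
  rows <- list()
  for (k in seq_len(nrow(exposure))) {
    prof <- exposure[k, ]
    for (j in seq_along(metals)) {
      m <- metals[j]; t <- idx[j]
      conc <- tbl[[m]]
      co <- cdi_oral(conc, prof)
      cd <- cdi_dermal(conc, prof, toxicity$kp[t])
      hqo <- hazard_quotient(co, toxicity$rfd_oral[t])
      hqd <- hazard_quotient(cd, toxicity$rfd_dermal[t])
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = tbl$sample_id, cohort = prof$cohort, metal = m,
        concentration = conc,
        cdi_oral = co, cdi_dermal = cd,
        hq_oral = hqo, hq_dermal = hqd,
        hi_metal = hqo + hqd,
        flag_oral = hqo > 1, flag_dermal = hqd > 1,
        stringsAsFactors = FALSE
      )
    }
  }
  by_metal <- do.call(rbind, rows)
  agg <- stats::aggregate(cbind(hi_oral = hq_oral, hi_dermal = hq_dermal)
                          ~ sample_id + cohort, data = by_metal, FUN = sum)
  agg$flag_oral <- agg$hi_oral > 1
  agg$flag_dermal <- agg$hi_dermal > 1
  list(by_metal = by_metal, by_sample = agg)
}

#' Cohort summary of hazard quotients
#'
#' Min/max/mean per metal, route and cohort, plus the percentage of samples
#' with HQ strictly above 1.
#'
#' @param risk result of [assess_health_risk()].
#' @return data.frame with one row per cohort x metal x route.
#' @export
cohort_summary <- function(risk) {
  bm <- risk$by_metal
  if (!nrow(bm)) stop("empty risk result", call. = FALSE)
  out <- list()
  for (route in c("oral", "dermal")) {
    col <- paste0("hq_", route)
    sp <- split(bm, list(bm$cohort, bm$metal), drop = TRUE)
    for (g in sp) {
      v <- g[[col]]
      out[[length(out) + 1L]] <- data.frame(
        cohort = g$cohort[1], metal = g$metal[1], route = route,
        hq_min = min(v), hq_max = max(v), hq_mean = mean(v),
        pct_exceeding = 100 * mean(v > 1),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}
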