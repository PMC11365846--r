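# Ion-balance QA, chloro-alkaline indices, facies / origin / ratio
# classification, and the lab QA formulas. All classification happens in
# meq/L (mg/L divided by the pinned equivalent weight).

#' Convert ion concentrations from mg/L to meq/L
#'
#' @param x named numeric vector (names among `Ca, Mg, Na, K, Cl, SO4,
#'   HCO3, CO3, NO3`) or a sample table, in mg/L.
#' @return for a vector: named meq/L vector with attributes `cation_sum`
#'   and `anion_sum`; for a sample table: data.frame of meq/L columns plus
#'   `cation_sum`, `anion_sum`.
#' @export
#' @examples
#' to_meq(c(Ca = 40.08, Cl = 35.45))  # 2 meq/L Ca, 1 meq/L Cl
to_meq <- function(x) {
  if (is.data.frame(x)) {
    ions <- intersect(ION_NAMES, names(x))
    m <- as.data.frame(lapply(ions, function(i) x[[i]] / EQUIVALENT_WEIGHTS[[i]]))
    names(m) <- ions
    m$cation_sum <- rowSums(m[, intersect(CATIONS, ions), drop = FALSE])
    m$anion_sum <- rowSums(m[, intersect(ANIONS, ions), drop = FALSE])
    return(m)
  }
  unknown <- setdiff(names(x), ION_NAMES)
  if (length(unknown)) {
    stop("unknown ion(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  meq <- x / EQUIVALENT_WEIGHTS[names(x)]
  attr(meq, "cation_sum") <- sum(meq[names(meq) %in% CATIONS])
  attr(meq, "anion_sum") <- sum(meq[names(meq) %in% ANIONS])
  meq
}

#' Charge balance error (%)
#'
#' `CBE = (sum cations - sum anions) / (sum cations + sum anions) * 100`
#' with sums in meq/L. Samples with `|CBE| <= 5` are analytically
#' acceptable.
#'
#' @param tbl a sample table (or a data.frame with ion columns in mg/L).
#' @param tolerance acceptability threshold in percent (default 5).
#' @return data.frame with `sample_id`, `cbe` (signed %), `acceptable`.
#' @export
charge_balance_error <- function(tbl, tolerance = 5) {
  m <- to_meq(tbl)
  tot <- m$cation_sum + m$anion_sum
  if (any(tot <= 0)) {
    stop("charge balance undefined: all-zero ion composition in sample ",
         tbl$sample_id[which(tot <= 0)[1]], call. = FALSE)
  }
  cbe <- (m$cation_sum - m$anion_sum) / tot * 100
  data.frame(sample_id = tbl$sample_id, cbe = cbe,
             acceptable = abs(cbe) <= tolerance,
             stringsAsFactors = FALSE)
}

#' Chloro-alkaline indices CAI-I and CAI-II
#'
#' `CAI-I = [Cl - (Na + K)] / Cl` and
#' `CAI-II = [Cl - (Na + K)] / (SO4 + HCO3 + CO3 + NO3)`, all terms meq/L.
#' Negative values indicate direct ion exchange (aquifer Na/K released,
#' dissolved Ca/Mg sorbed); positive values reverse exchange. The
#' `"as_printed"` numerator variant `Cl - (Na - Ca)` reproduces the source
#' formula verbatim (an apparent typographic slip of the Schoeller index)
#' and is provided for comparison only.
#'
#' @param tbl sample table.
#' @param numerator `"schoeller"` (default) or `"as_printed"`.
#' @return data.frame `sample_id`, `cai1`, `cai2`, `exchange` ("direct",
#'   "reverse" or "none"). Zero denominators give `NA` for that index.
#' @export
cai_indices <- function(tbl, numerator = c("schoeller", "as_printed")) {
  numerator <- match.arg(numerator)
  m <- to_meq(tbl)
  num <- if (numerator == "schoeller") {
    m$Cl - (m$Na + m$K)
  } else {
    m$Cl - (m$Na - m$Ca)
  }
  den2 <- m$SO4 + m$HCO3 + m$CO3 + m$NO3
  cai1 <- ifelse(m$Cl > 0, num / m$Cl, NA_real_)
  cai2 <- ifelse(den2 > 0, num / den2, NA_real_)
  exchange <- ifelse(is.na(cai1), NA_character_,
                     ifelse(cai1 < 0, "direct",
                            ifelse(cai1 > 0, "reverse", "none")))
  data.frame(sample_id = tbl$sample_id, cai1 = cai1, cai2 = cai2,
             exchange = exchange, stringsAsFactors = FALSE)
}

# meq% of one group (cations or anions) for a meq data.frame
.meq_percent <- function(m, group) {
  tot <- rowSums(m[, group, drop = FALSE])
  sweep(m[, group, drop = FALSE], 1, tot, "/") * 100
}

#' Piper hydrochemical facies
#'
#' Dominance rules on cation and anion meq percentages. Cation side:
#' alkali-dominated when Na + K > 66%, alkaline-earth-dominated when
#' Ca + Mg > 66%, otherwise mixed (so a 55% Na / 35% Ca water is mixed
#' Na-Ca, not Na-type). Anion side: a single anion dominates at > 50%
#' (HCO3 grouped with CO3), Cl and SO4 are grouped at a combined > 66%,
#' otherwise mixed. Combinations outside the five named facies, and exact
#' ties on the thresholds, resolve to `"other"`.
#'
#' @param tbl sample table.
#' @return data.frame `sample_id`, `facies` with labels among `Na-Cl`,
#'   `Ca-Mg-HCO3`, `Na-Ca-HCO3`, `Ca-Mg-Cl/SO4`, `Na-HCO3`, `other`.
#' @export
piper_facies <- function(tbl) {
  m <- to_meq(tbl)
  if (any(m$cation_sum <= 0) || any(m$anion_sum <= 0)) {
    stop("zero ion sums: facies undefined", call. = FALSE)
  }
  catp <- .meq_percent(m, CATIONS)
  anp <- .meq_percent(m, ANIONS)
  facies <- character(nrow(m))
  for (i in seq_len(nrow(m))) {
    cp <- unlist(catp[i, ]); ap <- unlist(anp[i, ])
    cat_lab <- if (cp[["Na"]] + cp[["K"]] > 66) "Na"
      else if (cp[["Ca"]] + cp[["Mg"]] > 66) "CaMg"
      else "mixed"
    an_lab <- if (ap[["HCO3"]] + ap[["CO3"]] > 50) "HCO3"
      else if (ap[["Cl"]] > 50) "Cl"
      else if (ap[["SO4"]] > 50) "SO4"
      else if (ap[["Cl"]] + ap[["SO4"]] > 66) "Cl/SO4"
      else "mixed"
    top2 <- names(sort(cp, decreasing = TRUE))[1:2]
    facies[i] <-
      if (cat_lab == "Na" && an_lab == "Cl") "Na-Cl"
      else if (cat_lab == "Na" && an_lab == "HCO3") "Na-HCO3"
      else if (cat_lab == "CaMg" && an_lab == "HCO3") "Ca-Mg-HCO3"
      else if (cat_lab %in% c("CaMg", "mixed") &&
               an_lab %in% c("Cl", "SO4", "Cl/SO4")) "Ca-Mg-Cl/SO4"
      else if (cat_lab == "mixed" && an_lab == "HCO3" &&
               setequal(top2, c("Na", "Ca"))) "Na-Ca-HCO3"
      else "other"
  }
  data.frame(sample_id = tbl$sample_id, facies = facies,
             stringsAsFactors = FALSE)
}

# Gibbs boomerang digitized to rectangles; points outside every box are
# attached to the nearest zone by normalized distance in (log10 TDS, ratio)
# space.
.gibbs_zones <- data.frame(
  zone = c("rock-weathering", "evaporation/crystallization", "precipitation"),
  tds_lo = c(70, 1000, 1), tds_hi = c(1000, 1e5, 70),
  r_lo = c(0, 0.5, 0.5), r_hi = c(0.75, 1, 1)
)

.gibbs_assign <- function(tds, ratio) {
  z <- .gibbs_zones
  inside <- tds >= z$tds_lo & tds <= z$tds_hi & ratio >= z$r_lo & ratio <= z$r_hi
  if (any(inside)) return(z$zone[which(inside)[1]])
  # nearest zone centre, TDS on log10 scale normalized by its span
  lt <- log10(pmax(tds, 1))
  ctr_t <- log10(sqrt(z$tds_lo * z$tds_hi))
  ctr_r <- (z$r_lo + z$r_hi) / 2
  d <- ((lt - ctr_t) / 5)^2 + (ratio - ctr_r)^2
  z$zone[which.min(d)]
}

#' Gibbs ratios and mechanism zone
#'
#' Computes `Na/(Na+Ca)` and `Cl/(Cl+HCO3)` (meq/L) and assigns each sample
#' to rock-weathering, evaporation/crystallization, or precipitation
#' dominance from its TDS and cation ratio.
#'
#' @param tbl sample table.
#' @return data.frame `sample_id`, `na_ratio`, `cl_ratio`, `gibbs_zone`.
#' @export
gibbs_point <- function(tbl) {
  m <- to_meq(tbl)
  na_ratio <- ifelse(m$Na + m$Ca > 0, m$Na / (m$Na + m$Ca), NA_real_)
  cl_ratio <- ifelse(m$Cl + m$HCO3 > 0, m$Cl / (m$Cl + m$HCO3), NA_real_)
  zone <- vapply(seq_len(nrow(m)), function(i) {
    if (is.na(na_ratio[i])) return(NA_character_)
    .gibbs_assign(tbl$TDS[i], na_ratio[i])
  }, character(1))
  data.frame(sample_id = tbl$sample_id, na_ratio = na_ratio,
             cl_ratio = cl_ratio, gibbs_zone = zone,
             stringsAsFactors = FALSE)
}

#' Sulin genetic classification of water origin
#'
#' Classical decision rules on equivalent ratios: with `r(Na)/r(Cl) > 1`,
#' excess Na balanced by SO4 (`(rNa - rCl)/rSO4 > 1`) marks Na2SO4-type
#' deep meteoric water, otherwise NaHCO3-type shallow meteoric; with
#' `r(Na)/r(Cl) < 1`, `(rCl - rNa)/rMg < 1` marks MgCl2-type old marine,
#' otherwise CaCl2-type recent marine.
#'
#' @param tbl sample table.
#' @return data.frame `sample_id`, `sulin` (one of `shallow meteoric`,
#'   `deep meteoric`, `old marine`, `recent marine`), `salt_type`.
#' @export
sulin_class <- function(tbl) {
  m <- to_meq(tbl)
  n <- nrow(m)
  cls <- character(n); salt <- character(n)
  for (i in seq_len(n)) {
    rna <- m$Na[i]; rcl <- m$Cl[i]; rso4 <- m$SO4[i]; rmg <- m$Mg[i]
    if (rcl <= 0 || rna / rcl > 1) {
      if (rso4 > 0 && (rna - rcl) / rso4 > 1) {
        cls[i] <- "deep meteoric"; salt[i] <- "Na2SO4"
      } else {
        cls[i] <- "shallow meteoric"; salt[i] <- "NaHCO3"
      }
    } else if (rna / rcl < 1) {
      if (rmg <= 0) { cls[i] <- NA_character_; salt[i] <- NA_character_; next }
      if ((rcl - rna) / rmg < 1) {
        cls[i] <- "old marine"; salt[i] <- "MgCl2"
      } else {
        cls[i] <- "recent marine"; salt[i] <- "CaCl2"
      }
    } else { # rNa == rCl exactly: balanced halite signature, treat as shallow
      cls[i] <- "shallow meteoric"; salt[i] <- "NaHCO3"
    }
  }
  data.frame(sample_id = tbl$sample_id, sulin = cls, salt_type = salt,
             stringsAsFactors = FALSE)
}

#' Ionic ratio panel
#'
#' Emits the diagnostic equivalent ratios used to attribute ion sources
#' (halite vs silicate weathering, gypsum vs carbonate, exchange), each
#' with the side of the 1:1 line, plus `log10(Mg/Na)` and `log10(Ca/Na)`.
#'
#' @param tbl sample table.
#' @return data.frame, one row per sample; `NA` where a denominator is 0.
#' @export
ionic_ratio_table <- function(tbl) {
  m <- to_meq(tbl)
  sdiv <- function(a, b) ifelse(b > 0, a / b, NA_real_)
  r <- data.frame(
    sample_id = tbl$sample_id,
    na_cl = sdiv(m$Na, m$Cl),
    ca_so4 = sdiv(m$Ca, m$SO4),
    ca_mg = sdiv(m$Ca, m$Mg),
    ca_hco3 = sdiv(m$Ca, m$HCO3),
    camg_hco3so4 = sdiv(m$Ca + m$Mg, m$HCO3 + m$SO4),
    cl_na = sdiv(m$Cl, m$Na),
    no3_na = sdiv(m$NO3, m$Na),
    log_mg_na = ifelse(m$Na > 0 & m$Mg > 0, log10(m$Mg / m$Na), NA_real_),
    log_ca_na = ifelse(m$Na > 0 & m$Ca > 0, log10(m$Ca / m$Na), NA_real_),
    stringsAsFactors = FALSE
  )
  side <- function(x) ifelse(is.na(x), NA_character_,
                             ifelse(x > 1, "above 1:1",
                                    ifelse(x < 1, "below 1:1", "on 1:1 line")))
  for (col in c("na_cl", "ca_so4", "ca_mg", "ca_hco3", "camg_hco3so4")) {
    r[[paste0(col, "_side")]] <- side(r[[col]])
  }
  r
}

#' Analytical QA statistics: LOD, LOQ, %RSD
#'
#' `LOD = 3 * SD(blank)`, `LOQ = 10 * SD(blank)` (so LOQ/LOD is exactly
#' 10/3), and `%RSD = 100 * SD / mean` of replicate readings, using the
#' sample (n-1) standard deviation.
#'
#' @param blank_sd standard deviation of the blank method (>= 0).
#' @param replicates numeric vector of replicate readings (>= 2 values),
#'   or `NULL` to skip the RSD.
#' @return list with `lod`, `loq`, `rsd_percent`.
#' @export
qa_stats <- function(blank_sd, replicates = NULL) {
  stopifnot(is.numeric(blank_sd), blank_sd >= 0)
  rsd <- NA_real_
  if (!is.null(replicates)) {
    if (length(replicates) < 2) {
      stop("need at least 2 replicates for %RSD", call. = FALSE)
    }
    mu <- mean(replicates)
    if (mu == 0) stop("%RSD undefined: replicate mean is 0", call. = FALSE)
    rsd <- 100 * stats::sd(replicates) / mu
  }
  list(lod = 3 * blank_sd, loq = 10 * blank_sd, rsd_percent = rsd)
}

#' Full hydrochemical screening panel
#'
#' Joins charge balance, chloro-alkaline indices, Piper facies, Gibbs zone,
#' Sulin class and the ionic ratios into one per-sample table.
#'
#' @param tbl sample table.
#' @param cai_numerator passed to [cai_indices()].
#' @return data.frame keyed by `sample_id`.
#' @export
hydrochem_panel <- function(tbl, cai_numerator = "schoeller") {
  out <- charge_balance_error(tbl)
  out <- merge(out, cai_indices(tbl, cai_numerator), by = "sample_id", sort = FALSE)
  out <- merge(out, piper_facies(tbl), by = "sample_id", sort = FALSE)
  out <- merge(out, gibbs_point(tbl), by = "sample_id", sort = FALSE)
  out <- merge(out, sulin_class(tbl), by = "sample_id", sort = FALSE)
  out <- merge(out, ionic_ratio_table(tbl), by = "sample_id", sort = FALSE)
  out[match(tbl$sample_id, out$sample_id), ]
}
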