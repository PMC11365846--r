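# Probabilistic hazard-quotient simulation. Each input variable of the
# exposure chain gets a distribution spec; draws are seeded through
# per-variable substreams derived from one master seed, so adding a metal
# or reordering variables never perturbs the other draws.

#' Build a distribution specification
#'
#' Families: `"point"` (degenerate), `"normal"` and `"lognormal"`
#' (optionally truncated via `lower`/`upper`), `"trunclnorm"` /
#' `"truncnorm"` (moment-matched to `mean`/`sd`, then rejection-truncated),
#' and `"empirical"` (bootstrap of `values`).
#'
#' @param variable variable name (used for substream seeding).
#' @param family distribution family.
#' @param mean,sd target moments (natural scale) for the (log)normal
#'   families; `sd = 0` collapses to a point mass.
#' @param lower,upper optional truncation bounds.
#' @param values sample vector for the empirical family.
#' @param strict if `TRUE`, moment targets the truncated family cannot
#'   represent are an error; otherwise the spec falls back to naive
#'   (untruncated) moment matching and records `fit$exact = FALSE`.
#' @return object of class `"dist_spec"`.
#' @export
dist_spec <- function(variable, family = c("point", "normal", "lognormal",
                                           "trunclnorm", "truncnorm",
                                           "empirical"),
                      mean = NA_real_, sd = NA_real_,
                      lower = -Inf, upper = Inf, values = NULL,
                      strict = FALSE) {
  family <- match.arg(family)
  if (!is.na(sd) && sd < 0) stop("sd must be >= 0", call. = FALSE)
  if (lower > upper) stop("truncation bounds out of order", call. = FALSE)
  if (family == "empirical" && !length(values)) {
    stop("empirical spec needs values", call. = FALSE)
  }
  if (!is.na(sd) && sd == 0 && family != "empirical") family <- "point"
  fit <- NULL
  if (family %in% c("normal", "lognormal", "truncnorm", "trunclnorm") &&
      is.finite(upper) && (is.finite(lower) || family %in% c("lognormal", "trunclnorm"))) {
    fit <- .fit_truncated(family, mean, sd, max(lower, 0), upper,
                          strict = strict)
  }
  structure(list(variable = variable, family = family, mean = mean, sd = sd,
                 lower = lower, upper = upper, values = values, fit = fit),
            class = "dist_spec")
}

# Moment-matched lognormal parameters: E[X] = mean, SD[X] = sd.
.lnorm_params <- function(mean, sd) {
  if (mean <= 0) stop("lognormal moment matching needs mean > 0", call. = FALSE)
  s2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

# Mean and SD of a lognormal(mu, sig) truncated to [lo, hi].
.trunclnorm_moments <- function(mu, sig, lo, hi) {
  a <- (log(max(lo, 1e-300)) - mu) / sig
  b <- (log(hi) - mu) / sig
  z <- stats::pnorm(b) - stats::pnorm(a)
  m1 <- exp(mu + sig^2 / 2) *
    (stats::pnorm(b - sig) - stats::pnorm(a - sig)) / z
  m2 <- exp(2 * mu + 2 * sig^2) *
    (stats::pnorm(b - 2 * sig) - stats::pnorm(a - 2 * sig)) / z
  c(mean = m1, sd = sqrt(max(m2 - m1^2, 0)))
}

# Mean and SD of a normal(mu, sig) truncated to [lo, hi].
.truncnorm_moments <- function(mu, sig, lo, hi) {
  a <- (lo - mu) / sig
  b <- (hi - mu) / sig
  z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  m1 <- mu + sig * (da - db) / z
  v <- sig^2 * (1 + (a * da - b * db) / z - ((da - db) / z)^2)
  c(mean = m1, sd = sqrt(max(v, 0)))
}

# Solve for the (log)normal parameters whose TRUNCATED distribution has the
# requested mean/sd; naive (untruncated) matching followed by truncation
# would bias the realized mean low whenever the fitted tail extends past
# the upper bound. Targets the family cannot reach (solver residual above
# ~1% on either moment; e.g. a sample sd larger than any distribution on
# the observed range can have) fall back to naive matching with
# `exact = FALSE`, or are an error when `strict`.
.fit_truncated <- function(family, mean, sd, lo, hi, strict = FALSE) {
  lognormal <- family %in% c("lognormal", "trunclnorm")
  momf <- if (lognormal) .trunclnorm_moments else .truncnorm_moments
  start <- if (lognormal) {
    p <- .lnorm_params(mean, sd); c(p$meanlog, log(p$sdlog))
  } else {
    c(mean, log(sd))
  }
  obj <- function(p) {
    mm <- momf(p[1], exp(p[2]), lo, hi)
    if (any(!is.finite(mm)) || mm[2] <= 0) return(1e6)
    ((mm[1] - mean) / mean)^2 + ((mm[2] - sd) / sd)^2
  }
  o <- stats::optim(start, obj, method = "Nelder-Mead",
                    control = list(maxit = 5000, reltol = 1e-12))
  if (o$value > 1e-4) {
    if (strict) {
      stop("infeasible statistics: no truncated ", family,
           " on [", lo, ", ", hi, "] has mean ", mean, " and sd ", sd,
           call. = FALSE)
    }
    return(list(location = start[1], scale = exp(start[2]), exact = FALSE))
  }
  list(location = o$par[1], scale = exp(o$par[2]), exact = TRUE)
}

#' Draw from a distribution spec using the current RNG state
#'
#' Truncation is by rejection (resampling the rejected tail), so all draws
#' respect the bounds exactly; normal-family draws are additionally floored
#' at 0 when the lower bound allows negative values.
#'
#' @param spec a [dist_spec()].
#' @param n number of draws.
#' @return numeric vector of length `n`.
#' @export
draw_dist <- function(spec, n) {
  stopifnot(inherits(spec, "dist_spec"))
  lo <- max(spec$lower, if (spec$family %in% c("normal", "truncnorm")) 0 else -Inf)
  hi <- spec$upper
  gen <- switch(spec$family,
    point = function(k) rep(spec$mean, k),
    empirical = function(k) sample(spec$values, k, replace = TRUE),
    normal = ,
    truncnorm = {
      loc <- if (is.null(spec$fit)) spec$mean else spec$fit$location
      scl <- if (is.null(spec$fit)) spec$sd else spec$fit$scale
      function(k) stats::rnorm(k, loc, scl)
    },
    lognormal = ,
    trunclnorm = {
      p <- if (is.null(spec$fit)) {
        q <- .lnorm_params(spec$mean, spec$sd)
        list(location = q$meanlog, scale = q$sdlog)
      } else spec$fit
      function(k) stats::rlnorm(k, p$location, p$scale)
    }
  )
  x <- gen(n)
  if (spec$family %in% c("point", "empirical")) return(pmin(pmax(x, lo), hi))
  for (iter in 1:1000) {
    bad <- which(x < lo | x > hi)
    if (!length(bad)) return(x)
    x[bad] <- gen(length(bad))
  }
  stop("rejection sampling failed for variable '", spec$variable,
       "': bounds too tight for the fitted distribution", call. = FALSE)
}

# Deterministic 31-bit substream seed from a master seed and a label.
.substream_seed <- function(master, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 1999993
  as.integer((as.numeric(master) * 2003 + h) %% 2147483647)
}

#' Build the default distribution set from a cohort
#'
#' Metal concentrations become truncated lognormals moment-matched to the
#' cohort mean/SD and truncated to the observed range (`"empirical"`
#' bootstraps the column instead). Ingestion rate, exposure duration, skin
#' area and body weight become normals centred on the deterministic profile
#' value with `sd = cv * mean` (truncated at 0 and +/- 3 SD); exposure
#' frequency, exposure time and the unit conversion factor stay point
#' masses.
#'
#' @param tbl sample table supplying the metal concentrations.
#' @param exposure exposure profiles ([default_exposure()]).
#' @param cv_map named coefficients of variation for the stochastic
#'   exposure variables.
#' @param metals metals to model.
#' @param conc_family `"trunclnorm"` or `"empirical"`.
#' @return list with `concentration` (per metal) and `exposure`
#'   (per cohort, per variable) specs.
#' @export
build_distributions <- function(tbl, exposure = default_exposure(),
                                cv_map = c(ir = 0.10, sa = 0.10, bw = 0.10,
                                           ed = 0.20),
                                metals = intersect(PTE_NAMES, names(tbl)),
                                conc_family = c("trunclnorm", "empirical")) {
  conc_family <- match.arg(conc_family)
  conc <- lapply(metals, function(m) {
    v <- tbl[[m]]
    if (length(v) < 2) stop("metal ", m, " has fewer than 2 observations; ",
                            "supply an explicit spec", call. = FALSE)
    if (conc_family == "empirical") {
      dist_spec(m, "empirical", values = v)
    } else if (stats::sd(v) == 0) {
      dist_spec(m, "point", mean = v[1])
    } else {
      dist_spec(m, "trunclnorm", mean = mean(v), sd = stats::sd(v),
                lower = min(v), upper = max(v))
    }
  })
  names(conc) <- metals
  expo <- list()
  for (k in seq_len(nrow(exposure))) {
    prof <- exposure[k, ]
    specs <- list()
    for (v in c("ir", "ed", "ef", "et", "sa", "cf", "bw")) {
      mu <- prof[[v]]
      cv <- if (v %in% names(cv_map)) cv_map[[v]] else 0
      nm <- paste(prof$cohort, v, sep = ".")
      specs[[v]] <- if (cv > 0) {
        dist_spec(nm, "truncnorm", mean = mu, sd = cv * mu,
                  lower = max(0, mu - 3 * cv * mu), upper = mu + 3 * cv * mu)
      } else {
        dist_spec(nm, "point", mean = mu)
      }
    }
    expo[[prof$cohort]] <- specs
  }
  list(concentration = conc, exposure = expo)
}

#' Monte Carlo simulation of hazard quotients
#'
#' For every cohort and metal, draws `n_iter` concentration and exposure
#' vectors (independent variables, per-variable substreams spawned from the
#' master seed), pushes each draw through the deterministic CDI/HQ chain
#' ([cdi_oral()], [cdi_dermal()], [hazard_quotient()]) and records the HQ
#' draws. `at` follows `ed` (non-carcinogenic convention `at = 365 ed`).
#'
#' @param specs distribution set from [build_distributions()].
#' @param toxicity toxicity table.
#' @param n_iter iterations (default 10000).
#' @param seed master seed; required, there is no hidden default.
#' @param cohorts,routes which cohorts/routes to simulate.
#' @param percentiles summary percentiles (in (0, 100)).
#' @return object of class `"hq_simulation"`: list with `draws`
#'   (`[[cohort]][[metal]][[route]]` numeric vectors), `summary`
#'   (data.frame), `n_iter`, `seed`.
#' @export
simulate_hq <- function(specs, toxicity = default_toxicity(),
                        n_iter = 10000, seed = NULL,
                        cohorts = names(specs$exposure),
                        routes = c("oral", "dermal"),
                        percentiles = c(5, 50, 95)) {
  if (is.null(seed)) stop("an explicit seed is required", call. = FALSE)
  stopifnot(n_iter >= 1, all(percentiles > 0 & percentiles < 100))
  draws <- list()
  for (cohort in cohorts) {
    espec <- specs$exposure[[cohort]]
    if (is.null(espec)) stop("no exposure specs for cohort ", cohort,
                             call. = FALSE)
    prof <- list()
    for (v in names(espec)) {
      set.seed(.substream_seed(seed, paste0("expo.", cohort, ".", v)))
      prof[[v]] <- draw_dist(espec[[v]], n_iter)
    }
    prof$at <- 365 * prof$ed
    prof <- as.data.frame(prof)
    draws[[cohort]] <- list()
    for (m in names(specs$concentration)) {
      set.seed(.substream_seed(seed, paste0("conc.", m)))
      conc <- draw_dist(specs$concentration[[m]], n_iter)
      t <- match(m, toxicity$metal)
      if (is.na(t)) stop("no toxicity entry for ", m, call. = FALSE)
      res <- list()
      if ("oral" %in% routes) {
        res$oral <- hazard_quotient(cdi_oral(conc, prof),
                                    toxicity$rfd_oral[t])
      }
      if ("dermal" %in% routes) {
        res$dermal <- hazard_quotient(cdi_dermal(conc, prof, toxicity$kp[t]),
                                      toxicity$rfd_dermal[t])
      }
      draws[[cohort]][[m]] <- res
    }
  }
  out <- structure(list(draws = draws, n_iter = n_iter, seed = seed,
                        percentiles = percentiles),
                   class = "hq_simulation")
  out$summary <- summarize_simulation(out)
  out
}

#' Summarize a hazard-quotient simulation
#'
#' @param sim an `"hq_simulation"` object.
#' @param threshold exceedance threshold (default 1, strict `>`).
#' @param percentiles percentile levels; defaults to those of the run.
#' @return data.frame, one row per cohort x metal x route: mean, sd,
#'   percentiles, exceedance fraction.
#' @export
summarize_simulation <- function(sim, threshold = 1, percentiles = NULL) {
  if (is.null(percentiles)) percentiles <- sim$percentiles
  rows <- list()
  for (cohort in names(sim$draws)) {
    for (m in names(sim$draws[[cohort]])) {
      for (route in names(sim$draws[[cohort]][[m]])) {
        v <- sim$draws[[cohort]][[m]][[route]]
        qs <- stats::quantile(v, percentiles / 100, names = FALSE, type = 7)
        row <- data.frame(cohort = cohort, metal = m, route = route,
                          mean = mean(v), sd = stats::sd(v),
                          stringsAsFactors = FALSE)
        for (i in seq_along(percentiles)) {
          row[[paste0("p", percentiles[i])]] <- qs[i]
        }
        row$frac_exceeding <- mean(v > threshold)
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  do.call(rbind, rows)
}

#' Calibration check: deterministic vs simulated hazard quotients
#'
#' Compares the deterministic HQ computed at the mean inputs with the
#' simulated mean HQ, per cohort/metal/route. Because the HQ is linear in
#' the concentration, the two agree up to Monte Carlo error and the small
#' Jensen terms of the nonlinear exposure factors (1/BW, ED/AT).
#'
#' @param deterministic data.frame with columns `cohort`, `metal`, `route`,
#'   `hq` (HQ at mean inputs).
#' @param sim an `"hq_simulation"` object.
#' @param tolerance flag threshold on the relative difference.
#' @return data.frame with `hq_deterministic`, `hq_simulated`, `rel_diff`,
#'   `flag`.
#' @export
calibration_check <- function(deterministic, sim, tolerance = 0.1) {
  s <- sim$summary
  merged <- merge(deterministic, s[, c("cohort", "metal", "route", "mean")],
                  by = c("cohort", "metal", "route"))
  if (nrow(merged) != nrow(deterministic)) {
    stop("cohort/metal/route keys do not match the simulation", call. = FALSE)
  }
  merged$rel_diff <- (merged$mean - merged$hq) / merged$hq
  merged$flag <- abs(merged$rel_diff) > tolerance
  names(merged)[names(merged) == "hq"] <- "hq_deterministic"
  names(merged)[names(merged) == "mean"] <- "hq_simulated"
  merged
}
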