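test_that("to_meq matches equivalent-weight arithmetic and is linear", {
  m <- to_meq(c(Ca = 40.08, Cl = 35.45))
  expect_equal(unname(m[["Ca"]]), 2, tolerance = 1e-12)
  expect_equal(unname(m[["Cl"]]), 1, tolerance = 1e-12)
  expect_equal(attr(m, "cation_sum"), 2)
  expect_equal(attr(m, "anion_sum"), 1)

  z <- to_meq(c(Ca = 0, Na = 0, Cl = 0))
  expect_true(all(z == 0) && attr(z, "cation_sum") == 0)

  expect_error(to_meq(c(Li = 1)), "unknown ion")

  # linearity over random compositions
  set.seed(3)
  for (i in 1:10) {
    x <- stats::setNames(runif(9, 0, 500), ION_NAMES <- c("Ca","Mg","Na","K","Cl","SO4","HCO3","CO3","NO3"))
    expect_equal(as.numeric(to_meq(2 * x)), as.numeric(2 * to_meq(x)))
  }
})

test_that("charge balance error is signed, gated at 5%, antisymmetric", {
  expect_equal(charge_balance_error(meq_table(10, 10))$cbe, 0)
  r <- charge_balance_error(meq_table(10.5, 9.5))
  expect_equal(r$cbe, 5, tolerance = 1e-9)
  expect_true(r$acceptable)
  r <- charge_balance_error(meq_table(9, 11))
  expect_equal(r$cbe, -10, tolerance = 1e-9)
  expect_false(r$acceptable)

  # antisymmetry under swapping the cation/anion sums
  set.seed(4)
  a <- runif(20, 1, 30); b <- runif(20, 1, 30)
  expect_equal(charge_balance_error(meq_table(a, b))$cbe,
               -charge_balance_error(meq_table(b, a))$cbe)

  zero <- as.data.frame(balanced_table(1))
  zero[, c("Ca","Mg","Na","K","Cl","SO4","HCO3","CO3","NO3")] <- 0
  expect_error(charge_balance_error(sample_table(zero)), "all-zero")
})

test_that("chloro-alkaline indices follow the Schoeller definition", {
  # Cl 2, Na+K 1, denom2 4 (meq/L) -> (0.5, 0.25)
  tbl <- sample_table(data.frame(
    sample_id = "a", pH = 7, EC = 1, TDS = 1, TH = 1,
    Ca = 0, Mg = 0, Na = 1 * 22.99, K = 0,
    Cl = 2 * 35.45, SO4 = 4 * 48.03, HCO3 = 0, CO3 = 0, NO3 = 0,
    Fe = 0, Mn = 0, Cu = 0, Zn = 0))
  r <- cai_indices(tbl)
  expect_equal(r$cai1, 0.5, tolerance = 1e-12)
  expect_equal(r$cai2, 0.25, tolerance = 1e-12)
  expect_identical(r$exchange, "reverse")

  tbl$Na <- 2 * 22.99
  r <- cai_indices(tbl)
  expect_equal(r$cai1, 0); expect_equal(r$cai2, 0)

  # Cl 1, Na+K 3, denom2 2 -> (-2, -1), direct exchange
  tbl2 <- tbl
  tbl2$Cl <- 1 * 35.45; tbl2$Na <- 3 * 22.99; tbl2$SO4 <- 2 * 48.03
  r <- cai_indices(tbl2)
  expect_equal(r$cai1, -2, tolerance = 1e-12)
  expect_equal(r$cai2, -1, tolerance = 1e-12)
  expect_identical(r$exchange, "direct")

  # CAI-I and CAI-II always share a sign (positive denominators)
  tbl3 <- random_table(50, seed = 5)
  r <- cai_indices(tbl3)
  expect_true(all(sign(r$cai1) == sign(r$cai2)))

  # as-printed numerator variant uses Cl - (Na - Ca)
  tbl4 <- tbl
  tbl4$Ca <- 1 * 20.04
  r <- cai_indices(tbl4, numerator = "as_printed")
  expect_equal(r$cai1, (2 - (2 - 1)) / 2, tolerance = 1e-12)
})

test_that("piper facies dominance rules recover end-members", {
  mk <- function(ca = 0, mg = 0, na = 0, k = 0, cl = 0, so4 = 0, hco3 = 0) {
    sample_table(data.frame(
      sample_id = "x", pH = 7, EC = 1, TDS = 500, TH = 1,
      Ca = ca * 20.04, Mg = mg * 12.15, Na = na * 22.99, K = k * 39.10,
      Cl = cl * 35.45, SO4 = so4 * 48.03, HCO3 = hco3 * 61.02,
      CO3 = 0, NO3 = 0, Fe = 0, Mn = 0, Cu = 0, Zn = 0))
  }
  expect_identical(piper_facies(mk(na = 9, ca = 1, cl = 9, hco3 = 1))$facies, "Na-Cl")
  expect_identical(piper_facies(mk(ca = 4.5, mg = 3.5, na = 2, hco3 = 8.5, cl = 1.5))$facies, "Ca-Mg-HCO3")
  expect_identical(piper_facies(mk(na = 5.5, ca = 3.5, mg = 1, hco3 = 7, cl = 3))$facies, "Na-Ca-HCO3")
  expect_identical(piper_facies(mk(na = 9, ca = 1, hco3 = 9, cl = 1))$facies, "Na-HCO3")
  expect_identical(piper_facies(mk(ca = 4, mg = 4, na = 2, cl = 5, so4 = 4, hco3 = 1))$facies, "Ca-Mg-Cl/SO4")
  expect_error(piper_facies(mk()), "zero ion sums")
})

test_that("gibbs ratios and zone boxes behave as specified", {
  tbl <- balanced_table(1) # Na == Ca would need equal meq; here Na=Ca=2 meq
  g <- gibbs_point(tbl)
  expect_equal(g$na_ratio, 0.5)
  expect_equal(g$cl_ratio, 0.5)

  mk <- function(tds, na, ca) {
    df <- as.data.frame(balanced_table(1))
    df$TDS <- tds; df$Na <- na * 22.99; df$Ca <- ca * 20.04
    sample_table(df)
  }
  expect_identical(gibbs_point(mk(300, 4, 6))$gibbs_zone, "rock-weathering")
  expect_identical(gibbs_point(mk(4900, 9, 1))$gibbs_zone,
                   "evaporation/crystallization")
  expect_identical(gibbs_point(mk(30, 9, 1))$gibbs_zone, "precipitation")
})

test_that("sulin classification follows the rule table", {
  mk <- function(na, cl, so4 = 0.1, mg = 1, hco3 = 5) {
    sample_table(data.frame(
      sample_id = "x", pH = 7, EC = 1, TDS = 500, TH = 1,
      Ca = 20.04, Mg = mg * 12.15, Na = na * 22.99, K = 0,
      Cl = cl * 35.45, SO4 = so4 * 48.03, HCO3 = hco3 * 61.02,
      CO3 = 0, NO3 = 0, Fe = 0, Mn = 0, Cu = 0, Zn = 0))
  }
  # Na/Cl > 1, excess Na not matched by SO4 -> NaHCO3 shallow meteoric
  expect_identical(sulin_class(mk(na = 6, cl = 2, so4 = 10))$sulin, "shallow meteoric")
  # Na/Cl > 1 with excess Na matched by SO4 -> Na2SO4 deep meteoric
  expect_identical(sulin_class(mk(na = 6, cl = 2, so4 = 2))$sulin, "deep meteoric")
  # Na/Cl < 1, (Cl-Na)/Mg < 1 -> old marine
  expect_identical(sulin_class(mk(na = 4, cl = 5, mg = 2))$sulin, "old marine")
  # Na/Cl < 1, (Cl-Na)/Mg > 1 -> recent marine
  expect_identical(sulin_class(mk(na = 1, cl = 5, mg = 2))$sulin, "recent marine")
})

test_that("ionic ratio panel reports ratios and 1:1 sides", {
  r <- ionic_ratio_table(balanced_table(1)) # Na=Cl=2 meq, Ca=HCO3=2 meq
  expect_equal(r$na_cl, 1)
  expect_identical(r$na_cl_side, "on 1:1 line")
  expect_equal(r$ca_hco3, 1)
  df <- as.data.frame(balanced_table(1))
  df$SO4 <- 1 * 48.03 # Ca 2 meq vs SO4 1 meq
  r <- ionic_ratio_table(sample_table(df))
  expect_equal(r$ca_so4, 2)
  expect_identical(r$ca_so4_side, "above 1:1")
  expect_equal(r$camg_hco3so4, 2 / 3)
  df$SO4 <- 0; df$Cl <- 0
  r <- ionic_ratio_table(sample_table(df))
  expect_true(is.na(r$na_cl)) # division by zero -> undefined marker
})

test_that("qa_stats: LOD, LOQ and %RSD", {
  q <- qa_stats(0.01)
  expect_equal(q$lod, 0.03)
  expect_equal(q$loq, 0.10)
  expect_equal(qa_stats(1)$loq / qa_stats(1)$lod, 10 / 3, tolerance = 1e-12)
  expect_equal(qa_stats(0, c(1, 1, 1))$rsd_percent, 0)
  expect_equal(qa_stats(0, c(9, 10, 11))$rsd_percent, 10, tolerance = 1e-12)
  expect_error(qa_stats(0, c(1)), "at least 2")
  expect_error(qa_stats(0, c(-1, 1)), "mean is 0")
})

test_that("hydrochem_panel joins all classifiers per sample", {
  tbl <- generate_cohort(n = 8, seed = 6)
  p <- hydrochem_panel(tbl)
  expect_identical(p$sample_id, tbl$sample_id)
  expect_true(all(c("cbe", "cai1", "facies", "gibbs_zone", "sulin",
                    "na_cl") %in% names(p)))
  expect_true(all(abs(p$cbe) <= 5))
})
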