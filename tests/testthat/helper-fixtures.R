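# Fixtures built in code. Canonical test seed: 1.

# A tiny hand-made, exactly charge-balanced sample table (meq/L:
# cations Ca 2 + Na 2 = 4, anions Cl 2 + HCO3 2 = 4).
balanced_table <- function(n = 1) {
  df <- data.frame(
    sample_id = paste0("B", seq_len(n)),
    pH = rep(7.2, n), EC = rep(500, n), TDS = rep(320, n), TH = rep(150, n),
    Ca = rep(2 * 20.04, n), Mg = rep(0, n), Na = rep(2 * 22.99, n),
    K = rep(0, n),
    Cl = rep(2 * 35.45, n), SO4 = rep(0, n), HCO3 = rep(2 * 61.02, n),
    CO3 = rep(0, n), NO3 = rep(0, n),
    Fe = rep(0.05, n), Mn = rep(0.02, n), Cu = rep(0.01, n),
    Zn = rep(0.03, n)
  )
  sample_table(df)
}

# Table with prescribed cation/anion meq sums split over Na and Cl only.
meq_table <- function(cation_meq, anion_meq) {
  n <- length(cation_meq)
  sample_table(data.frame(
    sample_id = paste0("M", seq_len(n)),
    pH = 7, EC = 100, TDS = 100, TH = 50,
    Ca = 0, Mg = 0, Na = cation_meq * 22.99, K = 0,
    Cl = anion_meq * 35.45, SO4 = 0, HCO3 = 0, CO3 = 0, NO3 = 0,
    Fe = 0, Mn = 0, Cu = 0, Zn = 0
  ))
}

# Random positive sample table for property-style tests.
random_table <- function(n, seed) {
  set.seed(seed)
  sample_table(data.frame(
    sample_id = paste0("R", seq_len(n)),
    pH = runif(n, 6, 8.5), EC = runif(n, 300, 8000),
    TDS = runif(n, 200, 5000), TH = runif(n, 50, 2000),
    Ca = runif(n, 2, 600), Mg = runif(n, 8, 130), Na = runif(n, 14, 1500),
    K = runif(n, 1, 70), Cl = runif(n, 13, 2700), SO4 = runif(n, 1, 900),
    HCO3 = runif(n, 65, 850), CO3 = 0, NO3 = runif(n, 0.1, 150),
    Fe = runif(n, 1e-4, 0.6), Mn = runif(n, 0.002, 1.7),
    Cu = runif(n, 0.002, 0.16), Zn = runif(n, 0.003, 0.88)
  ))
}

# Toxicity table with synthetic backgrounds filled in (RI needs c_bg).
toxicity_with_bg <- function() {
  tox <- default_toxicity()
  tox$c_bg <- c(Fe = 20, Mn = 15, Cu = 5, Zn = 30)[tox$metal]
  tox
}

table2_extremes <- function() {
  tg <- cohort_targets()
  stats::setNames(
    lapply(c("Fe", "Mn", "Cu", "Zn"),
           function(m) c(min = tg$min[tg$parameter == m],
                         max = tg$max[tg$parameter == m])),
    c("Fe", "Mn", "Cu", "Zn"))
}
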