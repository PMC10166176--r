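test_that("attrition-saturated and deathless limits are exact", {
  lt0 <- zero_lifetable()
  s1 <- exp_grid(0.05)
  s2 <- exp_grid(0.03)
  # a = 1: nobody reaches 2L, OS equals the (adjusted) 1L curve
  tr1 <- run_sequence(sequence_spec("a1", s1, 1, s2), lt0)
  expect_equal(tr1$os_grid, s1, tolerance = 1e-12)
  expect_equal(tr1$occ_2L, rep(0, 181))
  # a = 0, immortal 2L, zero background: nobody ever dies
  tr0 <- run_sequence(sequence_spec("a0", s1, 0, rep(1, 181)), lt0)
  expect_equal(tr0$os_grid, rep(1, 181))
  expect_equal(tr0$occ_dead, rep(0, 181))
})

test_that("occupancies conserve mass and OS is nonincreasing", {
  set.seed(9)
  lt <- generate_lifetable(60, 60)
  for (i in 1:5) {
    s1 <- cumprod(c(1, stats::runif(180, 0.9, 1)))
    s2 <- cumprod(c(1, stats::runif(180, 0.92, 1)))
    a <- stats::runif(1)
    tr <- run_sequence(sequence_spec("r", s1, a, s2), lt)
    expect_lt(max(abs(tr$occ_1L + tr$occ_2L + tr$occ_dead - 1)), 1e-10)
    expect_true(all(tr$occ_1L >= 0 & tr$occ_1L <= 1))
    expect_true(all(tr$occ_2L >= 0 & tr$occ_2L <= 1))
    expect_true(all(diff(tr$os_grid) <= 1e-12))
  }
})

test_that("semi-Markov engine matches the microsimulation oracle", {
  lt0 <- zero_lifetable()
  spec <- sequence_spec("oracle", exp_grid(0.05), 0.3, exp_grid(0.03))
  tr <- run_sequence(spec, lt0)
  n <- 100000
  sim <- microsim_os(n, 0.05, 0.3, 0.03, 180, seed = 1)
  se <- sqrt(pmax(sim * (1 - sim), 1e-12) / n)
  expect_true(all(abs(tr$os_grid - sim) <= 3 * se + 1e-9))
})

test_that("second-line occupancy matches the geometric-series closed form", {
  # exponential 1L and 2L curves admit a closed-form convolution:
  # occ_2L(t) = (1-a)(1-alpha) beta^(t-1) ((alpha/beta)^t - 1)/(alpha/beta - 1)
  # with alpha = exp(-lambda1), beta = exp(-lambda2)
  lam1 <- 0.05
  lam2 <- 0.03
  a <- 0.3
  tr <- run_sequence(
    sequence_spec("geom", exp_grid(lam1), a, exp_grid(lam2)),
    zero_lifetable())
  alpha <- exp(-lam1)
  beta <- exp(-lam2)
  r <- alpha / beta
  closed <- c(0, vapply(1:180, function(t)
    (1 - a) * (1 - alpha) * beta^(t - 1) * (r^t - 1) / (r - 1),
    numeric(1)))
  expect_equal(tr$occ_2L, closed, tolerance = 1e-12)
  expect_true(all(tr$occ_2L >= 0))
})

test_that("memoryless second-line variant reads hazards at model time", {
  lt0 <- zero_lifetable()
  s1 <- exp_grid(0.05)
  s2 <- exp_grid(0.03)
  tr_sm <- run_sequence(sequence_spec("x", s1, 0.3, s2), lt0)
  tr_ml <- run_sequence(sequence_spec("x", s1, 0.3, s2), lt0,
                        second_line = "memoryless")
  # for an exponential 2L curve the two formulations coincide
  expect_equal(tr_ml$os_grid, tr_sm$os_grid, tolerance = 1e-10)
  # for a non-constant-hazard 2L curve they differ
  s2w <- exp(-(0:180 / 40)^1.5)
  s2w[1] <- 1
  tr2_sm <- run_sequence(sequence_spec("y", s1, 0.3, s2w), lt0)
  tr2_ml <- run_sequence(sequence_spec("y", s1, 0.3, s2w), lt0,
                         second_line = "memoryless")
  expect_gt(max(abs(tr2_sm$os_grid - tr2_ml$os_grid)), 1e-4)
})

test_that("life-years fall strictly as attrition rises", {
  lt0 <- zero_lifetable()
  s1 <- exp_grid(0.05)
  s2 <- exp_grid(0.03)
  ly <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(a)
    life_years(run_sequence(sequence_spec("a", s1, a, s2), lt0)),
    numeric(1))
  expect_true(all(diff(ly) < 0))
})

test_that("pointwise-dominating inputs yield a dominating OS curve", {
  lt <- generate_lifetable(60, 60)
  sA <- sequence_spec("A", exp_grid(0.04), 0.2, exp_grid(0.02))
  sB <- sequence_spec("B", exp_grid(0.06), 0.3, exp_grid(0.035))
  trA <- run_sequence(sA, lt)
  trB <- run_sequence(sB, lt)
  expect_true(all(trA$os_grid >= trB$os_grid - 1e-12))
})

test_that("median, landmarks and life-years match their scan oracles", {
  lt0 <- zero_lifetable()
  # immortal cohort: median not reached, all landmark rates 1, LY = horizon
  tr1 <- run_sequence(sequence_spec("im", rep(1, 181), 0, rep(1, 181)), lt0)
  expect_true(is.na(median_os(tr1)))
  expect_equal(unname(landmark_rates(tr1)), c(1, 1, 1))
  expect_equal(life_years(tr1), 15)

  # exponential OS with monthly hazard log(2)/60 crosses 0.5 at 60 cycles
  tr2 <- run_sequence(
    sequence_spec("exp", exp_grid(log(2) / 60), 1, rep(1, 181)), lt0)
  expect_equal(median_os(tr2), 5)

  # landmark closed form, exponential rate 0.01/month
  tr3 <- run_sequence(sequence_spec("lm", exp_grid(0.01), 1,
                                    rep(1, 181)), lt0)
  expect_equal(unname(landmark_rates(tr3, 5)), exp(-0.6), tolerance = 1e-12)
  expect_error(landmark_rates(tr3, 20), "beyond")

  # arbitrary trace: linear-scan and trapezoid oracles
  set.seed(13)
  g <- cumprod(c(1, stats::runif(180, 0.95, 1)))
  tr4 <- run_sequence(sequence_spec("rand", g, 1, rep(1, 181)), lt0,
                      background = "none")
  expect_equal(median_os(tr4) * 12, min(which(g <= 0.5)) - 1)
  expect_equal(life_years(tr4),
               sum((g[-1] + g[-181]) / 2) / 12, tolerance = 1e-12)

  # triangle area: linear descent 1 -> 0 over the horizon
  lin <- seq(1, 0, length.out = 181)
  tr5 <- run_sequence(sequence_spec("lin", lin, 1, rep(1, 181)), lt0,
                      background = "none")
  expect_equal(life_years(tr5), 7.5, tolerance = 1e-12)
})

test_that("sequence comparison tabulates pairwise differences", {
  lt0 <- zero_lifetable()
  mk <- function(rate, lab)
    run_sequence(sequence_spec(lab, exp_grid(rate), 1, rep(1, 181)), lt0)
  trs <- list(mk(0.01, "A"), mk(0.01, "B"), mk(0.02, "C"))
  cmp <- compare_sequences(trs, reference = "A")
  expect_equal(cmp$summary$d_median_vs_ref[1:2], c(0, 0))
  expect_equal(cmp$summary$d_life_years_vs_ref[2], 0)
  # pairwise matrix equals elementwise subtraction
  med <- vapply(trs, median_os, numeric(1))
  for (r in seq_len(nrow(cmp$differences))) {
    i <- match(cmp$differences$sequence[r], cmp$summary$label)
    j <- match(cmp$differences$versus[r], cmp$summary$label)
    expect_equal(cmp$differences$d_median_os_years[r], med[i] - med[j])
  }
  # printed-precision arithmetic of two medians
  expect_equal(round(8.9 - 6.92, 2), 1.98)
  expect_error(compare_sequences(trs[1]), "at least 2")
  short <- run_sequence(sequence_spec("S", exp_grid(0.01, 120), 1,
                                      rep(1, 121), horizon_cycles = 120),
                        lt0)
  expect_error(compare_sequences(list(trs[[1]], short)), "horizons")
})

test_that("cohort traces export the documented CSV layout", {
  lt0 <- zero_lifetable()
  tr <- run_sequence(sequence_spec("io", exp_grid(0.05), 0.3,
                                   exp_grid(0.03)), lt0)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, path)
  df <- utils::read.csv(path)
  expect_identical(names(df), c("cycle", "occ_1L", "occ_2L", "occ_dead",
                                "os"))
  expect_equal(df$os, tr$os_grid, tolerance = 1e-12)
})
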