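test_that("resampling to the common grid is exact for linear signals", {
  # already on the same grid: unchanged
  ses <- toy_session()
  rs <- resample_common_grid(cut_window(ses))
  expect_equal(rs$injection_curve$times, rs$contralateral_curve$times)

  # half-second offset, linear signal: interpolation is exact
  t1 <- 0:300
  t2 <- t1 + 0.5
  lin <- function(t) 2 + 0.25 * t
  ses2 <- administration_session(
    "p", 100,
    injection_curve = dose_rate_curve(t1, lin(t1), "injection"),
    contralateral_curve = dose_rate_curve(t2, lin(t2), "contralateral"),
    min_overlap = 120)
  rs2 <- resample_common_grid(ses2)
  expect_equal(rs2$contralateral_curve$values, lin(rs2$contralateral_curve$times),
               tolerance = 1e-12)
  expect_equal(rs2$injection_curve$times, rs2$contralateral_curve$times)

  # disjoint / insufficient overlap
  ses3 <- administration_session(
    "p", 100,
    injection_curve = dose_rate_curve(0:200, rep(1, 201), "injection"),
    contralateral_curve = dose_rate_curve(150:350, rep(1, 201), "contralateral"),
    min_overlap = 10)
  expect_error(resample_common_grid(ses3), "overlap")
})

test_that("delta_r_series is the pointwise arm difference", {
  t <- 0:199
  ses <- administration_session(
    "p", 100,
    injection_curve = dose_rate_curve(t, rep(500, 200), "injection"),
    contralateral_curve = dose_rate_curve(t, rep(500, 200), "contralateral"),
    min_overlap = 100)
  expect_true(all(delta_r_series(ses)$delta_r_usv_h == 0))

  ses2 <- administration_session(
    "p", 100,
    injection_curve = dose_rate_curve(t, rep(500, 200) + 390, "injection"),
    contralateral_curve = dose_rate_curve(t, rep(500, 200), "contralateral"),
    min_overlap = 100)
  expect_true(all(delta_r_series(ses2)$delta_r_usv_h == 390))

  solo <- administration_session("p", 100,
    injection_curve = dose_rate_curve(t, rep(500, 200), "injection"))
  expect_error(delta_r_series(solo), "single-detector")
})

test_that("detect_plateau finds the first stable window and errors when none exists", {
  # steps of 100 until t = 200 s, then steps of 5
  t <- 0:400
  v <- c(seq(0, by = 100, length.out = 201), seq(20005, by = 5, length.out = 200))
  expect_equal(detect_plateau(data.frame(t, v)), 200)

  # constant series: plateau at the first sample
  expect_equal(detect_plateau(data.frame(t = 0:100, v = rep(3, 101))), 0)

  # alternating +-20 per sample: never stable
  alt <- rep(c(0, 20), 200)
  expect_error(detect_plateau(data.frame(t = seq_along(alt), v = alt)),
               class = "plateau_not_reached")

  # `from` skips an early flat baseline
  v2 <- c(rep(0, 100), seq(0, by = 100, length.out = 101),
          seq(10005, by = 5, length.out = 200))
  expect_equal(detect_plateau(data.frame(t = seq_along(v2) - 1, v = v2),
                              from = 100), 200)
})

test_that("detect_plateau agrees with the brute-force window scan", {
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(100:1000, 1)
    # random walk whose step size shrinks over time so most series
    # eventually stabilise, some never do
    steps <- stats::rnorm(n - 1, sd = 40 * exp(-(1:(n - 1)) / (n / 3)))
    v <- cumsum(c(0, steps))
    t <- seq_len(n) - 1
    got <- tryCatch(detect_plateau(data.frame(t, v)), error = function(e) NA_real_)
    expect_identical(got, brute_plateau(t, v))
  }
})

test_that("metrics match closed forms on a noiseless constructed session", {
  ses <- toy_session(peak = 1000, plateau_in = 100, plateau_con = 80)
  cfg <- preprocess_config(smoothing_sigma = 0)
  m <- compute_metrics(ses, cfg)
  expect_equal(m$dr_in_max, 1000)
  expect_equal(m$dr_in_mean, 100)
  expect_equal(m$delta_p, 900)
  expect_equal(m$delta_p_nor, 0.9)
  expect_equal(m$delta_r_6min, 20)
  expect_equal(m$delta_r_nor, 20 / 1000)
  # identities (to within one ulp of the round trip)
  expect_identical(m$delta_p, m$dr_in_max - m$dr_in_mean)
  expect_equal(m$delta_p_nor * m$dr_in_max, m$delta_p, tolerance = 1e-14)
  expect_identical(m$delta_r_nor, m$delta_r_6min / m$dr_in_max)
})

test_that("normalised metrics are scale-invariant, absolute ones scale", {
  cfg <- preprocess_config(smoothing_sigma = 0)
  base <- compute_metrics(toy_session(), cfg)
  scaled_session <- toy_session(peak = 2500, plateau_in = 250, plateau_con = 200)
  sc <- compute_metrics(scaled_session, cfg)
  expect_equal(sc$delta_p_nor, base$delta_p_nor)
  expect_equal(sc$delta_r_nor, base$delta_r_nor)
  expect_equal(sc$dr_in_max, 2.5 * base$dr_in_max)
  expect_equal(sc$delta_r_6min, 2.5 * base$delta_r_6min)
})

test_that("adding a constant to both arms shifts exactly the absolute injection metrics", {
  cfg <- preprocess_config(smoothing_sigma = 0)
  m0 <- compute_metrics(toy_session(), cfg)
  shift <- 50
  m1 <- compute_metrics(toy_session(peak = 1050, plateau_in = 150,
                                    plateau_con = 130), cfg)
  # affected: the absolute injection-arm levels
  expect_equal(m1$dr_in_max, m0$dr_in_max + shift)
  expect_equal(m1$dr_in_mean, m0$dr_in_mean + shift)
  # unaffected: differences and the arm-difference metric
  expect_equal(m1$delta_p, m0$delta_p)
  expect_equal(m1$delta_r_6min, m0$delta_r_6min)
  expect_equal(m1$t_star, m0$t_star)
  # the normalisation denominators shift, so normalised metrics change
  expect_false(isTRUE(all.equal(m1$delta_p_nor, m0$delta_p_nor)))
})

test_that("raising the injection plateau lowers delta_p_nor and raises delta_r_6min", {
  cfg <- preprocess_config(smoothing_sigma = 0)
  plateaus <- c(100, 200, 300)
  res <- sapply(plateaus, function(p) {
    m <- compute_metrics(toy_session(plateau_in = p), cfg)
    c(m$delta_p_nor, m$delta_r_6min)
  })
  expect_true(all(diff(res[1, ]) < 0))
  expect_true(all(diff(res[2, ]) > 0))
})

test_that("single-detector mode computes the peak-drop family only", {
  gs <- generate_session("normal", seed = 31)
  solo <- administration_session("p", 200,
                                 injection_curve = gs$session$injection_curve)
  m <- compute_metrics(solo)
  expect_true(m$single_detector_mode)
  expect_null(m$delta_r_6min)
  expect_null(m$delta_r_nor)
  expect_true(is.finite(m$delta_p_nor))
  # close to the dual-detector value for the same injection arm
  m2 <- compute_metrics(gs$session)
  expect_equal(m$delta_p_nor, m2$delta_p_nor, tolerance = 0.05)
})
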