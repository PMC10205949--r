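test_that("generation is seed-deterministic and leaves the caller's RNG alone", {
  a <- generate_session("extravasation", seed = 7)
  b <- generate_session("extravasation", seed = 7)
  expect_identical(a$session$injection_curve$values,
                   b$session$injection_curve$values)
  expect_identical(a$truth, b$truth)

  set.seed(123); before <- runif(1)
  set.seed(123); invisible(generate_session("normal", seed = 9)); after <- runif(1)
  expect_identical(before, after)

  expect_error(generate_session("weird"))
})

test_that("noiseless sessions are exactly reproducible and recoverable end-to-end", {
  quiet <- class_curve_params(noise_cv = 0)
  gs <- generate_session("extravasation", params = quiet, seed = 13)
  # closed-form reconstruction from ground truth alone
  rebuilt <- noiseless_session(gs$truth, quiet)
  expect_equal(gs$session$injection_curve$values, rebuilt$injection,
               tolerance = 1e-12)
  expect_equal(gs$session$contralateral_curve$values, rebuilt$contralateral,
               tolerance = 1e-12)
  # the pipeline recovers the generator's ground truth
  m <- compute_metrics(gs$session)
  expect_equal(m$dr_in_max, gs$truth$dr_max, tolerance = 1e-9)
  expect_equal(m$delta_p_nor, gs$truth$delta_p_nor, tolerance = 0.01)
  expect_equal(m$delta_r_6min, gs$truth$delta_r_6min, tolerance = 5)
})

test_that("plateau noise has the configured ~10% coefficient of variation", {
  gs <- generate_session("extravasation", seed = 17)
  crv <- gs$session$injection_curve
  late <- crv$times >= 350 # last 300 s sit on the plateau
  cv <- stats::sd(crv$values[late]) / mean(crv$values[late])
  expect_gte(cv, 0.08)
  expect_lte(cv, 0.12)
})

test_that("cohorts have the requested composition and differ across master seeds", {
  coh <- generate_cohort(5, 2, 3, seed = 7)
  expect_length(coh, 10L)
  labels <- vapply(coh, function(s) s$truth$label, "")
  expect_identical(as.integer(table(labels)[c("normal", "abnormal", "extravasation")]),
                   c(5L, 2L, 3L))
  coh2 <- generate_cohort(5, 2, 3, seed = 8)
  expect_false(identical(coh[[1]]$session$injection_curve$values,
                         coh2[[1]]$session$injection_curve$values))
  expect_identical(vapply(coh2, function(s) s$truth$label, ""), labels)
  expect_error(generate_cohort(0, 0, 0))
})

test_that("phantoms integrate to the requested activity and match the Gaussian mass profile", {
  ph <- generate_phantom(5, spot_sigma = 6, shape = c(32, 32, 32),
                         voxel_size = 3, seed = 4)
  vox_ml <- prod(ph$voxel_size) / 1000
  total_mbq <- sum(ph$values) * vox_ml / 1e6
  expect_equal(total_mbq, 5, tolerance = 0.001 * 5)

  # determinism
  ph2 <- generate_phantom(5, spot_sigma = 6, shape = c(32, 32, 32),
                          voxel_size = 3, seed = 4)
  expect_identical(ph$values, ph2$values)

  # mass fraction inside the ThXX mask: brute-force integration of the
  # discretised profile against the chi-square(3) closed form of a
  # continuous 3-D Gaussian
  frac_in <- function(f) {
    mask <- ph$values >= f * max(ph$values)
    sum(ph$values[mask]) / sum(ph$values)
  }
  expect_equal(frac_in(0.40), stats::pchisq(-2 * log(0.40), df = 3),
               tolerance = 0.05)
  expect_equal(frac_in(0.10), stats::pchisq(-2 * log(0.10), df = 3),
               tolerance = 0.05)
  # Th10 captures most of the depot (>= 60%); Th40 analytically cannot
  expect_gte(frac_in(0.10), 0.6)

  expect_error(generate_phantom(5, spot_sigma = 60, shape = c(16, 16, 16),
                                voxel_size = 3), "spot larger than grid")
  expect_error(generate_phantom(-1))
})

test_that("generated cohorts reproduce the class statistics they target", {
  # medium-n recovery of the extravasation-class means (the deep 200-session
  # version lives in the acceptance suite); the peak is a single noisy
  # sample, so per-session recovery noise on delta_p_nor has SD ~ 0.06 and
  # bounds here are 3-standard-error bounds
  n <- 60
  dp <- dr <- tdp <- tdr <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    gs <- generate_session("extravasation", seed = 300 + i)
    m <- tryCatch(suppressWarnings(compute_metrics(gs$session)),
                  error = function(e) NULL)
    if (is.null(m)) next
    dp[i] <- m$delta_p_nor; dr[i] <- m$delta_r_6min
    tdp[i] <- gs$truth$delta_p_nor; tdr[i] <- gs$truth$delta_r_6min
  }
  ok <- !is.na(dp)
  expect_gt(mean(ok), 0.9)
  expect_lt(abs(mean(dp[ok] - tdp[ok])),
            3 * stats::sd(dp[ok] - tdp[ok]) / sqrt(sum(ok)))
  expect_lt(abs(mean(dr[ok] - tdr[ok])),
            3 * stats::sd(dr[ok] - tdr[ok]) / sqrt(sum(ok)))
  expect_lt(abs(mean(dp[ok]) - 0.44), 0.04)
  expect_lt(abs(mean(dr[ok]) - 390), 15)
})
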