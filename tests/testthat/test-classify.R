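test_that("fit_threshold separates a toy cohort and matches the grid oracle", {
  x <- c(0.40, 0.45, 0.85, 0.90, 0.95)
  y <- c(1, 1, 0, 0, 0)
  mod <- fit_threshold(x, y, "delta_p_nor")
  expect_gt(mod$a, 0.45)
  expect_lt(mod$a, 0.85)
  expect_identical(mod$direction, "extravasation_below")
  expect_lt(mod$k, 0)

  # grid oracle: any a in the inter-class gap classifies perfectly; the
  # fitted a must be one of the zero-error thresholds found by brute force
  grid <- seq(0.30, 1.05, by = 0.005)
  err <- sapply(grid, function(a) sum((x < a) != (y == 1)))
  zero <- range(grid[err == 0])
  expect_gte(mod$a, zero[1] - 0.005)
  expect_lte(mod$a, zero[2] + 0.005)

  expect_error(fit_threshold(x, rep(0, 5)), "both outcome classes")
  expect_error(fit_threshold(x[1:3], y[1:3]), ">= 4")
  expect_error(fit_threshold(x, c(1, 2, 0, 0, 0)), "0 or 1")
})

test_that("fit_threshold is order-invariant and exactly affine-equivariant", {
  set.seed(12)
  x <- c(rnorm(20, 0.9, 0.06), rnorm(4, 0.45, 0.05))
  y <- c(rep(0, 20), rep(1, 4))
  mod <- fit_threshold(x, y)
  perm <- sample(length(x))
  expect_equal(fit_threshold(x[perm], y[perm])$a, mod$a, tolerance = 1e-9)

  # v -> alpha v + beta maps a -> alpha a + beta and k -> k / alpha
  alpha <- 730; beta <- -12
  mod2 <- fit_threshold(alpha * x + beta, y)
  expect_equal(mod2$a, alpha * mod$a + beta, tolerance = 1e-6 * abs(alpha * mod$a))
  expect_equal(mod2$k, mod$k / alpha, tolerance = 1e-6 * abs(mod$k / alpha))
})

test_that("classify_session reproduces the three class archetypes", {
  models <- list(
    delta_p_nor = threshold_model("delta_p_nor", a = 0.61, k = -20,
                                  direction = "extravasation_below"),
    delta_r_6min = threshold_model("delta_r_6min", a = 302, k = 0.05,
                                   direction = "extravasation_above"))
  lab <- function(dp, dr) {
    as.character(classify_session(list(delta_p_nor = dp, delta_r_6min = dr),
                                  models))
  }
  expect_identical(lab(0.44, 390), "extravasation") # class means, extravasation
  expect_identical(lab(0.91, 24), "normal")         # class means, normal
  expect_identical(lab(0.77, 150), "abnormal")      # class means, abnormal

  # OR rule: either metric alone can trigger extravasation
  expect_identical(lab(0.90, 400), "extravasation")
  expect_identical(lab(0.40, 20), "extravasation")

  # a value exactly at the threshold is NOT extravasation
  expect_identical(lab(0.61, 302), "abnormal")
  expect_identical(lab(0.61, 24), "abnormal") # 0.61 < normal band edge 0.79

  # single-metric decision is flagged
  res <- classify_session(list(delta_p_nor = 0.91), models)
  expect_identical(as.character(res), "normal")
  expect_true(attr(res, "single_metric"))
})

test_that("threshold models persist through JSON", {
  tmp <- withr::local_tempfile(fileext = ".json")
  models <- list(
    delta_p_nor = fit_threshold(c(0.4, 0.45, 0.85, 0.9, 0.95),
                                c(1, 1, 0, 0, 0), "delta_p_nor"))
  write_threshold_models(models, tmp)
  back <- read_threshold_models(tmp)
  expect_equal(back$delta_p_nor$a, models$delta_p_nor$a, tolerance = 1e-12)
  expect_identical(back$delta_p_nor$direction, models$delta_p_nor$direction)
})

test_that("AUC sample size reproduces the large-sample estimate and its monotonicities", {
  spec <- sample_size_spec(auc_null = 0.80, auc_alt = 0.90, alpha = 0.05,
                           power = 0.90, prevalence = 0.06)
  n <- sample_size_auc(spec)
  expect_gte(n, 800)
  expect_lte(n, 1200)

  # power monotonicity checks
  n_easy <- sample_size_auc(sample_size_spec(auc_alt = 0.95))
  expect_lt(n_easy, n)
  n_lax_alpha <- sample_size_auc(sample_size_spec(alpha = 0.2))
  expect_lt(n_lax_alpha, n)
  # balanced classes need far fewer patients than 6% prevalence
  n_balanced <- sample_size_auc(sample_size_spec(prevalence = 0.5))
  expect_lt(n_balanced, n)
  # hypotheses approaching each other: n diverges monotonically
  gaps <- c(0.10, 0.05, 0.02)
  ns <- sapply(gaps, function(g) sample_size_auc(sample_size_spec(auc_alt = 0.80 + g)))
  expect_true(all(diff(ns) > 0))

  expect_error(sample_size_spec(auc_null = 0.9, auc_alt = 0.85))
})

test_that("balanced-prevalence advantage agrees with a rank-sum power simulation", {
  # simulation oracle: empirical AUC test power at fixed n under the
  # binormal model matched to AUC 0.9, for prevalence 0.06 vs 0.5
  set.seed(99)
  n <- 400
  mu <- sqrt(2) * qnorm(0.9) # binormal separation giving AUC = 0.9
  power_sim <- function(prev, reps = 300) {
    n_pos <- ceiling(prev * n); n_neg <- n - n_pos
    crit <- qnorm(0.95)
    mean(replicate(reps, {
      pos <- rnorm(n_pos, mu); neg <- rnorm(n_neg)
      auc_hat <- mean(outer(pos, neg, ">")) +
        0.5 * mean(outer(pos, neg, "=="))
      se0 <- sqrt(extrawatch:::auc_variance(0.8, n_pos, n_neg))
      (auc_hat - 0.8) / se0 > crit
    }))
  }
  expect_gt(power_sim(0.5), power_sim(0.06))
})
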