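# one modest cohort shared across the file (20 subjects, 60 s records)
cohort20 <- generate_cohort(20, seed = 101)
results20 <- run_cohort(cohort20, duration = 60, window_length = 30)

test_that("generated cohorts respect the covariate ranges and gender split", {
  expect_equal(nrow(cohort20), 20L)
  expect_true(all(cohort20$weight_lb >= 123 & cohort20$weight_lb <= 285.8))
  expect_true(all(cohort20$height_in >= 57 & cohort20$height_in <= 73))
  expect_true(all(cohort20$age_yr >= 29 & cohort20$age_yr <= 79))
  expect_true(all(cohort20$rr_bpm >= 12 & cohort20$rr_bpm <= 25))
  expect_true(all(cohort20$hr_bpm >= 55 & cohort20$hr_bpm <= 120))
  expect_equal(sum(cohort20$gender == "male"), 8L)
  expect_equal(sum(cohort20$gender == "female"), 12L)
})

test_that("cohort generation is seed-reproducible, n=0 is empty, ranges validated", {
  expect_identical(generate_cohort(20, seed = 101), cohort20)
  expect_equal(nrow(generate_cohort(0, seed = 1)), 0L)
  expect_error(generate_cohort(5, seed = 1, ranges = list(bogus = c(0, 1))),
               "unknown range")
  expect_error(generate_cohort(5, seed = 1, ranges = list(rr_bpm = c(9, 3))))
  # non-20 cohorts are balanced
  g <- table(generate_cohort(11, seed = 2)$gender)
  expect_lte(abs(g[["male"]] - g[["female"]]), 1)
})

test_that("a noiseless subject is measured almost exactly", {
  subj <- generate_cohort(1, seed = 7, thermal_std = 0, phase_walk_std = 0)
  res <- run_trial(subj, duration = 60, window_length = 30)
  expect_lte(abs(res$rr_error), 0.2)
  expect_lte(abs(res$hr_error), 0.5)
  expect_equal(res$rr_error, res$measured_rr - res$reference_rr)
  expect_equal(res$hr_error, res$measured_hr - res$reference_hr)
})

test_that("the manual-count reference rounds RR to whole breaths", {
  subj <- generate_cohort(1, seed = 7)
  res <- run_trial(subj, duration = 60, reference = "manual-count")
  expect_identical(res$reference_rr, round(subj$rr_bpm))
  expect_identical(res$reference_hr, subj$hr_bpm)
})

test_that("cohort-level accuracy matches the bench claim in simulation", {
  expect_lte(median(abs(results20$rr_error)), 0.5)
  # HR errors exceed RR errors in median, as in the clinic
  expect_gte(median(abs(results20$hr_error)), median(abs(results20$rr_error)))
})

test_that("covariates have no effect on accuracy by construction", {
  for (covar in c("weight_lb", "height_in", "age_yr")) {
    fit <- summary(stats::lm(abs(results20$hr_error) ~ results20[[covar]]))
    expect_gt(stats::coef(fit)[2, "Pr(>|t|)"], 0.05)
    fit_rr <- summary(stats::lm(abs(results20$rr_error) ~ results20[[covar]]))
    expect_gt(stats::coef(fit_rr)[2, "Pr(>|t|)"], 0.05)
  }
})

test_that("the covariate-effect hook does inject a weight effect", {
  ch <- generate_cohort(40, seed = 5, noise_weight_slope = 0.9)
  expect_gt(stats::cor(ch$weight_lb, ch$thermal_std_v), 0.99)
  ch0 <- generate_cohort(40, seed = 5)
  expect_true(all(ch0$thermal_std_v == ch0$thermal_std_v[1]))
})

test_that("bad posture degrades accuracy on matched seeds", {
  base <- generate_cohort(4, seed = 33, thermal_std = 1.5e-4)
  bad <- base
  bad$posture <- "Bad"
  bad$amplitude_scale <- 0.2
  res_good <- run_cohort(base, duration = 60)
  res_bad <- run_cohort(bad, duration = 60)
  tot <- function(r) abs(r$rr_error) + abs(r$hr_error)
  expect_gte(sum(tot(res_bad)), sum(tot(res_good)))
})

test_that("error_stats matches hand-computed and brute-force summaries", {
  res <- tibble::tibble(rr_error = c(0.5, 0.5, 0.5), hr_error = c(1, 2, 3))
  st <- error_stats(res)
  rr <- st[st$metric == "rr_error", ]
  expect_equal(rr$median, 0.5)
  expect_equal(rr$sd, 0)
  res2 <- tibble::tibble(rr_error = c(1, 2, 3, 4, 10), hr_error = 0)
  st2 <- error_stats(res2)
  rr2 <- st2[st2$metric == "rr_error", ]
  expect_equal(rr2$median, 3)
  expect_equal(rr2$sd, 3.5355, tolerance = 1e-4)
  # brute-force oracle on random inputs: sort-based median, explicit n-1 sd
  brute_median <- function(x) {
    s <- sort(x); n <- length(s)
    if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  }
  brute_sd <- function(x) sqrt(sum((x - sum(x) / length(x))^2) / (length(x) - 1))
  withr::with_seed(9, {
    for (rep in 1:20) {
      n <- sample(2:30, 1)
      r <- tibble::tibble(rr_error = rnorm(n), hr_error = rnorm(n, 0, 5))
      st <- error_stats(r)
      for (m in c("rr_error", "hr_error")) {
        row <- st[st$metric == m, ]
        expect_equal(row$median, brute_median(r[[m]]))
        expect_equal(row$sd, brute_sd(r[[m]]))
        expect_true(row$q1 <= row$median && row$median <= row$q3)
      }
    }
  })
})

test_that("grouping partitions the cohort without loss", {
  st <- error_stats(results20, group_by = "gender")
  expect_equal(sum(st$n[st$metric == "rr_error"]), 20L)
  st_w <- error_stats(results20, group_by = "weight",
                      bin_edges = c(123, 200, 285.8))
  expect_equal(sum(st_w$n[st_w$metric == "hr_error"]), 20L)
  expect_error(error_stats(results20, group_by = "shoe_size"), "unknown")
  expect_error(error_stats(results20[0, ]), "empty")
})

test_that("absolute-error mode reports magnitudes", {
  res <- tibble::tibble(rr_error = c(-1, 1), hr_error = c(-4, 2))
  st <- error_stats(res, error = "absolute")
  expect_equal(st$median[st$metric == "rr_error"], 1)
  expect_equal(st$median[st$metric == "hr_error"], 3)
})

test_that("drop_outliers removes exactly the largest |HR error|", {
  res <- tibble::tibble(id = 1:5, rr_error = 0,
                        hr_error = c(2, -1, 43, -3, 0.5))
  expect_identical(drop_outliers(res, "none"), res)
  kept <- drop_outliers(res, "max-abs-hr")
  expect_equal(nrow(kept), 4L)
  expect_false(3 %in% kept$id)
  # when the dropped case is a genuine extreme outlier (far beyond the
  # rest, as in the clinic), its removal tightens the remaining spread
  withr::with_seed(4, {
    for (rep in 1:25) {
      body <- rnorm(sample(3:12, 1), 0, 3)
      extreme <- sample(c(-1, 1), 1) * runif(1, 25, 45)
      r <- tibble::tibble(rr_error = 0, hr_error = c(body, extreme))
      expect_lt(sd(drop_outliers(r, "max-abs-hr")$hr_error), sd(r$hr_error))
    }
  })
})

test_that("tidy and glance summarize trial results", {
  td <- tidy(results20)
  expect_equal(nrow(td), 40L)
  expect_setequal(unique(td$metric), c("rr_error", "hr_error"))
  expect_equal(td$abs_error, abs(td$error))
  gl <- glance(results20)
  expect_equal(gl$n, 20L)
  expect_equal(gl$rr_median_abs_error, median(abs(results20$rr_error)))
})

test_that("autoplot and boxplot helpers return ggplot objects", {
  rec <- synthesize_quadrature(radar_config(), vital_profile(), duration = 5)
  expect_s3_class(autoplot(rec), "ggplot")
  ph <- arctan_demodulate(rec)
  expect_s3_class(autoplot(ph), "ggplot")
  expect_s3_class(plot_error_boxplots(results20, group_by = "gender"), "ggplot")
  expect_s3_class(plot_error_boxplots(results20, group_by = "weight"), "ggplot")
})
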