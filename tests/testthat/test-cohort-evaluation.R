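test_that("Welch t matches the textbook formula and its invariances", {
  a <- c(1, 2, 3); b <- c(1, 2, 3, 4, 5, 6)
  res <- welch_t(a, b)
  # direct-formula oracle
  se <- sqrt(var(a) / 3 + var(b) / 6)
  t_ref <- (mean(a) - mean(b)) / se
  df_ref <- se^4 / ((var(a) / 3)^2 / 2 + (var(b) / 6)^2 / 5)
  p_ref <- 2 * pt(-abs(t_ref), df_ref)
  expect_equal(res$t_stat, t_ref, tolerance = 1e-10)
  expect_equal(res$df, df_ref, tolerance = 1e-10)
  expect_equal(res$p_value, p_ref, tolerance = 1e-10)

  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_stat, 0)
  expect_equal(same$p_value, 1)

  shifted <- welch_t(a + 10, b + 10)
  expect_equal(shifted$t_stat, res$t_stat, tolerance = 1e-12)
  expect_equal(shifted$p_value, res$p_value, tolerance = 1e-12)

  expect_error(welch_t(1, b), "at least 2")
})

test_that("Pearson correlation handles exact and simulated cases", {
  x <- c(1, 2, 4, 8, 9)
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_r(x, -x)$r, -1, tolerance = 1e-12)
  expect_error(pearson_r(x, rep(3, 5)), "constant")
  expect_error(pearson_r(1:2, 2:3), "at least 3")

  # bivariate normal with true rho = 0.7: mean estimate within 0.05
  withr::with_seed(31, {
    r_hat <- replicate(500, {
      z <- rnorm(200)
      y <- 0.7 * z + sqrt(1 - 0.49) * rnorm(200)
      pearson_r(z, y)$r
    })
  })
  expect_equal(mean(r_hat), 0.7, tolerance = 0.05)
})

test_that("Kaplan-Meier/log-rank reduces correctly in degenerate and forced cases", {
  t1 <- c(2, 4, 6, 8, 10); e1 <- c(TRUE, TRUE, FALSE, TRUE, TRUE)
  km <- km_logrank(c(t1, t1), c(e1, e1), rep(c("A", "B"), each = 5))
  expect_equal(km$logrank_stat, 0, tolerance = 1e-12)
  expect_equal(km$p_value, 1, tolerance = 1e-12)

  # no censoring: KM equals the empirical survival function
  tt <- c(1, 3, 5, 7, 9, 11)
  km2 <- km_logrank(c(tt, tt + 20), rep(TRUE, 12), rep(c("A", "B"), each = 6))
  crvA <- dplyr::filter(tidy(km2), group == "A")
  expect_equal(crvA$survival, 1 - seq_len(6) / 6, tolerance = 1e-12)
  # all A times below all B times: median of A below median of B
  medA <- min(crvA$time[crvA$survival <= 0.5])
  crvB <- dplyr::filter(tidy(km2), group == "B")
  medB <- min(crvB$time[crvB$survival <= 0.5])
  expect_lt(medA, medB)

  expect_error(km_logrank(t1, e1, rep("A", 5)), "2 groups")
  expect_error(km_logrank(c(1, 2), c(FALSE, FALSE), c("A", "B")), "no events")
})

test_that("log-rank detects a threefold hazard difference in simulation", {
  detected <- vapply(1:200, function(s) {
    withr::with_seed(4000 + s, {
      time <- c(rexp(150, 3), rexp(150, 1))
      grp <- rep(c("hi", "lo"), each = 150)
      km_logrank(time, rep(TRUE, 300), grp)$p_value < 0.01
    })
  }, logical(1))
  expect_gte(mean(detected), 0.95)
})

test_that("Cox fit recovers a planted hazard ratio and rejects degenerate designs", {
  hr_in_band <- vapply(1:100, function(s) {
    withr::with_seed(5000 + s, {
      x <- rep(c(0, 1), each = 250)
      time <- rexp(500, rate = 0.05 * 2^x)
      fit <- cox_multivariate(time, rep(TRUE, 500), data.frame(x = x))
      hr <- tidy(fit)$hazard_ratio
    })
    hr >= 1.6 && hr <= 2.5
  }, logical(1))
  expect_gte(mean(hr_in_band), 0.9)

  # permuted covariate: log-HR centred at zero
  loghr <- vapply(1:60, function(s) {
    withr::with_seed(6000 + s, {
      x <- sample(rep(c(0, 1), each = 100))
      time <- rexp(200, rate = 0.05)
      log(tidy(cox_multivariate(time, rep(TRUE, 200),
                                data.frame(x = x)))$hazard_ratio)
    })
  }, numeric(1))
  expect_lt(abs(mean(loghr)), 0.1)

  withr::with_seed(9, {
    x <- rnorm(50)
    expect_error(
      cox_multivariate(rexp(50), rep(TRUE, 50),
                       data.frame(a = x, b = x)),
      "collinear")
  })
})

test_that("evaluation statistics are invariant to sample ordering", {
  withr::with_seed(40, {
    time <- rexp(80, 0.05)
    event <- runif(80) < 0.7
    grp <- sample(c("EI_H", "EI_L"), 80, replace = TRUE)
    perm <- sample(80)
  })
  a <- km_logrank(time, event, grp)
  b <- km_logrank(time[perm], event[perm], grp[perm])
  expect_equal(a$logrank_stat, b$logrank_stat, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
})
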