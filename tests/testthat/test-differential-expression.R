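ann_for <- function(m, kras_mut = integer(0), egfr_mut = integer(0)) {
  tibble::tibble(
    sample_id = colnames(m),
    egfr_status = ifelse(seq_len(ncol(m)) %in% egfr_mut,
                         "hotspot_mutant", "wild_type"),
    kras_status = ifelse(seq_len(ncol(m)) %in% kras_mut,
                         "mutant", "wild_type"))
}

test_that("KRAS-mutant samples are excluded, order preserved", {
  m <- make_expr(5, 10)
  flt <- exclude_kras_mutants(m, ann_for(m, kras_mut = c(2, 5, 9)))
  expect_equal(ncol(flt$matrix), 7)
  expect_identical(colnames(flt$matrix), colnames(m)[-c(2, 5, 9)])
  expect_identical(flt$annotation$sample_id, colnames(flt$matrix))

  ident <- exclude_kras_mutants(m, ann_for(m))
  expect_identical(ident$matrix, m)

  expect_error(exclude_kras_mutants(m, ann_for(m, kras_mut = 1:10)),
               "no samples remain")
  expect_error(exclude_kras_mutants(m, ann_for(m)[-3, ]), "S03")
})

test_that("moderated t matches a direct per-gene formula oracle to 1e-10", {
  m <- make_expr(50, 20, seed = 11)
  mutant <- rep(c(TRUE, FALSE), each = 10)
  res <- moderated_t_test(m, mutant)
  prior <- attr(res, "moderation")
  expect_gt(prior$d0, 0)
  expect_gt(prior$s0_sq, 0)
  orc <- moderated_t_oracle(m, mutant, prior$d0, prior$s0_sq)
  expect_equal(res$t_stat, unname(orc[, "t"]), tolerance = 1e-10)
  expect_equal(res$p_value, unname(orc[, "p"]), tolerance = 1e-10)
  expect_equal(res$fold_change, 2^res$log_fc, tolerance = 1e-12)
})

test_that("moderated t agrees with limma's empirical-Bayes fit", {
  skip_if_not_installed("limma")
  mutant <- rep(c(TRUE, FALSE), each = 8)
  design <- cbind(Intercept = 1, mutant = as.integer(mutant))

  # heteroskedastic genes: informative (finite d0) prior
  m <- make_expr(200, 16, seed = 5)
  m <- m * withr::with_seed(6, runif(200, 0.3, 1.5))
  res <- moderated_t_test(m, mutant)
  ebfit <- limma::eBayes(limma::lmFit(m, design))
  expect_true(is.finite(attr(res, "moderation")$d0))
  expect_equal(attr(res, "moderation")$d0, ebfit$df.prior, tolerance = 1e-6)
  expect_equal(attr(res, "moderation")$s0_sq, ebfit$s2.prior, tolerance = 1e-6)
  expect_equal(res$t_stat, unname(ebfit$t[, "mutant"]), tolerance = 1e-6)
  expect_equal(res$p_value, unname(ebfit$p.value[, "mutant"]), tolerance = 1e-6)

  # homoskedastic genes: prior degenerates to a common variance (d0 = Inf)
  m2 <- make_expr(200, 16, seed = 7, sd = 0.7)
  res2 <- moderated_t_test(m2, mutant)
  ebfit2 <- limma::eBayes(limma::lmFit(m2, design))
  expect_equal(attr(res2, "moderation")$d0, ebfit2$df.prior)
  expect_equal(attr(res2, "moderation")$s0_sq, ebfit2$s2.prior,
               tolerance = 1e-10)
  expect_equal(res2$t_stat, unname(ebfit2$t[, "mutant"]), tolerance = 1e-8)
})

test_that("degenerate and limiting cases behave as the shrinkage formula dictates", {
  m <- make_expr(10, 8, seed = 3)
  mutant <- rep(c(TRUE, FALSE), each = 4)
  m[1, ] <- rep(c(5, 6, 7, 8), 2)  # same values in both groups
  res <- moderated_t_test(m, mutant)
  expect_equal(res$t_stat[1], 0)
  expect_equal(res$p_value[1], 1)

  # d0 = Inf: every gene is scored against the common prior variance
  res_inf <- moderated_t_test(m, mutant, prior = list(d0 = Inf, s0_sq = 0.5))
  z <- (res_inf$mean_mut - res_inf$mean_wt) / sqrt(0.5 * (1 / 4 + 1 / 4))
  expect_equal(res_inf$t_stat, z, tolerance = 1e-12)

  # moderation off: ordinary pooled-variance two-sample t
  res0 <- moderated_t_test(m, mutant, moderation = FALSE)
  for (g in c(2, 5, 9)) {
    tt <- t.test(m[g, mutant], m[g, !mutant], var.equal = TRUE)
    expect_equal(res0$t_stat[g], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res0$p_value[g], tt$p.value, tolerance = 1e-10)
  }

  expect_error(moderated_t_test(m, c(TRUE, rep(FALSE, 7))), "at least 2")
})

test_that("label swap negates log_fc and t and preserves p; shifts cancel", {
  m <- make_expr(30, 12, seed = 21)
  mutant <- rep(c(TRUE, FALSE), times = c(5, 7))
  a <- moderated_t_test(m, mutant)
  b <- moderated_t_test(m, !mutant)
  expect_equal(a$log_fc, -b$log_fc, tolerance = 1e-12)
  expect_equal(a$t_stat, -b$t_stat, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)

  m2 <- m
  m2[7, ] <- m2[7, ] + 3.5
  c_ <- moderated_t_test(m2, mutant)
  expect_equal(c_$t_stat[7], a$t_stat[7], tolerance = 1e-10)
  expect_equal(c_$p_value[7], a$p_value[7], tolerance = 1e-10)
})

test_that("DEG filter applies strict p and fold-change thresholds", {
  recs <- tibble::tibble(
    gene_id = c("a", "b", "c", "d", "e"),
    p_value = c(0.005, 0.005, 0.01, 0.005, 0.0001),
    fold_change = c(1.5, 1.2, 2.0, 1 / 1.3, 1.0),
    log_fc = log2(fold_change),
    direction = ifelse(log_fc > 0, "up", "down"))
  kept <- filter_degs(recs)
  expect_identical(kept$gene_id, c("a", "d"))  # b: fc == 1.2; c: p == 0.01; e: fc 1
  expect_error(filter_degs(recs, p_max = 0), "p_max")
  expect_error(filter_degs(recs, p_max = 1.5), "p_max")
  expect_error(filter_degs(recs, fc_min = 1), "fc_min")
})
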