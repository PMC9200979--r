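# Validation regression, correlations, PCA, augmented-RCBD adjustment,
# heritability, normality diagnostics.

test_that("validation regression separates correlation from accuracy", {
  r <- validation_regression(c(1, 2, 3, 5), c(1, 2, 3, 5))
  expect_equal(r$r_squared, 1)
  expect_equal(r$mean_abs_pct_error, 0)
  expect_equal(r$slope, 1)
  # perfectly correlated but 100% off
  r2 <- validation_regression(c(1, 2, 3), c(2, 4, 6))
  expect_equal(r2$r_squared, 1, tolerance = 1e-12)
  expect_equal(r2$mean_abs_pct_error, 100)
  # four-point case against closed-form least squares
  truth <- c(1, 2, 3, 4); est <- c(1.1, 1.9, 3.2, 3.8)
  sxy <- sum((truth - mean(truth)) * (est - mean(est)))
  sxx <- sum((truth - mean(truth))^2)
  syy <- sum((est - mean(est))^2)
  r3 <- validation_regression(truth, est)
  expect_equal(r3$slope, sxy / sxx, tolerance = 1e-12)
  expect_equal(r3$intercept, mean(est) - sxy / sxx * mean(truth),
               tolerance = 1e-12)
  expect_equal(r3$r_squared, sxy^2 / (sxx * syy), tolerance = 1e-12)
  expect_equal(r3$mean_abs_pct_error,
               mean(abs(est - truth) / truth) * 100, tolerance = 1e-12)
  expect_equal(r3$max_abs_pct_error, 10, tolerance = 1e-12)
  expect_error(validation_regression(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(validation_regression(1:2, 1:2), "at least 3")
})

test_that("correlation matrix reports df = n - 2 and exact Pearson r", {
  set.seed(10)
  x <- matrix(rnorm(19 * 4), 19, 4, dimnames = list(NULL, letters[1:4]))
  cm <- correlation_matrix(x)
  expect_true(all(cm$df_matrix[upper.tri(cm$df_matrix)] == 17))  # n = 19
  expect_equal(cm$r_matrix, t(cm$r_matrix))
  expect_true(all(diag(cm$r_matrix) == 1))
  # y = 2x exactly
  z <- cbind(x = x[, 1], y = 2 * x[, 1])
  cz <- correlation_matrix(z)
  expect_equal(cz$r_matrix["x", "y"], 1, tolerance = 1e-12)
  expect_lt(cz$p_matrix["x", "y"], 1e-12)
  expect_equal(cz$stars["x", "y"], "***")
  # four-point pair against the direct formula
  a <- c(1, 2, 4, 7); b <- c(2, 1, 5, 6)
  rf <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  ca <- correlation_matrix(cbind(a, b))
  expect_equal(ca$r_matrix["a", "b"], rf, tolerance = 1e-12)
  tt <- rf * sqrt(2 / (1 - rf^2))
  expect_equal(ca$p_matrix["a", "b"], 2 * pt(-abs(tt), 2), tolerance = 1e-12)
  # constant column is marked missing, not an error
  cc <- correlation_matrix(cbind(a, const = rep(1, 4)))
  expect_true(is.na(cc$r_matrix["a", "const"]))
})

test_that("PCA eigenvalues behave like a correlation-matrix decomposition", {
  set.seed(20)
  x <- matrix(rnorm(50 * 6), 50, 6)
  p <- pca_traits(x)
  expect_equal(sum(p$eigenvalues), 6, tolerance = 1e-9)   # trace
  expect_true(all(diff(p$eigenvalues) <= 1e-12))
  expect_true(all(diff(p$cumulative_pct) >= -1e-12))
  expect_equal(p$cumulative_pct[6], 100, tolerance = 1e-9)
  # two variables: eigenvalues are 1 +/- r
  y2 <- cbind(rnorm(40), rnorm(40))
  r <- cor(y2)[1, 2]
  p2 <- pca_traits(y2)
  expect_equal(p2$eigenvalues, c(1 + abs(r), 1 - abs(r)), tolerance = 1e-9)
  # near-uncorrelated wide table: eigenvalues near 1
  big <- matrix(rnorm(10000 * 5), 10000, 5)
  expect_lt(max(abs(pca_traits(big)$eigenvalues - 1)), 0.1)
  # sign convention: largest-magnitude loading entry positive
  expect_true(all(apply(p$loadings, 2, function(l) max(l) >= abs(min(l)))))
  # affine rescaling of a column leaves the standardised PCA unchanged
  xs <- x; xs[, 1] <- xs[, 1] * 37 + 5
  expect_equal(pca_traits(xs)$eigenvalues, p$eigenvalues, tolerance = 1e-9)
  expect_error(pca_traits(cbind(c(1, NA, 3), c(1, 2, 3))), "missing")
})

test_that("Federer adjustment recovers genotype values exactly without noise", {
  # noiseless toy: mean 50, two checks, three blocks with effects that sum
  # to zero, tests in known blocks
  mu <- 50
  g_check <- c(c1 = 0, c2 = 2)
  b <- c(block_1 = -2, block_2 = 3, block_3 = -1)
  g_test <- c(t1 = 5, t2 = -3, t3 = 1)
  test_block <- c(t1 = "block_1", t2 = "block_2", t3 = "block_3")
  rec <- rbind(
    expand.grid(genotype_id = names(g_check), block_id = names(b),
                stringsAsFactors = FALSE),
    data.frame(genotype_id = names(g_test), block_id = test_block))
  rec$is_check <- rec$genotype_id %in% names(g_check)
  rec$value <- mu +
    ifelse(rec$is_check, g_check[rec$genotype_id], g_test[rec$genotype_id]) +
    b[rec$block_id]
  fit <- augmented_rcbd_adjust(rec, "value")
  expect_equal(fit$block_effects[paste0("block_", 1:3)], b,
               tolerance = 1e-12, ignore_attr = TRUE)
  adj <- setNames(fit$adjusted_means$adjusted_mean,
                  fit$adjusted_means$genotype_id)
  expect_equal(adj[names(g_test)], mu + g_test, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(adj[names(g_check)], mu + g_check, tolerance = 1e-12,
               ignore_attr = TRUE)
  # zero block effects: adjusted equals raw
  rec0 <- rec
  rec0$value <- rec0$value - b[rec0$block_id]
  fit0 <- augmented_rcbd_adjust(rec0, "value")
  raw <- tapply(rec0$value, rec0$genotype_id, mean)
  expect_equal(setNames(fit0$adjusted_means$adjusted_mean,
                        fit0$adjusted_means$genotype_id)[names(raw)],
               raw, tolerance = 1e-12, ignore_attr = TRUE)
  # a block missing a check is a design error naming the block
  broken <- rec[!(rec$genotype_id == "c2" & rec$block_id == "block_3"), ]
  expect_error(augmented_rcbd_adjust(broken, "value"), "block_3")
})

test_that("the augmented ANOVA sums of squares add to the total", {
  d <- make_trial_dataset(29, 5, 9, sigma2_G = 4, sigma2_block = 2,
                          sigma2_e = 1, seed = 31)
  fit <- augmented_rcbd_adjust(d, "value")
  an <- fit$anova
  total_direct <- sum((d$value - mean(d$value))^2)
  expect_equal(an$sum_sq[an$source == "total"], total_direct,
               tolerance = 1e-9)
  main <- an$sum_sq[an$source %in% c("blocks (ignoring genotypes)",
                                     "genotypes (adjusted)",
                                     "residual (check replication)")]
  expect_equal(sum(main), total_direct, tolerance = 1e-9)
  expect_equal(an$df[an$source == "residual (check replication)"],
               (5 - 1) * (9 - 1))
})

test_that("heritability estimates track the injected variance components", {
  # definitional check on (almost) noiseless components
  d <- make_trial_dataset(60, 5, 9, sigma2_G = 3, sigma2_block = 1,
                          sigma2_e = 1, seed = 32)
  h <- broad_sense_heritability(d, "value")
  expect_gt(h$H2, 0.55)
  expect_lt(h$H2, 0.9)
  # sigma2_G = 0: the floor keeps the estimate at or near zero
  reps <- vapply(1:20, function(s) {
    d0 <- make_trial_dataset(29, 5, 9, sigma2_G = 0, sigma2_block = 1,
                             sigma2_e = 2, seed = 100 + s)
    broad_sense_heritability(d0, "value")$H2
  }, numeric(1))
  expect_true(all(reps >= 0))
  expect_lt(mean(reps), 0.2)
  expect_error(broad_sense_heritability(
    make_trial_dataset(1, 5, 9, seed = 1), "value"), "test genotypes")
})

test_that("normality diagnostics flag non-normal samples", {
  set.seed(33)
  nm <- normality_check(rnorm(1000))
  expect_gt(nm$shapiro_W, 0.99)
  expect_equal(nrow(nm$qq), 1000)
  set.seed(33)
  ex <- normality_check(rexp(1000))
  expect_lt(ex$shapiro_W, nm$shapiro_W)
  expect_error(normality_check(rep(1, 10)), "constant")
})
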