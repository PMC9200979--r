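# ---------------------------------------------------------------------------
# Field-trial statistics: validation regression, trait correlation matrix,
# PCA, augmented-RCBD adjusted means + ANOVA, broad-sense heritability,
# normality diagnostics.
# ---------------------------------------------------------------------------

#' Validation regression of 3D estimates against ground truth
#'
#' Ordinary least squares of the estimates on the truth, with the squared
#' Pearson correlation as R^2 and per-sample absolute percentage errors
#' relative to the truth. Both mean and maximum error are reported: a
#' perfect correlation says nothing about accuracy, so the two are kept
#' separate.
#'
#' @param truth numeric vector of reference measurements (> 0).
#' @param estimates numeric vector of 3D-derived values, same length.
#' @return list with `r_squared`, `slope`, `intercept`,
#'   `mean_abs_pct_error`, `max_abs_pct_error`, `n`.
#' @export
validation_regression <- function(truth, estimates) {
  truth <- as.numeric(truth); estimates <- as.numeric(estimates)
  if (length(truth) != length(estimates)) stop("length mismatch")
  if (length(truth) < 3L) stop("need at least 3 pairs")
  if (any(truth <= 0)) stop("truth values must be positive")
  if (stats::sd(truth) == 0)
    stop("constant truth: R^2 is undefined")
  fit <- stats::lm(estimates ~ truth)
  ape <- abs(estimates - truth) / truth * 100
  list(r_squared = stats::cor(truth, estimates)^2,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       mean_abs_pct_error = mean(ape),
       max_abs_pct_error = max(ape),
       n = length(truth))
}

#' Pairwise Pearson correlation matrix with significance
#'
#' Pearson r per trait pair (pairwise complete observations), two-sided P
#' from `t = r * sqrt(df / (1 - r^2))` with `df = n - 2`, and significance
#' stars at P < 0.05 (*), < 0.01 (**), < 0.001 (***). P values are reported
#' raw; set `bonferroni = TRUE` to adjust across the upper triangle.
#'
#' @param table numeric matrix or data.frame, plants x traits.
#' @param bonferroni adjust P values for the number of pairs (default off).
#' @return list with `r_matrix`, `p_matrix`, `df_matrix`, `stars`, `n`.
#' @export
correlation_matrix <- function(table, bonferroni = FALSE) {
  x <- as.matrix(table)
  if (!is.numeric(x)) stop("table must be numeric")
  p <- ncol(x)
  r <- matrix(NA_real_, p, p, dimnames = list(colnames(x), colnames(x)))
  pv <- r; dfm <- r
  for (i in seq_len(p)) for (j in seq_len(p)) {
    ok <- stats::complete.cases(x[, i], x[, j])
    n <- sum(ok)
    if (i == j) { r[i, j] <- 1; pv[i, j] <- 0; dfm[i, j] <- n - 2; next }
    if (n < 3L || stats::sd(x[ok, i]) == 0 || stats::sd(x[ok, j]) == 0) next
    rij <- stats::cor(x[ok, i], x[ok, j])
    df <- n - 2L
    tt <- rij * sqrt(df / max(1 - rij^2, 1e-300))
    r[i, j] <- rij
    pv[i, j] <- 2 * stats::pt(-abs(tt), df)
    dfm[i, j] <- df
  }
  if (bonferroni) {
    m <- p * (p - 1) / 2
    pv[upper.tri(pv) | lower.tri(pv)] <-
      pmin(1, pv[upper.tri(pv) | lower.tri(pv)] * m)
  }
  stars <- matrix("", p, p, dimnames = dimnames(r))
  stars[!is.na(pv) & pv < 0.05] <- "*"
  stars[!is.na(pv) & pv < 0.01] <- "**"
  stars[!is.na(pv) & pv < 0.001] <- "***"
  diag(stars) <- ""
  list(r_matrix = r, p_matrix = pv, df_matrix = dfm, stars = stars,
       n = nrow(x))
}

#' Principal component analysis of a trait table
#'
#' Eigendecomposition of the correlation matrix (standardised variables;
#' the covariance matrix when `standardize = FALSE`). Loadings are reported
#' as variable-PC correlations, each column oriented so its
#' largest-magnitude entry is positive, and flagged as significant
#' contributors at |loading| > `sig_threshold`.
#'
#' @param table numeric matrix or data.frame, plants x traits, complete.
#' @param standardize analyse the correlation matrix (default `TRUE`).
#' @param sig_threshold |loading| above which a variable is flagged
#'   (default 0.45).
#' @return list with `eigenvalues`, `loadings`, `pct_variance`,
#'   `cumulative_pct`, `significant` (logical matrix), `scores`.
#' @export
pca_traits <- function(table, standardize = TRUE, sig_threshold = 0.45) {
  x <- as.matrix(table)
  if (anyNA(x))
    stop("missing values in trait table: impute or remove incomplete rows first")
  if (nrow(x) <= 2L) stop("need at least 3 rows")
  xs <- scale(x, center = TRUE, scale = standardize)
  S <- stats::cov(xs)
  eig <- eigen(S, symmetric = TRUE)
  lam <- pmax(eig$values, 0)
  # loadings as variable-PC correlations: eigenvector * sqrt(eigenvalue),
  # divided by the variable sd (1 after standardisation)
  sds <- sqrt(diag(S))
  load <- sweep(eig$vectors, 2L, sqrt(lam), `*`) / sds
  for (k in seq_len(ncol(load))) {
    if (abs(min(load[, k])) > max(load[, k])) {
      load[, k] <- -load[, k]
      eig$vectors[, k] <- -eig$vectors[, k]
    }
  }
  dimnames(load) <- list(colnames(x), paste0("PC", seq_len(ncol(load))))
  pct <- lam / sum(lam) * 100
  scores <- xs %*% eig$vectors
  colnames(scores) <- colnames(load)
  list(eigenvalues = lam, loadings = load, pct_variance = pct,
       cumulative_pct = cumsum(pct), significant = abs(load) > sig_threshold,
       scores = scores)
}

# --- augmented RCBD -------------------------------------------------------

check_design <- function(records, trait) {
  req <- c("genotype_id", "block_id", "is_check", trait)
  if (!all(req %in% names(records)))
    stop("records must have columns: ", paste(req, collapse = ", "))
  checks <- unique(records$genotype_id[records$is_check])
  blocks <- unique(records$block_id)
  if (length(checks) < 2L) stop("need at least 2 check genotypes")
  if (length(blocks) < 2L) stop("need at least 2 blocks")
  for (b in blocks) {
    present <- records$genotype_id[records$block_id == b & records$is_check]
    miss <- setdiff(checks, present)
    if (length(miss))
      stop(sprintf("design error: block '%s' is missing check(s) %s",
                   b, paste(miss, collapse = ", ")))
  }
  list(checks = checks, blocks = blocks)
}

#' Adjusted means and ANOVA for an augmented RCBD
#'
#' Federer's adjustment: block effects are estimated from the replicated
#' checks (block mean of checks minus the grand check mean, so effects sum
#' to zero over blocks); each unreplicated test entry is adjusted by
#' subtracting its block's effect, and check means are averaged over blocks.
#' The ANOVA is the sequential block-then-genotype decomposition, with the
#' genotype line partitioned into among-checks, among-tests and
#' checks-vs-tests; the residual comes entirely from check replication, and
#' the sums of squares add to the total.
#'
#' @param records data.frame with `genotype_id`, `block_id`, `is_check` and
#'   the trait column (one row per plot).
#' @param trait name of the trait column.
#' @return list with `adjusted_means` (data.frame), `block_effects`,
#'   `anova` (data.frame), `sigma2_e` (check-replication error variance).
#' @export
augmented_rcbd_adjust <- function(records, trait = "value") {
  des <- check_design(records, trait)
  y <- records[[trait]]
  blk <- as.character(records$block_id)
  gen <- as.character(records$genotype_id)
  isc <- records$is_check
  check_grand <- mean(y[isc])
  blk_means <- tapply(y[isc], blk[isc], mean)
  blk_eff <- blk_means - check_grand
  adj <- ifelse(isc, y, y - blk_eff[blk])
  adj_means <- tapply(adj, gen, mean)
  out <- data.frame(genotype_id = names(adj_means),
                    adjusted_mean = as.numeric(adj_means),
                    is_check = names(adj_means) %in% des$checks,
                    row.names = NULL, stringsAsFactors = FALSE)

  # sequential ANOVA: blocks (ignoring genotypes), genotypes, residual
  dat <- data.frame(y = y, block = factor(blk), genotype = factor(gen),
                    entry_class = factor(ifelse(isc, "check", "test")))
  fit <- stats::lm(y ~ block + genotype, data = dat)
  an <- suppressWarnings(stats::anova(fit))  # F on a saturated fit unused
  ss_block <- an["block", "Sum Sq"]; df_block <- an["block", "Df"]
  ss_gen <- an["genotype", "Sum Sq"]; df_gen <- an["genotype", "Df"]
  ss_err <- an["Residuals", "Sum Sq"]; df_err <- an["Residuals", "Df"]
  # partition the genotype line: among checks / among tests / checks vs tests
  fit2 <- stats::lm(y ~ block + entry_class + genotype, data = dat)
  an2 <- suppressWarnings(stats::anova(fit2))
  ss_cvt <- an2["entry_class", "Sum Sq"]; df_cvt <- an2["entry_class", "Df"]
  ytest <- adj[!isc]
  ss_test <- if (length(ytest) > 1L) sum((ytest - mean(ytest))^2) else 0
  df_test <- max(length(unique(gen[!isc])) - 1L, 0L)
  ss_check <- max(ss_gen - ss_cvt - ss_test, 0)
  df_check <- length(des$checks) - 1L
  sigma2_e <- ss_err / df_err
  anova_tab <- data.frame(
    source = c("blocks (ignoring genotypes)", "genotypes (adjusted)",
               "  among checks", "  among tests (adjusted)",
               "  checks vs tests", "residual (check replication)", "total"),
    df = c(df_block, df_gen, df_check, df_test, df_cvt, df_err,
           df_block + df_gen + df_err),
    sum_sq = c(ss_block, ss_gen, ss_check, ss_test, ss_cvt, ss_err,
               ss_block + ss_gen + ss_err),
    stringsAsFactors = FALSE)
  anova_tab$mean_sq <- anova_tab$sum_sq / pmax(anova_tab$df, 1)
  list(adjusted_means = out, block_effects = blk_eff, anova = anova_tab,
       sigma2_e = sigma2_e)
}

#' Broad-sense heritability from an augmented RCBD
#'
#' `H^2 = sigma2_G / (sigma2_G + sigma2_e)`. The error variance comes from
#' the check-replication residual mean square. The genotypic variance is the
#' variance among adjusted test-entry values minus the error carried by each
#' adjusted value: an adjusted test value contains the plot error plus the
#' block-effect estimation error (`sigma2_e / n_checks`, plus a small grand
#' -mean term), so that full multiplier of `sigma2_e` is subtracted;
#' negative estimates are floored at zero.
#'
#' @param records data.frame as in [augmented_rcbd_adjust()].
#' @param trait trait column name.
#' @return list with `sigma2_G`, `sigma2_e`, `H2`, `floored` (logical).
#' @export
broad_sense_heritability <- function(records, trait = "value") {
  des <- check_design(records, trait)
  n_tests <- length(unique(records$genotype_id[!records$is_check]))
  if (n_tests < 2L) stop("need at least 2 test genotypes")
  fit <- augmented_rcbd_adjust(records, trait)
  adj <- fit$adjusted_means
  ytest <- adj$adjusted_mean[!adj$is_check]
  s2e <- fit$sigma2_e
  c <- length(des$checks); J <- length(des$blocks)
  infl <- 1 + 1 / c * (1 - 1 / J)  # Var(y_adj) = s2G + s2e * infl
  s2g_raw <- stats::var(ytest) - s2e * infl
  floored <- s2g_raw < 0
  s2g <- max(s2g_raw, 0)
  H2 <- if (s2g + s2e > 0) s2g / (s2g + s2e) else 0
  list(sigma2_G = s2g, sigma2_e = s2e, H2 = min(max(H2, 0), 1),
       floored = floored)
}

#' Normality diagnostics
#'
#' Theoretical-vs-sample quantile pairs (for a normal Q-Q plot) and the
#' Shapiro-Wilk statistic as a numeric summary.
#'
#' @param values numeric vector, length >= 3, non-constant.
#' @return list with `qq` (data.frame `theoretical`, `sample`),
#'   `shapiro_W`, `shapiro_p`.
#' @export
normality_check <- function(values) {
  values <- as.numeric(values[!is.na(values)])
  if (length(values) < 3L) stop("need at least 3 values")
  if (stats::sd(values) == 0) stop("constant input: normality is undefined")
  n <- length(values)
  qq <- data.frame(
    theoretical = stats::qnorm(stats::ppoints(n)),
    sample = sort(values))
  sw <- stats::shapiro.test(if (n > 5000) sample(values, 5000) else values)
  list(qq = qq, shapiro_W = unname(sw$statistic), shapiro_p = sw$p.value)
}
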