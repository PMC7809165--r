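flat_covariates <- function(ids, responses, seed = 1) {
  out <- tibble::tibble(sample_id = ids)
  withr::with_seed(seed, {
    for (r in responses) {
      out[[paste0("cgb_", r)]] <- rnorm(length(ids))
      out[[paste0("sr_", r)]] <- rnorm(length(ids))
    }
  })
  out
}

test_that("a noiseless proportional response is recovered exactly", {
  n <- 60
  ids <- sprintf("s%d", 1:n)
  withr::with_seed(2, f <- rnorm(n))
  resp <- tibble::tibble(sample_id = ids, y = 2 * f)
  feats <- tibble::tibble(sample_id = ids, f1 = f)
  covs <- flat_covariates(ids, "y")
  des <- tibble::tibble(sample_id = ids, damline = rep(1:2, n / 2))
  out <- scan_association(resp, feats, covs, des)
  # response is standardized internally, so the slope is 2 / sd(y)
  expect_equal(out$estimate, 2 / sd(resp$y), tolerance = 1e-10)
  expect_lt(out$p_value, 1e-200)
  # all of the (standardized) response variance is absorbed; the population
  # variance convention gives (n - 1) / n of the sample variance
  expect_equal(out$var_absorbed, (n - 1) / n, tolerance = 1e-10)
})

test_that("scan coefficients and SEs match the normal-equations oracle", {
  n <- 30
  ids <- sprintf("s%d", 1:n)
  withr::with_seed(8, {
    f <- rbinom(n, 2, 0.4)
    y <- 0.4 * f + rnorm(n)
  })
  resp <- tibble::tibble(sample_id = ids, y = y)
  feats <- tibble::tibble(sample_id = ids, f1 = f)
  covs <- flat_covariates(ids, "y", seed = 9)
  des <- tibble::tibble(sample_id = ids, damline = rep(1:2, 15))
  out <- scan_association(resp, feats, covs, des)
  X <- cbind(1, f, covs$cgb_y, des$damline, covs$sr_y)
  ys <- standardize_oracle(y)
  bhat <- unname(solve(t(X) %*% X, t(X) %*% ys))
  res <- ys - X %*% bhat
  s2 <- sum(res^2) / (n - 5)
  se <- unname(sqrt(diag(solve(t(X) %*% X)) * s2))
  expect_equal(out$estimate, bhat[2], tolerance = 1e-10)
  expect_equal(out$se, se[2], tolerance = 1e-10)
  expect_equal(out$df, n - 5)
  tv <- bhat[2] / se[2]
  expect_equal(out$p_value, 2 * pt(abs(tv), n - 5, lower.tail = FALSE),
               tolerance = 1e-12)
  # nuisance coefficients come from the same full fit
  expect_equal(out$b_cgb, bhat[3], tolerance = 1e-10)
  expect_equal(out$b_damline, bhat[4], tolerance = 1e-10)
  expect_equal(out$b_sr, bhat[5], tolerance = 1e-10)
})

test_that("type-I error is calibrated at the nominal level on null features", {
  n <- 500
  ids <- sprintf("s%d", 1:n)
  withr::with_seed(101, {
    resp <- tibble::tibble(sample_id = ids, y = rnorm(n))
    fm <- matrix(rnorm(n * 2000), n, 2000,
                 dimnames = list(NULL, paste0("f", 1:2000)))
  })
  feats <- dplyr::bind_cols(tibble::tibble(sample_id = ids),
                            tibble::as_tibble(as.data.frame(fm)))
  covs <- flat_covariates(ids, "y", seed = 102)
  des <- tibble::tibble(sample_id = ids, damline = rep(1:2, n / 2))
  out <- scan_association(resp, feats, covs, des)
  rej <- mean(out$p_value < 0.05)
  expect_gte(rej, 0.04)
  expect_lte(rej, 0.06)
})

test_that("coefficients are invariant to covariate location and scale", {
  co <- small_cohort()
  dat <- chain_data()
  m <- attr(dat, "otus")[2]
  base <- scan_association(dat[c("sample_id", "bf2")],
                           dat[c("sample_id", m)],
                           dat[c("sample_id", "cgb_bf2", "sr_bf2")],
                           dat[c("sample_id", "damline")], model = "mwas")
  shifted <- dat
  shifted$cgb_bf2 <- 3 + 10 * dat$cgb_bf2
  shifted$sr_bf2 <- -2 + 0.5 * dat$sr_bf2
  moved <- scan_association(shifted[c("sample_id", "bf2")],
                            shifted[c("sample_id", m)],
                            shifted[c("sample_id", "cgb_bf2", "sr_bf2")],
                            shifted[c("sample_id", "damline")], model = "mwas")
  expect_equal(base$estimate, moved$estimate, tolerance = 1e-10)
  expect_equal(base$p_value, moved$p_value, tolerance = 1e-10)
})

test_that("the same engine serves the genotype-to-microbe scan", {
  dat <- chain_data()
  m <- attr(dat, "otus")[3]
  as_gm <- scan_association(dat[c("sample_id", m)],
                            dat[c("sample_id", "snp_1", "snp_2")],
                            dat[c("sample_id", paste0(c("cgb_", "sr_"), m))],
                            dat[c("sample_id", "damline")], model = "gm")
  as_gwas <- scan_association(dat[c("sample_id", m)],
                              dat[c("sample_id", "snp_1", "snp_2")],
                              dat[c("sample_id", paste0(c("cgb_", "sr_"), m))],
                              dat[c("sample_id", "damline")], model = "gwas")
  expect_equal(as_gm$estimate, as_gwas$estimate)
  expect_equal(as_gm$p_value, as_gwas$p_value)
  expect_equal(unique(as_gm$model), "gm")
})

test_that("monomorphic features are flagged untestable, not dropped", {
  n <- 40
  ids <- sprintf("s%d", 1:n)
  resp <- tibble::tibble(sample_id = ids, y = withr::with_seed(4, rnorm(n)))
  feats <- tibble::tibble(sample_id = ids, mono = rep(1, n),
                          ok = withr::with_seed(5, rbinom(n, 2, 0.3)))
  covs <- flat_covariates(ids, "y")
  des <- tibble::tibble(sample_id = ids, damline = rep(1:2, n / 2))
  out <- scan_association(resp, feats, covs, des)
  expect_equal(nrow(out), 2)
  expect_true(out$untestable[out$feature == "mono"])
  expect_true(is.na(out$estimate[out$feature == "mono"]))
  expect_false(out$untestable[out$feature == "ok"])
})

test_that("p-value adjustment matches the hand-computed definitions", {
  expect_equal(adjust_pvalues(0.01, "bonferroni"), 0.01)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "bonferroni"),
               c(0.03, 0.06, 0.09))
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "fdr_bh"),
               c(0.03, 0.03, 0.03))
  p <- c(0.001, 0.5, 0.04, 0.2)
  expect_true(all(adjust_pvalues(p, "bonferroni") >= p))
  expect_true(all(adjust_pvalues(p, "fdr_bh") >= p))
  expect_error(adjust_pvalues(c(0.1, NaN)), "NaN")
  expect_error(adjust_pvalues(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("variance absorbed follows the population-variance definition", {
  expect_equal(variance_absorbed(0, c(1, 5, 9)), 0)
  z <- standardize_oracle(rnorm(50))
  z <- z / sqrt(mean((z - mean(z))^2))       # population-SD 1
  expect_equal(variance_absorbed(1, z), 1, tolerance = 1e-12)
  withr::with_seed(6, x <- rnorm(200))
  x <- x * sqrt(0.5) / sqrt(mean((x - mean(x))^2))
  expect_equal(variance_absorbed(0.3, x), 0.045, tolerance = 1e-12)
  expect_error(variance_absorbed(1, numeric(0)), "empty")
})

test_that("a feature can clear FDR yet fail Bonferroni", {
  # many moderate signals: BH keeps them, Bonferroni does not
  n <- 300
  ids <- sprintf("s%d", 1:n)
  withr::with_seed(12, {
    fm <- matrix(rnorm(n * 40), n, 40, dimnames = list(NULL, paste0("f", 1:40)))
    y <- rowSums(fm[, 1:20]) * 0.12 + rnorm(n)
  })
  resp <- tibble::tibble(sample_id = ids, y = y)
  feats <- dplyr::bind_cols(tibble::tibble(sample_id = ids),
                            tibble::as_tibble(as.data.frame(fm)))
  covs <- flat_covariates(ids, "y", seed = 13)
  des <- tibble::tibble(sample_id = ids, damline = rep(1:2, n / 2))
  out <- scan_association(resp, feats, covs, des, model = "mwas")
  mixed <- out$p_fdr < 0.05 & out$p_bonferroni >= 0.05
  expect_true(any(mixed))
})
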