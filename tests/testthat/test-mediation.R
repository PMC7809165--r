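test_that("a broken first path gives a null indirect effect", {
  n <- 800
  dat <- toy_mediation_data(n, alpha = 0, beta = 0.5, gamma = 0.3, seed = 71)
  fit <- fit_mediation(dat, "p", "m", "g",
                       covariates_m = c("c1", "c3", "c2"),
                       covariates_p = c("c1", "c3", "c2"))
  expect_lt(abs(fit$alpha), 3 * fit$se_alpha)
  se_ind <- sqrt(fit$alpha^2 * fit$se_beta^2 + fit$beta^2 * fit$se_alpha^2)
  expect_lt(abs(fit$indirect), 3 * se_ind)
  expect_lt(fit$ratio, 0.5)
})

test_that("total effect decomposes exactly under matched covariates", {
  dat <- chain_data()
  covs <- covs_p_of("bf1")
  for (g in c("snp_3", "snp_5")) {
    fit <- fit_mediation(dat, "bf1", "otu_4", g,
                         covariates_m = covs, covariates_p = covs)
    total <- scan_association(dat[c("sample_id", "bf1")],
                              dat[c("sample_id", g)],
                              dat[c("sample_id", "cgb_bf1", "sr_bf1")],
                              dat[c("sample_id", "damline")])
    expect_equal(fit$gamma_dir + fit$alpha * fit$beta, total$estimate,
                 tolerance = 1e-12)
    expect_equal(fit$total_check, total$estimate, tolerance = 1e-12)
  }
})

test_that("equation-wise OLS equals brute-force joint Gaussian ML", {
  dat <- toy_mediation_data(200, alpha = 0.5, beta = 0.4, gamma = 0.1,
                            seed = 99)
  fit <- fit_mediation(dat, "p", "m", "g",
                       covariates_m = c("c1", "c3", "c2"),
                       covariates_p = c("c1", "c3", "c2"))
  # independent oracle: numerically maximize the joint normal likelihood of
  # the recursive system in all coefficients and both error variances
  P <- standardize_oracle(dat$p)
  Xm <- cbind(1, dat$g, dat$c1, dat$c3, dat$c2)
  Xp <- cbind(1, dat$m, dat$g, dat$c1, dat$c3, dat$c2)
  nll <- function(th) {
    bm <- th[1:5]; bp <- th[6:11]
    sm <- exp(th[12]); sp <- exp(th[13])
    -sum(dnorm(dat$m, Xm %*% bm, sm, log = TRUE)) -
      sum(dnorm(P, Xp %*% bp, sp, log = TRUE))
  }
  start <- c(mean(dat$m), rep(0, 4), rep(0, 6), log(sd(dat$m)), 0)
  opt <- optim(start, nll, method = "BFGS",
               control = list(maxit = 4000, reltol = 1e-16))
  opt <- optim(opt$par, nll, method = "BFGS",
               control = list(maxit = 4000, reltol = 1e-16))
  expect_lt(abs(opt$par[2] - fit$alpha), 1e-6)
  expect_lt(abs(opt$par[7] - fit$beta), 1e-6)
  expect_lt(abs(opt$par[8] - fit$gamma_dir), 1e-6)
})

test_that("the Mod2 slope differs from beta-prime by the omitted-variable adjustment", {
  dat <- chain_data()
  fit <- fit_mediation(dat, "bf1", "otu_4", "snp_3",
                       covariates_m = covs_p_of("bf1"),
                       covariates_p = covs_p_of("bf1"))
  mwas <- scan_association(dat[c("sample_id", "bf1")],
                           dat[c("sample_id", "otu_4")],
                           dat[c("sample_id", "cgb_bf1", "sr_bf1")],
                           dat[c("sample_id", "damline")], model = "mwas")
  # beta_mod2 = beta' + gamma' * delta, delta the slope of G on M after the
  # shared covariates (classical omitted-variable algebra)
  covX <- cbind(1, dat$cgb_bf1, dat$damline, dat$sr_bf1)
  rM <- qr.resid(qr(covX), dat$otu_4)
  rG <- qr.resid(qr(covX), dat$snp_3)
  delta <- sum(rM * rG) / sum(rM^2)
  expect_equal(mwas$estimate, fit$beta + fit$gamma_dir * delta,
               tolerance = 1e-10)
})

test_that("constant marker or mediator yields an untestable fit", {
  dat <- toy_mediation_data(50, seed = 3)
  dat$g <- 1
  fit <- fit_mediation(dat, "p", "m", "g",
                       covariates_m = c("c1", "c3", "c2"),
                       covariates_p = c("c1", "c3", "c2"))
  expect_true(length(fit$untestable) > 0)
  expect_true(is.na(fit$indirect))
  expect_error(sobel_test(fit), "untestable")
  expect_identical(glance(fit)$untestable, TRUE)
})

test_that("mediation ratio follows the absolute-value convention with limits", {
  fake <- function(ind, g) {
    f <- structure(list(indirect = ind, gamma_dir = g,
                        untestable = character(0)),
                   class = "path_fit")
    f
  }
  expect_equal(mediation_ratio(fake(0.2, 0.1)), 2)
  expect_equal(mediation_ratio(fake(0.1, 0.1)), 1)     # fails the strict > 1
  expect_equal(mediation_ratio(fake(-0.3, 0.1)), 3)    # sign-blind
  expect_equal(mediation_ratio(fake(0.05, 0)), Inf)    # dominant by default
  expect_equal(mediation_ratio(fake(0, 0)), 0)
})

test_that("the Sobel statistic matches its formula and symmetries", {
  fake <- function(a, sa, b, sb) {
    structure(list(alpha = a, se_alpha = sa, beta = b, se_beta = sb,
                   untestable = character(0)), class = "path_fit")
  }
  out <- sobel_test(fake(0.5, 0.1, 0.4, 0.1))
  expect_equal(out$z, 0.2 / sqrt(0.25 * 0.01 + 0.16 * 0.01),
               tolerance = 1e-10)
  expect_equal(out$z, 3.1235, tolerance = 1e-4)
  expect_lt(abs(out$p_value - 0.0018), 5e-5)
  # zero product
  out0 <- sobel_test(fake(0, 0.1, 0.4, 0.1))
  expect_equal(out0$z, 0)
  expect_equal(out0$p_value, 1)
  # sign antisymmetry
  pos <- sobel_test(fake(0.5, 0.1, 0.4, 0.1))
  neg <- sobel_test(fake(-0.5, 0.1, 0.4, 0.1))
  expect_equal(neg$z, -pos$z)
  expect_equal(neg$p_value, pos$p_value)
})

test_that("the vectorized path scan reproduces the per-triple fit", {
  dat <- chain_data()
  scan <- scan_mediation(dat, "bf1", "otu_4", paste0("snp_", 1:8),
                         covariates_m = covs_m_of("otu_4"),
                         covariates_p = covs_p_of("bf1"))
  for (g in c("snp_1", "snp_3", "snp_7")) {
    fit <- fit_mediation(dat, "bf1", "otu_4", g,
                         covariates_m = covs_m_of("otu_4"),
                         covariates_p = covs_p_of("bf1"))
    row <- scan[scan$marker == g, ]
    expect_equal(row$alpha, fit$alpha, tolerance = 1e-10)
    expect_equal(row$se_alpha, fit$se_alpha, tolerance = 1e-10)
    expect_equal(row$beta, fit$beta, tolerance = 1e-10)
    expect_equal(row$se_beta, fit$se_beta, tolerance = 1e-10)
    expect_equal(row$gamma_dir, fit$gamma_dir, tolerance = 1e-10)
    expect_equal(row$se_gamma_dir, fit$se_gamma_dir, tolerance = 1e-10)
    expect_equal(row$ratio, fit$ratio, tolerance = 1e-10)
    expect_equal(row$sobel_z, sobel_test(fit)$z, tolerance = 1e-10)
  }
})

test_that("tidy and glance expose both equations coherently", {
  dat <- chain_data()
  fit <- fit_mediation(dat, "bf1", "otu_4", "snp_3",
                       covariates_m = covs_m_of("otu_4"),
                       covariates_p = covs_p_of("bf1"))
  td <- tidy(fit)
  expect_setequal(unique(td$equation), c("mediator", "phenotype"))
  expect_equal(td$estimate[td$equation == "mediator" & td$term == "alpha"],
               fit$alpha)
  gl <- glance(fit)
  expect_equal(gl$indirect, fit$alpha * fit$beta)
  expect_equal(gl$sobel_z, sobel_test(fit)$z)
})
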