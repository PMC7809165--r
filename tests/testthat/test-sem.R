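one_factor_data <- function(n, loadings = c(1, 0.8, 0.6), uniq = 0.5,
                            seed = 1, eta_sd = 1) {
  withr::with_seed(seed, {
    eta <- rnorm(n, 0, eta_sd)
    out <- tibble::tibble(.rows = n)
    for (i in seq_along(loadings)) {
      out[[paste0("i", i)]] <- loadings[i] * eta +
        rnorm(n, 0, sqrt(uniq[min(i, length(uniq))]))
    }
    out
  })
}

test_that("an exactly identified model reproduces the sample covariance (F = 0)", {
  withr::with_seed(41, {
    dat <- tibble::tibble(g = rbinom(300, 2, 0.3))
    dat$y <- 0.4 * dat$g + rnorm(300)
  })
  spec <- latent_spec("pi1", "y")        # degenerate: latent == indicator
  fit <- fit_sem(dat, spec, "mod1L", marker = "g", damline = NULL)
  expect_lt(fit$discrepancy, 1e-8)
  expect_equal(unname(fit$sigma_hat), unname(fit$sample_cov),
               tolerance = 1e-5)
})

test_that("loadings and structural effects are recovered in simulation", {
  dat <- one_factor_data(2000, loadings = c(1, 0.8, 0.6), uniq = 0.5,
                         seed = 42)
  fit <- fit_sem(dat, latent_spec("f", c("i1", "i2", "i3")), "cfa")
  est <- fit$estimates
  l2 <- est[est$label == "loading_i2", ]
  l3 <- est[est$label == "loading_i3", ]
  expect_lt(abs(l2$estimate - 0.8), 3 * l2$se)
  expect_lt(abs(l3$estimate - 0.6), 3 * l3$se)
  for (u in paste0("uniq_i", 1:3)) {
    row <- est[est$label == u, ]
    expect_lt(abs(row$estimate - 0.5), 3 * row$se)
  }
  expect_true(fit$convergence$information_ok)   # locally identified
  expect_false(fit$heywood)
})

test_that("the measurement model agrees with dedicated ML factor analysis", {
  dat <- one_factor_data(1500, loadings = c(1, 0.9, 0.7), uniq = c(0.6, 0.5, 0.4),
                         seed = 43)
  std <- dplyr::mutate(dat, dplyr::across(dplyr::everything(),
                                          standardize_oracle))
  fit <- fit_sem(std, latent_spec("f", c("i1", "i2", "i3")), "cfa")
  est <- fit$estimates
  lam <- c(1, est$estimate[est$label == "loading_i2"],
           est$estimate[est$label == "loading_i3"])
  psi <- est$estimate[est$label == "dist_pi"]
  uniq <- est$estimate[match(paste0("uniq_i", 1:3), est$label)]
  implied_sd <- sqrt(lam^2 * psi + uniq)
  std_loadings <- lam * sqrt(psi) / implied_sd
  fa <- factanal(covmat = stats::cov(as.matrix(std)), factors = 1,
                 n.obs = nrow(std))
  expect_equal(abs(std_loadings), abs(unname(fa$loadings[, 1])),
               tolerance = 1e-4)
})

test_that("the latent regression collapses to OLS on the indicator mean as uniqueness vanishes", {
  n <- 1500
  withr::with_seed(44, {
    g <- rbinom(n, 2, 0.4)
    eta <- 0.3 * g + rnorm(n)
    dat <- tibble::tibble(g = g,
                          i1 = eta + rnorm(n, 0, 1e-4),
                          i2 = eta + rnorm(n, 0, 1e-4),
                          i3 = eta + rnorm(n, 0, 1e-4))
  })
  fit <- fit_sem(dat, latent_spec("f", c("i1", "i2", "i3")), "mod1L",
                 marker = "g", damline = NULL)
  ols <- coef(lm(rowMeans(dat[c("i1", "i2", "i3")]) ~ dat$g))[2]
  expect_equal(sem_gamma <- fit$estimates$estimate[
    fit$estimates$label == "gamma"], unname(ols), tolerance = 1e-3)
  expect_true(fit$heywood)   # uniquenesses at the boundary, by construction
})

test_that("the fit is invariant to indicator ordering up to the scale constraint", {
  dat <- one_factor_data(1000, loadings = c(1, 0.8, 0.6), uniq = 0.5,
                         seed = 45)
  f1 <- fit_sem(dat, latent_spec("f", c("i1", "i2", "i3")), "cfa")
  f2 <- fit_sem(dat, latent_spec("f", c("i2", "i3", "i1")), "cfa")
  std_solution <- function(fit, items) {
    est <- fit$estimates
    lam <- vapply(items, function(it) {
      r <- est$estimate[est$label == paste0("loading_", it)]
      if (length(r)) r else 1
    }, numeric(1))
    psi <- est$estimate[est$label == "dist_pi"]
    uniq <- est$estimate[match(paste0("uniq_", items), est$label)]
    lam * sqrt(psi) / sqrt(lam^2 * psi + uniq)
  }
  s1 <- std_solution(f1, c("i1", "i2", "i3"))
  s2 <- std_solution(f2, c("i1", "i2", "i3"))
  expect_equal(s1, s2, tolerance = 1e-4)
})

test_that("the full structural model carries the latent indirect effect", {
  n <- 1200
  withr::with_seed(46, {
    g <- rbinom(n, 2, 0.3)
    m <- 0.5 * g + rnorm(n)
    eta <- 0.4 * m + rnorm(n, 0, 0.8)     # mediated-only chain to the factor
    dat <- tibble::tibble(g = g, m = m,
                          i1 = eta + rnorm(n, 0, sqrt(0.5)),
                          i2 = 0.8 * eta + rnorm(n, 0, sqrt(0.5)),
                          i3 = 0.6 * eta + rnorm(n, 0, sqrt(0.5)))
  })
  fit <- fit_sem(dat, latent_spec("f", c("i1", "i2", "i3")), "mod4L",
                 marker = "g", mediator = "m", damline = NULL)
  est <- fit$estimates
  a <- est[est$label == "alpha", ]
  b <- est[est$label == "beta", ]
  gd <- est[est$label == "gamma_dir", ]
  expect_lt(abs(a$estimate - 0.5), 3 * a$se)
  expect_lt(abs(b$estimate - 0.4), 3 * b$se)
  expect_lt(abs(gd$estimate - 0), 3 * gd$se)
  ind <- indirect_effect_latent(fit)
  se_ind <- sqrt(a$estimate^2 * b$se^2 + b$estimate^2 * a$se^2)
  expect_lt(abs(ind - 0.2), 3 * se_ind)
  # null first path: the indirect effect vanishes
  withr::with_seed(47, dat0 <- dplyr::mutate(dat, m = rnorm(n)))
  fit0 <- fit_sem(dat0, latent_spec("f", c("i1", "i2", "i3")), "mod4L",
                  marker = "g", mediator = "m", damline = NULL)
  a0 <- fit0$estimates[fit0$estimates$label == "alpha", ]
  expect_lt(abs(indirect_effect_latent(fit0)), 3 * abs(a0$se * 0.5) + 0.05)
})

test_that("the latent indirect effect is a state error outside the full model", {
  dat <- one_factor_data(400, seed = 48)
  dat$g <- withr::with_seed(48, rbinom(400, 2, 0.3))
  fit <- fit_sem(dat, latent_spec("f", c("i1", "i2", "i3")), "mod1L",
                 marker = "g", damline = NULL)
  expect_error(indirect_effect_latent(fit), "mod4L")
})

test_that("degenerate one-indicator constructs reduce to the measured path model", {
  dat <- chain_data()
  m <- "otu_4"
  pf <- fit_mediation(dat, "bf4", m, "snp_2",
                      covariates_m = covs_m_of(m),
                      covariates_p = covs_p_of("bf4"))
  std <- dplyr::mutate(dat, bf4 = standardize_oracle(bf4))
  sf <- fit_sem(std, latent_spec("pi1", "bf4", cgb = "cgb_bf4", sr = "sr_bf4"),
                "mod4L", marker = "snp_2", mediator = m,
                mediator_covariates = paste0(c("cgb_", "sr_"), m))
  expect_equal(sem_indirect <- indirect_effect_latent(sf),
               pf$indirect, tolerance = 1e-4)
  lab <- sf$estimates$label
  expect_equal(sf$estimates$estimate[lab == "alpha"], pf$alpha,
               tolerance = 1e-4)
  expect_equal(sf$estimates$estimate[lab == "beta"], pf$beta,
               tolerance = 1e-4)
  expect_equal(sf$estimates$estimate[lab == "gamma_dir"], pf$gamma_dir,
               tolerance = 1e-4)
})
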