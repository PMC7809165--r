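one_way_design <- function(k, r, pen_sd, noise_sd = 1, seed = 1) {
  withr::with_seed(seed, {
    pen_eff <- rnorm(k, 0, pen_sd)
    tibble::tibble(
      sample_id = sprintf("s%d", seq_len(k * r)),
      y = rep(pen_eff, each = r) + rnorm(k * r, 0, noise_sd),
      cg = "cg_1", damline = 1, sire = "sire_1",
      pen = rep(sprintf("pen_%d", seq_len(k)), each = r))
  })
}

test_that("REML variance components match closed-form ANOVA on a balanced one-way design", {
  k <- 8; r <- 6
  df <- one_way_design(k, r, pen_sd = 1.2, seed = 11)
  fit <- fit_design_model(df, "y")
  # closed form on the standardized response (the model standardizes y)
  y <- (df$y - mean(df$y)) / sd(df$y)
  means <- tapply(y, df$pen, mean)
  msb <- r * sum((means - mean(y))^2) / (k - 1)
  msw <- sum((y - means[df$pen])^2) / (k * (r - 1))
  expect_equal(fit$varcomp$variance[2], msw, tolerance = 1e-6)
  expect_equal(fit$varcomp$variance[1], max((msb - msw) / r, 0),
               tolerance = 1e-6)
})

test_that("with no pen signal the fit degenerates to OLS on the fixed effects", {
  co <- small_cohort()
  df <- dplyr::mutate(co$design, y = withr::with_seed(21, {
    0.5 * (cg == "cg_03") + 0.2 * damline + rnorm(dplyr::n(), 0, 1)
  }))
  fit <- fit_design_model(df, "y")
  expect_lt(fit$varcomp$variance[1], 1e-6)
  ols <- lm(standardize_oracle(df$y) ~ cg + damline + sire,
            data = dplyr::mutate(df, cg = factor(cg), sire = factor(sire)))
  cf <- coef(ols)
  expect_equal(fit$solutions$intercept, unname(cf["(Intercept)"]),
               tolerance = 1e-5)
  expect_equal(fit$solutions$damline, unname(cf["damline"]), tolerance = 1e-5)
  got <- fit$solutions$cg$estimate[fit$solutions$cg$level == "cg_03"]
  expect_equal(got, unname(cf["cgcg_03"]), tolerance = 1e-5)
})

test_that("pen BLUPs shrink toward zero and approach raw pen deviations as signal grows", {
  raw_dev <- function(df) {
    y <- (df$y - mean(df$y)) / sd(df$y)
    tapply(y, df$pen, mean) - mean(y)
  }
  weak <- one_way_design(3, 10, pen_sd = 0.3, seed = 5)
  strong <- one_way_design(3, 10, pen_sd = 30, seed = 5)
  f_w <- fit_design_model(weak, "y")
  f_s <- fit_design_model(strong, "y")
  dev_w <- raw_dev(weak)[f_w$blup$level]
  dev_s <- raw_dev(strong)[f_s$blup$level]
  ratio_w <- f_w$blup$estimate / dev_w
  ratio_s <- f_s$blup$estimate / dev_s
  expect_true(all(ratio_w > 0 & ratio_w < 1))       # shrunk toward zero
  expect_true(all(ratio_s > ratio_w))               # less shrinkage
  expect_true(all(ratio_s > 0.95))                  # near the raw deviations
})

test_that("collapsed covariates equal the incidence-matrix products, standardized", {
  co <- small_cohort()
  df <- dplyr::mutate(co$design,
                      y = withr::with_seed(33, rnorm(dplyr::n())))
  fit <- fit_design_model(df, "y")
  cc <- collapse_covariates(fit, df)
  cg_sol <- setNames(fit$solutions$cg$estimate, fit$solutions$cg$level)
  pen_sol <- setNames(fit$blup$estimate, fit$blup$level)
  sire_sol <- setNames(fit$solutions$sire$estimate, fit$solutions$sire$level)
  manual_cgb <- cg_sol[df$cg] + pen_sol[df$pen]      # X_cg b_cg + Z_p u_p
  manual_sr <- sire_sol[df$sire]                     # X_s b_s
  expect_equal(cc$cgb, unname(standardize_oracle(manual_cgb)),
               tolerance = 1e-9)
  expect_equal(cc$sr, unname(standardize_oracle(manual_sr)), tolerance = 1e-9)
  expect_equal(mean(cc$cgb), 0, tolerance = 1e-9)
  expect_equal(sd(cc$cgb), 1, tolerance = 1e-9)
  expect_equal(mean(cc$sr), 0, tolerance = 1e-9)
  expect_equal(sd(cc$sr), 1, tolerance = 1e-9)
  # individuals sharing contemporary group and pen share the covariate
  same <- which(df$cg == df$cg[1] & df$pen == df$pen[1])
  expect_true(all(cc$cgb[same] == cc$cgb[same[1]]))
  expect_error(collapse_covariates(fit, dplyr::mutate(df, cg = "cg_99")),
               "unseen")
})

test_that("collapse_design yields one standardized pair per response, stable under row permutation", {
  co <- small_cohort()
  covs <- collapse_design(co$phenotypes, co$design)
  expect_setequal(setdiff(names(covs), "sample_id"),
                  c(paste0("cgb_", c("bf1", "bf2", "bf3", "bf4", "bft", "bel")),
                    paste0("sr_", c("bf1", "bf2", "bf3", "bf4", "bft", "bel"))))
  for (col in setdiff(names(covs), "sample_id")) {
    expect_equal(mean(covs[[col]]), 0, tolerance = 1e-9)
    expect_equal(sd(covs[[col]]), 1, tolerance = 1e-9)
  }
  perm <- withr::with_seed(3, sample(nrow(co$phenotypes)))
  covs_p <- collapse_design(co$phenotypes[perm, ], co$design)
  reord <- covs_p[match(covs$sample_id, covs_p$sample_id), ]
  expect_equal(reord$cgb_bf1, covs$cgb_bf1, tolerance = 1e-8)
  expect_equal(reord$sr_bel, covs$sr_bel, tolerance = 1e-8)
  vc <- attr(covs, "varcomp")
  expect_equal(nrow(vc), 6)
  expect_true(all(vc$var_pen >= 0) && all(vc$var_residual >= 0))
})
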