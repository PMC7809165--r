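#' Fit the recursive mediation path model
#'
#' The two-equation path model for one marker-microbe-phenotype triple:
#'
#' \deqn{M = \alpha' G + b_1 CGb_m + b_2 D + b_3 Sr_m + \epsilon_m}
#' \deqn{P = \beta' M + \gamma' G + b_1 CGb_p + b_2 D + b_3 Sr_p + \epsilon_p}
#'
#' The system is triangular (M never depends on P) with uncorrelated
#' equation errors, so equation-wise OLS is the maximum-likelihood solution
#' of the joint Gaussian model; that is what is computed, with classical
#' standard errors per equation. The indirect (mediated) effect is the
#' product \eqn{\alpha' \beta'}; with matched covariate sets in both
#' equations the total GWAS effect decomposes exactly as
#' \eqn{\gamma = \gamma' + \alpha' \beta'}.
#'
#' @param data Tibble holding all columns referenced below.
#' @param response Phenotype column (standardized before fitting).
#' @param mediator CLR microbial feature column.
#' @param marker Dosage column (0/1/2).
#' @param covariates_m Character vector of the three mediator-equation
#'   covariates, in order (CGb of the mediator, dam line, Sr of the
#'   mediator).
#' @param covariates_p Same for the phenotype equation.
#' @return A `path_fit`: estimates and SEs for `alpha`, `beta`, `gamma_dir`
#'   (the direct effect \eqn{\gamma'}), the nuisance coefficients, residual
#'   variances, `indirect = alpha * beta`, `total_check = gamma_dir +
#'   indirect` and the mediation ratio. Supports [tidy()] and [glance()].
#' @examples
#' cohort <- simulate_cohort(sim_config(
#'   n_individuals = 200, n_markers = 4, n_otus = 6, n_pens = 40,
#'   effects = list(alpha = data.frame(marker = "snp_1", otu = "otu_2",
#'                                     effect = 0.5),
#'                  beta = data.frame(otu = "otu_2", response = "bf1",
#'                                    effect = 0.4)),
#'   seed = 11))
#' dat <- mediation_data(cohort)
#' fit <- fit_mediation(dat, "bf1", "otu_2", "snp_1",
#'                      covariates_m = c("cgb_otu_2", "damline", "sr_otu_2"),
#'                      covariates_p = c("cgb_bf1", "damline", "sr_bf1"))
#' glance(fit)
#' @export
fit_mediation <- function(data, response, mediator, marker,
                          covariates_m, covariates_p) {
  cols <- c(response, mediator, marker, covariates_m, covariates_p)
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    abort(paste0("missing columns: ", paste(missing, collapse = ", ")))
  }
  P <- standardize(data[[response]])
  M <- data[[mediator]]
  G <- data[[marker]]
  untestable <- character(0)
  if (stats::sd(G) == 0) untestable <- c(untestable, "constant marker")
  if (stats::sd(M) == 0) untestable <- c(untestable, "constant mediator")
  if (length(untestable)) {
    return(new_path_fit(response, mediator, marker, untestable = untestable,
                        n = length(P)))
  }
  Xm <- cbind(1, G, as.matrix(data[covariates_m]))
  colnames(Xm) <- c("(Intercept)", "alpha", paste0("b", 1:3))
  eq_m <- ols_equation(M, Xm)
  Xp <- cbind(1, M, G, as.matrix(data[covariates_p]))
  colnames(Xp) <- c("(Intercept)", "beta", "gamma_dir", paste0("b", 1:3))
  eq_p <- ols_equation(P, Xp)
  new_path_fit(response, mediator, marker, eq_m = eq_m, eq_p = eq_p,
               n = length(P))
}

# Classical OLS with coefficient covariance; returns estimates, SEs and the
# residual variance (ML convention divide-by-n is NOT used here: classical
# sigma^2 = RSS / (n - p) feeds the t-style standard errors).
ols_equation <- function(y, X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) abort("rank-deficient design in path equation")
  est <- qr.coef(qrX, y)
  res <- qr.resid(qrX, y)
  n <- length(y); p <- ncol(X)
  s2 <- sum(res^2) / (n - p)
  XtX_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(diag(XtX_inv) * s2)
  names(se) <- colnames(X)
  list(estimate = est, se = se, sigma2 = s2, df = n - p, residuals = res)
}

new_path_fit <- function(response, mediator, marker, eq_m = NULL, eq_p = NULL,
                         untestable = character(0), n = NA_integer_) {
  out <- list(response = response, mediator = mediator, marker = marker,
              eq_m = eq_m, eq_p = eq_p, untestable = untestable, n = n)
  if (is.null(eq_m)) {
    out[c("alpha", "beta", "gamma_dir", "indirect", "total_check")] <-
      NA_real_
  } else {
    a <- unname(eq_m$estimate["alpha"])
    b <- unname(eq_p$estimate["beta"])
    g <- unname(eq_p$estimate["gamma_dir"])
    out$alpha <- a
    out$beta <- b
    out$gamma_dir <- g
    out$se_alpha <- unname(eq_m$se["alpha"])
    out$se_beta <- unname(eq_p$se["beta"])
    out$se_gamma_dir <- unname(eq_p$se["gamma_dir"])
    out$indirect <- a * b
    out$total_check <- g + a * b
  }
  class(out) <- "path_fit"
  out$ratio <- if (is.null(eq_m)) NA_real_ else mediation_ratio(out)
  out
}

#' Mediation ratio
#'
#' Magnitude of the indirect over the direct effect,
#' \eqn{|\alpha'\beta'| / |\gamma'|}. The absolute-value convention keeps
#' opposite-sign dominant mediation (a mediated path masking a direct one)
#' in play. When the direct effect is exactly zero but the indirect is not,
#' `Inf` is returned: the mediated path trivially dominates. When both are
#' zero the ratio is 0 and the fit is flagged untestable for this screen.
#'
#' @param fit A `path_fit`.
#' @return Non-negative ratio (possibly `Inf`). Candidates pass the
#'   screening rule when strictly greater than 1.
#' @export
mediation_ratio <- function(fit) {
  stopifnot(inherits(fit, "path_fit"))
  ind <- fit$indirect
  g <- fit$gamma_dir
  if (is.na(ind) || is.na(g)) return(NA_real_)
  if (g == 0) {
    if (ind == 0) {
      fit$untestable <- c(fit$untestable, "zero direct and indirect effect")
      return(0)
    }
    return(Inf)
  }
  abs(ind) / abs(g)
}

#' Sobel test of the mediated effect
#'
#' Normal-approximation test of the product \eqn{\alpha'\beta'}:
#' \deqn{z = \frac{\alpha'\beta'}
#'   {\sqrt{\alpha'^2 SE_{\beta'}^2 + \beta'^2 SE_{\alpha'}^2}}}
#' with a two-sided normal p-value. The sampling distribution of a product
#' of coefficients is generally non-normal, which is why the empirical
#' bootstrap and permutation tests ([bootstrap_test()],
#' [permutation_test()]) are the confirmatory instruments; Sobel remains the
#' fast deterministic screen.
#'
#' @param fit A `path_fit` with positive standard errors.
#' @return Tibble with columns `z` and `p_value`.
#' @export
sobel_test <- function(fit) {
  stopifnot(inherits(fit, "path_fit"))
  if (length(fit$untestable)) abort("untestable fit (constant marker or mediator)")
  a <- fit$alpha; b <- fit$beta
  sa <- fit$se_alpha; sb <- fit$se_beta
  if (any(c(sa, sb) <= 0)) abort("standard errors must be positive")
  denom <- sqrt(a^2 * sb^2 + b^2 * sa^2)
  num <- a * b
  if (denom == 0) {
    if (num != 0) abort("zero Sobel denominator with nonzero product")
    return(tibble::tibble(z = 0, p_value = 1))
  }
  z <- num / denom
  tibble::tibble(z = z, p_value = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
}

#' @export
print.path_fit <- function(x, ...) {
  cat(sprintf("<path_fit> %s -> %s -> %s (n = %s)\n", x$marker, x$mediator,
              x$response, x$n))
  if (length(x$untestable)) {
    cat("  untestable:", paste(x$untestable, collapse = "; "), "\n")
    return(invisible(x))
  }
  cat(sprintf("  alpha' = %.4f (SE %.4f), beta' = %.4f (SE %.4f), gamma' = %.4f (SE %.4f)\n",
              x$alpha, x$se_alpha, x$beta, x$se_beta, x$gamma_dir,
              x$se_gamma_dir))
  cat(sprintf("  indirect = %.4f, ratio = %.3f\n", x$indirect, x$ratio))
  invisible(x)
}

#' @method tidy path_fit
#' @export
tidy.path_fit <- function(x, ...) {
  if (length(x$untestable)) {
    return(tibble::tibble(equation = character(0), term = character(0),
                          estimate = numeric(0), std.error = numeric(0)))
  }
  eq <- function(e, label) {
    tibble::tibble(equation = label, term = names(e$estimate),
                   estimate = unname(e$estimate), std.error = unname(e$se)) |>
      dplyr::mutate(statistic = .data$estimate / .data$std.error,
                    p.value = 2 * stats::pt(abs(.data$statistic), e$df,
                                            lower.tail = FALSE))
  }
  dplyr::bind_rows(eq(x$eq_m, "mediator"), eq(x$eq_p, "phenotype"))
}

#' @method glance path_fit
#' @export
glance.path_fit <- function(x, ...) {
  sob <- if (length(x$untestable)) {
    tibble::tibble(z = NA_real_, p_value = NA_real_)
  } else {
    sobel_test(x)
  }
  tibble::tibble(marker = x$marker, mediator = x$mediator,
                 response = x$response,
                 alpha = x$alpha, beta = x$beta, gamma_dir = x$gamma_dir,
                 indirect = x$indirect, total_check = x$total_check,
                 ratio = x$ratio, sobel_z = sob$z, sobel_p = sob$p_value,
                 n = x$n,
                 untestable = length(x$untestable) > 0)
}
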