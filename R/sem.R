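#' Specify a latent construct and its nuisance adjusters
#'
#' A latent phenotype (e.g. lifetime or terminal fat deposition) is measured
#' by three correlated indicators. Its nuisance adjustment re-uses the
#' collapsed design covariates of those indicators: the three per-trait
#' `cgb` columns load on one latent adjuster (`CG` construct) and the three
#' `sr` columns on another (`Sr` construct), both with loadings estimated
#' during the fit. Identification follows the marker-variable convention:
#' the first indicator of every construct has its loading fixed to 1.
#'
#' A single-indicator spec is accepted as the degenerate limit (loading 1,
#' uniqueness fixed to 0, so the "latent" equals its indicator); this is the
#' bridge to the measured-variable path model.
#'
#' @param factor Name of the latent construct (e.g. `"fatt"`).
#' @param indicators Character vector of indicator columns (3 in the
#'   intended use).
#' @param cgb,sr Character vectors of the per-indicator collapsed
#'   covariates forming the latent adjusters, or `NULL` to omit adjusters.
#' @return A `latent_spec`.
#' @export
latent_spec <- function(factor, indicators, cgb = NULL, sr = NULL) {
  stopifnot(is.character(indicators), length(indicators) >= 1)
  if (length(indicators) == 2) {
    warn("two-indicator constructs are not identified on their own")
  }
  if (!is.null(cgb)) stopifnot(length(cgb) >= 1)
  if (!is.null(sr)) stopifnot(length(sr) >= 1)
  structure(list(factor = factor, indicators = indicators,
                 cgb = cgb, sr = sr,
                 identification = "first loading fixed to 1"),
            class = "latent_spec")
}

# ---------------------------------------------------------------------------
# RAM machinery: Sigma(theta) = F (I - A)^-1 S (I - A)^-T F' over all
# variables (observed then latent). Parameters live in a table with one row
# per (matrix, row, col) slot; free variance-type parameters are optimized on
# the log scale so uniquenesses and disturbances stay non-negative.
# ---------------------------------------------------------------------------

ram_param <- function(mat, row, col, label, free = TRUE, start = 0,
                      vtype = "coef") {
  tibble::tibble(mat = mat, row = row, col = col, label = label,
                 free = free, start = start, vtype = vtype)
}

build_sem_model <- function(data, spec, model, marker, mediator,
                            mediator_covariates, damline) {
  stopifnot(inherits(spec, "latent_spec"))
  ind <- spec$indicators
  one_ind <- length(ind) == 1L
  obs <- ind
  lat <- spec$factor
  use_adj <- !is.null(spec$cgb)
  if (use_adj) {
    obs <- c(obs, spec$cgb, spec$sr)
    lat <- c(lat, ".cg_adj", ".sr_adj")
  }
  predictors <- character(0)
  if (model %in% c("mod1L", "mod4L")) {
    stopifnot(!is.null(marker))
    predictors <- c(predictors, marker)
  }
  if (model %in% c("mod2L", "mod4L")) {
    stopifnot(!is.null(mediator))
    predictors <- c(predictors, mediator)
  }
  if (!is.null(damline)) predictors <- c(predictors, damline)
  med_covs <- character(0)
  if (model == "mod4L" && !is.null(mediator_covariates)) {
    med_covs <- unname(mediator_covariates)
  }
  obs <- c(obs, predictors, med_covs)
  if (anyDuplicated(obs)) abort("duplicated observed variable in SEM spec")
  vars <- c(obs, lat)
  vix <- setNames(seq_along(vars), vars)

  pars <- list()
  add <- function(...) pars[[length(pars) + 1L]] <<- ram_param(...)

  # measurement blocks
  load_block <- function(factor_name, items, prefix) {
    add("A", vix[items[1]], vix[factor_name], paste0(prefix, items[1]),
        free = FALSE, start = 1)
    for (it in items[-1]) {
      add("A", vix[it], vix[factor_name], paste0(prefix, it), start = 1)
    }
    for (it in items) {
      fixed0 <- length(items) == 1L      # degenerate construct: no uniqueness
      add("S", vix[it], vix[it], paste0("uniq_", it), free = !fixed0,
          start = if (fixed0) 0 else NA, vtype = "var")
    }
  }
  load_block(spec$factor, ind, "loading_")
  if (use_adj) {
    load_block(".cg_adj", spec$cgb, "adj_loading_")
    load_block(".sr_adj", spec$sr, "adj_loading_")
  }

  # structural regressions into the latent phenotype
  pi_ix <- vix[spec$factor]
  if (model == "mod1L") add("A", pi_ix, vix[marker], "gamma")
  if (model == "mod2L") add("A", pi_ix, vix[mediator], "beta")
  if (model == "mod4L") {
    add("A", pi_ix, vix[mediator], "beta")
    add("A", pi_ix, vix[marker], "gamma_dir")
  }
  if (model != "cfa") {
    if (use_adj) add("A", pi_ix, vix[".cg_adj"], "b1")
    if (!is.null(damline)) add("A", pi_ix, vix[damline], "b2")
    if (use_adj) add("A", pi_ix, vix[".sr_adj"], "b3")
  }
  add("S", pi_ix, pi_ix, "dist_pi", vtype = "var", start = NA)

  # mediator equation of the full structural model
  if (model == "mod4L") {
    m_ix <- vix[mediator]
    add("A", m_ix, vix[marker], "alpha")
    if (length(med_covs) >= 1) add("A", m_ix, vix[med_covs[1]], "b1m")
    if (!is.null(damline)) add("A", m_ix, vix[damline], "b2m")
    if (length(med_covs) >= 2) add("A", m_ix, vix[med_covs[2]], "b3m")
    add("S", m_ix, m_ix, "dist_m", vtype = "var", start = NA)
  }

  # saturated exogenous block: predictors (except an endogenous mediator),
  # mediator covariates and the latent adjusters covary freely
  exo <- c(setdiff(predictors, if (model == "mod4L") mediator else character(0)),
           med_covs,
           if (use_adj) c(".cg_adj", ".sr_adj"))
  if (model == "mod2L") exo <- union(exo, mediator)
  for (i in seq_along(exo)) {
    for (j in seq_len(i)) {
      a <- exo[i]; b <- exo[j]
      if (a == b) {
        add("S", vix[a], vix[a], paste0("var_", a), vtype = "var", start = NA)
      } else {
        add("S", vix[a], vix[b], paste0("cov_", b, "_", a), start = NA)
      }
    }
  }

  pt <- dplyr::bind_rows(pars)
  list(vars = vars, obs = obs, lat = lat, pt = pt, spec = spec, model = model,
       marker = marker, mediator = mediator, exo = exo, damline = damline)
}

# Start values: sample moments for the exogenous block, half-variances for
# uniquenesses and disturbances, OLS of the indicator mean on predictors for
# the structural coefficients.
sem_start_values <- function(mdl, data, S_samp) {
  pt <- mdl$pt
  v <- function(name) {
    if (name %in% colnames(S_samp)) S_samp[name, name] else NA_real_
  }
  ind1 <- mdl$spec$indicators[1]
  start <- pt$start
  for (i in seq_len(nrow(pt))) {
    if (!pt$free[i] || !is.na(start[i])) next
    lab <- pt$label[i]
    a <- mdl$vars[pt$row[i]]; b <- mdl$vars[pt$col[i]]
    start[i] <-
      if (grepl("^uniq_", lab)) max(0.5 * v(a), 1e-3)
      else if (lab == "dist_pi") max(0.5 * v(ind1), 1e-3)
      else if (lab == "dist_m") max(0.5 * v(mdl$mediator), 1e-3)
      else if (grepl("^var_", lab)) {
        nm <- sub("^var_", "", lab)
        if (nm %in% colnames(S_samp)) S_samp[nm, nm]
        else max(0.5 * v(mdl$spec$cgb[1] %||% ind1), 1e-3)
      }
      else if (grepl("^cov_", lab)) {
        if (a %in% colnames(S_samp) && b %in% colnames(S_samp)) S_samp[a, b] else 0
      }
      else 0
  }
  # OLS-informed structural coefficients
  coef_rows <- which(pt$free & pt$label %in%
                       c("alpha", "beta", "gamma", "gamma_dir", "b2", "b2m"))
  if (length(coef_rows)) {
    ybar <- rowMeans(as.matrix(data[mdl$spec$indicators]))
    preds <- intersect(c(mdl$marker, mdl$mediator, mdl$damline),
                       colnames(S_samp))
    if (length(preds)) {
      fit <- stats::lm.fit(cbind(1, as.matrix(data[preds])), ybar)
      cf <- setNames(fit$coefficients[-1], preds)
      for (i in coef_rows) {
        src <- mdl$vars[pt$col[i]]
        if (src %in% names(cf) && is.finite(cf[src])) start[i] <- cf[src]
      }
    }
  }
  start[is.na(start)] <- 0
  pmax_var <- pt$vtype == "var" & pt$free
  start[pmax_var] <- pmax(start[pmax_var], 1e-4)
  start
}

# Precompute linear fill indices so the objective avoids per-parameter loops.
sem_indices <- function(mdl) {
  t_ <- length(mdl$vars)
  pt <- mdl$pt
  isA <- pt$mat == "A"
  list(t = t_,
       a_rows = which(isA), a_lin = (pt$col[isA] - 1L) * t_ + pt$row[isA],
       s_rows = which(!isA),
       s_lin = (pt$col[!isA] - 1L) * t_ + pt$row[!isA],
       s_lin_t = (pt$row[!isA] - 1L) * t_ + pt$col[!isA],
       n_obs = length(mdl$obs))
}

sem_sigma <- function(mdl, values, ix = sem_indices(mdl)) {
  A <- matrix(0, ix$t, ix$t)
  S <- matrix(0, ix$t, ix$t)
  A[ix$a_lin] <- values[ix$a_rows]
  S[ix$s_lin] <- values[ix$s_rows]
  S[ix$s_lin_t] <- values[ix$s_rows]
  IAinv <- tryCatch(solve(diag(ix$t) - A), error = function(e) NULL)
  if (is.null(IAinv)) return(NULL)
  Sig <- IAinv %*% S %*% t(IAinv)
  Sig[seq_len(ix$n_obs), seq_len(ix$n_obs), drop = FALSE]
}

sem_discrepancy <- function(mdl, values, S_samp, logdet_S,
                            ix = sem_indices(mdl)) {
  Sig <- sem_sigma(mdl, values, ix)
  if (is.null(Sig) || any(!is.finite(Sig))) return(NA_real_)
  ch <- tryCatch(chol(Sig), error = function(e) NULL)
  if (is.null(ch)) return(NA_real_)
  logdet <- 2 * sum(log(diag(ch)))
  Sinv <- chol2inv(ch)
  logdet + sum(Sinv * S_samp) - logdet_S - ncol(S_samp)
}

# free-parameter vector <-> optimizer scale (log for variance-type params)
to_opt <- function(x, vtypes) ifelse(vtypes == "var", log(pmax(x, 1e-12)), x)
from_opt <- function(x, vtypes) ifelse(vtypes == "var", exp(x), x)

#' Fit a latent-variable structural equation model
#'
#' Fits, by maximum-likelihood covariance-structure estimation, one of:
#'
#' * `mod1L` — total genomic effect on the latent phenotype:
#'   \eqn{\Pi = \gamma G + b_1 CG_\pi + b_2 D + b_3 Sr_\pi + \epsilon};
#' * `mod2L` — microbial effect on the latent phenotype:
#'   \eqn{\Pi = \beta M + b_1 CG_\pi + b_2 D + b_3 Sr_\pi + \epsilon};
#' * `mod4L` — full mediation model, adding the mediator equation
#'   \eqn{M = \alpha G + b_{1m} CGb_m + b_{2m} D + b_{3m} Sr_m + \epsilon_m}
#'   so the latent indirect effect \eqn{\alpha \beta} is available;
#' * `cfa` — the measurement model alone (no predictors or adjusters), the
#'   reduction used to cross-check loadings against dedicated factor
#'   analysis.
#'
#' Parameters minimize the ML discrepancy
#' \eqn{F = \log|\Sigma(\theta)| + tr(S\Sigma(\theta)^{-1}) - \log|S| - k}
#' over the model-implied covariance of all observed variables, with the
#' mean structure saturated and the exogenous block free. Optimization is
#' quasi-Newton (BFGS) on log-scale variances from two deterministic starts
#' (sample-moment/OLS-informed and a neutral start); standard errors come
#' from the inverse observed information (numeric Hessian of the
#' discrepancy in natural parameters, scaled by 2/n). Uniqueness variances
#' are bounded at zero by the log parameterization; estimates collapsing to
#' the boundary are flagged as Heywood cases.
#'
#' @param data Tibble holding every referenced column.
#' @param spec A [latent_spec()].
#' @param model `"mod1L"`, `"mod2L"`, `"mod4L"` or `"cfa"`.
#' @param marker Dosage column (mod1L / mod4L).
#' @param mediator CLR feature column (mod2L / mod4L).
#' @param mediator_covariates Length-2 character vector, the mediator
#'   equation's collapsed covariates `(cgb, sr)` (mod4L).
#' @param damline Dam-line column name, or `NULL` to omit.
#' @return A `sem_fit` with an estimates table (`label`, `estimate`, `se`),
#'   the discrepancy value, a convergence record and the Heywood flag.
#'   Supports [tidy()] and [glance()].
#' @export
fit_sem <- function(data, spec, model = c("mod4L", "mod1L", "mod2L", "cfa"),
                    marker = NULL, mediator = NULL,
                    mediator_covariates = NULL, damline = "damline") {
  model <- match.arg(model)
  if (model == "cfa") damline <- NULL
  if (!is.null(damline) && !damline %in% names(data)) damline <- NULL
  mdl <- build_sem_model(data, spec, model, marker, mediator,
                         mediator_covariates, damline)
  missing <- setdiff(mdl$obs, names(data))
  if (length(missing)) {
    abort(paste0("missing columns: ", paste(missing, collapse = ", ")))
  }
  X <- as.matrix(data[mdl$obs])
  n <- nrow(X)
  k <- ncol(X)
  if (n <= k) abort("need more samples than observed variables")
  S_samp <- stats::cov(X) * (n - 1) / n
  ch_s <- tryCatch(chol(S_samp), error = function(e) NULL)
  if (is.null(ch_s)) abort("sample covariance of observed variables is not positive definite")
  logdet_S <- 2 * sum(log(diag(ch_s)))

  pt <- mdl$pt
  free <- pt$free
  fixed_vals <- ifelse(free, 0, pt$start)
  vtypes <- pt$vtype[free]

  ix <- sem_indices(mdl)
  fill <- function(theta_nat) {
    vals <- fixed_vals
    vals[free] <- theta_nat
    vals
  }
  obj_nat <- function(theta_nat) {
    f <- sem_discrepancy(mdl, fill(theta_nat), S_samp, logdet_S, ix)
    if (!is.finite(f)) 1e8 + sum(theta_nat^2) else f
  }
  obj_opt <- function(theta_opt) obj_nat(from_opt(theta_opt, vtypes))

  # variance-type parameters are bounded below (log scale) so boundary
  # (Heywood) solutions terminate instead of drifting toward -Inf
  lower <- ifelse(vtypes == "var", log(1e-5), -Inf)
  run_from <- function(s0) {
    o <- stats::optim(to_opt(s0, vtypes), obj_opt, method = "L-BFGS-B",
                      lower = lower,
                      control = list(maxit = 500, factr = 1e7))
    stats::optim(o$par, obj_opt, method = "L-BFGS-B", lower = lower,
                 control = list(maxit = 500, factr = 1e3))
  }
  start1 <- sem_start_values(mdl, data, S_samp)[free]
  best <- run_from(start1)
  if (!is.finite(best$value) || best$value > 1e4) {
    start2 <- start1
    start2[!vtypes %in% "var" & !grepl("^cov_", pt$label[free])] <- 0
    alt <- run_from(start2)
    if (is.finite(alt$value) && alt$value < best$value) best <- alt
  }
  theta_hat <- from_opt(best$par, vtypes)
  Fval <- best$value
  if (!is.finite(Fval) || Fval > 1e7) {
    abort("SEM optimization failed to reach an admissible solution")
  }
  # gradient on the optimizer scale: log-parameterized variances make the
  # boundary (Heywood) direction flat, so this reflects actual convergence
  grad <- tryCatch(
    numeric_grad(obj_opt, best$par),
    error = function(e) rep(NA_real_, length(theta_hat)))

  H <- tryCatch(stats::optimHess(theta_hat, obj_nat), error = function(e) NULL)
  se <- rep(NA_real_, length(theta_hat))
  info_ok <- FALSE
  if (!is.null(H)) {
    Hi <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(Hi)) {
      d <- diag(Hi) * 2 / n
      se <- ifelse(d > 0, sqrt(pmax(d, 0)), NA_real_)
      info_ok <- TRUE
    }
  }
  est <- tibble::tibble(label = pt$label, free = pt$free,
                        estimate = fill(theta_hat),
                        se = NA_real_)
  est$se[est$free] <- se
  heywood <- any(grepl("^uniq_|^dist_", pt$label[free]) & theta_hat < 1e-4)
  structure(list(model = model, spec = spec, estimates = est,
                 discrepancy = Fval, n = n, k = k,
                 marker = mdl$marker, mediator = mdl$mediator,
                 convergence = list(code = best$convergence,
                                    grad_norm = max(abs(grad)),
                                    information_ok = info_ok),
                 heywood = heywood,
                 sigma_hat = sem_sigma(mdl, fill(theta_hat)),
                 sample_cov = S_samp,
                 internal = list(mdl = mdl, theta = theta_hat)),
            class = "sem_fit")
}

numeric_grad <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(i) {
    h <- eps * max(1, abs(x[i]))
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

sem_coef <- function(fit, label) {
  i <- match(label, fit$estimates$label)
  if (is.na(i)) abort(sprintf("no parameter '%s' in this model", label))
  fit$estimates$estimate[i]
}

sem_se <- function(fit, label) {
  i <- match(label, fit$estimates$label)
  if (is.na(i)) abort(sprintf("no parameter '%s' in this model", label))
  fit$estimates$se[i]
}

#' Latent indirect effect
#'
#' Product of the fitted genotype-to-microbe coefficient \eqn{\alpha'} and
#' the microbe-to-latent coefficient \eqn{\beta'_{\Pi \leftarrow m}} from a
#' full structural mediation fit.
#'
#' @param fit A `sem_fit` with `model = "mod4L"`.
#' @return The indirect effect (numeric scalar).
#' @export
indirect_effect_latent <- function(fit) {
  stopifnot(inherits(fit, "sem_fit"))
  if (fit$model != "mod4L") {
    abort("indirect effect is defined for the full mediation model (mod4L) only")
  }
  sem_coef(fit, "alpha") * sem_coef(fit, "beta")
}

#' @export
print.sem_fit <- function(x, ...) {
  cat(sprintf("<sem_fit> %s on factor '%s' (n = %d, %d observed vars)\n",
              x$model, x$spec$factor, x$n, x$k))
  cat(sprintf("  ML discrepancy %.6g; gradient max %.2e%s%s\n",
              x$discrepancy, x$convergence$grad_norm,
              if (x$heywood) "; Heywood case" else "",
              if (!x$convergence$information_ok) "; information singular" else ""))
  main <- x$estimates[x$estimates$label %in%
                        c("alpha", "beta", "gamma", "gamma_dir"), ]
  if (nrow(main)) print(as.data.frame(main[c("label", "estimate", "se")]))
  invisible(x)
}

#' @method tidy sem_fit
#' @export
tidy.sem_fit <- function(x, ...) {
  dplyr::mutate(x$estimates,
                statistic = .data$estimate / .data$se,
                p.value = 2 * stats::pnorm(abs(.data$statistic),
                                           lower.tail = FALSE))
}

#' @method glance sem_fit
#' @export
glance.sem_fit <- function(x, ...) {
  tibble::tibble(model = x$model, factor = x$spec$factor,
                 discrepancy = x$discrepancy, n = x$n,
                 n_observed = x$k,
                 converged = x$convergence$code == 0,
                 grad_norm = x$convergence$grad_norm,
                 heywood = x$heywood)
}
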