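#' Model re-fitters for resampling
#'
#' [bootstrap_test()] and [permutation_test()] refit a model many times, so
#' they accept a *fitter*: a function taking a data tibble and returning a
#' named numeric vector of the quantities of interest. These constructors
#' build lean fitters for the two model families.
#'
#' `mediation_fitter()` returns `alpha`, `beta`, `gamma_dir` and `indirect`
#' from the measured two-equation path model; `sem_fitter()` returns the
#' structural coefficients and `indirect` from the latent model (markedly
#' slower per round, so latent-model resampling is usually run with fewer
#' rounds).
#'
#' @param response,mediator,marker,covariates_m,covariates_p As in
#'   [fit_mediation()].
#' @return A function `data -> named numeric vector`.
#' @name fitters
#' @export
mediation_fitter <- function(response, mediator, marker,
                             covariates_m, covariates_p) {
  force(response); force(mediator); force(marker)
  force(covariates_m); force(covariates_p)
  function(data) {
    P <- standardize(data[[response]])
    M <- data[[mediator]]
    G <- data[[marker]]
    cm <- qr.coef(qr(cbind(1, G, as.matrix(data[covariates_m]))), M)
    cp <- qr.coef(qr(cbind(1, M, G, as.matrix(data[covariates_p]))), P)
    a <- unname(cm[2]); b <- unname(cp[2]); g <- unname(cp[3])
    c(alpha = a, beta = b, gamma_dir = g, indirect = a * b)
  }
}

#' @rdname fitters
#' @param spec,mediator_covariates,damline As in [fit_sem()].
#' @export
sem_fitter <- function(spec, marker, mediator, mediator_covariates,
                       damline = "damline") {
  force(spec); force(marker); force(mediator)
  force(mediator_covariates); force(damline)
  function(data) {
    fit <- fit_sem(data, spec, model = "mod4L", marker = marker,
                   mediator = mediator,
                   mediator_covariates = mediator_covariates,
                   damline = damline)
    c(alpha = sem_coef(fit, "alpha"), beta = sem_coef(fit, "beta"),
      gamma_dir = sem_coef(fit, "gamma_dir"),
      indirect = indirect_effect_latent(fit))
  }
}

#' Total-effect fitter (single-equation GWAS coefficient)
#'
#' @rdname fitters
#' @param covariates Covariate columns of the total-effect equation.
#' @export
total_effect_fitter <- function(response, marker, covariates) {
  force(response); force(marker); force(covariates)
  function(data) {
    y <- standardize(data[[response]])
    cf <- qr.coef(qr(cbind(1, data[[marker]], as.matrix(data[covariates]))), y)
    c(gamma = unname(cf[2]))
  }
}

#' Percentile bootstrap over records
#'
#' Resamples complete records (rows, covariates travelling with their row)
#' with replacement, refits, and builds the percentile interval of the
#' target parameter over rounds. Significance is declared when 0 falls
#' outside the interval. Rounds where the fitter fails (e.g. a resample
#' with a monomorphic marker) are recorded and excluded; more than 10%
#' failures aborts as an unstable model.
#'
#' @param data Cohort tibble of complete cases.
#' @param fitter Function `data -> named numeric vector` (see
#'   [mediation_fitter()]), deterministic given its data.
#' @param target Name of the parameter to test (default `"indirect"`).
#' @param n_rounds Resampling rounds (default 1000).
#' @param level Interval coverage (default 0.95).
#' @param seed Integer seed; same seed, same rounds, same decision.
#' @param keep_rounds Retain the per-round estimates in the result.
#' @return A `medipath_test` tibble row: method, target, point `estimate`,
#'   `lower`/`upper` bounds, `n_rounds`, failure count, `significant`.
#' @export
bootstrap_test <- function(data, fitter, target = "indirect",
                           n_rounds = 1000, level = 0.95, seed = 1,
                           keep_rounds = FALSE) {
  if (anyNA(data)) abort("data must be complete cases")
  point <- fitter(data)[target]
  if (is.na(point)) abort(sprintf("fitter does not produce target '%s'", target))
  n <- nrow(data)
  draws <- withr::with_seed(seed, {
    vapply(seq_len(n_rounds), function(r) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(fitter(data[idx, , drop = FALSE])[target],
               error = function(e) NA_real_)
    }, numeric(1))
  })
  finish_test("bootstrap", target, point, draws, n_rounds, level, seed,
              keep_rounds, decide = function(lo, hi, point) lo > 0 | hi < 0)
}

#' Path-breaking permutation test
#'
#' Shuffles the mediator column only, which severs both arms of the
#' mediated path (genotype to microbe and microbe to phenotype) while
#' leaving the direct path intact, then refits each round to build the
#' percentile null interval of the target. Significance is declared when
#' the observed (unpermuted) estimate falls outside the null interval.
#' Per-coefficient null draws for \eqn{\alpha'} and \eqn{\beta'} are kept
#' alongside the product for audit.
#'
#' @inheritParams bootstrap_test
#' @param mediator Name of the mediator column to shuffle.
#' @return A `medipath_test` tibble row; `lower`/`upper` are the null
#'   interval bounds.
#' @export
permutation_test <- function(data, fitter, mediator, target = "indirect",
                             n_rounds = 1000, level = 0.95, seed = 1,
                             keep_rounds = FALSE) {
  if (anyNA(data)) abort("data must be complete cases")
  if (!mediator %in% names(data)) abort("mediator column not found")
  obs <- fitter(data)
  point <- obs[target]
  if (is.na(point)) abort(sprintf("fitter does not produce target '%s'", target))
  n <- nrow(data)
  audit <- intersect(c("alpha", "beta"), names(obs))
  draws_all <- withr::with_seed(seed, {
    lapply(seq_len(n_rounds), function(r) {
      shuffled <- data
      shuffled[[mediator]] <- shuffled[[mediator]][sample.int(n)]
      tryCatch(fitter(shuffled)[c(target, audit)],
               error = function(e) setNames(rep(NA_real_, 1 + length(audit)),
                                            c(target, audit)))
    })
  })
  draws <- vapply(draws_all, `[[`, numeric(1), target)
  res <- finish_test("permutation", target, point, draws, n_rounds, level,
                     seed, keep_rounds,
                     decide = function(lo, hi, point) point < lo | point > hi)
  if (length(audit)) {
    attr(res, "null_draws") <- stats::setNames(
      lapply(audit, function(a) vapply(draws_all, `[[`, numeric(1), a)), audit)
  }
  res
}

finish_test <- function(method, target, point, draws, n_rounds, level, seed,
                        keep_rounds, decide) {
  failed <- sum(is.na(draws))
  if (failed > 0.10 * n_rounds) {
    abort(sprintf("%d/%d %s rounds failed: unstable model", failed, n_rounds,
                  method))
  }
  ok <- draws[!is.na(draws)]
  alpha <- (1 - level) / 2
  bounds <- stats::quantile(ok, c(alpha, 1 - alpha), names = FALSE, type = 7)
  out <- tibble::tibble(method = method, target = target,
                        estimate = unname(point),
                        lower = bounds[1], upper = bounds[2],
                        n_rounds = n_rounds, n_failed = failed,
                        level = level, seed = seed,
                        significant = decide(bounds[1], bounds[2],
                                             unname(point)))
  if (keep_rounds) attr(out, "rounds") <- ok
  class(out) <- c("medipath_test", class(out))
  out
}

#' Joint empirical decision
#'
#' A mediated path is declared significant only when every required
#' empirical method agrees (by default both the bootstrap and the
#' permutation test on the same triple).
#'
#' @param results A `medipath_test` tibble (rows from [bootstrap_test()] /
#'   [permutation_test()] on the same target).
#' @param rule Methods that must all be significant.
#' @return Logical flag.
#' @export
joint_decision <- function(results, rule = c("bootstrap", "permutation")) {
  if (length(rule) == 0) abort("empty requirement set")
  missing <- setdiff(rule, results$method)
  if (length(missing)) {
    abort(paste0("missing method(s): ", paste(missing, collapse = ", ")))
  }
  all(vapply(rule, function(m) {
    all(results$significant[results$method == m])
  }, logical(1)))
}
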