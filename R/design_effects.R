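#' Fit the nuisance mixed model for one response
#'
#' Structural-equation software handles cross-classified factors poorly, so
#' the framework first absorbs them into two linear covariates per response.
#' Step one is this model, fitted by REML for each standardized response
#' (trait or CLR microbial feature):
#'
#' \deqn{y = CG + D + S + pen + \epsilon}
#'
#' with contemporary group (`cg`) and sire (`sire`) as fixed cross-classified
#' effects, dam line (`damline`, coded 1/2) as a fixed numeric covariate and
#' the physical pen as a single random effect. Fixed effects use drop-first
#' reference coding; the collapsed covariates built from the solutions are
#' invariant to that choice once standardized.
#'
#' @param data Tibble holding the response column plus `cg`, `damline`,
#'   `sire`, `pen`.
#' @param response Name of the response column; standardized to mean 0, SD 1
#'   before fitting.
#' @return A `design_fit` with per-level fixed solutions, pen BLUPs,
#'   variance components and a convergence/singularity record. Supports
#'   [tidy()] and [glance()].
#' @seealso [collapse_covariates()], [collapse_design()]
#' @export
fit_design_model <- function(data, response) {
  need <- c(response, "cg", "damline", "sire", "pen")
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    abort(paste0("missing columns: ", paste(missing, collapse = ", ")))
  }
  df <- data.frame(y = standardize(data[[response]]),
                   cg = factor(data$cg),
                   damline = as.numeric(data$damline),
                   sire = factor(data$sire),
                   pen = factor(data$pen))
  # degenerate toys (single level / constant covariate) drop the term; its
  # solutions are then zero for every level
  fixed <- c(if (nlevels(df$cg) > 1) "cg",
             if (stats::sd(df$damline) > 0) "damline",
             if (nlevels(df$sire) > 1) "sire")
  form <- stats::as.formula(paste("y ~", paste(c("1", fixed), collapse = " + "),
                                  "+ (1 | pen)"))
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  fit <- withCallingHandlers(
    lme4::lmer(form, data = df, REML = TRUE, control = ctrl),
    message = function(m) invokeRestart("muffleMessage"))
  fe <- lme4::fixef(fit)
  cg_levels <- levels(df$cg)
  sire_levels <- levels(df$sire)
  pick_levels <- function(prefix, levels) {
    est <- setNames(numeric(length(levels)), levels)
    hits <- grep(paste0("^", prefix), names(fe), value = TRUE)
    est[sub(prefix, "", hits)] <- fe[hits]
    tibble::tibble(level = levels, estimate = unname(est))
  }
  re <- lme4::ranef(fit)$pen
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_pen <- vc$vcov[vc$grp == "pen"]
  var_res <- vc$vcov[vc$grp == "Residual"]
  structure(list(
    response = response,
    solutions = list(
      intercept = unname(fe["(Intercept)"]),
      cg = pick_levels("cg", cg_levels),
      damline = if ("damline" %in% names(fe)) unname(fe["damline"]) else 0,
      sire = pick_levels("sire", sire_levels)),
    blup = tibble::tibble(level = rownames(re), estimate = re[[1]]),
    varcomp = tibble::tibble(component = c("pen", "residual"),
                             variance = c(var_pen, var_res)),
    singular = lme4::isSingular(fit),
    logLik = as.numeric(stats::logLik(fit)),
    n = nrow(df)), class = "design_fit")
}

#' Collapse mixed-model solutions into linear covariates
#'
#' Step two of the nuisance-absorption procedure: for each individual, the
#' contemporary-group solution of its group plus the BLUP of its pen form
#' `cgb`, and the solution of its sire forms `sr`. Both covariates are then
#' standardized to mean 0, SD 1, which also removes the dependence on the
#' reference-level constraint used during fitting.
#'
#' @param fit A `design_fit` from [fit_design_model()].
#' @param data The same design tibble the model was fitted on (columns `cg`,
#'   `sire`, `pen`; any extra rows with unseen levels are an error).
#' @return Tibble with `sample_id` (if present in `data`), `cgb` and `sr`.
#' @export
collapse_covariates <- function(fit, data) {
  stopifnot(inherits(fit, "design_fit"))
  lookup <- function(tab, values, what) {
    idx <- match(as.character(values), tab$level)
    if (anyNA(idx)) {
      abort(sprintf("unseen %s level(s): %s", what,
                    paste(unique(values[is.na(idx)]), collapse = ", ")))
    }
    tab$estimate[idx]
  }
  cgb <- lookup(fit$solutions$cg, data$cg, "contemporary-group") +
    lookup(fit$blup, data$pen, "pen")
  sr <- lookup(fit$solutions$sire, data$sire, "sire")
  out <- tibble::tibble(cgb = standardize(cgb), sr = standardize(sr))
  if ("sample_id" %in% names(data)) {
    out <- dplyr::bind_cols(tibble::tibble(sample_id = data$sample_id), out)
  }
  out
}

#' Collapse nuisance structure for every response
#'
#' Runs [fit_design_model()] + [collapse_covariates()] for each response
#' column of a wide table (traits or CLR features), yielding one
#' standardized `(cgb, sr)` covariate pair per response, named
#' `cgb_<response>` / `sr_<response>`.
#'
#' @param responses Wide tibble, `sample_id` plus one column per response.
#' @param design Design tibble with `sample_id`, `cg`, `damline`, `sire`,
#'   `pen`.
#' @return Tibble `sample_id` + collapsed covariate pairs; variance
#'   components per response are attached as the `varcomp` attribute.
#' @export
collapse_design <- function(responses, design) {
  resp_cols <- value_columns(responses)
  joined <- dplyr::inner_join(responses, design, by = "sample_id")
  if (nrow(joined) != nrow(responses)) {
    abort("design table does not cover all samples")
  }
  out <- tibble::tibble(sample_id = joined$sample_id)
  vcs <- vector("list", length(resp_cols))
  for (i in seq_along(resp_cols)) {
    r <- resp_cols[i]
    fit <- fit_design_model(joined, r)
    cc <- collapse_covariates(fit, joined)
    out[[paste0("cgb_", r)]] <- cc$cgb
    out[[paste0("sr_", r)]] <- cc$sr
    vcs[[i]] <- tibble::tibble(response = r,
                               var_pen = fit$varcomp$variance[1],
                               var_residual = fit$varcomp$variance[2],
                               singular = fit$singular)
  }
  attr(out, "varcomp") <- dplyr::bind_rows(vcs)
  out
}

#' @export
print.design_fit <- function(x, ...) {
  cat(sprintf("<design_fit> response '%s' (n = %d)\n", x$response, x$n))
  cat(sprintf("  variance components: pen %.4f, residual %.4f%s\n",
              x$varcomp$variance[1], x$varcomp$variance[2],
              if (x$singular) " (singular fit: pen variance at boundary)" else ""))
  invisible(x)
}

#' @method tidy design_fit
#' @export
tidy.design_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(term = "(Intercept)", level = NA_character_,
                   type = "fixed", estimate = x$solutions$intercept),
    dplyr::mutate(x$solutions$cg, term = "cg", type = "fixed"),
    tibble::tibble(term = "damline", level = NA_character_, type = "fixed",
                   estimate = x$solutions$damline),
    dplyr::mutate(x$solutions$sire, term = "sire", type = "fixed"),
    dplyr::mutate(x$blup, term = "pen", type = "random")) |>
    dplyr::select("term", "level", "type", "estimate")
}

#' @method glance design_fit
#' @export
glance.design_fit <- function(x, ...) {
  tibble::tibble(var_pen = x$varcomp$variance[1],
                 var_residual = x$varcomp$variance[2],
                 singular = x$singular, logLik = x$logLik, n = x$n)
}
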