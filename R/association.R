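#' Single-feature association scans
#'
#' One engine serves the three scans of the framework: GWAS of a phenotype
#' on marker dosage (total effect \eqn{\gamma}), MWAS of a phenotype on a
#' CLR microbial feature (\eqn{\beta}), and the genotype-to-microbe scan of
#' a CLR feature on dosage (\eqn{\alpha}). Each (response, feature) pair is
#' fitted by OLS:
#'
#' \deqn{y = intercept + effect \cdot feature + b_1 CGb + b_2 D + b_3 Sr + \epsilon}
#'
#' where `CGb` and `Sr` are that response's collapsed nuisance covariates
#' (see [collapse_design()]) and `D` is the dam line code. Two-sided t-tests
#' use n - 5 degrees of freedom (intercept + feature + three covariates).
#' Internally the covariates are projected out once per response
#' (Frisch-Waugh), so the scan is linear in the number of features.
#'
#' Responses are standardized to mean 0, SD 1 before fitting, so the MWAS
#' `var_absorbed` column (population variance of `effect * feature`) is
#' directly a proportion of phenotypic variance. Markers with missing
#' dosages are mean-imputed per marker; constant features are flagged
#' `untestable` rather than dropped.
#'
#' @param responses Wide tibble, `sample_id` + one column per response.
#' @param features Wide tibble, `sample_id` + one column per feature
#'   (dosage 0/1/2 or CLR abundance).
#' @param covariates Per-response collapsed covariates from
#'   [collapse_design()] (`cgb_<response>`, `sr_<response>`).
#' @param design Design tibble contributing the `damline` column.
#' @param model Label for the scan: `"gwas"` (Mod1-style), `"mwas"`
#'   (Mod2-style) or `"gm"` (genotype-to-microbe, Mod3-style). The fitting
#'   path is identical; the label tags the output.
#' @return A `medipath_scan` tibble: one row per response x feature with
#'   `estimate`, `se`, `statistic`, `df`, `p_value`, Bonferroni/FDR adjusted
#'   p-values (family = features within each response), `var_absorbed` and
#'   the nuisance coefficients `b_cgb`, `b_damline`, `b_sr`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_individuals = 80, n_markers = 12,
#'                                      n_otus = 6, n_pens = 24, seed = 3))
#' covs <- collapse_design(cohort$phenotypes, cohort$design)
#' scan_association(cohort$phenotypes, cohort$genotypes, covs, cohort$design)
#' @export
scan_association <- function(responses, features, covariates, design,
                             model = c("gwas", "mwas", "gm")) {
  model <- match.arg(model)
  resp_cols <- value_columns(responses)
  feat_cols <- value_columns(features)
  df <- dplyr::inner_join(responses, features, by = "sample_id") |>
    dplyr::inner_join(covariates, by = "sample_id") |>
    dplyr::inner_join(dplyr::select(design, "sample_id", "damline"),
                      by = "sample_id")
  n <- nrow(df)
  if (n < 6L) abort("need at least 6 complete samples")
  fmat <- as.matrix(df[feat_cols])
  # mean-impute missing feature values (e.g. sporadic missing genotypes)
  if (anyNA(fmat)) {
    for (j in seq_len(ncol(fmat))) {
      miss <- is.na(fmat[, j])
      if (any(miss)) fmat[miss, j] <- mean(fmat[, j], na.rm = TRUE)
    }
  }
  out <- vector("list", length(resp_cols))
  for (ri in seq_along(resp_cols)) {
    r <- resp_cols[ri]
    need <- paste0(c("cgb_", "sr_"), r)
    if (!all(need %in% names(df))) {
      abort(sprintf("covariates for response '%s' not found (%s)",
                    r, paste(need, collapse = ", ")))
    }
    y <- standardize(df[[r]])
    X <- cbind(`(Intercept)` = 1, cgb = df[[need[1]]],
               damline = as.numeric(df$damline), sr = df[[need[2]]])
    qrX <- qr(X)
    base_coef <- qr.coef(qrX, y)              # covariate-only solutions
    ry <- qr.resid(qrX, y)
    rf <- qr.resid(qrX, fmat)
    f_coef <- qr.coef(qrX, fmat)              # feature-on-covariate solutions
    ssf <- colSums(rf^2)
    testable <- ssf > 1e-12 * n
    slope <- ifelse(testable, colSums(rf * ry) / ssf, NA_real_)
    rss <- sum(ry^2) - ifelse(testable, slope^2 * ssf, 0)
    dfree <- n - 5L
    se <- sqrt(pmax(rss, 0) / dfree / ssf)
    tstat <- slope / se
    pval <- 2 * stats::pt(abs(tstat), dfree, lower.tail = FALSE)
    covs_adj <- base_coef - t(t(f_coef) * ifelse(testable, slope, 0))
    va <- vapply(seq_along(feat_cols), function(j) {
      if (!testable[j]) return(NA_real_)
      pop_var(slope[j] * fmat[, j])
    }, numeric(1))
    out[[ri]] <- tibble::tibble(
      model = model, response = r, feature = feat_cols,
      estimate = unname(slope),
      se = unname(ifelse(testable, se, NA_real_)),
      statistic = unname(ifelse(testable, tstat, NA_real_)), df = dfree,
      p_value = unname(ifelse(testable, pval, NA_real_)),
      p_bonferroni = unname(adjust_pvalues(
        ifelse(testable, pval, NA_real_), "bonferroni", allow_na = TRUE)),
      p_fdr = unname(adjust_pvalues(
        ifelse(testable, pval, NA_real_), "fdr_bh", allow_na = TRUE)),
      var_absorbed = va,
      b_cgb = unname(covs_adj["cgb", ]),
      b_damline = unname(covs_adj["damline", ]),
      b_sr = unname(covs_adj["sr", ]),
      untestable = unname(!testable))
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("medipath_scan", class(res))
  res
}

#' Variance absorbed by a fitted feature effect
#'
#' The population variance (divide by n) of the fitted contribution
#' `coefficient * feature_values`. When the response was standardized this
#' is directly the proportion of phenotypic variance the feature absorbs,
#' the quantity used by the mediator-selection screen (> 1%).
#'
#' @param coefficient Fitted effect.
#' @param feature_values Feature values of the analyzed sample.
#' @return Non-negative proportion.
#' @export
variance_absorbed <- function(coefficient, feature_values) {
  if (length(feature_values) == 0L) abort("empty feature vector")
  pop_var(coefficient * feature_values)
}

#' Multiple-testing adjustment
#'
#' Bonferroni (`min(1, m p)`) or Benjamini-Hochberg step-up FDR with
#' monotonicity enforcement, as thin wrappers over [stats::p.adjust()].
#'
#' @param p Vector of raw p-values in \[0, 1\].
#' @param method `"bonferroni"` or `"fdr_bh"`.
#' @param allow_na Permit NA entries (untestable features); NaN is always an
#'   error.
#' @return Adjusted p-values, same length and order.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "fdr_bh"),
                           allow_na = FALSE) {
  method <- match.arg(method)
  if (any(is.nan(p))) abort("NaN p-values are not interpretable")
  if (!allow_na && anyNA(p)) abort("NA p-values are not interpretable")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) abort("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = c(bonferroni = "bonferroni", fdr_bh = "BH")[method])
}
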