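#' Assemble the analysis table for a cohort
#'
#' Runs the standard preprocessing chain and joins everything the models
#' need into one wide tibble: OTU counts are filtered ([filter_otus()]),
#' zero-replaced ([replace_zeros()]) and CLR-transformed
#' ([clr_transform()]); nuisance structure is collapsed into `(cgb, sr)`
#' covariate pairs for every trait and every CLR feature
#' ([collapse_design()]); genotypes, traits, CLR features, covariates and
#' the dam line code are joined by `sample_id`.
#'
#' @param cohort A `medipath_cohort` (or a list with elements `genotypes`,
#'   `otu`, `phenotypes`, `design`).
#' @param min_total,max_zero_fraction Feature filter thresholds
#'   (see [filter_otus()]).
#' @param delta_fraction Zero-replacement fraction (see [replace_zeros()]).
#' @return Wide tibble keyed by `sample_id`; attributes `traits`, `otus`
#'   (features kept after filtering), `stage` and `varcomp`.
#' @export
mediation_data <- function(cohort, min_total = 1200, max_zero_fraction = 0.80,
                           delta_fraction = 0.65) {
  otu <- filter_otus(cohort$otu, min_total, max_zero_fraction)
  if (length(value_columns(otu)) == 0L) abort("no OTU features survive filtering")
  clr <- clr_transform(replace_zeros(otu, delta_fraction))
  traits <- value_columns(cohort$phenotypes)
  covs_p <- collapse_design(cohort$phenotypes, cohort$design)
  covs_m <- collapse_design(clr, cohort$design)
  out <- cohort$phenotypes |>
    dplyr::inner_join(clr, by = "sample_id") |>
    dplyr::inner_join(cohort$genotypes, by = "sample_id") |>
    dplyr::inner_join(covs_p, by = "sample_id") |>
    dplyr::inner_join(covs_m, by = "sample_id") |>
    dplyr::inner_join(dplyr::select(cohort$design, "sample_id", "damline"),
                      by = "sample_id")
  attr(out, "traits") <- traits
  attr(out, "otus") <- value_columns(clr)
  attr(out, "stage") <- otu_stage(cohort$otu)
  attr(out, "varcomp") <- dplyr::bind_rows(attr(covs_p, "varcomp"),
                                           attr(covs_m, "varcomp"))
  out
}

stage_rank <- function(stage) {
  r <- suppressWarnings(as.numeric(gsub("[^0-9.]", "", stage)))
  ifelse(is.na(r), 0, r)
}

#' Select microbial mediators for a trait triplet
#'
#' A feature qualifies as a mediator of a latent construct's trait triplet
#' when, in the MWAS, it is (i) Bonferroni-significant on all three traits,
#' (ii) absorbs more than `min_var_absorbed` of the variance of all three,
#' and (iii) is compatible with the causal timing: a feature sampled after
#' a trait was recorded cannot mediate it, so the mediator's stage must not
#' come after the triplet's recording stage.
#'
#' @param mwas A `medipath_scan` from [scan_association()] with the triplet
#'   traits as responses and candidate features as features.
#' @param traits Character vector of the three trait columns.
#' @param mediator_stage Stage label of the features (single label, or a
#'   named vector per feature).
#' @param trait_stage Stage label at which the triplet was recorded.
#' @param alpha Bonferroni-adjusted significance level (default 0.05).
#' @param min_var_absorbed Minimum variance-absorbed proportion on every
#'   trait (default 0.01, i.e. 1%).
#' @return Tibble with one row per feature: the three-part rule columns
#'   (`all_significant`, `all_absorbing`, `stage_compatible`), summary
#'   statistics and the final `selected` flag.
#' @export
select_mediators <- function(mwas, traits, mediator_stage = "S2",
                             trait_stage = "S3", alpha = 0.05,
                             min_var_absorbed = 0.01) {
  missing <- setdiff(traits, unique(mwas$response))
  if (length(missing)) {
    abort(paste0("MWAS results missing for trait(s): ",
                 paste(missing, collapse = ", ")))
  }
  sub <- dplyr::filter(mwas, .data$response %in% traits)
  per <- sub |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(
      n_traits = dplyr::n(),
      all_significant = all(!.data$untestable) &&
        all(.data$p_bonferroni < alpha),
      all_absorbing = all(!.data$untestable) &&
        all(.data$var_absorbed > min_var_absorbed),
      max_p_bonferroni = max(.data$p_bonferroni),
      min_var_absorbed = min(.data$var_absorbed),
      .groups = "drop")
  if (any(per$n_traits != length(traits))) {
    abort("every feature must be scanned on every trait of the triplet")
  }
  stages <- if (length(mediator_stage) == 1L && is.null(names(mediator_stage))) {
    setNames(rep(mediator_stage, nrow(per)), per$feature)
  } else {
    mediator_stage
  }
  per$stage <- unname(stages[per$feature])
  per$stage_compatible <- stage_rank(per$stage) <= stage_rank(trait_stage)
  per$selected <- per$all_significant & per$all_absorbing &
    per$stage_compatible
  dplyr::rename(per, mediator = "feature")
}

#' Mediation path scan over all markers
#'
#' Fits the two-equation path model of [fit_mediation()] for one
#' (mediator, response) pair against every marker column, using the
#' Frisch-Waugh projection so the scan is linear in the number of markers
#' and numerically identical to the per-triple fit. Returns one row per
#' marker with the three path coefficients, their SEs, the indirect effect,
#' the mediation ratio and the Sobel test.
#'
#' @param data Analysis table from [mediation_data()].
#' @param response,mediator Columns as in [fit_mediation()].
#' @param markers Character vector of marker columns to scan.
#' @param covariates_m,covariates_p Covariate column triplets as in
#'   [fit_mediation()].
#' @return Tibble, one row per marker.
#' @export
scan_mediation <- function(data, response, mediator, markers,
                           covariates_m, covariates_p) {
  P <- standardize(data[[response]])
  M <- data[[mediator]]
  G <- as.matrix(data[markers])
  if (anyNA(G)) {
    for (j in seq_len(ncol(G))) {
      miss <- is.na(G[, j])
      if (any(miss)) G[miss, j] <- mean(G[, j], na.rm = TRUE)
    }
  }
  n <- length(P)
  Xm <- cbind(1, as.matrix(data[covariates_m]))
  Xp <- cbind(1, as.matrix(data[covariates_p]))
  qm <- qr(Xm); qp <- qr(Xp)
  rM_m <- qr.resid(qm, M)
  rG_m <- qr.resid(qm, G)
  ss_gm <- colSums(rG_m^2)
  testable <- matrixStats_colvar(G) > 0
  alpha <- ifelse(testable, colSums(rG_m * rM_m) / ss_gm, NA_real_)
  rss_m <- sum(rM_m^2) - alpha^2 * ss_gm
  df_m <- n - 5L
  se_alpha <- sqrt(pmax(rss_m, 0) / df_m / ss_gm)

  rP <- qr.resid(qp, P)
  rM_p <- qr.resid(qp, M)
  rG_p <- qr.resid(qp, G)
  a <- sum(rM_p^2)
  b <- colSums(rG_p * rM_p)
  cc <- colSums(rG_p^2)
  d <- sum(rM_p * rP)
  e <- colSums(rG_p * rP)
  det <- a * cc - b^2
  beta <- (cc * d - b * e) / det
  gamma <- (a * e - b * d) / det
  df_p <- n - 6L
  rss_p <- sum(rP^2) - beta * d - gamma * e
  s2_p <- pmax(rss_p, 0) / df_p
  se_beta <- sqrt(s2_p * cc / det)
  se_gamma <- sqrt(s2_p * a / det)

  ind <- alpha * beta
  ratio <- ifelse(gamma == 0, ifelse(ind == 0, 0, Inf), abs(ind) / abs(gamma))
  sob_den <- sqrt(alpha^2 * se_beta^2 + beta^2 * se_alpha^2)
  z <- ifelse(sob_den > 0, ind / sob_den, 0)
  keep <- function(x) unname(ifelse(testable, x, NA_real_))
  tibble::tibble(response = response, mediator = mediator, marker = markers,
                 alpha = keep(alpha), se_alpha = keep(se_alpha),
                 beta = keep(beta), se_beta = keep(se_beta),
                 gamma_dir = keep(gamma), se_gamma_dir = keep(se_gamma),
                 indirect = keep(ind), ratio = keep(ratio),
                 sobel_z = keep(z),
                 sobel_p = keep(2 * stats::pnorm(abs(z),
                                                 lower.tail = FALSE)),
                 untestable = unname(!testable))
}

matrixStats_colvar <- function(m) {
  colMeans(m^2) - colMeans(m)^2
}

#' Screen candidates for empirical testing
#'
#' Mediation candidates are triples whose mediation ratio strictly exceeds
#' `ratio_threshold` (mediated path stronger than direct). Total-effect
#' candidates are markers whose GWAS \eqn{\gamma} p-value falls below
#' `gamma_p_threshold`; these are later tested by bootstrap only.
#'
#' @param fits Tibble of path-scan rows (from [scan_mediation()]).
#' @param total_fits A `medipath_scan` of total effects (GWAS).
#' @param ratio_threshold Strict lower bound on the ratio (default 1).
#' @param gamma_p_threshold Upper bound on the total-effect p-value
#'   (default 0.01).
#' @return List with tibbles `mediation` and `total`.
#' @export
screen_candidates <- function(fits, total_fits, ratio_threshold = 1,
                              gamma_p_threshold = 0.01) {
  med <- dplyr::filter(fits, !.data$untestable,
                       .data$ratio > ratio_threshold)
  tot <- dplyr::filter(tibble::as_tibble(total_fits), !.data$untestable,
                       .data$p_value < gamma_p_threshold)
  list(mediation = med, total = tot)
}

#' Group significant markers into contiguous SNP windows
#'
#' Discovered markers are summarized per chromosome as windows of
#' contiguous genotyped SNPs: scanning left to right, a marker joins the
#' current window while its panel index is within `window_size` of the
#' window's seed (first) marker; otherwise it seeds a new window. Windows
#' are counted in panel-index space (consecutive genotyped SNPs), not base
#' pairs.
#'
#' @param markers Tibble with columns `marker`, `chrom`, `index` (ordinal
#'   position on the genotyped panel within its chromosome) and optionally
#'   `pos`.
#' @param window_size Index span of a window (default 10).
#' @return Tibble: one row per window with `chrom`, `start_index`,
#'   `end_index`, start/end positions when available, `n_markers` and the
#'   member list.
#' @export
group_windows <- function(markers, window_size = 10) {
  need <- c("marker", "chrom", "index")
  missing <- setdiff(need, names(markers))
  if (length(missing)) {
    abort(paste0("missing columns: ", paste(missing, collapse = ", ")))
  }
  if (anyNA(markers$chrom) || anyNA(markers$index)) {
    abort("every marker needs a chromosome and panel index")
  }
  if (nrow(markers) == 0L) {
    return(tibble::tibble(window = integer(0), chrom = markers$chrom[0],
                          start_index = numeric(0), end_index = numeric(0),
                          n_markers = integer(0), members = list()))
  }
  sorted <- dplyr::arrange(markers, .data$chrom, .data$index)
  win <- integer(nrow(sorted))
  w <- 0L
  seed_idx <- -Inf
  seed_chr <- NULL
  for (i in seq_len(nrow(sorted))) {
    if (is.null(seed_chr) || sorted$chrom[i] != seed_chr ||
        sorted$index[i] - seed_idx > window_size) {
      w <- w + 1L
      seed_idx <- sorted$index[i]
      seed_chr <- sorted$chrom[i]
    }
    win[i] <- w
  }
  sorted$window <- win
  out <- sorted |>
    dplyr::group_by(.data$window, .data$chrom) |>
    dplyr::summarise(start_index = min(.data$index),
                     end_index = max(.data$index),
                     n_markers = dplyr::n(),
                     members = list(.data$marker), .groups = "drop")
  if ("pos" %in% names(markers)) {
    pos <- markers[c("marker", "pos")]
    out$start_pos <- vapply(out$members, function(m) {
      min(pos$pos[pos$marker %in% m])
    }, numeric(1))
    out$end_pos <- vapply(out$members, function(m) {
      max(pos$pos[pos$marker %in% m])
    }, numeric(1))
  }
  out
}

#' Count annotation overlaps for marker windows
#'
#' Generic interval-overlap counter: given windows (with `chrom`,
#' `start_pos`, `end_pos`) and a BED-like annotation table (`chrom`,
#' `start`, `end`, `category`), counts overlapping annotation records per
#' category.
#'
#' @param windows Output of [group_windows()] with positions.
#' @param annotation Tibble with `chrom`, `start`, `end`, `category`.
#' @return Tibble `category`, `n_overlaps`.
#' @export
count_overlaps <- function(windows, annotation) {
  stopifnot(all(c("chrom", "start", "end", "category") %in% names(annotation)))
  if (nrow(windows) == 0L) {
    return(tibble::tibble(category = unique(annotation$category),
                          n_overlaps = 0L))
  }
  stopifnot(all(c("start_pos", "end_pos") %in% names(windows)))
  counts <- vapply(split(annotation, annotation$category), function(ann) {
    total <- 0L
    for (i in seq_len(nrow(windows))) {
      hit <- ann$chrom == windows$chrom[i] &
        ann$start <= windows$end_pos[i] & ann$end >= windows$start_pos[i]
      total <- total + sum(hit)
    }
    total
  }, integer(1))
  tibble::tibble(category = names(counts), n_overlaps = unname(counts))
}

#' Pipeline configuration
#'
#' Collects the thresholds and sizes of [run_pipeline()]. Defaults follow
#' the framework's screening rules: OTU filter at 1200 total counts / 80%
#' zeros, mediator selection at Bonferroni 0.05 with more than 1% variance
#' absorbed, mediation ratio strictly greater than 1, total-effect
#' bootstrap only below p = 0.01, 1000 empirical rounds at 95% intervals.
#' `max_candidates` caps how many screened triples (ordered by Sobel
#' p-value) enter empirical testing, which bounds desk-scale runtime;
#' latent-model refits are restricted to `latent_max_markers` top markers
#' per mediator for the same reason, and latent-path resampling is off by
#' default (`latent_rounds = 0`), in which case latent discoveries are
#' declared by the ratio screen plus Sobel at 0.05.
#'
#' @param ... Overrides of the defaults listed above.
#' @return Named list of settings.
#' @export
pipeline_config <- function(...) {
  cfg <- list(min_total = 1200, max_zero_fraction = 0.80,
              delta_fraction = 0.65,
              alpha_mediator = 0.05, min_var_absorbed = 0.01,
              ratio_threshold = 1, gamma_p_threshold = 0.01,
              n_rounds = 1000, level = 0.95,
              max_candidates = 100, max_total_candidates = 50,
              latent = TRUE, latent_max_markers = 10, latent_rounds = 0,
              window_size = 10, seed = 1,
              factors = list(fatg = c("bf1", "bf2", "bf3"),
                             fatt = c("bf4", "bft", "bel")),
              trait_stages = c(fatg = "S2", fatt = "S3"))
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    abort(paste0("unknown pipeline settings: ", paste(unknown, collapse = ", ")))
  }
  cfg[names(over)] <- over
  cfg
}

#' Run the full discovery pipeline
#'
#' Executes, deterministically under `config$seed`: preprocessing and
#' covariate collapsing ([mediation_data()]), the GWAS and MWAS scans,
#' mediator selection per latent construct, the mediation path scan over
#' all markers for every selected (mediator, trait) pair, the ratio and
#' total-effect screens, bootstrap + permutation testing of the screened
#' triples, optional latent-model fits for the strongest candidates,
#' discovery tabulation with the measured/latent partition, and contiguous
#' SNP window grouping of the discovered markers.
#'
#' @param cohort A `medipath_cohort` or equivalent list.
#' @param config Settings from [pipeline_config()].
#' @return A `discovery_table`: row-level records (`discoveries`, `totals`,
#'   `mediation_scans`, `mediator_selection`, latent fits), summary
#'   `counts`, `windows`, the measured/latent `venn` partition and a run
#'   `log`. All summary numbers are recomputable from the row-level records
#'   via [summarize_discoveries()].
#' @export
run_pipeline <- function(cohort, config = pipeline_config()) {
  log <- list()
  note <- function(stage, message, count = NA_integer_) {
    log[[length(log) + 1L]] <<- tibble::tibble(stage = stage,
                                               message = message,
                                               count = count)
  }
  fail <- function(stage, e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
  }
  dat <- tryCatch(mediation_data(cohort, config$min_total,
                                 config$max_zero_fraction,
                                 config$delta_fraction),
                  error = function(e) fail("preprocess", e))
  traits <- attr(dat, "traits")
  otus <- attr(dat, "otus")
  stage_m <- attr(dat, "stage")
  markers <- value_columns(cohort$genotypes)
  note("preprocess", sprintf("%d features kept of %d", length(otus),
                             length(value_columns(cohort$otu))),
       length(otus))

  covs_of <- function(r) paste0(c("cgb_", "sr_"), r)
  trait_tab <- dat[c("sample_id", traits)]
  otu_tab <- dat[c("sample_id", otus)]
  geno_tab <- dat[c("sample_id", markers)]
  cov_tab <- dat[c("sample_id", grep("^(cgb|sr)_", names(dat), value = TRUE))]
  design_tab <- dat[c("sample_id", "damline")]

  gwas <- tryCatch(
    scan_association(trait_tab, geno_tab, cov_tab, design_tab, "gwas"),
    error = function(e) fail("gwas", e))
  note("gwas", sprintf("%d trait x marker fits", nrow(gwas)), nrow(gwas))
  mwas <- tryCatch(
    scan_association(trait_tab, otu_tab, cov_tab, design_tab, "mwas"),
    error = function(e) fail("mwas", e))
  note("mwas", sprintf("%d trait x feature fits", nrow(mwas)), nrow(mwas))

  selections <- list()
  for (f in names(config$factors)) {
    sel <- tryCatch(
      select_mediators(mwas, config$factors[[f]],
                       mediator_stage = stage_m,
                       trait_stage = config$trait_stages[[f]],
                       alpha = config$alpha_mediator,
                       min_var_absorbed = config$min_var_absorbed),
      error = function(e) fail("select_mediators", e))
    sel$factor <- f
    selections[[f]] <- sel
  }
  selection <- dplyr::bind_rows(selections)
  chosen <- dplyr::filter(selection, .data$selected)
  note("select_mediators", sprintf("%d mediator x factor selections",
                                   nrow(chosen)), nrow(chosen))

  scans <- list()
  for (i in seq_len(nrow(chosen))) {
    f <- chosen$factor[i]
    m <- chosen$mediator[i]
    for (tr in config$factors[[f]]) {
      scans[[paste(m, tr)]] <- scan_mediation(
        dat, tr, m, markers,
        covariates_m = c(covs_of(m)[1], "damline", covs_of(m)[2]),
        covariates_p = c(covs_of(tr)[1], "damline", covs_of(tr)[2]))
    }
  }
  med_scan <- dplyr::bind_rows(scans)
  note("mediation_scan", sprintf("%d path fits", nrow(med_scan)),
       nrow(med_scan))

  screened <- screen_candidates(
    if (nrow(med_scan)) med_scan else empty_med_scan(),
    gwas, config$ratio_threshold, config$gamma_p_threshold)
  note("screen", sprintf("%d mediation, %d total-effect candidates",
                         nrow(screened$mediation), nrow(screened$total)),
       nrow(screened$mediation))

  med_cand <- dplyr::arrange(screened$mediation, .data$sobel_p) |>
    utils::head(config$max_candidates)
  disc <- vector("list", nrow(med_cand))
  for (i in seq_len(nrow(med_cand))) {
    row <- med_cand[i, ]
    fitter <- mediation_fitter(
      row$response, row$mediator, row$marker,
      covariates_m = c(covs_of(row$mediator)[1], "damline",
                       covs_of(row$mediator)[2]),
      covariates_p = c(covs_of(row$response)[1], "damline",
                       covs_of(row$response)[2]))
    sd_boot <- layer_seed(config$seed, 10L + 2L * i)
    sd_perm <- layer_seed(config$seed, 11L + 2L * i)
    sub <- dat[unique(c(row$response, row$mediator, row$marker, "damline",
                        covs_of(row$mediator), covs_of(row$response)))]
    bt <- bootstrap_test(sub, fitter, "indirect", config$n_rounds,
                         config$level, sd_boot)
    pt_ <- permutation_test(sub, fitter, row$mediator, "indirect",
                            config$n_rounds, config$level, sd_perm)
    disc[[i]] <- dplyr::mutate(row,
      boot_lower = bt$lower, boot_upper = bt$upper,
      boot_significant = bt$significant,
      perm_lower = pt_$lower, perm_upper = pt_$upper,
      perm_significant = pt_$significant,
      joint_significant = joint_decision(dplyr::bind_rows(bt, pt_)))
  }
  discoveries <- dplyr::bind_rows(disc)
  if (nrow(discoveries) == 0L) discoveries <- empty_discoveries()
  note("empirical", sprintf("%d triples tested, %d pass both tests",
                            nrow(discoveries),
                            sum(discoveries$joint_significant)),
       sum(discoveries$joint_significant))

  tot_cand <- dplyr::arrange(screened$total, .data$p_value) |>
    utils::head(config$max_total_candidates)
  tot <- vector("list", nrow(tot_cand))
  for (i in seq_len(nrow(tot_cand))) {
    row <- tot_cand[i, ]
    fitter <- total_effect_fitter(
      row$response, row$feature,
      c(covs_of(row$response)[1], "damline", covs_of(row$response)[2]))
    sub <- dat[unique(c(row$response, row$feature, "damline",
                        covs_of(row$response)))]
    bt <- bootstrap_test(sub, fitter, "gamma", config$n_rounds, config$level,
                         layer_seed(config$seed, 5000L + i))
    tot[[i]] <- dplyr::mutate(row, boot_lower = bt$lower,
                              boot_upper = bt$upper,
                              boot_significant = bt$significant)
  }
  totals <- dplyr::bind_rows(tot)
  note("total_bootstrap", sprintf("%d markers bootstrapped", nrow(totals)),
       if (nrow(totals)) sum(totals$boot_significant) else 0L)

  latent <- run_latent_stage(dat, discoveries, chosen, config, covs_of, note)

  sig_measured <- unique(discoveries$marker[discoveries$joint_significant])
  sig_latent <- if (nrow(latent$fits)) {
    unique(latent$fits$marker[latent$fits$significant])
  } else {
    character(0)
  }
  venn <- tibble::tibble(
    set = c("measured_only", "shared", "latent_only"),
    n_markers = c(length(setdiff(sig_measured, sig_latent)),
                  length(intersect(sig_measured, sig_latent)),
                  length(setdiff(sig_latent, sig_measured))))

  sig_all <- union(sig_measured, sig_latent)
  win_in <- dplyr::filter(cohort$markers, .data$marker %in% sig_all)
  windows <- group_windows(win_in, config$window_size)
  note("windows", sprintf("%d windows from %d markers", nrow(windows),
                          length(sig_all)), nrow(windows))

  out <- structure(list(discoveries = discoveries, totals = totals,
                        mediation_scans = med_scan,
                        mediator_selection = selection,
                        mwas = mwas, gwas = gwas,
                        latent = latent$fits, venn = venn,
                        windows = windows,
                        log = dplyr::bind_rows(log),
                        config = config),
                   class = "discovery_table")
  out$counts <- summarize_discoveries(out)
  out
}

run_latent_stage <- function(dat, discoveries, chosen, config, covs_of, note) {
  empty <- tibble::tibble(factor = character(0), mediator = character(0),
                          marker = character(0), alpha = numeric(0),
                          beta = numeric(0), gamma_dir = numeric(0),
                          indirect = numeric(0), ratio = numeric(0),
                          sobel_p = numeric(0), significant = logical(0))
  if (!config$latent || nrow(chosen) == 0L || nrow(discoveries) == 0L) {
    note("latent", "latent stage skipped", 0L)
    return(list(fits = empty))
  }
  fits <- list()
  for (i in seq_len(nrow(chosen))) {
    f <- chosen$factor[i]
    m <- chosen$mediator[i]
    ind <- config$factors[[f]]
    spec <- latent_spec(f, ind,
                        cgb = paste0("cgb_", ind), sr = paste0("sr_", ind))
    cand <- discoveries |>
      dplyr::filter(.data$mediator == m) |>
      dplyr::arrange(.data$sobel_p)
    top <- utils::head(unique(cand$marker), config$latent_max_markers)
    for (g in top) {
      fit <- tryCatch(
        fit_sem(dat, spec, "mod4L", marker = g, mediator = m,
                mediator_covariates = covs_of(m)),
        error = function(e) NULL)
      if (is.null(fit)) next
      a <- sem_coef(fit, "alpha"); b <- sem_coef(fit, "beta")
      gd <- sem_coef(fit, "gamma_dir")
      ind_eff <- a * b
      rto <- if (gd == 0) ifelse(ind_eff == 0, 0, Inf) else abs(ind_eff / gd)
      sa <- sem_se(fit, "alpha"); sb <- sem_se(fit, "beta")
      den <- sqrt(a^2 * sb^2 + b^2 * sa^2)
      pz <- if (is.finite(den) && den > 0) {
        2 * stats::pnorm(abs(ind_eff / den), lower.tail = FALSE)
      } else {
        NA_real_
      }
      sig <- if (config$latent_rounds > 0) {
        fitter <- sem_fitter(spec, g, m, covs_of(m))
        bt <- bootstrap_test(dat, fitter, "indirect", config$latent_rounds,
                             config$level, layer_seed(config$seed, 9000L + i))
        pt_ <- permutation_test(dat, fitter, m, "indirect",
                                config$latent_rounds, config$level,
                                layer_seed(config$seed, 9500L + i))
        joint_decision(dplyr::bind_rows(bt, pt_))
      } else {
        rto > config$ratio_threshold && !is.na(pz) && pz < 0.05
      }
      fits[[paste(f, m, g)]] <- tibble::tibble(
        factor = f, mediator = m, marker = g, alpha = a, beta = b,
        gamma_dir = gd, indirect = ind_eff, ratio = rto, sobel_p = pz,
        significant = sig)
    }
  }
  res <- if (length(fits)) dplyr::bind_rows(fits) else empty
  note("latent", sprintf("%d latent mediation fits", nrow(res)), nrow(res))
  list(fits = res)
}

empty_med_scan <- function() {
  tibble::tibble(response = character(0), mediator = character(0),
                 marker = character(0), alpha = numeric(0),
                 se_alpha = numeric(0), beta = numeric(0),
                 se_beta = numeric(0), gamma_dir = numeric(0),
                 se_gamma_dir = numeric(0), indirect = numeric(0),
                 ratio = numeric(0), sobel_z = numeric(0),
                 sobel_p = numeric(0), untestable = logical(0))
}

empty_discoveries <- function() {
  dplyr::mutate(empty_med_scan(), boot_lower = numeric(0),
                boot_upper = numeric(0), boot_significant = logical(0),
                perm_lower = numeric(0), perm_upper = numeric(0),
                perm_significant = logical(0), joint_significant = logical(0))
}

#' Recompute the summary counts of a discovery table
#'
#' Summary numbers are always derivable from the row-level records; this
#' recomputes them (discoveries per response x mediator, total-effect
#' counts, window count) from scratch.
#'
#' @param x A `discovery_table`.
#' @return Tibble of summary counts.
#' @export
summarize_discoveries <- function(x) {
  stopifnot(inherits(x, "discovery_table"))
  med <- x$discoveries |>
    dplyr::group_by(.data$response, .data$mediator) |>
    dplyr::summarise(kind = "mediated",
                     n_candidates = dplyr::n(),
                     n_significant = sum(.data$joint_significant),
                     .groups = "drop")
  tot <- if (nrow(x$totals)) {
    x$totals |>
      dplyr::group_by(.data$response) |>
      dplyr::summarise(mediator = NA_character_, kind = "total",
                       n_candidates = dplyr::n(),
                       n_significant = sum(.data$boot_significant),
                       .groups = "drop")
  } else {
    NULL
  }
  dplyr::bind_rows(med, tot)
}

#' @export
print.discovery_table <- function(x, ...) {
  cat("<discovery_table>\n")
  cat(sprintf("  %d mediation triples tested, %d pass bootstrap+permutation\n",
              nrow(x$discoveries), sum(x$discoveries$joint_significant)))
  cat(sprintf("  %d total-effect candidates, %d windows\n",
              nrow(x$totals), nrow(x$windows)))
  if (nrow(x$counts)) {
    print(as.data.frame(x$counts))
  }
  invisible(x)
}
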