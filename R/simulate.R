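#' Configure a synthetic cohort
#'
#' Builds the configuration for [simulate_cohort()]. Defaults describe the
#' smoke-test preset (500 individuals, 2,000 markers); `preset = "cohort"`
#' switches to the full commercial-pig-like cohort scale (1,183 individuals,
#' 40,542 markers). The cross-classified nuisance structure defaults to 12
#' contemporary groups, 2 dam lines, 28 sires and 331 pens, pens nested
#' within contemporary groups.
#'
#' Six fat-deposition traits (`bf1`\ldots`bf4`, `bft`, `bel`) load on two
#' latent factors: `fatg` (lifetime backfat growth, indicators bf1-bf3) and
#' `fatt` (terminal fat deposition, indicators bf4/bft/bel). Planted effects
#' are supplied as data frames: `alpha` (marker, otu, effect) acts on CLR
#' abundances, `beta` (otu, response, effect) and `gamma` (marker, response,
#' effect) act on traits or latent factor scores.
#'
#' @param n_individuals,n_markers,n_otus Cohort dimensions.
#' @param maf_range Interval in (0, 0.5] from which per-marker minor-allele
#'   frequencies are drawn uniformly.
#' @param rarefaction_depth Total count per sample for the multinomial read
#'   draw (default 10,000, the depth the pipeline assumes upstream).
#' @param n_cg,n_sires,n_pens,n_damlines Nuisance-factor level counts.
#' @param effects List with data frames `alpha`, `beta`, `gamma` as above
#'   (any may be absent or empty).
#' @param loadings Data frame `trait, factor, loading, uniqueness` mapping
#'   the six traits to the two latent factors.
#' @param variances Named list of nuisance variances: `cg`, `pen`, `sire`,
#'   `resid` for the trait layer; `otu_cg`, `otu_pen`, `otu_noise` for the
#'   latent log-abundance layer.
#' @param damline_effect Additive effect of dam line (coded 1/2) on every
#'   factor score.
#' @param otu_baseline_sd SD of per-feature baseline log-abundances; larger
#'   values spread feature proportions over more orders of magnitude and so
#'   produce more sampling zeros.
#' @param stage Stage label for the simulated OTU table.
#' @param seed Integer seed; identical configurations reproduce the cohort
#'   byte for byte.
#' @param preset `"smoke"` (default) or `"cohort"` for the full scale.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_individuals = 500, n_markers = 2000,
                       maf_range = c(0.05, 0.5), n_otus = 50,
                       rarefaction_depth = 10000,
                       n_cg = 12, n_sires = 28, n_pens = 331, n_damlines = 2,
                       effects = list(), loadings = default_loadings(),
                       variances = list(cg = 0.10, pen = 0.05, sire = 0.05,
                                        resid = 0.55, otu_cg = 0.10,
                                        otu_pen = 0.05, otu_noise = 1),
                       damline_effect = 0.10, otu_baseline_sd = 1.5,
                       stage = "S2", seed = 1,
                       preset = c("smoke", "cohort")) {
  preset <- match.arg(preset)
  if (preset == "cohort") {
    if (missing(n_individuals)) n_individuals <- 1183
    if (missing(n_markers)) n_markers <- 40542
  }
  cfg <- list(n_individuals = n_individuals, n_markers = n_markers,
              maf_range = maf_range, n_otus = n_otus,
              rarefaction_depth = rarefaction_depth, n_cg = n_cg,
              n_sires = n_sires, n_pens = n_pens, n_damlines = n_damlines,
              effects = effects, loadings = tibble::as_tibble(loadings),
              variances = variances, damline_effect = damline_effect,
              otu_baseline_sd = otu_baseline_sd, stage = stage,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @export
default_loadings <- function() {
  tibble::tibble(
    trait = c("bf1", "bf2", "bf3", "bf4", "bft", "bel"),
    factor = c("fatg", "fatg", "fatg", "fatt", "fatt", "fatt"),
    loading = c(1.0, 0.9, 0.8, 1.0, 0.8, 0.6),
    uniqueness = c(0.50, 0.40, 0.45, 0.35, 0.50, 0.60))
}

validate_sim_config <- function(cfg) {
  counts <- c(cfg$n_individuals, cfg$n_markers, cfg$n_otus,
              cfg$rarefaction_depth, cfg$n_cg, cfg$n_sires, cfg$n_pens,
              cfg$n_damlines)
  if (!all(vapply(counts, is_count, logical(1)))) {
    abort("all cohort dimensions must be positive integers")
  }
  mr <- cfg$maf_range
  if (length(mr) != 2 || mr[1] <= 0 || mr[2] > 0.5 || mr[1] > mr[2]) {
    abort("maf_range must lie within (0, 0.5]")
  }
  if (any(unlist(cfg$variances) < 0)) abort("variances must be non-negative")
  if (any(cfg$loadings$uniqueness < 0)) abort("uniqueness variances must be non-negative")
  markers <- paste0("snp_", seq_len(cfg$n_markers))
  otus <- paste0("otu_", seq_len(cfg$n_otus))
  responses <- c(cfg$loadings$trait, unique(cfg$loadings$factor))
  check_ids <- function(ids, universe, what) {
    bad <- setdiff(ids, universe)
    if (length(bad)) {
      abort(sprintf("effect spec references unknown %s: %s", what,
                    paste(utils::head(bad, 5), collapse = ", ")))
    }
  }
  ef <- cfg$effects
  if (!is.null(ef$alpha) && nrow(ef$alpha)) {
    check_ids(ef$alpha$marker, markers, "marker ids")
    check_ids(ef$alpha$otu, otus, "otu ids")
  }
  if (!is.null(ef$beta) && nrow(ef$beta)) {
    check_ids(ef$beta$otu, otus, "otu ids")
    check_ids(ef$beta$response, responses, "response ids")
  }
  if (!is.null(ef$gamma) && nrow(ef$gamma)) {
    check_ids(ef$gamma$marker, markers, "marker ids")
    check_ids(ef$gamma$response, responses, "response ids")
  }
  invisible(cfg)
}

#' Simulate a cohort with known ground truth
#'
#' Generates, in four independent random streams (genotypes, design,
#' microbiome, phenotypes), a cohort with the statistical structure the
#' mediation framework assumes:
#'
#' * per-marker dosages drawn as Binomial(2, MAF), MAF uniform in
#'   `maf_range`, markers spread over 18 autosomes;
#' * contemporary groups crossed with pens nested in groups, random-balanced
#'   sires and a binary dam line coded 1/2;
#' * latent log-abundances built as a linear model in dosage and design
#'   effects plus Gaussian noise, mapped to counts by a single multinomial
#'   draw per sample at `rarefaction_depth` from the softmax of the latent
#'   row (low-proportion features then show sampling zeros, which is the
#'   only zero-inflation mechanism);
#' * traits built as loading x factor score + uniqueness noise, the factor
#'   score being the sum of planted direct effects, planted beta x true CLR
#'   mediator values, design effects and a residual.
#'
#' The `truth` element records every planted coefficient, the loadings, the
#' realized factor scores and the nuisance draws before any downstream noise.
#'
#' @param config A [sim_config()].
#' @return A `medipath_cohort` list: `genotypes`, `otu` (counts, stage
#'   attached), `phenotypes`, `design`, `markers` (chromosome/index/position
#'   metadata), `truth`, `config`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_individuals = 60, n_markers = 10,
#'                                      n_otus = 8, n_pens = 24, seed = 7))
#' dplyr::glimpse(cohort$phenotypes)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  n <- config$n_individuals
  ids <- sprintf("id_%04d", seq_len(n))
  markers <- paste0("snp_", seq_len(config$n_markers))
  otus <- paste0("otu_", seq_len(config$n_otus))

  # --- genotype layer -------------------------------------------------------
  geno <- withr::with_seed(layer_seed(config$seed, 1L), {
    maf <- runif(config$n_markers, config$maf_range[1], config$maf_range[2])
    dos <- vapply(maf, function(p) rbinom(n, 2L, p), integer(n))
    list(maf = maf, dosage = dos)
  })
  dosage <- geno$dosage
  colnames(dosage) <- markers
  chrom <- sort(rep_len(seq_len(18L), config$n_markers))
  marker_meta <- tibble::tibble(marker = markers, chrom = chrom) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(index = dplyr::row_number(), pos = .data$index * 50000L) |>
    dplyr::ungroup()

  # --- design layer ---------------------------------------------------------
  design <- withr::with_seed(layer_seed(config$seed, 2L), {
    cg <- sample(rep_len(seq_len(config$n_cg), n))
    pen_of_cg <- split(seq_len(config$n_pens),
                       rep_len(seq_len(config$n_cg), config$n_pens))
    pen <- vapply(cg, function(g) {
      pool <- pen_of_cg[[g]]
      pool[sample.int(length(pool), 1L)]
    }, integer(1))
    sire <- sample(rep_len(seq_len(config$n_sires), n))
    damline <- sample(rep_len(seq_len(config$n_damlines), n))
    tibble::tibble(sample_id = ids,
                   cg = sprintf("cg_%02d", cg),
                   damline = damline,
                   sire = sprintf("sire_%02d", sire),
                   pen = sprintf("pen_%03d", pen))
  })

  ef <- config$effects
  alpha <- effect_frame(ef$alpha, c("marker", "otu", "effect"))
  beta <- effect_frame(ef$beta, c("otu", "response", "effect"))
  gamma <- effect_frame(ef$gamma, c("marker", "response", "effect"))
  v <- config$variances

  # --- microbiome layer -----------------------------------------------------
  micro <- withr::with_seed(layer_seed(config$seed, 3L), {
    baseline <- rnorm(config$n_otus, 0, config$otu_baseline_sd)
    cg_eff <- matrix(rnorm(config$n_cg * config$n_otus, 0, sqrt(v$otu_cg)),
                     config$n_cg, config$n_otus)
    pen_eff <- matrix(rnorm(config$n_pens * config$n_otus, 0, sqrt(v$otu_pen)),
                      config$n_pens, config$n_otus)
    noise <- matrix(rnorm(n * config$n_otus, 0, sqrt(v$otu_noise)),
                    n, config$n_otus)
    cg_idx <- as.integer(sub("cg_", "", design$cg))
    pen_idx <- as.integer(sub("pen_", "", design$pen))
    lat <- matrix(baseline, n, config$n_otus, byrow = TRUE) +
      cg_eff[cg_idx, , drop = FALSE] + pen_eff[pen_idx, , drop = FALSE] + noise
    if (nrow(alpha)) {
      for (k in seq_len(nrow(alpha))) {
        j <- match(alpha$otu[k], otus)
        lat[, j] <- lat[, j] + alpha$effect[k] * dosage[, alpha$marker[k]]
      }
    }
    counts <- t(vapply(seq_len(n), function(i) {
      p <- exp(lat[i, ] - max(lat[i, ]))
      as.integer(rmultinom(1L, config$rarefaction_depth, p / sum(p)))
    }, integer(config$n_otus)))
    list(latent = lat, counts = counts,
         nuisance = list(cg = cg_eff, pen = pen_eff))
  })
  clr_true <- micro$latent - rowMeans(micro$latent)
  colnames(clr_true) <- otus
  counts <- micro$counts
  colnames(counts) <- otus

  # --- phenotype layer ------------------------------------------------------
  load_tab <- config$loadings
  factors <- unique(load_tab$factor)
  phen <- withr::with_seed(layer_seed(config$seed, 4L), {
    cg_idx <- as.integer(sub("cg_", "", design$cg))
    pen_idx <- as.integer(sub("pen_", "", design$pen))
    sire_idx <- as.integer(sub("sire_", "", design$sire))
    cg_f <- matrix(rnorm(config$n_cg * length(factors), 0, sqrt(v$cg)),
                   config$n_cg, length(factors), dimnames = list(NULL, factors))
    pen_f <- matrix(rnorm(config$n_pens * length(factors), 0, sqrt(v$pen)),
                    config$n_pens, length(factors), dimnames = list(NULL, factors))
    sire_f <- matrix(rnorm(config$n_sires * length(factors), 0, sqrt(v$sire)),
                     config$n_sires, length(factors), dimnames = list(NULL, factors))
    scores <- matrix(0, n, length(factors), dimnames = list(NULL, factors))
    for (f in factors) {
      eta <- cg_f[cg_idx, f] + pen_f[pen_idx, f] + sire_f[sire_idx, f] +
        config$damline_effect * (design$damline - mean(c(1, config$n_damlines))) +
        rnorm(n, 0, sqrt(v$resid))
      g_f <- gamma[gamma$response == f, , drop = FALSE]
      for (k in seq_len(nrow(g_f))) {
        eta <- eta + g_f$effect[k] * dosage[, g_f$marker[k]]
      }
      b_f <- beta[beta$response == f, , drop = FALSE]
      for (k in seq_len(nrow(b_f))) {
        eta <- eta + b_f$effect[k] * clr_true[, b_f$otu[k]]
      }
      scores[, f] <- eta
    }
    traits <- matrix(0, n, nrow(load_tab), dimnames = list(NULL, load_tab$trait))
    for (t in seq_len(nrow(load_tab))) {
      tr <- load_tab$trait[t]
      y <- load_tab$loading[t] * scores[, load_tab$factor[t]] +
        rnorm(n, 0, sqrt(load_tab$uniqueness[t]))
      g_t <- gamma[gamma$response == tr, , drop = FALSE]
      for (k in seq_len(nrow(g_t))) y <- y + g_t$effect[k] * dosage[, g_t$marker[k]]
      b_t <- beta[beta$response == tr, , drop = FALSE]
      for (k in seq_len(nrow(b_t))) y <- y + b_t$effect[k] * clr_true[, b_t$otu[k]]
      traits[, tr] <- y
    }
    list(traits = traits, scores = scores,
         nuisance = list(cg = cg_f, pen = pen_f, sire = sire_f))
  })

  otu_tab <- matrix_tibble(counts, ids)
  otu_tab <- set_otu_kind(otu_tab, "counts")
  otu_stage(otu_tab) <- config$stage

  truth <- list(
    effects = dplyr::bind_rows(
      if (nrow(alpha)) dplyr::transmute(alpha, type = "alpha",
        marker = .data$marker, feature = .data$otu, response = .data$otu,
        value = .data$effect),
      if (nrow(beta)) dplyr::transmute(beta, type = "beta",
        marker = NA_character_, feature = .data$otu, response = .data$response,
        value = .data$effect),
      if (nrow(gamma)) dplyr::transmute(gamma, type = "gamma",
        marker = .data$marker, feature = NA_character_,
        response = .data$response, value = .data$effect)),
    loadings = load_tab,
    factor_scores = matrix_tibble(phen$scores, ids),
    clr_true = matrix_tibble(clr_true, ids),
    maf = tibble::tibble(marker = markers, maf = geno$maf),
    nuisance = list(otu = micro$nuisance, trait = phen$nuisance))

  structure(list(genotypes = matrix_tibble(dosage, ids),
                 otu = otu_tab,
                 phenotypes = matrix_tibble(phen$traits, ids),
                 design = design,
                 markers = marker_meta,
                 truth = truth,
                 config = config),
            class = "medipath_cohort")
}

effect_frame <- function(x, cols) {
  if (is.null(x) || nrow(tibble::as_tibble(x)) == 0L) {
    out <- tibble::as_tibble(stats::setNames(
      rep(list(character(0)), length(cols)), cols))
    out$effect <- numeric(0)
    return(out)
  }
  out <- tibble::as_tibble(x)
  stopifnot(all(cols %in% names(out)))
  out[cols]
}

#' @export
print.medipath_cohort <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<medipath_cohort> %d individuals, %d markers, %d OTUs (stage %s)\n",
              cfg$n_individuals, cfg$n_markers, cfg$n_otus, otu_stage(x$otu)))
  cat(sprintf("  design: %d CGs, %d pens, %d sires, %d dam lines\n",
              cfg$n_cg, cfg$n_pens, cfg$n_sires, cfg$n_damlines))
  cat(sprintf("  planted effects: %d\n", nrow(x$truth$effects)))
  invisible(x)
}
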