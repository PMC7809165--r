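#' Preprocessing of OTU count tables
#'
#' OTU tables are wide tibbles with a `sample_id` column followed by one
#' numeric column per microbial feature. Counts enter as non-negative
#' integers (typically rarefied to a common depth upstream); preprocessing
#' filters sparse features, replaces zeros multiplicatively and applies the
#' centered log-ratio (CLR) transform so that downstream models can treat
#' relative abundances as unconstrained real covariates.
#'
#' The state of a table (`"counts"`, `"composition"` or `"clr"`) is tracked
#' in the `otu_kind` attribute and re-inferred from the values when the
#' attribute has been stripped by intermediate manipulation, so a CLR table
#' is never silently re-filtered or re-transformed.
#'
#' @name otu-preprocessing
NULL

otu_kind <- function(otu) {
  kind <- attr(otu, "otu_kind", exact = TRUE)
  if (!is.null(kind)) return(kind)
  m <- wide_matrix(otu)
  if (any(m < 0)) return("clr")
  if (all(m == round(m))) return("counts")
  "composition"
}

set_otu_kind <- function(otu, kind) {
  attr(otu, "otu_kind") <- kind
  otu
}

#' Stage label of an OTU table
#'
#' Fecal samples are collected at successive time points (stages, e.g.
#' `"S1"`, `"S2"`, `"S3"`); the stage restricts which traits a feature may
#' mediate (a microbe sampled after a trait was recorded cannot cause it).
#'
#' @param otu An OTU table (wide tibble with `sample_id`).
#' @return The stage label (character scalar), `"S2"` if never set.
#' @seealso [select_mediators()] for the causal-timing screen.
#' @export
otu_stage <- function(otu) attr(otu, "stage", exact = TRUE) %||% "S2"

#' @rdname otu_stage
#' @param value New stage label.
#' @export
`otu_stage<-` <- function(otu, value) {
  attr(otu, "stage") <- value
  otu
}

#' Per-feature presence
#'
#' Presence is the fraction of samples in which a feature has a nonzero
#' count; sparse features (low presence) are candidates for removal.
#'
#' @param otu An OTU count table.
#' @return A tibble with columns `feature` and `presence` (in \[0, 1\]).
#' @export
otu_presence <- function(otu) {
  if (otu_kind(otu) != "counts") abort("presence is defined on count tables")
  m <- wide_matrix(otu)
  tibble::tibble(feature = colnames(m), presence = unname(colMeans(m > 0)))
}

#' Filter sparse OTU features
#'
#' Removes features with an overall count below `min_total` or a zero count
#' in more than `max_zero_fraction` of the samples. Both rules are evaluated
#' jointly on the incoming counts; the sample set is never changed. The ids
#' of removed features are attached as the `removed_features` attribute.
#'
#' @param otu An OTU count table (wide tibble, `sample_id` first).
#' @param min_total Minimum total count over all samples (default 1200).
#' @param max_zero_fraction Maximum tolerated fraction of zero cells per
#'   feature (default 0.80; a feature zero in *more* than this fraction is
#'   removed).
#' @return The filtered count table; `attr(., "removed_features")` lists the
#'   dropped feature ids.
#' @examples
#' otu <- tibble::tibble(sample_id = paste0("s", 1:5),
#'                       a = c(300, 300, 300, 300, 0),
#'                       b = c(1, 0, 0, 0, 0))
#' filter_otus(otu, min_total = 1200, max_zero_fraction = 0.8)
#' @export
filter_otus <- function(otu, min_total = 1200, max_zero_fraction = 0.80) {
  if (otu_kind(otu) != "counts") {
    abort("filter_otus() needs a count table; this table is already transformed")
  }
  m <- wide_matrix(otu)
  if (any(m < 0) || any(m != round(m))) abort("counts must be non-negative integers")
  totals <- colSums(m)
  zero_frac <- colMeans(m == 0)
  keep <- totals >= min_total & zero_frac <= max_zero_fraction
  out <- dplyr::select(otu, dplyr::all_of(c("sample_id", colnames(m)[keep])))
  out <- set_otu_kind(out, "counts")
  otu_stage(out) <- otu_stage(otu)
  attr(out, "removed_features") <- colnames(m)[!keep]
  out
}

#' Multiplicative zero replacement
#'
#' Converts counts to row proportions and replaces each zero cell by
#' `delta_fraction` of one count at that row's sequencing depth
#' (`delta_fraction / row_total`); nonzero cells are shrunk multiplicatively
#' so each row still sums to one. This is the deterministic multiplicative
#' replacement of compositional data analysis, used here so that the CLR
#' transform is defined on strictly positive compositions.
#'
#' @param otu A filtered OTU count table.
#' @param delta_fraction Fraction of a single count used as the imputed
#'   proportion for zero cells (default 0.65).
#' @return A composition table (rows sum to 1, all cells positive).
#' @export
replace_zeros <- function(otu, delta_fraction = 0.65) {
  if (otu_kind(otu) != "counts") abort("replace_zeros() expects a count table")
  m <- wide_matrix(otu)
  totals <- rowSums(m)
  if (any(totals == 0)) {
    abort("a sample with all-zero counts cannot form a composition")
  }
  props <- m / totals
  delta <- delta_fraction / totals            # imputed proportion per row
  out <- props
  for (i in seq_len(nrow(m))) {
    z <- m[i, ] == 0
    if (any(z)) {
      out[i, z] <- delta[i]
      out[i, !z] <- props[i, !z] * (1 - sum(z) * delta[i])
    }
  }
  res <- matrix_tibble(out, otu[["sample_id"]])
  res <- set_otu_kind(res, "composition")
  otu_stage(res) <- otu_stage(otu)
  res
}

#' Centered log-ratio transform
#'
#' Maps each strictly positive composition row `x` to
#' `log(x) - mean(log(x))`, so every row sums to zero and relative
#' abundances become unconstrained, scale-invariant real covariates.
#'
#' @param otu A composition table with strictly positive cells (counts with
#'   no zeros are also accepted and normalized internally).
#' @return A CLR table (rows sum to 0).
#' @export
clr_transform <- function(otu) {
  kind <- otu_kind(otu)
  if (kind == "clr") abort("table is already CLR-transformed")
  m <- wide_matrix(otu)
  if (any(m <= 0)) {
    abort("non-positive cells present; run replace_zeros() before clr_transform()")
  }
  lm_ <- log(m)
  out <- lm_ - rowMeans(lm_)
  res <- matrix_tibble(out, otu[["sample_id"]])
  res <- set_otu_kind(res, "clr")
  otu_stage(res) <- otu_stage(otu)
  res
}

#' Validate rarefaction depth
#'
#' Rarefaction to a common depth is assumed to have happened upstream; this
#' check warns when row totals are unequal, which would make proportions
#' incomparable across samples.
#'
#' @param otu An OTU count table.
#' @return Invisibly, the vector of row totals.
#' @export
check_rarefied <- function(otu) {
  if (otu_kind(otu) != "counts") abort("rarefaction check applies to counts")
  totals <- rowSums(wide_matrix(otu))
  if (length(unique(totals)) > 1L) {
    warn(sprintf("unequal sample depths (range %d-%d); table does not look rarefied",
                 min(totals), max(totals)))
  }
  invisible(totals)
}
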