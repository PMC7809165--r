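#' Read and write the tabular interchange formats
#'
#' Genotypes travel as PLINK `.raw`-style whitespace tables (header
#' `FID IID PAT MAT SEX PHENOTYPE` followed by one dosage column per marker,
#' values 0/1/2), OTU counts as TSV (rows = samples, columns = features),
#' phenotypes and design factors as CSV with a header.
#'
#' @name medipath-io
NULL

#' @describeIn medipath-io Write a genotype tibble (`sample_id` + marker
#'   dosage columns) as a PLINK `.raw`-style table.
#' @param genotypes Wide genotype tibble (`sample_id` + 0/1/2 dosages).
#' @param path Output file path.
#' @export
write_plink_raw <- function(genotypes, path) {
  m <- wide_matrix(genotypes)
  out <- data.frame(FID = genotypes$sample_id, IID = genotypes$sample_id,
                    PAT = 0L, MAT = 0L, SEX = 0L, PHENOTYPE = -9L,
                    check.names = FALSE)
  out <- cbind(out, as.data.frame(m, check.names = FALSE))
  readr::write_delim(out, path, delim = " ")
  invisible(path)
}

#' @describeIn medipath-io Read a PLINK `.raw`-style dosage table into a wide
#'   genotype tibble keyed by `IID`.
#' @export
read_plink_raw <- function(path) {
  raw <- readr::read_table(path, show_col_types = FALSE)
  meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  missing <- setdiff(meta, names(raw))
  if (length(missing)) {
    abort(paste0("not a .raw-style table; missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  markers <- setdiff(names(raw), meta)
  out <- dplyr::bind_cols(tibble::tibble(sample_id = as.character(raw$IID)),
                          raw[markers])
  bad <- vapply(out[markers], function(x) any(!x %in% c(0, 1, 2, NA)), logical(1))
  if (any(bad)) abort("dosage columns must contain only 0/1/2 (or NA)")
  out
}

#' @describeIn medipath-io Write an OTU table (counts or CLR) as TSV.
#' @param otu OTU table to write.
#' @export
write_otu_tsv <- function(otu, path) {
  readr::write_tsv(otu, path)
  invisible(path)
}

#' @describeIn medipath-io Read an OTU table from TSV; `stage` labels the
#'   sampling time point.
#' @param stage Stage label to attach (default `"S2"`).
#' @export
read_otu_tsv <- function(path, stage = "S2") {
  otu <- readr::read_tsv(path, show_col_types = FALSE)
  names(otu)[1] <- "sample_id"
  otu$sample_id <- as.character(otu$sample_id)
  otu_stage(otu) <- stage
  otu
}

#' @describeIn medipath-io Write a phenotype or design tibble as CSV.
#' @param df Tibble to write.
#' @export
write_cohort_csv <- function(df, path) {
  readr::write_csv(df, path)
  invisible(path)
}

#' @describeIn medipath-io Read a phenotype or design tibble from CSV.
#' @export
read_cohort_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if ("sample_id" %in% names(df)) df$sample_id <- as.character(df$sample_id)
  df
}

#' @describeIn medipath-io Write a whole simulated cohort (genotypes, OTU
#'   counts, phenotypes, design, truth) to a directory of plain-text files.
#' @param cohort A `medipath_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if absent).
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_plink_raw(cohort$genotypes, file.path(dir, "genotypes.raw"))
  write_otu_tsv(cohort$otu, file.path(dir, "otu_counts.tsv"))
  write_cohort_csv(cohort$phenotypes, file.path(dir, "phenotypes.csv"))
  write_cohort_csv(cohort$design, file.path(dir, "design.csv"))
  write_cohort_csv(cohort$markers, file.path(dir, "markers.csv"))
  yaml::write_yaml(list(stage = otu_stage(cohort$otu)), file.path(dir, "meta.yaml"))
  invisible(dir)
}
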