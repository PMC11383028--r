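#' Read a peptide intensity table
#'
#' Reads a TSV/CSV table with a `peptide_id` first column and one column of
#' intensities per sample. Missing-value encoding is explicit, never
#' inferred: under `"blank_is_missing"` empty cells (or `NA`) are missing
#' and a literal `0` is an observed zero; under `"zero_is_missing"` zeros
#' are missing too.
#'
#' @param path path to the table. Comma-separated when the extension is
#'   `.csv`, tab-separated otherwise (override with `sep`).
#' @param dialect missing-value dialect, see [proxidiff_config()].
#' @param sep field separator; default inferred from the extension.
#' @return a [pqm()] object at stage `"raw"`.
#' @export
read_peptide_table <- function(path,
                               dialect = c("blank_is_missing",
                                           "zero_is_missing"),
                               sep = NULL) {
  dialect <- match.arg(dialect)
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  df <- read.table(path, header = TRUE, sep = sep, quote = "",
                   check.names = FALSE, colClasses = NA,
                   stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if (ncol(df) < 2L) stop("peptide table needs id + >=1 sample column",
                          call. = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate peptide ids", call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric intensity values", call. = FALSE)
  rownames(m) <- ids
  observed <- !is.na(m)
  if (dialect == "zero_is_missing") observed <- observed & (m != 0)
  if (any(m[observed] < 0)) stop("negative intensity values", call. = FALSE)
  m[!observed] <- 0
  pqm(m, observed = observed, stage = "raw")
}

#' Write a peptide intensity table
#'
#' Inverse of [read_peptide_table()]: missing entries are written as empty
#' fields under `"blank_is_missing"` and as `0` under `"zero_is_missing"`.
#'
#' @param x a [pqm()] object.
#' @param path output path (`.csv` for comma-separated, else TSV).
#' @param dialect missing-value dialect.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(x,
                                path,
                                dialect = c("blank_is_missing",
                                            "zero_is_missing")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(x, "pqm"))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  m <- x$intensity
  df <- data.frame(peptide_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (dialect == "blank_is_missing") {
    for (j in seq_len(ncol(m))) {
      col <- format_num(m[, j])
      col[!x$observed[, j]] <- ""
      df[[j + 1L]] <- col
    }
  } else {
    for (j in seq_len(ncol(m))) {
      v <- m[, j]
      v[!x$observed[, j]] <- 0
      df[[j + 1L]] <- format_num(v)
    }
  }
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Full-precision, locale-independent numeric formatting for round-trips.
format_num <- function(v) {
  vapply(v, function(x) format(x, digits = 17, scientific = FALSE,
                               trim = TRUE), character(1))
}

#' Read a sample design table
#'
#' CSV with columns `sample_id`, `genotype`, `construct`, `replicate`,
#' `is_spqc`; validated by [sample_design()]. Row order is preserved.
#'
#' @param path path to the CSV file.
#' @return a [sample_design()] table.
#' @export
read_design <- function(path) {
  df <- tryCatch(
    read.table(path, header = TRUE, sep = ",", quote = "",
               stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse design file: ",
                             conditionMessage(e), call. = FALSE))
  sample_design(df)
}

#' Write a sample design table
#' @param design a [sample_design()] table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  df <- as.data.frame(design)
  df$genotype[is.na(df$genotype)] <- ""
  df$construct[is.na(df$construct)] <- ""
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a peptide-to-protein map
#'
#' TSV with columns `peptide_id` and `protein_accessions`
#' (semicolon-separated candidate accessions, at least one per peptide).
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `peptide_id` and `candidates` (the
#'   semicolon-joined accession string).
#' @export
read_peptide_map <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", quote = "",
                   stringsAsFactors = FALSE)
  if (!all(c("peptide_id", "protein_accessions") %in% names(df))) {
    stop("map must have columns peptide_id, protein_accessions",
         call. = FALSE)
  }
  if (anyDuplicated(df$peptide_id)) {
    stop("duplicate peptide ids in map", call. = FALSE)
  }
  if (any(!nzchar(df$protein_accessions))) {
    stop("peptide with zero candidate proteins", call. = FALSE)
  }
  data.frame(peptide_id = as.character(df$peptide_id),
             candidates = as.character(df$protein_accessions),
             stringsAsFactors = FALSE)
}

#' Write a peptide-to-protein map
#' @param map data.frame with `peptide_id` and `candidates` columns.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_peptide_map <- function(map, path) {
  df <- data.frame(peptide_id = map$peptide_id,
                   protein_accessions = map$candidates)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write pipeline results to a directory
#'
#' Writes one TSV per differential contrast, the per-genotype bait
#' enrichment tables, the gained/lost interactor lists with provenance,
#' QC summaries, PCA coordinates, the imputation audit, the rolled-up
#' protein matrix and a run-metadata JSON recording the configuration and
#' seed. Outputs are deterministic: the same fitted object always produces
#' byte-identical files.
#'
#' @param fit a fitted [proxidiff()] object.
#' @param out_dir output directory; created if absent.
#' @return character vector of files written (the manifest), invisibly.
#' @export
write_results <- function(fit, out_dir) {
  stopifnot(inherits(fit, "proxidiff"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir,
                  call. = FALSE)
  }
  manifest <- character(0)
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <<- c(manifest, name)
  }

  emit(fit$contrast, "contrast_GS_vs_WT_EZR.tsv")
  emit(fit$enrichment$WT$table, "enrichment_WT_EZR_vs_CYT.tsv")
  emit(fit$enrichment$GS$table, "enrichment_GS_EZR_vs_CYT.tsv")
  emit(fit$calls$provenance, "interactors_high_confidence.tsv")
  emit(fit$audit, "imputation_audit.tsv")

  pm <- data.frame(protein = rownames(fit$proteins$intensity),
                   peptide_count = fit$proteins$peptide_count,
                   fit$proteins$intensity, check.names = FALSE)
  emit(pm, "protein_matrix.tsv")

  qc <- fit$qc
  qcs <- data.frame(metric = c("mean_spqc_cv",
                               paste0("mean_cv_", names(qc$group_cv))),
                    value = c(if (is.null(qc$spqc_cv)) NA_real_ else
                                qc$spqc_cv$mean_cv,
                              vapply(qc$group_cv, function(g) g$mean_cv,
                                     numeric(1))))
  emit(qcs, "qc_summary.tsv")
  pca <- data.frame(sample_id = rownames(qc$pca$coordinates),
                    qc$pca$coordinates,
                    check.names = FALSE)
  emit(pca, "pca_coordinates.tsv")

  meta <- list(package = "proxidiff",
               version = as.character(utils::packageVersion("proxidiff")),
               config = fit$config[!vapply(fit$config, is.null,
                                           logical(1))])
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- c(manifest, "run_metadata.json")
  invisible(file.path(out_dir, manifest))
}
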