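#' Peptide quantification matrix
#'
#' Container for a peptide x sample intensity matrix with an explicit
#' missingness mask and a processing-stage marker. Intensities are kept on
#' the linear (raw) scale throughout; log2 happens only inside the
#' statistics. Unobserved entries are stored as 0 internally but are never
#' interpreted as measured zeros: the `observed` mask is authoritative.
#'
#' @param intensity numeric matrix, peptides in rows (rownames = peptide
#'   ids), samples in columns (colnames = sample ids). Must be finite and
#'   non-negative wherever `observed` is `TRUE`.
#' @param observed logical matrix of the same shape; `TRUE` where the entry
#'   was measured. Defaults to all-observed.
#' @param stage processing stage, one of
#'   `"raw"`, `"filtered"`, `"total_normalized"`, `"imputed"`,
#'   `"trimmed_normalized"`. Stages only ever advance in that order.
#' @return an object of class `"pqm"`: a list with elements `intensity`,
#'   `observed` and `stage`.
#' @examples
#' m <- matrix(c(1e6, 2e6, 0, 4e6), 2, 2,
#'             dimnames = list(c("PEPA", "PEPB"), c("s1", "s2")))
#' x <- pqm(m, observed = m > 0)
#' n_missing(x)
#' @export
pqm <- function(intensity, observed = NULL, stage = "raw") {
  if (!is.matrix(intensity) || !is.numeric(intensity)) {
    stop("`intensity` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(intensity) > 0L && is.null(rownames(intensity))) {
    stop("`intensity` must have peptide rownames", call. = FALSE)
  }
  if (ncol(intensity) > 0L && is.null(colnames(intensity))) {
    stop("`intensity` must have sample colnames", call. = FALSE)
  }
  if (is.null(rownames(intensity))) rownames(intensity) <- character(0)
  if (anyDuplicated(rownames(intensity))) {
    stop("duplicate peptide ids in intensity matrix", call. = FALSE)
  }
  if (anyDuplicated(colnames(intensity))) {
    stop("duplicate sample ids in intensity matrix", call. = FALSE)
  }
  if (is.null(observed)) {
    observed <- matrix(TRUE, nrow(intensity), ncol(intensity),
                       dimnames = dimnames(intensity))
  }
  if (!is.matrix(observed) || !is.logical(observed) ||
      !identical(dim(observed), dim(intensity))) {
    stop("`observed` must be a logical matrix matching `intensity`",
         call. = FALSE)
  }
  stage <- match.arg(stage, pqm_stages())
  vals <- intensity[observed]
  if (length(vals) && (any(!is.finite(vals)) || any(vals < 0))) {
    stop("observed intensities must be finite and >= 0", call. = FALSE)
  }
  intensity[!observed] <- 0
  dimnames(observed) <- dimnames(intensity)
  structure(list(intensity = intensity, observed = observed, stage = stage),
            class = "pqm")
}

pqm_stages <- function() {
  c("raw", "filtered", "total_normalized", "imputed", "trimmed_normalized")
}

# Advance the stage marker; transitions only move forward in the enum.
advance_stage <- function(x, new_stage) {
  from <- match(x$stage, pqm_stages())
  to <- match(new_stage, pqm_stages())
  if (is.na(to) || to < from) {
    stop(sprintf("invalid stage transition %s -> %s", x$stage, new_stage),
         call. = FALSE)
  }
  x$stage <- new_stage
  x
}

require_stage <- function(x, stage) {
  if (!inherits(x, "pqm")) stop("expected a `pqm` object", call. = FALSE)
  if (!identical(x$stage, stage)) {
    stop(sprintf("expected a matrix at stage '%s', got '%s'",
                 stage, x$stage), call. = FALSE)
  }
  invisible(x)
}

#' @export
print.pqm <- function(x, ...) {
  cat(sprintf("Peptide quant matrix [%s]: %d peptides x %d samples, %d missing\n",
              x$stage, nrow(x$intensity), ncol(x$intensity), n_missing(x)))
  invisible(x)
}

#' Number of unobserved entries in a quant matrix
#' @param x a [pqm()] object.
#' @return integer count of entries with `observed = FALSE`.
#' @export
n_missing <- function(x) {
  stopifnot(inherits(x, "pqm"))
  sum(!x$observed)
}

#' Sample design table
#'
#' Validate a per-sample annotation table for the two-genotype, two-construct
#' BioID design with pooled SPQC injections.
#'
#' @param df data.frame with columns `sample_id`, `genotype` (`"WT"` or
#'   `"GS"`; ignored for SPQC rows), `construct` (`"EZR"` bait or `"CYT"`
#'   cytosolic control; ignored for SPQC rows), `replicate` (positive
#'   integer) and `is_spqc` (logical).
#' @return the validated data.frame with class `"sample_design"`. A warning
#'   is emitted (and the attribute `small_groups` set) when a biological
#'   group has fewer than 2 replicates; such groups are rejected later by
#'   the statistics, not at read time.
#' @export
sample_design <- function(df) {
  required <- c("sample_id", "genotype", "construct", "replicate", "is_spqc")
  if (!is.data.frame(df) || !all(required %in% names(df))) {
    stop("design must have columns ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0L) stop("design table is empty", call. = FALSE)
  df <- df[, required]
  df$sample_id <- as.character(df$sample_id)
  df$is_spqc <- as.logical(df$is_spqc)
  if (any(is.na(df$is_spqc))) stop("is_spqc must be TRUE/FALSE", call. = FALSE)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample ids in design", call. = FALSE)
  }
  bio <- !df$is_spqc
  df$genotype <- as.character(df$genotype)
  df$construct <- as.character(df$construct)
  # SPQC pools carry no genotype/construct semantics
  df$genotype[!bio] <- NA_character_
  df$construct[!bio] <- NA_character_
  if (!all(df$genotype[bio] %in% c("WT", "GS"))) {
    stop("unknown genotype token; expected WT or GS", call. = FALSE)
  }
  if (!all(df$construct[bio] %in% c("EZR", "CYT"))) {
    stop("unknown construct token; expected EZR or CYT", call. = FALSE)
  }
  df$replicate <- as.integer(df$replicate)
  if (any(bio & (is.na(df$replicate) | df$replicate < 1L))) {
    stop("replicate must be a positive integer", call. = FALSE)
  }
  key <- paste(df$genotype[bio], df$construct[bio], df$replicate[bio])
  if (anyDuplicated(key)) {
    stop("duplicated (genotype, construct, replicate) in design",
         call. = FALSE)
  }
  sizes <- table(paste(df$genotype[bio], df$construct[bio], sep = "_"))
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    warning("biological group(s) with a single replicate: ",
            paste(small, collapse = ", "),
            "; group statistics will refuse them", call. = FALSE)
    attr(df, "small_groups") <- small
  }
  class(df) <- c("sample_design", "data.frame")
  df
}

#' Biological groups of a design
#'
#' @param design a [sample_design()] table.
#' @return named list of sample-id character vectors, one per
#'   genotype x construct group (SPQC samples excluded), named
#'   `"WT_EZR"`, `"WT_CYT"`, `"GS_EZR"`, `"GS_CYT"` as present.
#' @export
biological_groups <- function(design) {
  bio <- design[!design$is_spqc, , drop = FALSE]
  split(bio$sample_id, paste(bio$genotype, bio$construct, sep = "_"))
}

#' SPQC sample ids of a design
#' @param design a [sample_design()] table.
#' @return character vector of SPQC sample ids (possibly empty).
#' @export
spqc_samples <- function(design) {
  design$sample_id[design$is_spqc]
}

group_samples <- function(design, genotype, construct) {
  design$sample_id[!design$is_spqc &
                     design$genotype == genotype &
                     design$construct == construct]
}
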