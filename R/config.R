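#' Pipeline configuration
#'
#' Collects the tunable constants of the analysis. Defaults are the values
#' used throughout: fold-change screen at 1.5, unadjusted p at 0.05,
#' 10% trimming per tail, 20 log10-intensity bins for binned-normal
#' imputation, a 5e6 intensity cutoff for misaligned-feature zeroing, and a
#' 2% low-value imputation quantile.
#'
#' @param missing_dialect how the peptide table encodes missing values:
#'   `"blank_is_missing"` (empty cell / NA; a literal 0 is an observed zero)
#'   or `"zero_is_missing"` (0 and blanks are both missing).
#' @param fc_threshold signed fold-change threshold (> 1) for Up/Down
#'   labels and enrichment calls.
#' @param p_threshold unadjusted p-value threshold in (0, 1).
#' @param trim_fraction fraction trimmed from each tail in trimmed-mean
#'   normalization; in (0, 0.5).
#' @param n_bins number of equal-width log10-intensity bins used by the
#'   binned-normal imputation branch.
#' @param misaligned_cutoff intensity above which a mostly-missing
#'   peptide-group is treated as a misaligned feature and zeroed.
#' @param low_percentile quantile of all detected values used as the
#'   low-value imputation floor; in (0, 1).
#' @param seed integer seed controlling the stochastic imputation draws.
#'   Required before [impute_missing()] runs.
#' @return an object of class `"proxidiff_config"` (a named list).
#' @examples
#' cfg <- proxidiff_config(seed = 7)
#' cfg$fc_threshold
#' @export
proxidiff_config <- function(missing_dialect = c("blank_is_missing",
                                                 "zero_is_missing"),
                             fc_threshold = 1.5,
                             p_threshold = 0.05,
                             trim_fraction = 0.10,
                             n_bins = 20L,
                             misaligned_cutoff = 5e6,
                             low_percentile = 0.02,
                             seed = NULL) {
  missing_dialect <- match.arg(missing_dialect)
  stopifnot(is.numeric(fc_threshold), length(fc_threshold) == 1L,
            fc_threshold > 1,
            is.numeric(p_threshold), p_threshold > 0, p_threshold < 1,
            is.numeric(trim_fraction), trim_fraction > 0,
            trim_fraction < 0.5,
            is.numeric(n_bins), n_bins >= 1,
            is.numeric(misaligned_cutoff), misaligned_cutoff > 0,
            is.numeric(low_percentile), low_percentile > 0,
            low_percentile < 1)
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    if (is.na(seed)) stop("seed must be an integer", call. = FALSE)
  }
  structure(list(missing_dialect = missing_dialect,
                 fc_threshold = fc_threshold,
                 p_threshold = p_threshold,
                 trim_fraction = trim_fraction,
                 n_bins = as.integer(n_bins),
                 misaligned_cutoff = misaligned_cutoff,
                 low_percentile = low_percentile,
                 seed = seed),
            class = "proxidiff_config")
}

#' @export
print.proxidiff_config <- function(x, ...) {
  cat("proxidiff configuration:\n")
  for (nm in names(x)) {
    cat(sprintf("  %-18s %s\n", nm,
                if (is.null(x[[nm]])) "<unset>" else format(x[[nm]])))
  }
  invisible(x)
}
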