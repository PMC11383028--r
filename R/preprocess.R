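#' Filter peptides by observation count
#'
#' A peptide is kept only if it was measured at least twice across all
#' samples (SPQC included) and in at least 50% of the replicates of at
#' least one biological (genotype x construct) group. Survivor order is
#' preserved; the operation is idempotent.
#'
#' @param x a [pqm()] object at stage `"raw"`.
#' @param design a [sample_design()] covering every sample column of `x`.
#' @return a [pqm()] at stage `"filtered"` containing only surviving
#'   peptides.
#' @export
filter_peptides <- function(x, design) {
  require_stage(x, "raw")
  check_design_match(x, design)
  obs <- x$observed
  total_ok <- rowSums(obs) >= 2L
  groups <- biological_groups(design)
  group_ok <- Reduce(`|`, lapply(groups, function(s) {
    rowMeans(obs[, s, drop = FALSE]) >= 0.5
  }))
  keep <- total_ok & group_ok
  pqm(x$intensity[keep, , drop = FALSE],
      observed = obs[keep, , drop = FALSE],
      stage = "raw") |> advance_stage("filtered")
}

check_design_match <- function(x, design) {
  if (!setequal(colnames(x$intensity), design$sample_id)) {
    stop("design sample ids do not match matrix columns", call. = FALSE)
  }
  invisible(TRUE)
}

#' Total-intensity normalization
#'
#' Scales each sample so that its total observed intensity equals the mean
#' total across samples. After the operation every column's observed sum is
#' identical.
#'
#' @param x a [pqm()] at stage `"filtered"`.
#' @return list with `matrix` (a [pqm()] at stage `"total_normalized"`) and
#'   `factors` (named per-sample scale factors).
#' @export
total_intensity_normalize <- function(x) {
  require_stage(x, "filtered")
  totals <- colSums(x$intensity)  # unobserved entries are stored as 0
  if (any(totals <= 0)) {
    stop("sample with zero observed total intensity: ",
         paste(colnames(x$intensity)[totals <= 0], collapse = ", "),
         call. = FALSE)
  }
  reference <- mean(totals)
  factors <- reference / totals
  out <- sweep(x$intensity, 2L, factors, `*`)
  list(matrix = pqm(out, observed = x$observed, stage = "raw") |>
         advance_stage("total_normalized"),
       factors = factors)
}

#' Three-branch missing-value imputation
#'
#' For every (peptide, biological group) with missing entries:
#' \describe{
#'   \item{binned_normal}{if fewer than half of the group's values are
#'     missing, each missing entry is drawn from a normal distribution with
#'     the mean and sd of all observed values in the log10-intensity bin
#'     (of `config$n_bins` equal-width bins spanning all observed values)
#'     that contains the peptide-group's observed mean; draws are truncated
#'     at > 0.}
#'   \item{misaligned_zero}{if at least half are missing and the observed
#'     mean exceeds `config$misaligned_cutoff`, the feature is treated as a
#'     misaligned chromatographic match and every entry of that peptide in
#'     that group (observed ones included) is set to 0.}
#'   \item{low_value}{otherwise missing entries are set to the
#'     `config$low_percentile` quantile of all detected values (a single
#'     deterministic left-censoring floor).}
#' }
#' SPQC columns form their own group and only ever receive the low-value
#' branch: pooled injections are technical replicates, and drawing
#' binned-normal values across heterogeneous pools would be meaningless.
#' Observed values outside the misaligned branch are never altered. A bin
#' holding fewer than 2 observed values falls back to the global mean/sd
#' (recorded in the audit).
#'
#' @param x a [pqm()] at stage `"total_normalized"`.
#' @param design a [sample_design()] covering the sample columns.
#' @param config a [proxidiff_config()] with a non-`NULL` `seed` (the draws
#'   are stochastic and must be reproducible).
#' @return list with elements `matrix` (stage `"imputed"`, no missing
#'   entries left), `audit` (one row per (peptide, group) that had missing
#'   values: branch taken, bin index, number of values drawn, the values,
#'   and the low-value floor), `low_floor` (the low-value quantile) and
#'   `zero_floor` (half the low-value quantile; the floor used later when
#'   log2-transforming values that branch 2 zeroed).
#' @export
impute_missing <- function(x, design, config) {
  require_stage(x, "total_normalized")
  check_design_match(x, design)
  if (is.null(config$seed)) {
    stop("config$seed must be set: imputation draws are stochastic",
         call. = FALSE)
  }
  I <- x$intensity
  O <- x$observed

  obs_vals <- I[O]
  if (!length(obs_vals)) stop("no observed values to impute from",
                              call. = FALSE)
  qlow <- unname(quantile(obs_vals, config$low_percentile, type = 7))
  pos <- obs_vals[obs_vals > 0]
  lv <- log10(pos)
  rng <- range(lv)
  n_bins <- config$n_bins
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  assign_bin <- function(v) {
    pmin(pmax(findInterval(v, breaks, rightmost.closed = TRUE), 1L), n_bins)
  }
  bin_idx <- assign_bin(lv)
  bin_n <- tabulate(bin_idx, nbins = n_bins)
  bin_mean <- rep(NA_real_, n_bins)
  bin_sd <- rep(NA_real_, n_bins)
  agg_m <- tapply(pos, bin_idx, mean)
  agg_s <- tapply(pos, bin_idx, sd)
  bin_mean[as.integer(names(agg_m))] <- agg_m
  bin_sd[as.integer(names(agg_s))] <- agg_s
  global_mean <- mean(pos)
  global_sd <- if (length(pos) > 1L) sd(pos) else 0

  groups <- biological_groups(design)
  spqc <- spqc_samples(design)
  if (length(spqc)) groups <- c(groups, list(SPQC = spqc))

  # one audit record per (peptide, group) with missing values; preallocated
  n_rec <- sum(vapply(groups, function(cols) {
    sum(rowSums(!O[, cols, drop = FALSE]) > 0L)
  }, numeric(1)))
  aud_pep <- character(n_rec); aud_grp <- character(n_rec)
  aud_branch <- character(n_rec); aud_bin <- rep(NA_integer_, n_rec)
  aud_fb <- logical(n_rec); aud_n <- integer(n_rec)
  aud_val <- character(n_rec)
  k <- 0L

  local_seed(config$seed, {
    for (g in names(groups)) {
      cols <- groups[[g]]
      Og <- O[, cols, drop = FALSE]
      nmiss <- rowSums(!Og)
      rows <- which(nmiss > 0L)
      if (!length(rows)) next
      ncolg <- length(cols)
      is_spqc_group <- identical(g, "SPQC")
      for (r in rows) {
        ov <- I[r, cols][Og[r, ]]
        frac_missing <- nmiss[r] / ncolg
        gmean <- if (length(ov)) mean(ov) else NaN
        k <- k + 1L
        aud_pep[k] <- rownames(I)[r]
        aud_grp[k] <- g
        if (!is_spqc_group && frac_missing < 0.5) {
          fallback <- FALSE
          b <- NA_integer_
          if (is.finite(gmean) && gmean > 0) {
            b <- assign_bin(log10(gmean))
            if (bin_n[b] >= 2L) {
              mu <- bin_mean[b]; s <- bin_sd[b]
            } else {
              fallback <- TRUE
            }
          } else {
            fallback <- TRUE
          }
          if (fallback) {
            mu <- global_mean; s <- global_sd
          }
          draws <- draw_truncated_normal(nmiss[r], mu, s, floor_at = qlow)
          I[r, cols][!Og[r, ]] <- draws
          O[r, cols] <- TRUE
          aud_branch[k] <- "binned_normal"
          aud_bin[k] <- b
          aud_fb[k] <- fallback
          aud_n[k] <- nmiss[r]
          aud_val[k] <- paste(signif(draws, 8), collapse = ";")
        } else if (!is_spqc_group && is.finite(gmean) &&
                   gmean > config$misaligned_cutoff) {
          I[r, cols] <- 0
          O[r, cols] <- TRUE
          aud_branch[k] <- "misaligned_zero"
          aud_n[k] <- ncolg
          aud_val[k] <- paste(rep("0", ncolg), collapse = ";")
        } else {
          I[r, cols][!Og[r, ]] <- qlow
          O[r, cols] <- TRUE
          aud_branch[k] <- "low_value"
          aud_n[k] <- nmiss[r]
          aud_val[k] <- paste(rep(signif(qlow, 8), nmiss[r]),
                              collapse = ";")
        }
      }
    }
  })

  if (any(!O)) {
    # samples not covered by biological groups or SPQC cannot remain missing
    uncovered <- colnames(I)[colSums(!O) > 0]
    stop("missing values left in samples outside all groups: ",
         paste(uncovered, collapse = ", "), call. = FALSE)
  }
  audit <- data.frame(peptide_id = aud_pep, group = aud_grp,
                      branch = aud_branch, bin = aud_bin,
                      bin_fallback = aud_fb, n_imputed = aud_n,
                      values = aud_val,
                      low_floor = rep(qlow, n_rec),
                      stringsAsFactors = FALSE)
  list(matrix = pqm(I, observed = O, stage = "raw") |>
         advance_stage("imputed"),
       audit = audit,
       low_floor = qlow,
       zero_floor = qlow / 2)
}

# Normal draws truncated at > 0 (reject and resample); after 50 rounds any
# stragglers are set to the low-value floor so the imputed value is always a
# positive intensity.
draw_truncated_normal <- function(n, mu, s, floor_at) {
  if (!is.finite(s) || s < 0) s <- 0
  v <- rnorm(n, mu, s)
  it <- 0L
  while (any(v <= 0) && it < 50L) {
    bad <- v <= 0
    v[bad] <- rnorm(sum(bad), mu, s)
    it <- it + 1L
  }
  v[v <= 0] <- floor_at
  v
}

#' Trimmed-mean normalization
#'
#' Per sample, the mean of the positive intensities is computed after
#' discarding the `trim_fraction` highest and lowest values
#' (`floor(trim_fraction * n)` per tail); every sample is then rescaled so
#' all trimmed means equal their across-sample mean. Zeros (from the
#' misaligned-feature branch) are excluded from the trimming statistics but
#' are scaled like every other value (they stay 0).
#'
#' @param x a [pqm()] at stage `"imputed"` (no missing entries).
#' @param config a [proxidiff_config()]; `trim_fraction` is used.
#' @return list with `matrix` (stage `"trimmed_normalized"`) and `factors`
#'   (named per-sample scale factors, all strictly positive).
#' @export
trimmed_mean_normalize <- function(x, config = proxidiff_config()) {
  require_stage(x, "imputed")
  I <- x$intensity
  tm <- vapply(seq_len(ncol(I)), function(j) {
    v <- I[, j]
    v <- v[v > 0]
    n <- length(v)
    if (n < 3L) stop("sample with fewer than 3 positive values: ",
                     colnames(I)[j], call. = FALSE)
    k <- floor(config$trim_fraction * n)
    sv <- sort(v)
    mean(sv[(k + 1L):(n - k)])
  }, numeric(1))
  target <- mean(tm)
  factors <- target / tm
  names(factors) <- colnames(I)
  out <- sweep(I, 2L, factors, `*`)
  list(matrix = pqm(out, observed = x$observed, stage = "raw") |>
         advance_stage("trimmed_normalized"),
       factors = factors)
}
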