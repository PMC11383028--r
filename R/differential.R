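#' Per-protein Welch t-tests on log2 intensities
#'
#' For each protein, intensities of the two sample groups are floored at
#' `zero_floor`, log2-transformed, and compared with a two-tailed
#' heteroscedastic (Welch) t-test with Satterthwaite degrees of freedom.
#' The log2 fold-change is the difference of group means of log2 values
#' (group A minus group B), and the signed fold-change reports the ratio
#' `r = 2^log2FC` as `+r` when `r >= 1` and `-1/r` otherwise, so that its
#' magnitude is always at least 1.
#'
#' Degenerate rows (zero variance in both groups) resolve to `p = 1` when
#' the means are equal and `p = 0` otherwise, rather than erroring:
#' imputation floors can create exact ties.
#'
#' @param proteins protein matrix: either the list returned by
#'   [rollup_proteins()] or a plain numeric matrix (proteins x samples).
#' @param group_a,group_b character vectors of sample ids (>= 2 each).
#' @param zero_floor positive value replacing intensities <= 0 before log2
#'   (use the `zero_floor` reported by [impute_missing()]).
#' @return data.frame with one row per protein: `protein`, `mean_log2_a`,
#'   `mean_log2_b`, `log2FC`, `signed_FC`, `t`, `df`, `p`.
#' @examples
#' m <- rbind(P1 = c(2, 4, 8, 16, 32, 64))
#' colnames(m) <- c("a1", "a2", "a3", "b1", "b2", "b3")
#' log2_welch_test(m, c("a1", "a2", "a3"), c("b1", "b2", "b3"), 1e-6)
#' @export
log2_welch_test <- function(proteins, group_a, group_b, zero_floor) {
  mat <- protein_intensity(proteins)
  stopifnot(is.numeric(zero_floor), zero_floor > 0)
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  missing_ids <- setdiff(c(group_a, group_b), colnames(mat))
  if (length(missing_ids)) {
    stop("sample ids not in matrix: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  L <- log2(pmax(mat, zero_floor))
  A <- L[, group_a, drop = FALSE]
  B <- L[, group_b, drop = FALSE]
  na <- ncol(A); nb <- ncol(B)
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- rowSums((A - ma)^2) / (na - 1L)
  vb <- rowSums((B - mb)^2) / (nb - 1L)
  se2 <- va / na + vb / nb
  d <- ma - mb
  t_stat <- d / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1L) + (vb / nb)^2 / (nb - 1L))
  p <- 2 * pt(-abs(t_stat), df)
  degen <- se2 == 0
  if (any(degen)) {
    t_stat[degen] <- ifelse(d[degen] == 0, 0, sign(d[degen]) * Inf)
    df[degen] <- na + nb - 2L
    p[degen] <- ifelse(d[degen] == 0, 1, 0)
  }
  data.frame(protein = rownames(mat),
             mean_log2_a = unname(ma), mean_log2_b = unname(mb),
             log2FC = unname(d), signed_FC = signed_fc(unname(d)),
             t = unname(t_stat), df = unname(df), p = unname(p),
             stringsAsFactors = FALSE)
}

protein_intensity <- function(proteins) {
  if (is.list(proteins) && !is.null(proteins$intensity)) {
    proteins <- proteins$intensity
  }
  stopifnot(is.matrix(proteins), is.numeric(proteins))
  proteins
}

#' Signed fold-change from a log2 fold-change
#'
#' Maps the ratio `r = 2^log2fc` to `+r` when `r >= 1` and to `-1/r`
#' otherwise, the convention under which thresholds read "> 1.5 or
#' < -1.5". Reciprocal ratios map to sign-flipped values and the magnitude
#' is always >= 1.
#'
#' @param log2fc numeric vector of log2 fold-changes.
#' @return numeric vector of signed fold-changes.
#' @export
signed_fc <- function(log2fc) {
  r <- 2^log2fc
  ifelse(r >= 1, r, -1 / r)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (reported as "p.adjusted" in the
#' output tables); a validated interface to [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in input order; element-wise >= `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must be numbers in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Up/Down labeling of a differential table
#'
#' `Up` when the signed fold-change exceeds `fc_threshold` with unadjusted
#' `p < p_threshold`; `Down` when it is below `-fc_threshold` with
#' `p < p_threshold`; `none` otherwise. The screen deliberately uses the
#' unadjusted p-value; the BH-adjusted value is reported alongside.
#'
#' @param table data.frame with `signed_FC` and `p` columns.
#' @param config a [proxidiff_config()].
#' @return `table` with a `label` column added.
#' @export
label_updown <- function(table, config = proxidiff_config()) {
  stopifnot(all(c("signed_FC", "p") %in% names(table)))
  up <- table$signed_FC > config$fc_threshold & table$p < config$p_threshold
  down <- table$signed_FC < -config$fc_threshold &
    table$p < config$p_threshold
  table$label <- ifelse(up, "Up", ifelse(down, "Down", "none"))
  table
}

# Full differential table for one contrast: Welch tests, BH column, labels.
differential_table <- function(proteins, group_a, group_b, config,
                               zero_floor) {
  tab <- log2_welch_test(proteins, group_a, group_b, zero_floor)
  tab$p_adjusted <- bh_adjust(tab$p)
  label_updown(tab, config)
}
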