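#' Per-protein coefficient of variation
#'
#' %CV = 100 * sd / mean per protein over the named samples, on linear
#' intensities with the sample (n-1) standard deviation. Proteins with any
#' non-positive intensity among the samples are excluded (and reported),
#' since a %CV over values that include imputation zeros is not a
#' precision estimate.
#'
#' @param proteins protein matrix (see [log2_welch_test()]).
#' @param sample_set character vector of >= 2 sample ids.
#' @return list with `cv` (named per-protein %CV), `mean_cv` (their mean)
#'   and `excluded` (proteins left out).
#' @examples
#' m <- rbind(P1 = c(9, 10, 11))
#' colnames(m) <- paste0("s", 1:3)
#' protein_cv(m, colnames(m))$cv  # 10%
#' @export
protein_cv <- function(proteins, sample_set) {
  mat <- protein_intensity(proteins)
  if (length(sample_set) < 2L) {
    stop("need at least 2 samples for a %CV", call. = FALSE)
  }
  missing_ids <- setdiff(sample_set, colnames(mat))
  if (length(missing_ids)) {
    stop("sample ids not in matrix: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  sub <- mat[, sample_set, drop = FALSE]
  ok <- apply(sub, 1L, function(v) all(v > 0))
  excluded <- rownames(sub)[!ok]
  sub <- sub[ok, , drop = FALSE]
  m <- rowMeans(sub)
  s <- sqrt(rowSums((sub - m)^2) / (ncol(sub) - 1L))
  cv <- 100 * s / m
  list(cv = cv, mean_cv = mean(cv), excluded = excluded)
}

#' PCA sample embedding
#'
#' Projects samples onto the top two principal components of the
#' log2-transformed, per-protein-centered intensity matrix. A deterministic
#' sign convention is applied: within each component the loading of
#' largest magnitude is made positive, so results do not depend on sample
#' order or LAPACK sign choices.
#'
#' @param proteins protein matrix (see [log2_welch_test()]).
#' @param zero_floor positive floor applied before log2; defaults to half
#'   the smallest positive intensity.
#' @return list with `coordinates` (samples x 2 matrix, columns `PC1`,
#'   `PC2`) and `explained_variance` (fractions for all components,
#'   non-increasing, summing to <= 1).
#' @export
pca_embed <- function(proteins, zero_floor = NULL) {
  mat <- protein_intensity(proteins)
  if (ncol(mat) < 3L) stop("PCA needs at least 3 samples", call. = FALSE)
  if (is.null(zero_floor)) {
    posv <- mat[mat > 0]
    if (!length(posv)) stop("no positive intensities", call. = FALSE)
    zero_floor <- min(posv) / 2
  }
  L <- log2(pmax(mat, zero_floor))
  Lc <- L - rowMeans(L)
  pr <- prcomp(t(Lc), center = FALSE, scale. = FALSE)
  ev <- pr$sdev^2 / sum(pr$sdev^2)
  k <- min(2L, ncol(pr$x))
  coords <- pr$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    load <- pr$rotation[, j]
    if (load[which.max(abs(load))] < 0) coords[, j] <- -coords[, j]
  }
  colnames(coords) <- paste0("PC", seq_len(k))
  list(coordinates = coords, explained_variance = ev)
}

# All QC surfaces for a fitted pipeline: SPQC %CV, per-group %CV, PCA.
qc_summary <- function(proteins, design, zero_floor = NULL) {
  spqc <- spqc_samples(design)
  groups <- biological_groups(design)
  list(spqc_cv = if (length(spqc) >= 2L)
         protein_cv(proteins, spqc) else NULL,
       group_cv = lapply(groups, function(s) protein_cv(proteins, s)),
       pca = pca_embed(proteins, zero_floor))
}
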