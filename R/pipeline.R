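#' Run the full differential proximity-labeling pipeline
#'
#' Chains every stage: peptide filtering, total-intensity normalization,
#' three-branch imputation, trimmed-mean normalization, razor assignment,
#' protein grouping, roll-up, the per-genotype bait-enrichment contrasts,
#' the GS vs WT bait contrast, high-confidence gained/lost interactor
#' calling, and the QC surfaces (SPQC and group %CVs, PCA). Deterministic
#' given the inputs and `config$seed`.
#'
#' @param peptides a [pqm()] at stage `"raw"` (e.g. from
#'   [read_peptide_table()] or [simulate_bioid()]).
#' @param map peptide-to-protein candidate table (columns `peptide_id`,
#'   `candidates`).
#' @param design a [sample_design()].
#' @param config a [proxidiff_config()] with `seed` set.
#' @param protein_lengths optional named lengths for coverage-based master
#'   selection (see [group_proteins()]).
#' @return an object of class `"proxidiff"`; a list with elements
#'   `config`, `n_peptides_in`, `peptides` (the final trimmed-normalized
#'   matrix), `factors` (total and trimmed-mean scale factors), `audit`
#'   (imputation audit), `zero_floor`, `map` (resolved + grouped),
#'   `proteins` (rolled-up matrix), `enrichment` (`$WT`, `$GS`),
#'   `contrast` (GS vs WT EZR differential table), `calls`
#'   (gained/lost with provenance) and `qc`.
#' @examples
#' sim <- simulate_bioid(synth_params(n_proteins = 60, seed = 3))
#' fit <- proxidiff(sim$peptides, sim$map, sim$design,
#'                  proxidiff_config(seed = 3))
#' print(fit)
#' @export
proxidiff <- function(peptides, map, design,
                      config = proxidiff_config(seed = 1L),
                      protein_lengths = NULL) {
  stopifnot(inherits(peptides, "pqm"))
  if (!inherits(design, "sample_design")) design <- sample_design(design)
  if (is.null(config$seed)) {
    stop("config$seed must be set for a reproducible run", call. = FALSE)
  }

  filtered <- filter_peptides(peptides, design)
  tot <- total_intensity_normalize(filtered)
  imp <- impute_missing(tot$matrix, design, config)
  trm <- trimmed_mean_normalize(imp$matrix, config)

  resolved <- assign_razor(map, trm$matrix)
  grouped <- group_proteins(resolved, protein_lengths)
  proteins <- rollup_proteins(trm$matrix, grouped)

  zf <- imp$zero_floor
  enrich_wt <- bait_enrichment(proteins, design, "WT", config, zf)
  enrich_gs <- bait_enrichment(proteins, design, "GS", config, zf)
  contrast <- genotype_contrast(proteins, design, config, zf)
  calls <- call_high_confidence(enrich_wt, enrich_gs, contrast, config)

  qc <- qc_summary(proteins, design, zf)

  structure(list(config = config,
                 n_peptides_in = nrow(peptides$intensity),
                 peptides = trm$matrix,
                 factors = list(total = tot$factors,
                                trimmed = trm$factors),
                 audit = imp$audit,
                 zero_floor = zf,
                 map = grouped$map,
                 proteins = proteins,
                 enrichment = list(WT = enrich_wt, GS = enrich_gs),
                 contrast = contrast,
                 calls = calls,
                 design = design,
                 qc = qc),
            class = "proxidiff")
}

#' @export
print.proxidiff <- function(x, ...) {
  cat("Differential proximity-labeling analysis\n")
  cat(sprintf("  peptides: %d in, %d after filter; proteins: %d\n",
              x$n_peptides_in, nrow(x$peptides$intensity),
              nrow(x$proteins$intensity)))
  cat(sprintf("  bait-enriched: %d (WT), %d (GS)\n",
              length(x$enrichment$WT$enriched),
              length(x$enrichment$GS$enriched)))
  cat(sprintf("  altered proximity (GS vs WT EZR): %d Up, %d Down\n",
              sum(x$contrast$label == "Up"),
              sum(x$contrast$label == "Down")))
  cat(sprintf("  high-confidence: %d gained, %d lost\n",
              length(x$calls$gained), length(x$calls$lost)))
  invisible(x)
}

#' Summarize a fitted pipeline
#'
#' @param object a [proxidiff()] fit.
#' @param ... unused.
#' @return a list of class `"summary.proxidiff"` with counts, scale-factor
#'   ranges, %CV summaries and PCA explained variance.
#' @export
summary.proxidiff <- function(object, ...) {
  qc <- object$qc
  out <- list(
    n_peptides_in = object$n_peptides_in,
    n_peptides = nrow(object$peptides$intensity),
    n_proteins = nrow(object$proteins$intensity),
    n_imputed = sum(object$audit$n_imputed),
    branch_counts = table(object$audit$branch),
    factor_range = vapply(object$factors, range, numeric(2)),
    enriched = c(WT = length(object$enrichment$WT$enriched),
                 GS = length(object$enrichment$GS$enriched)),
    labels = table(object$contrast$label),
    gained = object$calls$gained,
    lost = object$calls$lost,
    mean_spqc_cv = if (is.null(qc$spqc_cv)) NA_real_ else
      qc$spqc_cv$mean_cv,
    mean_group_cv = vapply(qc$group_cv, function(g) g$mean_cv, numeric(1)),
    pca_explained = qc$pca$explained_variance[1:2])
  class(out) <- "summary.proxidiff"
  out
}

#' @export
print.summary.proxidiff <- function(x, ...) {
  cat("Differential proximity-labeling analysis\n")
  cat(sprintf("  peptides: %d in, %d kept; proteins: %d\n",
              x$n_peptides_in, x$n_peptides, x$n_proteins))
  cat(sprintf("  imputed values: %d (%s)\n", x$n_imputed,
              paste(names(x$branch_counts), x$branch_counts,
                    sep = "=", collapse = ", ")))
  cat(sprintf("  bait-enriched: WT %d, GS %d\n",
              x$enriched["WT"], x$enriched["GS"]))
  cat(sprintf("  GS vs WT EZR labels: %s\n",
              paste(names(x$labels), x$labels, sep = "=",
                    collapse = ", ")))
  cat(sprintf("  high-confidence gained (%d): %s\n", length(x$gained),
              paste(head(x$gained, 8), collapse = ", ")))
  cat(sprintf("  high-confidence lost (%d): %s\n", length(x$lost),
              paste(head(x$lost, 8), collapse = ", ")))
  cat(sprintf("  mean %%CV: SPQC %.1f; groups %s\n", x$mean_spqc_cv,
              paste(names(x$mean_group_cv),
                    sprintf("%.1f", x$mean_group_cv),
                    sep = "=", collapse = ", ")))
  cat(sprintf("  PCA explained variance: PC1 %.1f%%, PC2 %.1f%%\n",
              100 * x$pca_explained[1], 100 * x$pca_explained[2]))
  invisible(x)
}

#' Volcano plot of the genotype contrast
#'
#' Base-graphics volcano of the GS vs WT bait contrast; high-confidence
#' gained/lost proteins are highlighted.
#'
#' @param x a [proxidiff()] fit.
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.proxidiff <- function(x, ...) {
  tab <- x$contrast
  cfg <- x$config
  col <- rep(adjustcolor("grey40", 0.5), nrow(tab))
  col[tab$protein %in% x$calls$gained] <- "firebrick"
  col[tab$protein %in% x$calls$lost] <- "navy"
  plot(tab$log2FC, -log10(pmax(tab$p, 1e-300)), pch = 16, cex = 0.5,
       col = col, xlab = "log2 fold-change (GS vs WT, bait)",
       ylab = "-log10 p", ...)
  abline(v = c(-log2(cfg$fc_threshold), log2(cfg$fc_threshold)),
         h = -log10(cfg$p_threshold), lty = 2, col = "grey60")
  legend("topright", pch = 16, col = c("firebrick", "navy"),
         legend = c("gained", "lost"), bty = "n")
  invisible(x)
}
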