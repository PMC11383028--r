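#' Bait enrichment within one genotype
#'
#' Contrasts the bait (EZR) against the cytosolic control (CYT) samples of
#' one genotype and calls a protein bait-enriched when its signed
#' fold-change exceeds `config$fc_threshold` with unadjusted
#' `p < config$p_threshold`. The per-protein EZR/CYT signed fold-change is
#' the heatmap quantity reported for each genotype's interactome.
#'
#' @param proteins protein matrix (see [log2_welch_test()]).
#' @param design a [sample_design()].
#' @param genotype `"WT"` or `"GS"`.
#' @param config a [proxidiff_config()].
#' @param zero_floor floor for log2, from [impute_missing()].
#' @return list of class `"enrichment_call"`: `genotype`, `table` (the
#'   full differential table EZR vs CYT), `enriched` (character vector of
#'   enriched proteins) and `signed_FC` (named vector, the heatmap
#'   quantity).
#' @export
bait_enrichment <- function(proteins, design, genotype,
                            config = proxidiff_config(), zero_floor) {
  genotype <- match.arg(genotype, c("WT", "GS"))
  ezr <- group_samples(design, genotype, "EZR")
  cyt <- group_samples(design, genotype, "CYT")
  if (length(ezr) < 2L || length(cyt) < 2L) {
    stop("genotype ", genotype,
         " needs >= 2 replicates of both constructs", call. = FALSE)
  }
  tab <- differential_table(proteins, ezr, cyt, config, zero_floor)
  enriched <- tab$protein[tab$signed_FC > config$fc_threshold &
                            tab$p < config$p_threshold]
  structure(list(genotype = genotype, table = tab, enriched = enriched,
                 signed_FC = setNames(tab$signed_FC, tab$protein)),
            class = "enrichment_call")
}

#' Genotype contrast of bait samples
#'
#' Differential table for GS-EZR versus WT-EZR; its Up/Down labels are the
#' volcano sets of proteins with altered proximity to the bait in the
#' mutant genotype.
#'
#' @inheritParams bait_enrichment
#' @return a differential table (data.frame) with `p_adjusted` and `label`
#'   columns.
#' @export
genotype_contrast <- function(proteins, design, config = proxidiff_config(),
                              zero_floor) {
  gs <- group_samples(design, "GS", "EZR")
  wt <- group_samples(design, "WT", "EZR")
  if (length(gs) < 2L || length(wt) < 2L) {
    stop("both genotypes need >= 2 EZR replicates", call. = FALSE)
  }
  differential_table(proteins, gs, wt, config, zero_floor)
}

#' High-confidence gained/lost interactor calling
#'
#' Two-stage rule: a protein is called \emph{gained} when it is
#' bait-enriched in the mutant (GS) genotype and the GS vs WT bait
#' contrast has signed fold-change above `fc_threshold` with
#' `p < p_threshold`; \emph{lost} when it is bait-enriched in WT and the
#' contrast is below `-fc_threshold` with `p < p_threshold`. The
#' opposite-sign contrast requirements make the two sets disjoint by
#' construction.
#'
#' @param enrich_wt,enrich_gs [bait_enrichment()] results for WT and GS.
#' @param contrast the [genotype_contrast()] table. All three inputs must
#'   come from the same protein matrix.
#' @param config a [proxidiff_config()].
#' @param require_contrast_p require `p < p_threshold` in the genotype
#'   contrast (the default); set `FALSE` to screen on fold-change alone.
#' @return list of class `"interactor_calls"`: `gained`, `lost` (character
#'   vectors) and `provenance` (one row per called protein: the enrichment
#'   genotype it came from, its enrichment signed FC and p, and its
#'   contrast signed FC and p).
#' @export
call_high_confidence <- function(enrich_wt, enrich_gs, contrast,
                                 config = proxidiff_config(),
                                 require_contrast_p = TRUE) {
  stopifnot(inherits(enrich_wt, "enrichment_call"),
            inherits(enrich_gs, "enrichment_call"))
  if (enrich_wt$genotype != "WT" || enrich_gs$genotype != "GS") {
    stop("enrichment calls passed in the wrong order", call. = FALSE)
  }
  if (!setequal(contrast$protein, enrich_wt$table$protein) ||
      !setequal(contrast$protein, enrich_gs$table$protein)) {
    stop("inputs derive from different protein universes", call. = FALSE)
  }
  p_ok <- if (require_contrast_p) contrast$p < config$p_threshold else
    rep(TRUE, nrow(contrast))
  up <- contrast$protein[contrast$signed_FC > config$fc_threshold & p_ok]
  down <- contrast$protein[contrast$signed_FC < -config$fc_threshold & p_ok]
  gained <- sort(intersect(enrich_gs$enriched, up))
  lost <- sort(intersect(enrich_wt$enriched, down))

  prov_row <- function(p, call, enr) {
    et <- enr$table[enr$table$protein == p, ]
    ct <- contrast[contrast$protein == p, ]
    data.frame(protein = p, call = call, enriched_in = enr$genotype,
               enrichment_signed_FC = et$signed_FC, enrichment_p = et$p,
               contrast_signed_FC = ct$signed_FC, contrast_p = ct$p,
               stringsAsFactors = FALSE)
  }
  prov <- c(lapply(gained, prov_row, call = "gained", enr = enrich_gs),
            lapply(lost, prov_row, call = "lost", enr = enrich_wt))
  provenance <- if (length(prov)) do.call(rbind, prov) else
    data.frame(protein = character(0), call = character(0),
               enriched_in = character(0),
               enrichment_signed_FC = numeric(0), enrichment_p = numeric(0),
               contrast_signed_FC = numeric(0), contrast_p = numeric(0))
  structure(list(gained = gained, lost = lost, provenance = provenance),
            class = "interactor_calls")
}

#' @export
print.interactor_calls <- function(x, ...) {
  cat(sprintf("High-confidence interactors: %d gained, %d lost\n",
              length(x$gained), length(x$lost)))
  invisible(x)
}
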