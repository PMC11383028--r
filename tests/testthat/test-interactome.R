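# protein matrix over the standard design with chosen per-group means and
# small fixed jitter, for rule-level checks
interactome_matrix <- function(means, jitter = 0.03, seed = 1) {
  d <- std_design()
  set.seed(seed)
  prots <- rownames(means)
  m <- matrix(0, length(prots), 15,
              dimnames = list(prots, d$sample_id))
  for (g in colnames(means)) {
    cols <- biological_groups(d)[[g]]
    for (p in prots) {
      m[p, cols] <- means[p, g] * 2^rnorm(3, 0, jitter)
    }
  }
  m[, spqc_samples(d)] <- rowMeans(m[, 1:12, drop = FALSE])
  m
}

test_that("bait enrichment requires both fold-change and p thresholds", {
  means <- rbind(
    strong = c(WT_EZR = 4e6, WT_CYT = 1e6, GS_EZR = 4e6, GS_CYT = 1e6),
    weak   = c(WT_EZR = 1.4e6, WT_CYT = 1e6, GS_EZR = 1.4e6,
               GS_CYT = 1e6),
    flat   = c(WT_EZR = 1e6, WT_CYT = 1e6, GS_EZR = 1e6, GS_CYT = 1e6))
  m <- interactome_matrix(means)
  e <- bait_enrichment(m, std_design(), "WT", proxidiff_config(), 1)
  expect_true("strong" %in% e$enriched)
  expect_false("weak" %in% e$enriched)   # p fine, fold-change below 1.5
  expect_false("flat" %in% e$enriched)
  # the enriched set is exactly the rule applied to the table
  rule <- e$table$protein[e$table$signed_FC > 1.5 & e$table$p < 0.05]
  expect_setequal(e$enriched, rule)
  # signed_FC vector is the heatmap quantity for every tested protein
  expect_equal(unname(e$signed_FC["strong"]),
               e$table$signed_FC[e$table$protein == "strong"])
})

test_that("the genotype contrast labels planted gains and losses", {
  means <- rbind(
    gain = c(WT_EZR = 1e6, WT_CYT = 1e6, GS_EZR = 3e6, GS_CYT = 1e6),
    loss = c(WT_EZR = 3e6, WT_CYT = 1e6, GS_EZR = 1e6, GS_CYT = 1e6),
    null = c(WT_EZR = 2e6, WT_CYT = 1e6, GS_EZR = 2e6, GS_CYT = 1e6))
  m <- interactome_matrix(means)
  ct <- genotype_contrast(m, std_design(), proxidiff_config(), 1)
  expect_identical(ct$label[match(c("gain", "loss", "null"), ct$protein)],
                   c("Up", "Down", "none"))
})

test_that("high-confidence calls need enrichment plus the genotype contrast", {
  contrast <- data.frame(
    protein = c("both_up", "gs_only", "wt_down", "no_p", "small_fc"),
    signed_FC = c(1.8, 1.8, -1.8, 1.8, 1.2),
    p = c(0.01, 0.01, 0.01, 0.2, 0.01))
  et <- function(prots, fcs) {
    data.frame(protein = contrast$protein,
               signed_FC = ifelse(contrast$protein %in% prots, fcs, 1),
               p = ifelse(contrast$protein %in% prots, 0.001, 0.9))
  }
  e_gs <- fake_enrichment("GS", et(c("both_up", "gs_only", "no_p",
                                     "small_fc"), 2.3))
  e_wt <- fake_enrichment("WT", et(c("both_up", "wt_down"), 2.3))
  calls <- call_high_confidence(e_wt, e_gs, contrast, proxidiff_config())
  # no_p fails the contrast p, small_fc fails the contrast fold-change
  expect_setequal(calls$gained, c("both_up", "gs_only"))
  # wt_down: WT-enriched with contrast -1.8, p 0.01
  expect_setequal(calls$lost, "wt_down")
  # with the contrast-p requirement relaxed, no_p joins the gained set
  relaxed <- call_high_confidence(e_wt, e_gs, contrast,
                                  proxidiff_config(),
                                  require_contrast_p = FALSE)
  expect_setequal(relaxed$gained, c("both_up", "gs_only", "no_p"))
})

test_that("the Atg7-style lost pattern and its gained mirror are called", {
  contrast <- data.frame(protein = c("gainA", "lostB", "bothC"),
                         signed_FC = c(1.8, -1.8, 1.2),
                         p = c(0.01, 0.01, 0.01))
  enr <- function(genotype, prots) {
    data.frame(protein = contrast$protein,
               signed_FC = ifelse(contrast$protein %in% prots, 2.3, 1),
               p = ifelse(contrast$protein %in% prots, 0.001, 0.9)) |>
      fake_enrichment(genotype = genotype)
  }
  e_gs <- enr("GS", c("gainA", "bothC"))
  e_wt <- enr("WT", c("lostB", "bothC"))
  calls <- call_high_confidence(e_wt, e_gs, contrast, proxidiff_config())
  expect_identical(calls$gained, "gainA")
  expect_identical(calls$lost, "lostB")
  expect_length(intersect(calls$gained, calls$lost), 0L)
  prov <- calls$provenance
  expect_setequal(prov$protein, c("gainA", "lostB"))
  expect_identical(prov$enriched_in[prov$protein == "gainA"], "GS")
  expect_identical(prov$enriched_in[prov$protein == "lostB"], "WT")
})

test_that("shrinking the fold-change threshold grows both call sets", {
  set.seed(31)
  prots <- sprintf("P%02d", 1:40)
  contrast <- data.frame(protein = prots,
                         signed_FC = signed_fc(rnorm(40, 0, 1.2)),
                         p = runif(40, 0, 0.1))
  enr_tab <- data.frame(protein = prots,
                        signed_FC = signed_fc(rnorm(40, 1, 1)),
                        p = runif(40, 0, 0.1))
  e_wt <- fake_enrichment("WT", enr_tab)
  e_gs <- fake_enrichment("GS", enr_tab)
  loose <- call_high_confidence(e_wt, e_gs, contrast,
                                proxidiff_config(fc_threshold = 1.2))
  strict <- call_high_confidence(e_wt, e_gs, contrast,
                                 proxidiff_config(fc_threshold = 2))
  expect_true(all(strict$gained %in% loose$gained))
  expect_true(all(strict$lost %in% loose$lost))
})

test_that("mismatched protein universes are a consistency error", {
  contrast <- data.frame(protein = c("A", "B"), signed_FC = c(2, 2),
                         p = c(0.01, 0.01))
  tab <- data.frame(protein = c("A", "C"), signed_FC = c(2, 2),
                    p = c(0.01, 0.01))
  expect_error(
    call_high_confidence(fake_enrichment("WT", tab),
                         fake_enrichment("GS", tab), contrast,
                         proxidiff_config()),
    "universe")
})
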