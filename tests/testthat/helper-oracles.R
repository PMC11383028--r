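# Brute-force rule evaluators, written as literal transcriptions of the
# decision rules and kept independent of the package implementation. Used
# to verify filter, imputation branching, razor assignment, Up/Down
# labeling and high-confidence calling on randomized fixtures.

# obs: logical vector over all samples; groups: list of index vectors for
# the biological groups (SPQC columns excluded from the group clause).
oracle_filter_keep <- function(obs, groups) {
  if (sum(obs) < 2) return(FALSE)
  for (ix in groups) {
    if (mean(obs[ix]) >= 0.5) return(TRUE)
  }
  FALSE
}

# values/observed: one peptide's entries in one biological group.
oracle_branch <- function(values, observed, cutoff) {
  if (all(observed)) return("none")
  if (mean(!observed) < 0.5) return("binned_normal")
  ov <- values[observed]
  if (length(ov) > 0 && mean(ov) > cutoff) return("misaligned_zero")
  "low_value"
}

# cand: named list peptide_id -> candidate accessions.
oracle_razor <- function(cand) {
  counts <- table(unlist(cand, use.names = FALSE))
  out <- character(length(cand))
  for (i in seq_along(cand)) {
    cs <- unique(cand[[i]])
    n <- as.vector(counts[cs])
    best <- cs[n == max(n)]
    out[i] <- sort(best)[1]
  }
  names(out) <- names(cand)
  out
}

oracle_label <- function(signed_fc, p, fc_t, p_t) {
  if (p < p_t && signed_fc > fc_t) return("Up")
  if (p < p_t && signed_fc < -fc_t) return("Down")
  "none"
}

# enriched_wt/enriched_gs: character vectors; contrast: data.frame with
# protein, signed_FC, p.
oracle_calls <- function(enriched_wt, enriched_gs, contrast, fc_t, p_t) {
  gained <- character(0); lost <- character(0)
  for (i in seq_len(nrow(contrast))) {
    pr <- contrast$protein[i]
    if (pr %in% enriched_gs && contrast$signed_FC[i] > fc_t &&
        contrast$p[i] < p_t) {
      gained <- c(gained, pr)
    }
    if (pr %in% enriched_wt && contrast$signed_FC[i] < -fc_t &&
        contrast$p[i] < p_t) {
      lost <- c(lost, pr)
    }
  }
  list(gained = sort(gained), lost = sort(lost))
}

# Build an enrichment_call object from a bare table (for rule-level tests
# that do not need a protein matrix behind it).
fake_enrichment <- function(genotype, table, fc_t = 1.5, p_t = 0.05) {
  structure(list(genotype = genotype, table = table,
                 enriched = table$protein[table$signed_FC > fc_t &
                                            table$p < p_t],
                 signed_FC = setNames(table$signed_FC, table$protein)),
            class = "enrichment_call")
}
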