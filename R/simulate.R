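#' Parameters of the synthetic BioID dataset generator
#'
#' Describes the 12-sample (3 replicates x WT/GS x EZR/CYT) + 3-SPQC design
#' the generator emulates. Defaults are chosen to mirror the scale of a
#' typical in-vivo BioID study: ~7.5 peptides per protein, protein-level
#' group %CV near 20% (biological 16.5% + technical 11%), ~10% of proteins
#' proximal to the bait at 4-fold enrichment, a 3-fold genotype modulation
#' for 20% of the bait-proximal set, intensity-dependent dropout centred at
#' 1e5, and 1% misaligned features.
#'
#' @param n_proteins number of simulated proteins.
#' @param peptides_per_protein integer range `c(min, max)`; each protein
#'   gets a uniform draw of peptides in this range.
#' @param frac_bait_proximal fraction of proteins proximal to the bait.
#' @param bait_enrichment_fold fold enrichment of bait-proximal proteins in
#'   EZR columns (>= 1).
#' @param frac_genotype_modulated fraction of bait-proximal proteins whose
#'   proximity changes with genotype (split evenly into gained and lost).
#' @param genotype_fold fold applied (multiplied for gained, divided for
#'   lost) in GS-EZR columns (>= 1).
#' @param cv_biological,cv_technical lognormal coefficients of variation of
#'   the biological (per protein x biological sample) and technical (per
#'   protein x injection) noise.
#' @param abundance_meanlog,abundance_sdlog lognormal parameters of protein
#'   base abundance.
#' @param ionization_sdlog lognormal sd of the fixed per-peptide
#'   ionizability factor.
#' @param dropout_midpoint,dropout_steepness logistic dropout in log10
#'   intensity: an entry of intensity I is missing with probability
#'   `plogis(-steepness * (log10 I - log10 midpoint))`.
#' @param misaligned_rate fraction of peptides turned into misaligned
#'   features (one spurious high intensity in one column of a random
#'   biological group, the group's other columns missing).
#' @param misaligned_intensity range the spurious intensity is drawn from
#'   (log-uniform).
#' @param shared_peptide_rate fraction of peptides also mapped to a second,
#'   random protein (razor-rule exercise).
#' @param seed integer seed; fixes the full output.
#' @return a named list of class `"synth_params"`.
#' @export
synth_params <- function(n_proteins = 2000L,
                         peptides_per_protein = c(2L, 13L),
                         frac_bait_proximal = 0.10,
                         bait_enrichment_fold = 4,
                         frac_genotype_modulated = 0.20,
                         genotype_fold = 3,
                         cv_biological = 0.165,
                         cv_technical = 0.11,
                         abundance_meanlog = log(2e6),
                         abundance_sdlog = 1.2,
                         ionization_sdlog = 0.8,
                         dropout_midpoint = 1e5,
                         dropout_steepness = 2,
                         misaligned_rate = 0.01,
                         misaligned_intensity = c(2e7, 1e8),
                         shared_peptide_rate = 0.05,
                         seed = 1L) {
  p <- list(n_proteins = as.integer(n_proteins),
            peptides_per_protein = as.integer(peptides_per_protein),
            frac_bait_proximal = frac_bait_proximal,
            bait_enrichment_fold = bait_enrichment_fold,
            frac_genotype_modulated = frac_genotype_modulated,
            genotype_fold = genotype_fold,
            cv_biological = cv_biological,
            cv_technical = cv_technical,
            abundance_meanlog = abundance_meanlog,
            abundance_sdlog = abundance_sdlog,
            ionization_sdlog = ionization_sdlog,
            dropout_midpoint = dropout_midpoint,
            dropout_steepness = dropout_steepness,
            misaligned_rate = misaligned_rate,
            misaligned_intensity = misaligned_intensity,
            shared_peptide_rate = shared_peptide_rate,
            seed = as.integer(seed))
  fracs <- c(p$frac_bait_proximal, p$frac_genotype_modulated,
             p$misaligned_rate, p$shared_peptide_rate)
  if (any(fracs < 0 | fracs > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (p$bait_enrichment_fold < 1 || p$genotype_fold < 1) {
    stop("folds must be >= 1", call. = FALSE)
  }
  if (p$n_proteins < 1L || length(p$peptides_per_protein) != 2L ||
      any(p$peptides_per_protein < 1L) ||
      p$peptides_per_protein[1] > p$peptides_per_protein[2]) {
    stop("invalid protein/peptide counts", call. = FALSE)
  }
  if (p$cv_biological < 0 || p$cv_technical < 0 ||
      p$dropout_midpoint <= 0 || p$dropout_steepness <= 0) {
    stop("invalid noise/dropout parameters", call. = FALSE)
  }
  if (is.na(p$seed)) stop("seed must be an integer", call. = FALSE)
  class(p) <- "synth_params"
  p
}

# the 12-sample + 3-SPQC study design
standard_design <- function() {
  gen <- rep(c("WT", "GS"), each = 6)
  con <- rep(rep(c("EZR", "CYT"), each = 3), 2)
  rep_i <- rep(1:3, 4)
  df <- data.frame(
    sample_id = c(paste(gen, con, rep_i, sep = "_"), paste0("SPQC_", 1:3)),
    genotype = c(gen, rep(NA, 3)),
    construct = c(con, rep(NA, 3)),
    replicate = c(rep_i, 1:3),
    is_spqc = c(rep(FALSE, 12), rep(TRUE, 3)),
    stringsAsFactors = FALSE)
  sample_design(df)
}

# lognormal multiplier with unit mean and the given CV
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a complete synthetic BioID dataset
#'
#' Simulates the 12-sample + 3-SPQC design: protein base abundances are
#' lognormal; bait-proximal proteins are multiplied by
#' `bait_enrichment_fold` in EZR columns; gained (lost) proteins are
#' additionally multiplied (divided) by `genotype_fold` in GS-EZR columns;
#' biological and technical lognormal noise act at the protein x injection
#' level; each peptide is the protein value times a fixed lognormal
#' ionizability. SPQC columns are the noiseless mean of the 12 biological
#' columns with technical noise only, emulating a pool of equal volumes of
#' every sample. The matrix is complete (no missing values); apply
#' [apply_missingness()] for dropout and misaligned features.
#'
#' @param params a [synth_params()] object.
#' @return list with `peptides` (a [pqm()] at stage `"raw"`, fully
#'   observed), `map` (peptide-to-protein candidates), `design` (a
#'   [sample_design()]), `truth` (per-protein flags `bait_proximal`,
#'   `gained`, `lost` and expected EZR/CYT ratios per genotype) and
#'   `params`.
#' @export
generate_dataset <- function(params = synth_params()) {
  stopifnot(inherits(params, "synth_params"))
  local_seed(params$seed, {
    design <- standard_design()
    bio_ids <- design$sample_id[!design$is_spqc]
    spqc_ids <- spqc_samples(design)
    np <- params$n_proteins
    acc <- sprintf("PROT%05d", seq_len(np))

    bait <- runif(np) < params$frac_bait_proximal
    modulated <- bait & (runif(np) < params$frac_genotype_modulated)
    dir_up <- runif(np) < 0.5
    gained <- modulated & dir_up
    lost <- modulated & !dir_up

    # expected fold multiplier per protein x biological sample
    M <- matrix(1, np, length(bio_ids), dimnames = list(acc, bio_ids))
    ezr_cols <- bio_ids[grepl("_EZR_", bio_ids)]
    gs_ezr_cols <- bio_ids[grepl("^GS_EZR_", bio_ids)]
    M[bait, ezr_cols] <- params$bait_enrichment_fold
    M[gained, gs_ezr_cols] <- M[gained, gs_ezr_cols] * params$genotype_fold
    M[lost, gs_ezr_cols] <- M[lost, gs_ezr_cols] / params$genotype_fold

    A <- rlnorm(np, params$abundance_meanlog, params$abundance_sdlog)
    bio_noise <- matrix(rlnorm_cv(np * length(bio_ids),
                                  params$cv_biological),
                        np, length(bio_ids))
    tech_bio <- matrix(rlnorm_cv(np * length(bio_ids),
                                 params$cv_technical),
                       np, length(bio_ids))
    V_bio <- A * M * bio_noise * tech_bio

    pool <- rowMeans(A * M)  # noiseless equal-volume pool of all samples
    tech_spqc <- matrix(rlnorm_cv(np * length(spqc_ids),
                                  params$cv_technical),
                        np, length(spqc_ids))
    V <- cbind(V_bio, pool * tech_spqc)
    colnames(V) <- c(bio_ids, spqc_ids)

    npep <- sample(params$peptides_per_protein[1]:
                     params$peptides_per_protein[2],
                   np, replace = TRUE)
    pep_protein <- rep(seq_len(np), npep)
    pep_id <- sprintf("%s_pep%02d", acc[pep_protein],
                      sequence(npep))
    E <- rlnorm(length(pep_id), 0, params$ionization_sdlog)
    I <- V[pep_protein, , drop = FALSE] * E
    rownames(I) <- pep_id

    shared <- runif(length(pep_id)) < params$shared_peptide_rate &
      np > 1L
    other <- vapply(pep_protein, function(i) {
      j <- sample.int(np - 1L, 1L)
      if (j >= i) j <- j + 1L
      j
    }, integer(1))
    candidates <- ifelse(shared,
                         paste(acc[pep_protein], acc[other], sep = ";"),
                         acc[pep_protein])
    map <- data.frame(peptide_id = pep_id, candidates = candidates,
                      stringsAsFactors = FALSE)

    exp_wt <- ifelse(bait, params$bait_enrichment_fold, 1)
    exp_gs <- exp_wt * ifelse(gained, params$genotype_fold, 1) /
      ifelse(lost, params$genotype_fold, 1)
    truth <- data.frame(protein = acc, bait_proximal = bait,
                        gained = gained, lost = lost,
                        expected_ezr_cyt_wt = exp_wt,
                        expected_ezr_cyt_gs = exp_gs,
                        stringsAsFactors = FALSE)

    list(peptides = pqm(I, stage = "raw"), map = map, design = design,
         truth = truth, params = params)
  })
}

#' Apply intensity-dependent dropout and misaligned features
#'
#' Each entry of the complete matrix is dropped with probability
#' `plogis(-dropout_steepness * (log10 I - log10 dropout_midpoint))`, a
#' left-censoring-like missing-not-at-random mechanism. Additionally, with
#' probability `misaligned_rate` a peptide becomes a misaligned feature:
#' one random column of one random biological group receives a spurious
#' high intensity while the group's remaining columns are set missing —
#' the mostly-missing/high-intensity pattern the imputation's zeroing
#' branch is designed to catch.
#'
#' @param x a [pqm()] at stage `"raw"` that has not had missingness applied
#'   yet (calling this twice on the same matrix is an error).
#' @param params the [synth_params()] used to generate `x`. Randomness is
#'   seeded from `params$seed` (offset from the generator's stream), so the
#'   result is reproducible on its own.
#' @return list with `matrix` (the masked [pqm()]) and `cause` (character
#'   matrix: `"observed"`, `"dropout"` or `"misaligned"` per entry).
#' @export
apply_missingness <- function(x, params) {
  require_stage(x, "raw")
  stopifnot(inherits(params, "synth_params"))
  if (isTRUE(attr(x, "missingness_applied"))) {
    stop("missingness has already been applied to this matrix",
         call. = FALSE)
  }
  I <- x$intensity
  local_seed(params$seed + 1L, {
    p_drop <- stats::plogis(-params$dropout_steepness *
                              (log10(pmax(I, .Machine$double.xmin)) -
                                 log10(params$dropout_midpoint)))
    dropped <- matrix(runif(length(I)) < p_drop, nrow(I),
                      dimnames = dimnames(I))
    cause <- matrix("observed", nrow(I), ncol(I), dimnames = dimnames(I))
    cause[dropped] <- "dropout"

    design <- standard_design()
    groups <- biological_groups(design)
    mis <- which(runif(nrow(I)) < params$misaligned_rate)
    lo <- log10(params$misaligned_intensity[1])
    hi <- log10(params$misaligned_intensity[2])
    for (r in mis) {
      g <- groups[[sample.int(length(groups), 1L)]]
      spur <- sample(g, 1L)
      I[r, spur] <- 10^runif(1L, lo, hi)
      dropped[r, g] <- TRUE
      dropped[r, spur] <- FALSE
      cause[r, g] <- "misaligned"
    }
    observed <- !dropped
    I[!observed] <- 0
    out <- pqm(I, observed = observed, stage = "raw")
    attr(out, "missingness_applied") <- TRUE
    list(matrix = out, cause = cause)
  })
}

#' Simulate a full synthetic BioID dataset with missingness
#'
#' Convenience wrapper: [generate_dataset()] followed by
#' [apply_missingness()].
#'
#' @param params a [synth_params()] object.
#' @return as [generate_dataset()], with `peptides` masked and an extra
#'   `missing_cause` element.
#' @export
simulate_bioid <- function(params = synth_params()) {
  d <- generate_dataset(params)
  m <- apply_missingness(d$peptides, params)
  d$peptides <- m$matrix
  d$missing_cause <- m$cause
  d
}
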