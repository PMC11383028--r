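# Fixture builders shared across test files.

# The standard 12-biological-sample + 3-SPQC design.
std_design <- function() {
  gen <- rep(c("WT", "GS"), each = 6)
  con <- rep(rep(c("EZR", "CYT"), each = 3), 2)
  sample_design(data.frame(
    sample_id = c(paste(gen, con, rep(1:3, 4), sep = "_"),
                  paste0("SPQC_", 1:3)),
    genotype = c(gen, rep(NA, 3)),
    construct = c(con, rep(NA, 3)),
    replicate = c(rep(1:3, 4), 1:3),
    is_spqc = c(rep(FALSE, 12), rep(TRUE, 3))))
}

# A small raw pqm over the standard design with given intensities/mask.
make_pqm <- function(intensity, observed = NULL, stage = "raw") {
  pqm(intensity, observed = observed, stage = stage)
}

# Random raw matrix over the standard design: lognormal intensities with
# missingness rate `p_miss`.
random_pqm <- function(n_pep, p_miss = 0.2, seed = 1) {
  d <- std_design()
  set.seed(seed)
  m <- matrix(rlnorm(n_pep * 15, log(1e6), 1), n_pep, 15,
              dimnames = list(sprintf("pep%03d", seq_len(n_pep)),
                              d$sample_id))
  obs <- matrix(runif(length(m)) > p_miss, nrow(m),
                dimnames = dimnames(m))
  pqm(m, observed = obs)
}

# Build a pqm at a later stage without running earlier stages (tests of a
# single operation craft their input directly).
at_stage <- function(intensity, stage, observed = NULL) {
  x <- pqm(intensity, observed = observed, stage = "raw")
  x$stage <- stage
  x
}
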