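design15 <- std_design()

test_that("the peptide filter applies the twice-overall / half-in-a-group rule", {
  d <- design15
  m <- matrix(1e6, 4, 15, dimnames = list(paste0("pep", 1:4), d$sample_id))
  obs <- matrix(FALSE, 4, 15, dimnames = dimnames(m))
  obs["pep1", "WT_EZR_1"] <- TRUE                      # once overall
  obs["pep2", c("WT_EZR_1", "GS_EZR_1")] <- TRUE       # 1/3 in two groups
  obs["pep3", c("WT_EZR_1", "WT_EZR_2")] <- TRUE       # 2/3 in one group
  obs["pep4", c("SPQC_1", "SPQC_2", "SPQC_3")] <- TRUE # SPQC only
  f <- filter_peptides(pqm(m, observed = obs), d)
  expect_identical(rownames(f$intensity), "pep3")
  expect_identical(f$stage, "filtered")
})

test_that("the filter is idempotent and never adds peptides", {
  x <- random_pqm(60, p_miss = 0.5, seed = 7)
  f1 <- filter_peptides(x, design15)
  f2 <- filter_peptides(pqm(f1$intensity, observed = f1$observed), design15)
  expect_identical(f1$intensity, f2$intensity)
  expect_true(all(rownames(f1$intensity) %in% rownames(x$intensity)))
})

test_that("total-intensity normalization equalizes observed column sums", {
  m <- matrix(c(40, 60, 150, 50), 2, 2,
              dimnames = list(c("p1", "p2"), c("s1", "s2")))
  x <- at_stage(m, "filtered")
  r <- total_intensity_normalize(x)
  expect_equal(unname(r$factors), c(1.5, 0.75))       # totals 100 and 200
  expect_equal(unname(colSums(r$matrix$intensity)), c(150, 150))

  # equal sums: identity, all factors 1
  m2 <- matrix(c(10, 90, 60, 40), 2, 2,
               dimnames = list(c("p1", "p2"), c("s1", "s2")))
  r2 <- total_intensity_normalize(at_stage(m2, "filtered"))
  expect_equal(unname(r2$factors), c(1, 1))
  expect_equal(r2$matrix$intensity, m2)

  # single sample: reference equals itself
  m3 <- m2[, 1, drop = FALSE]
  r3 <- total_intensity_normalize(at_stage(m3, "filtered"))
  expect_equal(r3$matrix$intensity, m3)

  # idempotence: renormalizing changes nothing
  again <- total_intensity_normalize(at_stage(r$matrix$intensity,
                                              "filtered"))
  expect_equal(unname(again$factors), c(1, 1))
})

test_that("normalization only rescales observed entries and errors on empty columns", {
  x <- random_pqm(30, p_miss = 0.3, seed = 3)
  f <- filter_peptides(x, design15)
  r <- total_intensity_normalize(f)
  expect_identical(r$matrix$observed, f$observed)
  sums <- colSums(r$matrix$intensity * r$matrix$observed)
  expect_lt(diff(range(sums)) / mean(sums), 1e-9)

  m <- matrix(c(1, 2, 0, 0), 2, 2,
              dimnames = list(c("p1", "p2"), c("s1", "s2")))
  bad <- at_stage(m, "filtered",
                  observed = matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2))
  expect_error(total_intensity_normalize(bad), "zero observed total")
})

# builds a total_normalized matrix over the standard design from a list of
# per-group value vectors (NA = missing) repeated for each peptide row
impute_fixture <- function(rows) {
  d <- std_design()
  m <- matrix(1e6, length(rows), 15,
              dimnames = list(names(rows), d$sample_id))
  obs <- matrix(TRUE, length(rows), 15, dimnames = dimnames(m))
  for (r in names(rows)) {
    for (g in names(rows[[r]])) {
      cols <- biological_groups(d)[[g]]
      v <- rows[[r]][[g]]
      m[r, cols] <- ifelse(is.na(v), 0, v)
      obs[r, cols] <- !is.na(v)
    }
  }
  at_stage(m, "total_normalized", observed = obs)
}

test_that("imputation takes the documented branch per peptide-group", {
  x <- impute_fixture(list(
    pep1 = list(WT_EZR = c(1e6, NA, 1.2e6)),     # <50% missing
    pep2 = list(WT_EZR = c(6e6, NA, NA)),        # mostly missing, mean>5e6
    pep3 = list(WT_EZR = c(1e4, NA, NA))))       # mostly missing, low
  cfg <- proxidiff_config(seed = 1)
  r <- impute_missing(x, std_design(), cfg)
  aud <- r$audit[r$audit$group == "WT_EZR", ]
  expect_identical(aud$branch[aud$peptide_id == "pep1"], "binned_normal")
  expect_identical(aud$branch[aud$peptide_id == "pep2"], "misaligned_zero")
  expect_identical(aud$branch[aud$peptide_id == "pep3"], "low_value")

  wt <- biological_groups(std_design())$WT_EZR
  # branch 1 leaves observed values untouched and fills with positive draws
  expect_equal(r$matrix$intensity["pep1", wt][c(1, 3)],
               setNames(c(1e6, 1.2e6), wt[c(1, 3)]))
  expect_gt(r$matrix$intensity["pep1", wt[2]], 0)
  # branch 2 zeroes the whole peptide-group, measured values included
  expect_equal(unname(r$matrix$intensity["pep2", wt]), c(0, 0, 0))
  # branch 3 fills with the global low quantile
  obs_all <- x$intensity[x$observed]
  q <- unname(quantile(obs_all, cfg$low_percentile))
  expect_equal(unname(r$matrix$intensity["pep3", wt[2:3]]), c(q, q))
  expect_equal(r$low_floor, q)
  expect_equal(r$zero_floor, q / 2)
  # mask is complete afterwards
  expect_equal(n_missing(r$matrix), 0L)
  expect_identical(r$matrix$stage, "imputed")
})

test_that("imputation is seed-deterministic and requires a seed", {
  x <- random_pqm(40, p_miss = 0.25, seed = 5)
  f <- filter_peptides(x, design15)
  tn <- total_intensity_normalize(f)$matrix
  a <- impute_missing(tn, design15, proxidiff_config(seed = 33))
  b <- impute_missing(tn, design15, proxidiff_config(seed = 33))
  expect_identical(a$matrix$intensity, b$matrix$intensity)
  expect_identical(a$audit, b$audit)
  c <- impute_missing(tn, design15, proxidiff_config(seed = 34))
  expect_false(identical(a$matrix$intensity, c$matrix$intensity))
  expect_error(impute_missing(tn, design15, proxidiff_config()), "seed")
})

test_that("imputation preserves observed values outside the misaligned branch", {
  x <- random_pqm(60, p_miss = 0.3, seed = 11)
  f <- filter_peptides(x, design15)
  tn <- total_intensity_normalize(f)$matrix
  r <- impute_missing(tn, design15, proxidiff_config(seed = 1))
  zeroed <- unique(r$audit$peptide_id[r$audit$branch == "misaligned_zero"])
  keep <- !(rownames(tn$intensity) %in% zeroed)
  expect_equal(r$matrix$intensity[keep, ][tn$observed[keep, ]],
               tn$intensity[keep, ][tn$observed[keep, ]])
})

test_that("a fully observed matrix passes through imputation unchanged", {
  x <- random_pqm(20, p_miss = 0, seed = 2)
  f <- filter_peptides(x, design15)
  tn <- total_intensity_normalize(f)$matrix
  r <- impute_missing(tn, design15, proxidiff_config(seed = 1))
  expect_equal(r$matrix$intensity, tn$intensity)
  expect_equal(nrow(r$audit), 0L)
})

test_that("trimmed-mean normalization equalizes 10%-trimmed means", {
  m <- cbind(s1 = 1:10, s2 = 2 * (1:10))
  rownames(m) <- paste0("p", 1:10)
  r <- trimmed_mean_normalize(at_stage(m, "imputed"))
  # trimmed mean of 1..10 at 10% per tail is mean(2..9) = 5.5
  expect_equal(unname(r$factors), c(8.25 / 5.5, 8.25 / 11))
  tm_post <- apply(r$matrix$intensity, 2, function(v) {
    sv <- sort(v[v > 0]); mean(sv[2:(length(sv) - 1)])
  })
  expect_lt(diff(range(tm_post)) / mean(tm_post), 1e-9)
  expect_true(all(r$factors > 0))

  # samples already sharing a trimmed mean: identity
  m2 <- cbind(s1 = 1:10, s2 = 10:1)
  rownames(m2) <- paste0("p", 1:10)
  r2 <- trimmed_mean_normalize(at_stage(m2, "imputed"))
  expect_equal(r2$matrix$intensity, m2)

  # doubling one sample halves its factor relative to the other sample
  m3 <- cbind(s1 = 1:10, s2 = 1:10)
  rownames(m3) <- paste0("p", 1:10)
  base <- trimmed_mean_normalize(at_stage(m3, "imputed"))
  expect_equal(unname(base$factors[2] / base$factors[1]), 1)
  m4 <- m3; m4[, 2] <- 2 * m4[, 2]
  dbl <- trimmed_mean_normalize(at_stage(m4, "imputed"))
  expect_equal(unname(dbl$factors[2] / dbl$factors[1]), 0.5)
})

test_that("zeros are excluded from trimming statistics but still scaled", {
  m <- cbind(s1 = c(0, 0, 1:10), s2 = c(0, 0, 2 * (1:10)))
  rownames(m) <- paste0("p", 1:12)
  r <- trimmed_mean_normalize(at_stage(m, "imputed"))
  expect_equal(unname(r$factors), c(8.25 / 5.5, 8.25 / 11))
  expect_equal(unname(r$matrix$intensity[1:2, ]),
               matrix(0, 2, 2))
  expect_error(trimmed_mean_normalize(
    at_stage(cbind(s1 = c(1, 2, 0, 0),
                   s2 = c(1, 2, 3, 4)) |>
               `rownames<-`(paste0("p", 1:4)), "imputed")),
    "fewer than 3")
})
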