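#' Razor-peptide assignment
#'
#' Resolves shared peptides: a peptide matching multiple candidate proteins
#' is exclusively assigned to the candidate with the larger number of
#' identified peptides, counted over the peptides present in the matrix
#' (i.e. those surviving the filter). Ties break to the lexicographically
#' smaller accession, so the assignment is deterministic and independent of
#' input row order.
#'
#' @param map data.frame with columns `peptide_id` and `candidates`
#'   (semicolon-separated accessions), e.g. from [read_peptide_map()].
#'   Rows for peptides absent from the matrix are dropped.
#' @param x a [pqm()] object whose rownames define the identified peptides.
#' @return the map restricted to matrix peptides, with an `assigned`
#'   column added.
#' @export
assign_razor <- function(map, x) {
  stopifnot(is.data.frame(map),
            all(c("peptide_id", "candidates") %in% names(map)))
  peptides <- rownames(x$intensity)
  map <- map[map$peptide_id %in% peptides, , drop = FALSE]
  if (!nrow(map)) stop("no mapped peptides present in the matrix",
                       call. = FALSE)
  cand <- strsplit(map$candidates, ";", fixed = TRUE)
  if (any(lengths(cand) == 0L)) {
    stop("peptide with zero candidate proteins", call. = FALSE)
  }
  # identified-peptide count per candidate protein, over surviving peptides
  counts <- table(unlist(cand, use.names = FALSE))
  map$assigned <- vapply(cand, function(cs) {
    cs <- unique(cs)
    n <- as.vector(counts[cs])
    best <- cs[n == max(n)]
    sort(best)[1L]
  }, character(1))
  rownames(map) <- NULL
  map
}

#' Group indistinguishable proteins and pick master accessions
#'
#' Proteins identified by exactly the same set of peptides (their candidate
#' sets over the surviving peptides are identical) are indistinguishable
#' and merged into one protein group. The master accession is the member
#' with the highest percent coverage (sum of unique peptide lengths /
#' protein length) when `protein_lengths` is supplied; otherwise the member
#' with the most identified peptides — identical within a group by
#' construction, so the tie falls through to the lexicographically smaller
#' accession. All remaining ties break lexicographically.
#'
#' @param map a razor-resolved map from [assign_razor()].
#' @param protein_lengths optional named numeric vector of protein lengths
#'   (residues) for coverage-based master selection. Peptide length is
#'   taken as `nchar(peptide_id)`, i.e. ids are assumed to be sequences.
#' @return list with `map` (the input plus `group` and `master` columns;
#'   `master` is the master of the group holding the peptide's razor-
#'   assigned protein) and `groups` (data.frame: `master`, `accessions`
#'   (semicolon-separated), `n_peptides` = size of the shared peptide set).
#' @export
group_proteins <- function(map, protein_lengths = NULL) {
  stopifnot(is.data.frame(map), "assigned" %in% names(map))
  cand <- strsplit(map$candidates, ";", fixed = TRUE)
  long_acc <- unlist(cand, use.names = FALSE)
  long_pep <- rep(map$peptide_id, lengths(cand))
  pep_sets <- lapply(split(long_pep, long_acc), unique)
  keys <- vapply(pep_sets, function(p) paste(sort(p), collapse = "\r"),
                 character(1))
  by_key <- split(names(pep_sets), keys)

  master_of <- character(0)
  group_rows <- vector("list", length(by_key))
  for (i in seq_along(by_key)) {
    accs <- sort(by_key[[i]])
    peps <- pep_sets[[accs[1L]]]
    if (!is.null(protein_lengths) && all(accs %in% names(protein_lengths))) {
      covered <- sum(nchar(unique(peps)))
      coverage <- covered / protein_lengths[accs]
      master <- accs[coverage == max(coverage)][1L]  # accs sorted: lexicographic tie-break
    } else {
      # identical peptide counts within a group; lexicographic fallback
      master <- accs[1L]
    }
    master_of[accs] <- master
    group_rows[[i]] <- data.frame(master = master,
                                  accessions = paste(accs, collapse = ";"),
                                  n_peptides = length(peps),
                                  stringsAsFactors = FALSE)
  }
  groups <- do.call(rbind, group_rows)
  groups <- groups[order(groups$master), , drop = FALSE]
  rownames(groups) <- NULL
  group_str <- setNames(groups$accessions, groups$master)
  map$master <- unname(master_of[map$assigned])
  map$group <- unname(group_str[map$master])
  list(map = map, groups = groups)
}

#' Roll peptides up to protein intensities
#'
#' Sums the assigned peptide intensities per (protein group, sample); rows
#' are labeled by the group's master accession. Per-sample intensity is
#' conserved exactly: the sum over proteins equals the sum over assigned
#' peptides.
#'
#' @param x a [pqm()] at stage `"trimmed_normalized"` (no missing entries).
#' @param grouped result of [group_proteins()].
#' @return list with `intensity` (protein x sample numeric matrix),
#'   `peptide_count` (named integer vector) and `groups` (the group table).
#' @export
rollup_proteins <- function(x, grouped) {
  require_stage(x, "trimmed_normalized")
  map <- grouped$map
  idx <- match(map$peptide_id, rownames(x$intensity))
  if (anyNA(idx)) stop("mapped peptide missing from matrix", call. = FALSE)
  mat <- rowsum(x$intensity[idx, , drop = FALSE], group = map$master,
                reorder = TRUE)
  counts <- table(map$master)
  peptide_count <- as.integer(counts[rownames(mat)])
  names(peptide_count) <- rownames(mat)
  list(intensity = mat, peptide_count = peptide_count,
       groups = grouped$groups)
}
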