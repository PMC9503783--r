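#' Space and population coverage of a selection
#'
#' For a partitioned library and a selection of its compounds:
#' * space coverage `SC = 100 * k_oc / K` — the percentage of partitions
#'   occupied by at least one selected compound (`k_oc` occupied out of
#'   `K`);
#' * population coverage `PC = 100 * n_oc / N` — the percentage of all
#'   library compounds residing in the occupied partitions (`n_oc` is the
#'   total population of the occupied partitions).
#'
#' PC weights SC by partition occupancy: selecting one compound from a
#' hyper-populated cluster "represents" all of its members.
#'
#' @param part a `chem_partition`.
#' @param selection integer member indices, a `subset_declaration`, or a
#'   `selection_result`; must be non-empty, unique and in range.
#' @return a `coverage_result` with fields `k_oc`, `n_oc`, `K`, `N`, `sc`,
#'   `pc` (exact percentages; printing rounds to one decimal, half-up).
#' @examples
#' part <- partitioning(rep(1:5, each = 10))
#' coverage(part, c(1, 11, 21))   # 3 of 5 partitions -> SC = 60
#' @export
coverage <- function(part, selection) {
  .check(inherits(part, "chem_partition"), "part must be a chem_partition")
  ids <- .selection_ids(selection)
  .check(length(ids) >= 1L, "selection must be non-empty: coverage is undefined")
  .check(!anyDuplicated(ids), "selection indices must be unique")
  .check(all(ids >= 1L & ids <= part$N),
         "selection indices must lie in 1..%d", part$N)
  occ <- unique(part$labels[ids])
  k_oc <- length(occ)
  n_oc <- sum(part$populations[occ])
  structure(list(k_oc = k_oc, n_oc = n_oc, K = part$K, N = part$N,
                 sc = 100 * k_oc / part$K,
                 pc = 100 * n_oc / part$N,
                 selection_size = length(ids)),
            class = "coverage_result")
}

.selection_ids <- function(selection) {
  if (inherits(selection, "selection_result")) return(selection$member_ids)
  if (inherits(selection, "subset_declaration")) return(selection$member_ids)
  as.integer(selection)
}

#' @export
print.coverage_result <- function(x, ...) {
  cat(sprintf("SC = %.1f%% (%d of %d partitions)   PC = %.1f%% (%d of %d compounds)   [selection: %d]\n",
              round_pct(x$sc), x$k_oc, x$K,
              round_pct(x$pc), x$n_oc, x$N, x$selection_size))
  invisible(x)
}

#' Rational one-per-partition selection
#'
#' Selects, for every partition, the member nearest to the partition
#' centroid in the principal-component coordinates (the PAM medoid when the
#' partitioning came from k-medoids); ties broken by lowest compound index.
#' By construction the selection covers 100% of the partitioned space
#' (SC = PC = 100).
#'
#' @param part a `chem_partition`.
#' @param space the `chem_space` (or score matrix) the partitioning was
#'   built on; rows must align with the partition labels.
#' @return a `selection_result` with exactly `K` member indices, one per
#'   partition (ordered by partition id), `strategy = "rational"`.
#' @export
rational_select <- function(part, space) {
  .check(inherits(part, "chem_partition"), "part must be a chem_partition")
  x <- .space_scores(space)
  .check(nrow(x) == part$N,
         "space has %d rows but the partitioning covers %d compounds",
         nrow(x), part$N)
  if (part$method == "kmedoids" && !is.null(part$meta$medoid_ids)) {
    ids <- part$meta$medoid_ids[order(part$labels[part$meta$medoid_ids])]
  } else {
    ids <- integer(part$K)
    for (c in seq_len(part$K)) {
      members <- which(part$labels == c)
      if (length(members) == 1L) { ids[c] <- members; next }
      ctr <- colMeans(x[members, , drop = FALSE])
      d2 <- colSums((t(x[members, , drop = FALSE]) - ctr)^2)
      ids[c] <- members[which.min(d2)]   # which.min takes the first = lowest index
    }
  }
  structure(list(member_ids = ids, strategy = "rational",
                 partition_ref = part$method),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("Selection [%s]: %d compound(s)\n", x$strategy, length(x$member_ids)))
  invisible(x)
}

#' Monte-Carlo random-selection baseline
#'
#' Draws `reps` random selections of `sample_size` compounds uniformly
#' without replacement and averages their coverage — the reference against
#' which a declared (bibliographical) subset of the same size is judged.
#'
#' @param part a `chem_partition`.
#' @param sample_size selection size, `1..N`.
#' @param reps repetitions (default 5000).
#' @param seed RNG seed; results are reproducible given the seed.
#' @param keep_reps retain the per-repetition SC/PC vectors (default TRUE).
#' @return a `baseline_result`: `mean_sc`, `mean_pc`, `se_sc`, `se_pc`,
#'   `reps`, `sample_size`, and (optionally) `sc`, `pc` per-rep vectors.
#' @seealso [expected_coverage()] for the analytic expectation.
#' @export
random_baseline <- function(part, sample_size, reps = 5000L, seed = NULL,
                            keep_reps = TRUE) {
  .check(inherits(part, "chem_partition"), "part must be a chem_partition")
  sample_size <- as.integer(sample_size)
  .check(sample_size >= 1L && sample_size <= part$N,
         "sample_size must lie in 1..%d", part$N)
  N <- part$N; K <- part$K
  labels <- part$labels; pop <- part$populations
  sc <- pc <- numeric(reps)
  with_seed(seed, {
    for (r in seq_len(reps)) {
      occ <- unique(labels[sample.int(N, sample_size)])
      sc[r] <- 100 * length(occ) / K
      pc[r] <- 100 * sum(pop[occ]) / N
    }
  })
  structure(list(mean_sc = mean(sc), mean_pc = mean(pc),
                 se_sc = stats::sd(sc) / sqrt(reps),
                 se_pc = stats::sd(pc) / sqrt(reps),
                 reps = reps, sample_size = sample_size, seed = seed,
                 sc = if (keep_reps) sc, pc = if (keep_reps) pc),
            class = "baseline_result")
}

#' @export
print.baseline_result <- function(x, ...) {
  cat(sprintf("Random baseline (n = %d, %d reps): mean SC = %.1f%%  mean PC = %.1f%%\n",
              x$sample_size, x$reps, round_pct(x$mean_sc), round_pct(x$mean_pc)))
  invisible(x)
}

#' Analytic expectation of random-selection coverage
#'
#' Closed form for the mean SC/PC of a uniform without-replacement sample
#' of size `s`: a partition with population `n_c` is occupied with
#' probability `1 - C(N - n_c, s) / C(N, s)`, so
#' `E[SC] = (100/K) * sum_c [1 - C(N-n_c, s)/C(N, s)]` and
#' `E[PC] = (100/N) * sum_c n_c * [1 - C(N-n_c, s)/C(N, s)]`.
#' Computed with log-binomial coefficients for numerical stability.
#'
#' @param part a `chem_partition`.
#' @param sample_size selection size, `1..N`.
#' @return list with elements `sc` and `pc` (exact expected percentages).
#' @export
expected_coverage <- function(part, sample_size) {
  .check(inherits(part, "chem_partition"), "part must be a chem_partition")
  s <- as.integer(sample_size)
  .check(s >= 1L && s <= part$N, "sample_size must lie in 1..%d", part$N)
  N <- part$N
  pop <- part$populations
  lN <- lchoose(N, s)
  lmiss <- ifelse(N - pop >= s, lchoose(N - pop, s), -Inf)
  p_occ <- 1 - exp(lmiss - lN)
  list(sc = 100 * sum(p_occ) / part$K,
       pc = 100 * sum(pop * p_occ) / N)
}

#' Compare a declared subset against random and rational selections
#'
#' Reproduces the comparison protocol used to judge bibliographical
#' compound sets: for each requested partitioning method, the space is
#' divided into `k` partitions and three selections are scored — the
#' declared subset, a size-matched random baseline (Monte-Carlo mean or the
#' analytic expectation) and the rational one-per-partition reference.
#'
#' @param space a `chem_space` (or score matrix).
#' @param declared a `subset_declaration` or integer member indices.
#' @param k partition count (e.g. `default_k(N)` or the subset size).
#' @param methods partitioning methods to compare (see
#'   [partition_space()]).
#' @param baseline `"analytic"` (exact expectation, default) or `"mc"`
#'   (Monte-Carlo with `reps` repetitions).
#' @param reps,seed Monte-Carlo parameters (used when `baseline = "mc"`;
#'   `seed` also seeds k-means).
#' @return a `coverage_comparison` data.frame with columns `method`,
#'   `selection` (`declared`/`random`/`rational`), `size`, `sc`, `pc`
#'   (exact percentages; print rounds to one decimal).
#' @export
compare_selections <- function(space, declared, k,
                               methods = c("hrc_average", "hrc_complete",
                                           "hrc_ward", "kmeans", "kmedoids",
                                           "ov_binning"),
                               baseline = c("analytic", "mc"),
                               reps = 5000L, seed = 1L) {
  baseline <- match.arg(baseline)
  x <- .space_scores(space)
  ids <- .selection_ids(declared)
  .check(all(ids >= 1L & ids <= nrow(x)),
         "declared subset indices outside the library (offenders: %s)",
         paste(utils::head(ids[ids < 1L | ids > nrow(x)], 3L), collapse = ", "))
  s <- length(ids)
  rows <- list()
  for (m in methods) {
    part <- partition_space(x, k, method = m, seed = seed)
    dcov <- coverage(part, ids)
    rnd <- if (baseline == "analytic") expected_coverage(part, s)
           else { b <- random_baseline(part, s, reps = reps, seed = seed,
                                       keep_reps = FALSE)
                  list(sc = b$mean_sc, pc = b$mean_pc) }
    rcov <- coverage(part, rational_select(part, x))
    rows[[m]] <- data.frame(
      method = m,
      selection = c("declared", "random", "rational"),
      size = c(s, s, part$K),
      sc = c(dcov$sc, rnd$sc, rcov$sc),
      pc = c(dcov$pc, rnd$pc, rcov$pc),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("coverage_comparison", "data.frame")
  out
}

#' @export
print.coverage_comparison <- function(x, ...) {
  y <- as.data.frame(x)
  y$sc <- round_pct(y$sc)
  y$pc <- round_pct(y$pc)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
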