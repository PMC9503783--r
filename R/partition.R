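#' Standard cluster-count rules
#'
#' Rule-of-thumb partition counts used when a silhouette scan is
#' inconclusive (as is typical for large combinatorial libraries, whose
#' strong inter-descriptor correlation yields a concave silhouette curve
#' with no interior maximum): the square-root rule `ceil(sqrt(N))`, its
#' half, and ten times it.
#'
#' @param N library size (>= 2).
#' @param rule `"sqrt"` (default), `"half"` or `"ten"`.
#' @return integer partition count `K >= 1`.
#' @examples
#' default_k(25472)           # 160
#' default_k(25472, "half")   # 80
#' default_k(25472, "ten")    # 1600
#' @export
default_k <- function(N, rule = c("sqrt", "half", "ten")) {
  rule <- match.arg(rule)
  .check(is.numeric(N) && length(N) == 1L && N >= 2, "N must be a single number >= 2")
  r <- ceiling(sqrt(N))
  k <- switch(rule,
              sqrt = r,
              half = max(1, round(r / 2)),
              ten  = 10L * r)
  as.integer(k)
}

# ---- constructors -----------------------------------------------------------

# normalize a raw label vector: contiguous ids 1..K over occupied partitions
.relabel <- function(labels) {
  u <- sort(unique(labels))
  match(labels, u)
}

#' Construct a partitioning from a label vector
#'
#' Wraps an arbitrary exhaustive assignment (e.g. from an external
#' clustering) into the partition object used by the coverage statistics.
#' Labels are relabelled to contiguous ids `1..K` over occupied partitions.
#'
#' @param labels vector assigning each compound to a partition.
#' @param method method name recorded in the object (default `"declared"`).
#' @param k_nominal requested partition count, if different from the
#'   occupied count (binning methods may leave cells empty).
#' @return an object of class `chem_partition`: `labels` (1..K), `K`
#'   (occupied partitions), `N`, `populations`, `method`.
#' @export
partitioning <- function(labels, method = "declared", k_nominal = NULL) {
  .check(length(labels) >= 1L && !anyNA(labels), "labels must be complete and non-empty")
  lab <- .relabel(labels)
  K <- max(lab)
  structure(list(labels = lab,
                 K = K,
                 k_nominal = if (is.null(k_nominal)) K else as.integer(k_nominal),
                 N = length(lab),
                 populations = tabulate(lab, nbins = K),
                 method = method,
                 meta = list()),
            class = "chem_partition")
}

#' @export
print.chem_partition <- function(x, ...) {
  cat(sprintf("Partitioning [%s]: N = %d compounds in K = %d partitions",
              x$method, x$N, x$K))
  if (x$k_nominal != x$K) cat(sprintf(" (nominal %d)", x$k_nominal))
  cat("\n")
  print(population_stats(x))
  invisible(x)
}

#' Partition a chemical space
#'
#' Divides a chemical space into `k` partitions with one of the clustering
#' or cell-based methods studied for combinatorial-library coverage:
#' hierarchical agglomerative clustering with six linkage criteria on
#' Euclidean distances, k-means, k-medoids (PAM), equal-width binning and
#' optimum-variance binning. For the binning methods `k` is nominal: the
#' grid is the smallest `b^d >= k` over the first `d = min(m, 5)` principal
#' components, and `K` is the number of occupied cells.
#'
#' @param space a `chem_space` or a numeric score matrix.
#' @param k requested partition count.
#' @param method one of `"hrc_single"`, `"hrc_complete"`, `"hrc_median"`,
#'   `"hrc_average"`, `"hrc_centroid"`, `"hrc_ward"`, `"kmeans"`,
#'   `"kmedoids"`, `"binning"`, `"ov_binning"`.
#' @param seed RNG seed (k-means restarts); other methods are
#'   deterministic.
#' @param nstart k-means restarts keeping the best inertia (default 10).
#' @param dims number of leading components used by the binning methods
#'   (default `min(m, 5)`).
#' @return a `chem_partition` (see [partitioning()]).
#' @examples
#' sp <- matrix(rnorm(200), 100, 2)
#' p <- partition_space(sp, 10, "hrc_ward")
#' population_stats(p)
#' @export
partition_space <- function(space, k,
                            method = c("hrc_ward", "hrc_single", "hrc_complete",
                                       "hrc_median", "hrc_average", "hrc_centroid",
                                       "kmeans", "kmedoids", "binning", "ov_binning"),
                            seed = NULL, nstart = 10L, dims = NULL) {
  method <- match.arg(method)
  x <- .space_scores(space)
  N <- nrow(x)
  k <- as.integer(k)
  .check(k >= 1L && k <= N, "k must lie in 1..N (N = %d, k = %d)", N, k)

  part <- switch(
    method,
    hrc_single   = .cluster_hrc(x, k, "single"),
    hrc_complete = .cluster_hrc(x, k, "complete"),
    hrc_median   = .cluster_hrc(x, k, "median"),
    hrc_average  = .cluster_hrc(x, k, "average"),
    hrc_centroid = .cluster_hrc(x, k, "centroid"),
    hrc_ward     = .cluster_hrc(x, k, "ward"),
    kmeans       = .cluster_kmeans(x, k, seed = seed, nstart = nstart),
    kmedoids     = .cluster_kmedoids(x, k),
    binning      = .bin_space(x, k, dims = dims, optimal = FALSE),
    ov_binning   = .bin_space(x, k, dims = dims, optimal = TRUE))
  part$method <- method
  part
}

# ---- hierarchical -----------------------------------------------------------

# Euclidean-metric agglomerative clustering cut at k. Following hclust's
# contract, median and centroid linkage operate on squared Euclidean
# distances; Ward uses ward.D2 (unsquared). Inversions possible for
# median/centroid are tolerated: the tree is simply cut at k groups.
.cluster_hrc <- function(x, k, linkage) {
  d <- stats::dist(x)
  hm <- switch(linkage, ward = "ward.D2", single = "single",
               complete = "complete", average = "average",
               median = "median", centroid = "centroid")
  if (linkage %in% c("median", "centroid")) d <- d^2
  tree <- stats::hclust(d, method = hm)
  partitioning(stats::cutree(tree, k = k), method = paste0("hrc_", linkage))
}

# ---- relocation -------------------------------------------------------------

.cluster_kmeans <- function(x, k, seed = NULL, nstart = 10L) {
  if (k == 1L) {
    p <- partitioning(rep(1L, nrow(x)), method = "kmeans")
    p$meta$centers <- matrix(colMeans(x), 1L, dimnames = list(NULL, colnames(x)))
    p$meta$inertia <- sum(sweep(x, 2L, colMeans(x))^2)
    return(p)
  }
  ndistinct <- nrow(unique(x))
  .check(k <= ndistinct,
         "k = %d exceeds the number of distinct points (%d); clustering is degenerate",
         k, ndistinct)
  if (k == nrow(x)) {   # all-singleton limit; kmeans itself refuses k = n
    p <- partitioning(seq_len(nrow(x)), method = "kmeans")
    p$meta$centers <- x
    p$meta$inertia <- 0
    return(p)
  }
  km <- with_seed(seed,
                  stats::kmeans(x, centers = k, nstart = nstart, iter.max = 100L))
  p <- partitioning(km$cluster, method = "kmeans")
  p$meta$centers <- km$centers
  p$meta$inertia <- km$tot.withinss
  p
}

.cluster_kmedoids <- function(x, k) {
  ndistinct <- nrow(unique(x))
  .check(k <= ndistinct,
         "k = %d exceeds the number of distinct points (%d); clustering is degenerate",
         k, ndistinct)
  pm <- cluster::pam(x, k = k, metric = "euclidean", pamonce = 5,
                     keep.diss = FALSE, keep.data = FALSE)
  p <- partitioning(pm$clustering, method = "kmedoids")
  p$meta$medoid_ids <- as.integer(pm$id.med)
  p
}

# ---- cell-based -------------------------------------------------------------

# grid arity: smallest b with b^d >= k_nominal
.grid_arity <- function(k_nominal, d) {
  b <- max(1L, as.integer(ceiling(k_nominal^(1 / d) - 1e-9)))
  while (b^d < k_nominal) b <- b + 1L
  b
}

.bin_space <- function(x, k_nominal, dims = NULL, optimal = FALSE) {
  m <- ncol(x)
  d <- if (is.null(dims)) min(m, 5L) else min(as.integer(dims), m)
  .check(d >= 1L, "binning needs at least one dimension")
  b <- .grid_arity(k_nominal, d)
  cell <- rep(1L, nrow(x))
  mult <- 1L
  edges <- vector("list", d)
  for (j in seq_len(d)) {
    xj <- x[, j]
    if (b == 1L || length(unique(xj)) == 1L) {
      idx <- rep(1L, length(xj))
      edges[[j]] <- range(xj)
    } else {
      br <- if (optimal) .optimal_breaks_1d(xj, b)
            else seq(min(xj), max(xj), length.out = b + 1L)
      idx <- findInterval(xj, br, rightmost.closed = TRUE, all.inside = TRUE)
      edges[[j]] <- br
    }
    cell <- cell + (idx - 1L) * mult
    mult <- mult * b
  }
  p <- partitioning(cell, method = if (optimal) "ov_binning" else "binning",
                    k_nominal = k_nominal)
  p$meta$grid <- list(dims = d, bins_per_axis = b, edges = edges)
  p
}

# 1-D optimal-variance breakpoints: place b-1 interior edges minimizing the
# total within-bin sum of squares, by dynamic programming over contiguous
# segments (Fisher/Jenks style). Large inputs are compressed into <= 800
# weighted quantile groups before the DP; edges fall midway between
# adjacent group extremes.
.optimal_breaks_1d <- function(x, b, max_groups = 800L) {
  xs <- sort(x)
  n <- length(xs)
  ux <- unique(xs)
  if (length(ux) <= b) {
    # one bin per distinct value; pad with the outer range
    mids <- (utils::head(ux, -1) + utils::tail(ux, -1)) / 2
    return(c(ux[1], mids, ux[length(ux)]))
  }
  M <- min(n, max_groups)
  grp <- ceiling(seq_len(n) * M / n)
  w  <- as.numeric(tabulate(grp, nbins = M))
  s  <- as.numeric(tapply(xs, grp, sum))
  ss <- as.numeric(tapply(xs^2, grp, sum))
  gmin <- as.numeric(tapply(xs, grp, min))
  gmax <- as.numeric(tapply(xs, grp, max))
  cw <- cumsum(w); cs <- cumsum(s); css <- cumsum(ss)
  pad <- function(v) c(0, v)
  CW <- pad(cw); CS <- pad(cs); CSS <- pad(css)
  # cost(i, j): within-SS of groups i..j
  cost <- matrix(Inf, M, M)
  for (i in seq_len(M)) {
    j <- i:M
    Wij <- CW[j + 1L] - CW[i]
    Sij <- CS[j + 1L] - CS[i]
    cost[i, j] <- (CSS[j + 1L] - CSS[i]) - Sij^2 / Wij
  }
  D <- cost[1L, ]                    # best cost of 1 segment ending at j
  B <- matrix(0L, b, M)              # backtracking: last segment start
  B[1L, ] <- 1L
  for (kk in 2L:b) {
    Dn <- rep(Inf, M)
    for (j in kk:M) {
      i <- (kk - 1L):(j - 1L)        # boundary after group i
      v <- D[i] + cost[i + 1L, j]
      best <- which.min(v)
      Dn[j] <- v[best]
      B[kk, j] <- i[best] + 1L       # start of last segment
    }
    D <- Dn
  }
  # backtrack segment starts
  starts <- integer(b)
  j <- M
  for (kk in b:1L) {
    starts[kk] <- B[kk, j]
    j <- starts[kk] - 1L
  }
  interior <- (gmax[starts[-1L] - 1L] + gmin[starts[-1L]]) / 2
  c(gmin[1L], interior, gmax[M])
}

# ---- diagnostics ------------------------------------------------------------

#' Population-distribution diagnostics of a partitioning
#'
#' Mean and standard deviation of the per-partition populations and the
#' singleton percentage (share of partitions holding exactly one compound).
#' A balanced partitioning has small `sd` and few singletons; single,
#' median and centroid linkages typically concentrate most compounds in one
#' hyper-populated cluster and many singletons.
#'
#' @param part a `chem_partition`.
#' @return object of class `population_stats`: `mean` (= N/K), `sd`,
#'   `singleton_pct`, `K`, `N`.
#' @export
population_stats <- function(part) {
  .check(inherits(part, "chem_partition"), "part must be a chem_partition")
  pop <- part$populations
  structure(list(mean = part$N / part$K,
                 sd = if (length(pop) > 1L) stats::sd(pop) else 0,
                 singleton_pct = 100 * sum(pop == 1L) / part$K,
                 K = part$K, N = part$N),
            class = "population_stats")
}

#' @export
print.population_stats <- function(x, ...) {
  cat(sprintf("  population/partition: %d +/- %d   (%%singletons = %.1f, K = %d, N = %d)\n",
              as.integer(round_pct(x$mean, 0)), as.integer(round_pct(x$sd, 0)),
              round_pct(x$singleton_pct), x$K, x$N))
  invisible(x)
}

# ---- silhouette scan --------------------------------------------------------

#' Scan cluster counts by average silhouette
#'
#' Runs k-means for each candidate `k` and returns the average silhouette
#' width per `k` together with the argmax. The full curve is returned
#' because on combinatorial libraries the criterion often degenerates into
#' a concave curve with large values at extreme `k` (near-singleton
#' clusterings score highly), in which case no interior optimum exists and
#' a rule-of-thumb count ([default_k()]) should be used instead.
#'
#' @param space `chem_space` or score matrix.
#' @param k_values candidate cluster counts, each in `2..N-1`.
#' @param seed RNG seed for the k-means restarts.
#' @param nstart k-means restarts per `k`.
#' @return a `silhouette_scan`: data.frame with columns `k`, `silhouette`
#'   (`NA` where clustering was degenerate), and attribute `best_k`.
#' @export
silhouette_scan <- function(space, k_values, seed = NULL, nstart = 10L) {
  x <- .space_scores(space)
  N <- nrow(x)
  k_values <- as.integer(k_values)
  .check(all(k_values >= 2L & k_values <= N - 1L),
         "each k must lie in 2..N-1 (N = %d)", N)
  d <- stats::dist(x)
  scores <- vapply(k_values, function(k) {
    labs <- tryCatch(
      with_seed(if (is.null(seed)) NULL else seed + k,
                stats::kmeans(x, centers = k, nstart = nstart,
                              iter.max = 100L)$cluster),
      error = function(e) NULL)
    if (is.null(labs) || length(unique(labs)) < 2L) return(NA_real_)
    mean(cluster::silhouette(labs, d)[, "sil_width"])
  }, numeric(1))
  res <- data.frame(k = k_values, silhouette = scores)
  attr(res, "best_k") <- if (all(is.na(scores))) NA_integer_
                         else k_values[which.max(scores)]
  class(res) <- c("silhouette_scan", "data.frame")
  res
}

#' @export
print.silhouette_scan <- function(x, ...) {
  cat("Average-silhouette scan (k-means):\n")
  print.data.frame(x)
  cat(sprintf("best k: %s\n", attr(x, "best_k")))
  invisible(x)
}

#' @export
plot.silhouette_scan <- function(x, ...) {
  graphics::plot(x$k, x$silhouette, type = "b", pch = 16,
                 xlab = "k", ylab = "average silhouette width", ...)
  bk <- attr(x, "best_k")
  if (!is.na(bk)) graphics::abline(v = bk, lty = 2, col = "grey40")
  invisible(x)
}
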