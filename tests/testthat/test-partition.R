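test_that("square-root cluster-count rules behave as documented", {
  expect_equal(default_k(4), 2L)
  expect_equal(default_k(5), 3L)               # ceiling, not rounding
  expect_equal(default_k(100, "half"), 5L)
  expect_equal(default_k(100, "ten"), 100L)
  expect_error(default_k(1), ">= 2")
})

test_that("hierarchical clustering matches brute-force agglomeration on toy data", {
  set.seed(21)
  x <- matrix(runif(16), 8, 2)    # continuous: no distance ties
  for (link in c("single", "complete")) {
    for (k in 2:4) {
      p <- partition_space(x, k, paste0("hrc_", link))
      oracle <- naive_hclust(x, link, k)
      expect_equal(comembership(p$labels), comembership(oracle),
                   info = sprintf("%s linkage, k = %d", link, k))
    }
  }
})

test_that("extreme cuts give all-singleton and single-partition limits", {
  x <- matrix(rnorm(24), 12, 2)
  for (m in c("hrc_ward", "hrc_single", "kmeans")) {
    pN <- partition_space(x, 12, m, seed = 1)
    expect_equal(pN$K, 12L)
    expect_equal(population_stats(pN)$singleton_pct, 100)
    p1 <- partition_space(x, 1, m, seed = 1)
    expect_equal(p1$K, 1L)
    expect_equal(population_stats(p1)$sd, 0)
    expect_equal(coverage(p1, 5L)$pc, 100)
  }
})

test_that("relocation clustering separates well-separated blobs and is seed-stable", {
  set.seed(3)
  x <- rbind(matrix(rnorm(40, 0, 0.2), 20, 2),
             matrix(rnorm(40, 8, 0.2), 20, 2))
  truth <- rep(1:2, each = 20)
  for (m in c("kmeans", "kmedoids")) {
    p <- partition_space(x, 2, m, seed = 7)
    expect_equal(comembership(p$labels), comembership(truth), info = m)
  }
  a <- partition_space(x, 5, "kmeans", seed = 42)
  b <- partition_space(x, 5, "kmeans", seed = 42)
  expect_identical(a$labels, b$labels)

  k1 <- partition_space(x, 1, "kmeans")
  expect_equal(unname(k1$meta$centers[1, ]), unname(colMeans(x)))
  dup <- matrix(rep(c(1, 2), each = 6), 6, 2)
  expect_error(partition_space(dup, 4, "kmeans"), "distinct")
  expect_error(partition_space(dup, 4, "kmedoids"), "distinct")
})

test_that("equal-width binning assigns cells by interval arithmetic", {
  # uniform 1-D: 4 similar-count occupied bins
  x1 <- matrix(seq(0, 1, length.out = 40), ncol = 1)
  p <- partition_space(x1, 4, "binning")
  expect_equal(p$K, 4L)
  expect_true(all(p$populations == 10L))

  # all points identical: one occupied cell
  expect_equal(partition_space(matrix(1, 10, 3), 4, "binning")$K, 1L)

  # 20 planar points on a 3x3 grid vs hand-computed cell indices
  set.seed(13)
  x2 <- matrix(runif(40), 20, 2)
  p2 <- partition_space(x2, 9, "binning")
  manual_axis <- function(v) findInterval(v, seq(min(v), max(v), length.out = 4),
                                          rightmost.closed = TRUE, all.inside = TRUE)
  manual <- manual_axis(x2[, 1]) + 3 * (manual_axis(x2[, 2]) - 1)
  expect_equal(comembership(p2$labels), comembership(manual))
  # nominal grid may exceed occupied cells
  expect_lte(p2$K, 9L)
  expect_equal(p2$k_nominal, 9L)
})

test_that("optimum-variance binning places edges at the within-variance minimum", {
  # two tight clumps: the single interior edge must fall in the gap
  x <- matrix(c(rnorm(15, 0, 0.05), rnorm(15, 10, 0.05)), ncol = 1)
  p <- partition_space(x, 2, "ov_binning")
  edge <- p$meta$grid$edges[[1]][2]
  expect_gt(edge, 1); expect_lt(edge, 9)
  expect_equal(comembership(p$labels), comembership(rep(1:2, each = 15)))

  # exhaustive oracle on <= 30 points: every possible split position
  set.seed(31)
  y <- sort(runif(24))
  wss <- function(v) if (length(v) <= 1) 0 else sum((v - mean(v))^2)
  splits <- vapply(1:23, function(i) wss(y[1:i]) + wss(y[-(1:i)]), numeric(1))
  best <- which.min(splits)
  p2 <- partition_space(matrix(y, ncol = 1), 2, "ov_binning")
  expect_equal(sum(p2$labels == p2$labels[1]), best)

  # uniform data: optimal edges stay near the equal-width ones
  u <- matrix(seq(0, 1, length.out = 30), ncol = 1)
  p3 <- partition_space(u, 3, "ov_binning")
  spacing <- 1 / 29
  expect_lt(max(abs(p3$meta$grid$edges[[1]][2:3] - c(1 / 3, 2 / 3))), 2 * spacing)
})

test_that("population diagnostics match direct arithmetic", {
  part <- partitioning(rep(1:4, times = c(5, 3, 1, 1)))
  ps <- population_stats(part)
  expect_equal(ps$mean, 2.5)
  expect_equal(ps$sd, stats::sd(c(5, 3, 1, 1)))
  expect_equal(ps$singleton_pct, 50)
  expect_equal(population_stats(partitioning(rep(1:5, each = 3)))$sd, 0)
})

test_that("every method yields an exhaustive partition: populations sum to N", {
  set.seed(17)
  x <- matrix(rnorm(60 * 4), 60, 4)
  methods <- c("hrc_single", "hrc_complete", "hrc_median", "hrc_average",
               "hrc_centroid", "hrc_ward", "kmeans", "kmedoids",
               "binning", "ov_binning")
  for (m in methods) {
    p <- partition_space(x, 8, m, seed = 2)
    expect_equal(sum(p$populations), 60L, info = m)
    expect_equal(sort(unique(p$labels)), seq_len(p$K), info = m)
    expect_true(all(p$populations >= 1L), info = m)
  }
})

test_that("silhouette scan finds blob structure and flags degenerate cases", {
  set.seed(23)
  x <- rbind(matrix(rnorm(60, 0, 0.3), 30, 2),
             matrix(rnorm(60, 6, 0.3), 30, 2))
  scan <- silhouette_scan(x, 2:5, seed = 1)
  expect_equal(attr(scan, "best_k"), 2L)
  expect_true(all(scan$silhouette >= -1 & scan$silhouette <= 1, na.rm = TRUE))

  # fine-grained pathology: on data made of many tight clumps the score
  # keeps climbing towards near-degenerate clusterings, which is why the
  # full curve (not only the argmax) must be inspected
  set.seed(2)
  ctr <- matrix(runif(10, -20, 20), 5, 2)
  y <- ctr[rep(1:5, each = 2), ] + matrix(rnorm(20, 0, 0.01), 10, 2)
  hi <- silhouette_scan(y, c(2L, 5L), seed = 1)
  expect_gt(hi$silhouette[hi$k == 5], 0.9)
  expect_gt(hi$silhouette[hi$k == 5], hi$silhouette[hi$k == 2])

  # duplicate-only data: k-means is degenerate, recorded as missing
  dup <- matrix(1, 8, 2)
  scan_dup <- silhouette_scan(dup, 2L, seed = 1)
  expect_true(is.na(scan_dup$silhouette))
  expect_error(silhouette_scan(x, 1L), "2..N-1")
})

test_that("chaining-prone linkages give more singletons and spread than compact ones", {
  # one dense region plus scattered outliers; compared at equal K
  worse <- c("hrc_single", "hrc_median", "hrc_centroid")
  better <- c("hrc_ward", "hrc_average", "hrc_complete")
  wins_s <- wins_sd <- 0L; total <- 0L
  for (seed in 1:3) {
    set.seed(seed)
    x <- rbind(matrix(rnorm(160, 0, 0.3), 80, 2),
               matrix(runif(40, -50, 50), 20, 2))
    stats_of <- function(m) population_stats(partition_space(x, 15, m))
    sw <- lapply(worse, stats_of)
    sb <- lapply(better, stats_of)
    for (w in sw) for (b in sb) {
      total <- total + 1L
      wins_s <- wins_s + (w$singleton_pct >= b$singleton_pct)
      wins_sd <- wins_sd + (w$sd >= b$sd)
    }
  }
  expect_gte(wins_s / total, 0.9)
  expect_gte(wins_sd / total, 0.9)
})

test_that("k-means labels are invariant to row permutation up to renaming", {
  set.seed(29)
  centers <- matrix(c(0, 0, 0, 8, 0, 0, 0, 8, 0, 0, 0, 8), 4, 3, byrow = TRUE)
  x <- centers[rep(1:4, each = 10), ] + matrix(rnorm(120, 0, 0.4), 40, 3)
  p <- partition_space(x, 4, "kmeans", seed = 5)
  perm <- sample(40)
  p2 <- partition_space(x[perm, ], 4, "kmeans", seed = 5)
  expect_equal(comembership(p2$labels), comembership(p$labels[perm]))
})
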