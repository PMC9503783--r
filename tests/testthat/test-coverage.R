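test_that("coverage counts occupied partitions and their populations", {
  part <- partitioning(rep(1:4, times = c(5, 3, 1, 1)))
  cov <- coverage(part, c(1, 2, 6))     # two picks in partition 1, one in 2
  expect_equal(cov$k_oc, 2L)
  expect_equal(cov$n_oc, 8L)
  expect_equal(cov$sc, 100 * 2 / 4)
  expect_equal(cov$pc, 100 * 8 / 10)

  # invariant to partition relabelling
  shuffled <- partitioning(c(7, 7, 7, 7, 7, 2, 2, 2, 9, 4))
  cov2 <- coverage(shuffled, c(1, 2, 6))
  expect_equal(cov2$sc, cov$sc)
  expect_equal(cov2$pc, cov$pc)

  expect_error(coverage(part, integer(0)), "non-empty")
  expect_error(coverage(part, c(1, 1)), "unique")
  expect_error(coverage(part, 11), "1..10")
})

test_that("rational selection takes one nearest-to-centroid member per partition", {
  set.seed(41)
  x <- matrix(rnorm(30 * 2), 30, 2)
  for (m in c("hrc_ward", "kmeans", "kmedoids", "ov_binning")) {
    part <- partition_space(x, 6, m, seed = 3)
    sel <- rational_select(part, x)
    expect_equal(length(sel$member_ids), part$K, info = m)
    expect_equal(sort(unique(part$labels[sel$member_ids])), 1:part$K, info = m)
    cov <- coverage(part, sel)
    expect_equal(cov$sc, 100, info = m)
    expect_equal(cov$pc, 100, info = m)
  }
  # singleton partition contributes its sole member
  part <- partitioning(c(1, 1, 2))
  sel <- rational_select(part, matrix(c(0, 0, 0, 1, 9, 9), 3, 2, byrow = TRUE))
  expect_true(3L %in% sel$member_ids)
  # nearest-to-centroid, ties to the lowest index
  part2 <- partitioning(c(1, 1, 1))
  sel2 <- rational_select(part2, matrix(c(-1, 0, 1), 3, 1))
  expect_equal(sel2$member_ids, 2L)
  sym <- rational_select(partitioning(c(1, 1)), matrix(c(-1, 1), 2, 1))
  expect_equal(sym$member_ids, 1L)
  # PAM partitionings use the stored medoids
  set.seed(4)
  xk <- matrix(rnorm(20), 10, 2)
  pk <- partition_space(xk, 3, "kmedoids")
  expect_setequal(rational_select(pk, xk)$member_ids, pk$meta$medoid_ids)
})

test_that("coverage is monotone under selection supersets and bounded below by selection share", {
  set.seed(43)
  for (rep in 1:5) {
    labels <- sample.int(8, 60, replace = TRUE)
    part <- partitioning(labels)
    small <- sample.int(60, 10)
    big <- c(small, sample(setdiff(1:60, small), 15))
    cs <- coverage(part, small); cb <- coverage(part, big)
    expect_lte(cs$sc, cb$sc)
    expect_lte(cs$pc, cb$pc)
    expect_gte(cs$pc, 100 * 10 / 60)
    expect_gte(cb$pc, 100 * 25 / 60)
  }
})

test_that("random baseline reproduces exact limits and the exhaustive oracle", {
  part <- partitioning(rep(1:3, times = c(3, 2, 1)))
  # s = N: every partition occupied in every repetition
  full <- random_baseline(part, 6, reps = 50, seed = 1)
  expect_equal(full$mean_sc, 100)
  expect_equal(full$mean_pc, 100)
  # s = 1 on equal partitions: E[SC] = 100/K by symmetry
  eq <- partitioning(rep(1:4, each = 5))
  expect_equal(expected_coverage(eq, 1)$sc, 100 / 4)
  b1 <- random_baseline(eq, 1, reps = 4000, seed = 2)
  expect_lt(abs(b1$mean_sc - 25), 4 * b1$se_sc + 1e-9)

  # {3,2,1}, s = 2: exhaustive enumeration over all C(6,2) samples
  oracle <- exhaustive_coverage(part$labels, 2)
  ex <- expected_coverage(part, 2)
  expect_equal(ex$sc, oracle$sc, tolerance = 1e-12)
  expect_equal(ex$pc, oracle$pc, tolerance = 1e-12)
  mc <- random_baseline(part, 2, reps = 5000, seed = 3)
  expect_lt(abs(mc$mean_sc - oracle$sc), 3 * stats::sd(mc$sc) / sqrt(5000) * 3 + 0.5)
  expect_lt(abs(mc$mean_sc - oracle$sc), 4 * mc$se_sc + 1e-9)
  expect_lt(abs(mc$mean_pc - oracle$pc), 4 * mc$se_pc + 1e-9)

  # reproducibility and range containment
  mc2 <- random_baseline(part, 2, reps = 5000, seed = 3)
  expect_identical(mc$sc, mc2$sc)
  expect_true(mc$mean_sc >= min(mc$sc) && mc$mean_sc <= max(mc$sc))
  expect_error(random_baseline(part, 7), "1..6")
})

test_that("closed-form expectation equals 100 at s = N and handles large counts stably", {
  part <- partitioning(rep(1:5, times = c(1000, 400, 300, 200, 100)))
  ex <- expected_coverage(part, 2000)
  expect_equal(ex$sc, 100)
  expect_equal(ex$pc, 100)
  ex2 <- expected_coverage(part, 10)
  expect_true(ex2$sc > 0 && ex2$sc < 100)
  expect_true(is.finite(ex2$pc))
})

test_that("selection comparison covers declared, random and rational rows consistently", {
  set.seed(47)
  x <- matrix(rnorm(80 * 3), 80, 3)
  declared <- sample.int(80, 12)
  cmp <- compare_selections(x, declared, k = 9,
                            methods = c("hrc_ward", "kmeans"), seed = 5)
  expect_s3_class(cmp, "data.frame")
  expect_equal(nrow(cmp), 6L)
  rational <- cmp[cmp$selection == "rational", ]
  expect_true(all(rational$sc == 100 & rational$pc == 100))

  # a uniformly random declared subset sits inside the baseline's per-rep range
  part <- partition_space(x, 9, "hrc_ward")
  b <- random_baseline(part, 12, reps = 2000, seed = 6)
  dc <- coverage(part, declared)
  expect_gte(dc$sc, min(b$sc)); expect_lte(dc$sc, max(b$sc))

  expect_error(compare_selections(x, c(1, 200), k = 5), "outside")
})

test_that("a superset subset never covers less (BD vs BCL direction)", {
  sc <- generate_scenario(scenario_spec(seed = 19))
  space <- chem_space(sc$descriptors)
  part <- partition_space(space, 23, "hrc_ward")
  bd_cov <- coverage(part, sc$bd)
  bcl_cov <- coverage(part, sc$bcl_rows)
  expect_gte(bcl_cov$sc, bd_cov$sc)
  expect_gte(bcl_cov$pc, bd_cov$pc)
})
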