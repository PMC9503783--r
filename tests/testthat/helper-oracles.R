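# Independent oracles used to derive expected values: these deliberately
# avoid the package's code paths (naive O(n^3) agglomeration, exhaustive
# subset enumeration) and stay feasible only at toy sizes.

# Brute-force agglomerative clustering with set-level linkage definitions.
naive_hclust <- function(x, linkage = c("single", "complete"), k) {
  linkage <- match.arg(linkage)
  d <- as.matrix(stats::dist(x))
  clusters <- as.list(seq_len(nrow(x)))
  setdist <- function(a, b) {
    v <- d[a, b, drop = FALSE]
    if (linkage == "single") min(v) else max(v)
  }
  while (length(clusters) > k) {
    best <- Inf; bi <- bj <- NA_integer_
    for (i in 2:length(clusters)) for (j in seq_len(i - 1L)) {
      dd <- setdist(clusters[[i]], clusters[[j]])
      if (dd < best - 1e-12) { best <- dd; bi <- i; bj <- j }
    }
    clusters[[bj]] <- c(clusters[[bj]], clusters[[bi]])
    clusters[[bi]] <- NULL
  }
  labels <- integer(nrow(x))
  for (c in seq_along(clusters)) labels[clusters[[c]]] <- c
  labels
}

# Co-membership matrix: label-invariant representation of a partition.
comembership <- function(labels) outer(labels, labels, `==`)

# Exact mean SC/PC of uniform without-replacement samples, by enumerating
# every size-s subset.
exhaustive_coverage <- function(labels, s) {
  N <- length(labels)
  u <- sort(unique(labels))
  pop <- tabulate(match(labels, u))
  K <- length(u)
  combs <- utils::combn(N, s)
  sc <- pc <- numeric(ncol(combs))
  for (i in seq_len(ncol(combs))) {
    occ <- unique(match(labels[combs[, i]], u))
    sc[i] <- 100 * length(occ) / K
    pc[i] <- 100 * sum(pop[occ]) / N
  }
  list(sc = mean(sc), pc = mean(pc))
}

# Tiny SMILES libraries reused across tests.
toy_definition <- function() {
  markush_definition("O=C(N([*:2])C)c1ccc([*:1])cc1",
                     list(c("*F", "*Cl"), c("*C", "*CC", "*c1ccccc1")))
}
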