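#' Build a reduced-dimension chemical space by PCA
#'
#' Standardizes the descriptor matrix (z-scores; zero-variance columns are
#' removed first) and projects it onto the smallest number of leading
#' principal components whose cumulative explained variance reaches
#' `variance_target` (default 95%). Component signs are fixed so the
#' largest-magnitude loading of each component is positive, making scores
#' reproducible across platforms.
#'
#' @param desc a `descriptor_matrix` (see [compute_descriptors()]) or a
#'   plain numeric matrix.
#' @param variance_target fraction of total variance to retain, in (0, 1].
#' @return an object of class `chem_space`: `scores` (N x m), `loadings`
#'   (D x m), `explained_variance_ratio` (all components), `m`,
#'   `total_retained`, and the `center`/`scale` vectors needed to project
#'   new compounds.
#' @examples
#' x <- matrix(rnorm(300), 50, 6)
#' sp <- chem_space(descriptor_matrix(x), variance_target = 0.9)
#' sp
#' @seealso [predict.chem_space()], [partition_space()]
#' @export
chem_space <- function(desc, variance_target = 0.95) {
  if (inherits(desc, "descriptor_matrix")) desc <- desc$values
  desc <- as.matrix(desc)
  .check(is.numeric(desc) && !anyNA(desc), "descriptors must be numeric with no missing values")
  .check(nrow(desc) >= 3L, "at least 3 compounds are required to build a chemical space")
  .check(is.numeric(variance_target) && variance_target > 0 && variance_target <= 1,
         "variance_target must lie in (0, 1]")
  if (is.null(colnames(desc))) colnames(desc) <- sprintf("D%03d", seq_len(ncol(desc)))
  if (is.null(rownames(desc))) rownames(desc) <- sprintf("CPD-%06d", seq_len(nrow(desc)))

  sds <- apply(desc, 2L, stats::sd)
  keep <- sds > 0
  dropped <- colnames(desc)[!keep]
  .check(any(keep), "all descriptor columns are constant")
  x <- desc[, keep, drop = FALSE]
  ctr <- colMeans(x)
  scl <- sds[keep]
  z <- sweep(sweep(x, 2L, ctr), 2L, scl, "/")

  pca <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  ev <- pca$sdev^2
  ratio <- ev / sum(ev)
  m <- which(cumsum(ratio) >= variance_target - 1e-12)[1]
  .check(!is.na(m), "could not reach the variance target")

  load <- pca$rotation[, seq_len(m), drop = FALSE]
  scores <- pca$x[, seq_len(m), drop = FALSE]
  # deterministic sign: largest-|loading| entry positive per component
  for (j in seq_len(m)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  colnames(scores) <- colnames(load) <- paste0("PC", seq_len(m))
  structure(list(scores = scores,
                 loadings = load,
                 explained_variance_ratio = ratio,
                 m = m,
                 total_retained = sum(ratio[seq_len(m)]),
                 variance_target = variance_target,
                 center = ctr, scale = scl,
                 dropped_columns = dropped,
                 sdev = pca$sdev),
            class = "chem_space")
}

#' Project new compounds into an existing chemical space
#'
#' Applies the stored centering/scaling and loadings. Projecting a training
#' row reproduces its stored score; projecting the training column means
#' gives the origin.
#'
#' @param object a `chem_space`.
#' @param newdata a `descriptor_matrix` or numeric matrix whose columns
#'   match the descriptors the space was built from (extra columns that
#'   were dropped as constant are ignored).
#' @param ... unused.
#' @return an n x m matrix of principal-component coordinates.
#' @export
predict.chem_space <- function(object, newdata, ...) {
  if (inherits(newdata, "descriptor_matrix")) newdata <- newdata$values
  newdata <- as.matrix(newdata)
  if (is.null(colnames(newdata)) && ncol(newdata) == length(object$center))
    colnames(newdata) <- names(object$center)
  need <- names(object$center)
  .check(all(need %in% colnames(newdata)),
         "newdata lacks descriptor column(s): %s",
         paste(utils::head(setdiff(need, colnames(newdata)), 3L), collapse = ", "))
  x <- newdata[, need, drop = FALSE]
  z <- sweep(sweep(x, 2L, object$center), 2L, object$scale, "/")
  z %*% object$loadings
}

#' @export
print.chem_space <- function(x, ...) {
  cat(sprintf("Chemical space: %d compounds, %d principal component(s) retaining %.1f%% of variance (target %.0f%%)\n",
              nrow(x$scores), x$m, 100 * x$total_retained, 100 * x$variance_target))
  if (length(x$dropped_columns))
    cat(sprintf("  %d constant descriptor column(s) removed\n", length(x$dropped_columns)))
  ev <- utils::head(x$explained_variance_ratio, min(x$m, 8L))
  cat("  explained variance ratio:", paste(sprintf("%.3f", ev), collapse = " "),
      if (x$m > 8L) "..." else "", "\n")
  invisible(x)
}

# scores matrix from a chem_space or bare matrix
.space_scores <- function(space) {
  if (inherits(space, "chem_space")) space$scores
  else as.matrix(space)
}
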