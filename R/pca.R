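# PCA over the scenario x product flux distributions and cluster-structure
# diagnostics of the score geometry.

#' Assemble a flux matrix from labelled solutions
#'
#' Stacks optimal flux vectors into a matrix with one row per labelled
#' solution and one column per reaction (union over all solutions, sorted
#' by reaction id; a reaction absent from a solution contributes 0).
#'
#' @param solutions a named list of optimal [FluxSolution-class] objects;
#'   names are the row labels (e.g. `"malate|Ref"`)
#' @return a numeric matrix with unique row labels
#' @examples
#' \donttest{
#' tab <- runScenarioMatrix(buildCoreModel(), keep_solutions = TRUE)
#' fm <- assembleFluxMatrix(attr(tab, "solutions"))
#' dim(fm)
#' }
#' @export
assembleFluxMatrix <- function(solutions) {
  stopifnot(is.list(solutions))
  if (length(solutions) < 2L) {
    stop("need at least two solutions to assemble a flux matrix", call. = FALSE)
  }
  labels <- names(solutions)
  if (is.null(labels) || any(!nzchar(labels))) {
    stop("solutions must be named (row labels)", call. = FALSE)
  }
  if (anyDuplicated(labels)) {
    stop("duplicate solution label: ", labels[duplicated(labels)][1], call. = FALSE)
  }
  ok <- vapply(solutions, function(s) solutionStatus(s) == "optimal", TRUE)
  if (!all(ok)) {
    stop("non-optimal solution(s): ", paste(labels[!ok], collapse = ", "),
      call. = FALSE)
  }
  cols <- sort(unique(unlist(lapply(solutions, function(s) names(fluxes(s))))))
  out <- matrix(0, length(solutions), length(cols),
    dimnames = list(labels, cols))
  for (i in seq_along(solutions)) {
    v <- fluxes(solutions[[i]])
    out[i, names(v)] <- unname(v)
  }
  out
}

#' Principal component analysis of a flux matrix
#'
#' Singular-value decomposition of the (column-centred, optionally
#' unit-variance-scaled) flux matrix. The sign of each component is fixed
#' so that its largest-magnitude loading is positive, making the result
#' deterministic. With scaling requested, zero-variance columns are dropped
#' with a warning.
#'
#' @param matrix a flux matrix from [assembleFluxMatrix()] (>= 2 rows)
#' @param center subtract column means (default `TRUE`)
#' @param scale divide by column standard deviations (default `FALSE`;
#'   fluxes share units, so scaling is optional)
#' @return a list of class `"FluxPca"` with elements `scores` (rows x
#'   components), `loadings` (columns x components),
#'   `explained_variance_ratio` (in [0, 1], non-increasing, summing to at
#'   most 1), `center`, and `scale`
#' @examples
#' m <- matrix(rnorm(24), 6, 4)
#' p <- runFluxPCA(m)
#' p$explained_variance_ratio
#' @export
runFluxPCA <- function(matrix, center = TRUE, scale = FALSE) {
  stopifnot(is.matrix(matrix))
  if (nrow(matrix) < 2L) stop("PCA needs at least two rows", call. = FALSE)
  if (scale) {
    sds <- apply(matrix, 2, stats::sd)
    drop <- sds < 1e-12
    if (any(drop)) {
      warning("dropping ", sum(drop), " zero-variance column(s) before scaling")
      matrix <- matrix[, !drop, drop = FALSE]
    }
  }
  x <- scale(matrix, center = center, scale = scale)
  sv <- svd(x)
  ncomp <- min(nrow(matrix) - 1L, ncol(x))
  scores <- sv$u[, seq_len(ncomp), drop = FALSE] %*%
    diag(sv$d[seq_len(ncomp)], ncomp)
  loadings <- sv$v[, seq_len(ncomp), drop = FALSE]
  # sign convention: largest-magnitude loading of each component positive
  for (k in seq_len(ncomp)) {
    i <- which.max(abs(loadings[, k]))
    if (loadings[i, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  total_var <- sum(apply(x, 2, stats::var))
  evr <- if (total_var > 0) {
    (sv$d[seq_len(ncomp)]^2 / (nrow(x) - 1)) / total_var
  } else rep(0, ncomp)
  dimnames(scores) <- list(rownames(matrix), paste0("PC", seq_len(ncomp)))
  dimnames(loadings) <- list(colnames(x), paste0("PC", seq_len(ncomp)))
  structure(
    list(scores = scores, loadings = loadings,
      explained_variance_ratio = evr, center = center, scale = scale),
    class = "FluxPca")
}

#' @export
print.FluxPca <- function(x, ...) {
  cat("FluxPca:", nrow(x$scores), "observations,", ncol(x$scores), "components\n")
  cat("explained variance ratio:",
    paste(format(round(x$explained_variance_ratio[seq_len(min(4, length(x$explained_variance_ratio)))], 3)),
      collapse = ", "), "...\n")
  invisible(x)
}

#' Distances and cluster structure in PCA score space
#'
#' Euclidean distances between observations in the space of the first `k`
#' principal components, plus a single-linkage clustering cut at the
#' largest merge-height gap, reporting how many well-separated groups the
#' score geometry contains and their memberships.
#'
#' @param result a `"FluxPca"` object from [runFluxPCA()]
#' @param k number of score dimensions (default 2, as plotted)
#' @return a list with `distances` (symmetric matrix), `n_clusters`, and
#'   `clusters` (named integer vector of memberships)
#' @examples
#' m <- rbind(a = c(0, 0), b = c(0.1, 0), c = c(10, 10), d = c(10.1, 10))
#' scenarioDistances(runFluxPCA(m), k = 2)$n_clusters # 2
#' @export
scenarioDistances <- function(result, k = 2) {
  stopifnot(inherits(result, "FluxPca"))
  if (k > ncol(result$scores)) {
    stop("k exceeds the number of components (", ncol(result$scores), ")",
      call. = FALSE)
  }
  sc <- result$scores[, seq_len(k), drop = FALSE]
  d <- dist(sc)
  dm <- as.matrix(d)
  n <- nrow(sc)
  if (n < 3L || max(d) < 1e-9) {
    clusters <- setNames(rep(1L, n), rownames(sc))
    return(list(distances = dm, n_clusters = 1L, clusters = clusters))
  }
  hc <- hclust(d, method = "single")
  h <- hc$height                       # non-decreasing for single linkage
  gaps <- diff(c(0, h))
  cut_at <- which.max(gaps)            # cut just below the largest merge jump
  n_clusters <- n - cut_at + 1L
  clusters <- stats::cutree(hc, k = n_clusters)
  list(distances = dm, n_clusters = n_clusters, clusters = clusters)
}
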