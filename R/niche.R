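#' Principal component (niche) axes of environmental data
#'
#' Eigen-decomposition of the pooled environmental matrix; by default the
#' correlation matrix (variables standardized), optionally the covariance
#' matrix.  Constant columns are dropped with a warning.  Axis signs
#' follow the convention that the largest-magnitude loading of each axis
#' is positive.
#'
#' @param env_matrix numeric matrix or data.frame (points x variables),
#'   no missing values; typically pooled occurrence + background rows.
#' @param standardize use the correlation matrix (default `TRUE`).
#' @return object of class `niche_axes`: list with `loadings` (variables x
#'   axes, orthonormal columns), `variance_explained` (percent per axis),
#'   `center`, `scale`, `variables`.
#' @export
pca_env <- function(env_matrix, standardize = TRUE) {
  env <- as.matrix(env_matrix)
  stopifnot(is.numeric(env), nrow(env) >= 2L, ncol(env) >= 2L)
  if (anyNA(env)) stop("environmental matrix must not contain missing values")
  sds <- apply(env, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant column(s): ",
            paste(colnames(env)[sds == 0], collapse = ", "))
    env <- env[, sds > 0, drop = FALSE]
    if (ncol(env) < 2L) stop("fewer than 2 informative variables remain")
  }
  pca <- stats::prcomp(env, center = TRUE, scale. = standardize)
  load <- pca$rotation
  # sign convention: largest |loading| positive on every axis
  for (a in seq_len(ncol(load))) {
    peak <- which.max(abs(load[, a]))
    if (load[peak, a] < 0) load[, a] <- -load[, a]
  }
  ve <- 100 * pca$sdev^2 / sum(pca$sdev^2)
  structure(list(loadings = load,
                 variance_explained = ve,
                 center = pca$center,
                 scale = if (standardize) pca$scale else NULL,
                 variables = colnames(env)),
            class = "niche_axes")
}

#' Project environmental rows onto niche axes
#'
#' @param axes a [pca_env()] result.
#' @param env_matrix numeric matrix/data.frame with the same variables.
#' @return scores matrix (points x axes).
#' @export
niche_scores <- function(axes, env_matrix) {
  stopifnot(inherits(axes, "niche_axes"))
  env <- as.matrix(env_matrix)[, axes$variables, drop = FALSE]
  env <- sweep(env, 2L, axes$center)
  if (!is.null(axes$scale)) env <- sweep(env, 2L, axes$scale, "/")
  env %*% axes$loadings
}

#' Minimum convex polygon around occurrence points
#'
#' Convex hull of a set of 2-D points (e.g. longitude/latitude), the
#' conventional definition of a lineage's geographic background.
#'
#' @param points numeric matrix/data.frame (n x 2), `n >= 3`, not all
#'   collinear.
#' @return matrix of hull vertices (counter-clockwise, not closed), class
#'   `mcp`.
#' @export
minimum_convex_polygon <- function(points) {
  pts <- as.matrix(points)
  stopifnot(ncol(pts) == 2L, all(is.finite(pts)))
  if (nrow(unique(pts)) < 3L)
    stop("need at least 3 distinct points for a polygon")
  hull <- grDevices::chull(pts)
  verts <- pts[hull, , drop = FALSE]
  # shoelace area; zero means collinear input
  x <- verts[, 1L]; y <- verts[, 2L]
  area <- abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
  if (area <= .Machine$double.eps * max(abs(pts))^2)
    stop("occurrence points are collinear; buffer them before building a polygon")
  colnames(verts) <- c("lon", "lat")
  structure(verts, class = c("mcp", class(verts)))
}

#' Sample uniform random points inside a polygon
#'
#' Bounding-box rejection sampling; used to draw random background points
#' from within a minimum convex polygon.
#'
#' @param polygon vertex matrix (n x 2), e.g. [minimum_convex_polygon()].
#' @param n number of points (default 1000).
#' @param seed optional integer seed.
#' @return n x 2 matrix of points inside the polygon.
#' @export
sample_background <- function(polygon, n = 1000L, seed = NULL) {
  .seed_rng(seed)
  poly <- unclass(as.matrix(polygon))
  stopifnot(ncol(poly) == 2L, nrow(poly) >= 3L, .is_count(n))
  lo <- apply(poly, 2L, min)
  hi <- apply(poly, 2L, max)
  out <- matrix(NA_real_, n, 2L, dimnames = list(NULL, c("lon", "lat")))
  got <- 0L
  while (got < n) {
    m <- max(2L * (n - got), 100L)
    cand <- cbind(runif(m, lo[1L], hi[1L]), runif(m, lo[2L], hi[2L]))
    inside <- mgcv::in.out(rbind(poly, poly[1L, ]), cand)
    cand <- cand[inside, , drop = FALSE]
    take <- min(nrow(cand), n - got)
    if (take > 0L) {
      out[(got + 1L):(got + take), ] <- cand[seq_len(take), , drop = FALSE]
      got <- got + take
    }
  }
  out
}

#' Classify observed niche differences against a background null
#'
#' The decision rule of the background test: on each axis, `divergence`
#' when the observed between-lineage difference exceeds the upper bound of
#' the null interval of background divergence, `conservatism` when it
#' falls below the lower bound, `neither` inside the interval.
#'
#' @param observed numeric vector of observed absolute mean differences.
#' @param lower,upper numeric vectors: null interval bounds.
#' @return character vector of calls.
#' @export
niche_call <- function(observed, lower, upper) {
  stopifnot(length(observed) == length(lower),
            length(observed) == length(upper), all(lower <= upper))
  ifelse(observed > upper, "divergence",
         ifelse(observed < lower, "conservatism", "neither"))
}

#' Background test of niche divergence versus conservatism
#'
#' For each niche axis, compares the observed difference between lineage
#' means (`|mean(occ1) - mean(occ2)|` on axis scores) to a null
#' distribution of background divergence: each jackknife replicate
#' resamples a fraction of each background set (with replacement by
#' default) and records the absolute difference of the background means.
#' The null interval is the middle 95% of replicates and the call follows
#' [niche_call()]: observed above the interval is divergence, below is
#' conservatism (the lineages are more similar than their backgrounds),
#' inside is neither.
#'
#' @param occ1,occ2 occurrence environmental rows for the two lineages
#'   (matrix/data.frame with the axes' variables).
#' @param bg1,bg2 background environmental rows for the two lineages.
#' @param axes a [pca_env()] result; default: PCA of all rows pooled.
#' @param n_axes number of leading axes to test (default 3).
#' @param n_jackknife replicates (default 1000).
#' @param fraction fraction of each background resampled per replicate
#'   (default 0.75).
#' @param replace resample with replacement (default `TRUE`).
#' @param level confidence level of the null interval (default 0.95).
#' @param seed optional integer seed.
#' @return object of class `niche_test_result`: data.frame with one row
#'   per axis (`axis`, `variance_explained`, `observed`, `null_lower`,
#'   `null_upper`, `call`), with the axes object attached as attribute
#'   `"axes"`.
#' @export
niche_divergence_test <- function(occ1, occ2, bg1, bg2, axes = NULL,
                                  n_axes = 3L, n_jackknife = 1000L,
                                  fraction = 0.75, replace = TRUE,
                                  level = 0.95, seed = NULL) {
  .seed_rng(seed)
  stopifnot(nrow(occ1) >= 1L, nrow(occ2) >= 1L)
  if (nrow(bg1) < 2L || nrow(bg2) < 2L) stop("background sets must have >= 2 rows")
  stopifnot(fraction > 0, fraction <= 1, level > 0, level < 1)
  if (is.null(axes))
    axes <- pca_env(rbind(as.matrix(occ1), as.matrix(occ2),
                          as.matrix(bg1), as.matrix(bg2)))
  n_axes <- min(n_axes, ncol(axes$loadings))
  sc_o1 <- niche_scores(axes, occ1)[, seq_len(n_axes), drop = FALSE]
  sc_o2 <- niche_scores(axes, occ2)[, seq_len(n_axes), drop = FALSE]
  sc_b1 <- niche_scores(axes, bg1)[, seq_len(n_axes), drop = FALSE]
  sc_b2 <- niche_scores(axes, bg2)[, seq_len(n_axes), drop = FALSE]
  observed <- abs(colMeans(sc_o1) - colMeans(sc_o2))
  m1 <- max(1L, round(fraction * nrow(sc_b1)))
  m2 <- max(1L, round(fraction * nrow(sc_b2)))
  null_div <- matrix(NA_real_, n_jackknife, n_axes)
  for (r in seq_len(n_jackknife)) {
    i1 <- sample.int(nrow(sc_b1), m1, replace = replace)
    i2 <- sample.int(nrow(sc_b2), m2, replace = replace)
    null_div[r, ] <- abs(colMeans(sc_b1[i1, , drop = FALSE]) -
                           colMeans(sc_b2[i2, , drop = FALSE]))
  }
  alpha <- (1 - level) / 2
  lower <- apply(null_div, 2L, quantile, probs = alpha, names = FALSE)
  upper <- apply(null_div, 2L, quantile, probs = 1 - alpha, names = FALSE)
  res <- data.frame(axis = paste0("PC", seq_len(n_axes)),
                    variance_explained = axes$variance_explained[seq_len(n_axes)],
                    observed = observed,
                    null_lower = lower,
                    null_upper = upper,
                    call = niche_call(observed, lower, upper),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "axes") <- axes
  attr(res, "n_jackknife") <- n_jackknife
  attr(res, "fraction") <- fraction
  class(res) <- c("niche_test_result", "data.frame")
  res
}
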