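#' @title Principal-component analysis of CDR3 length distributions
#' @description Represents each germline segment's averaged CDR3 length
#'   distribution as a 22-vector of percentages over lengths 5-26,
#'   eigendecomposes the across-segment covariance matrix, and projects
#'   segments onto the eigenvectors. The leading components order segments by
#'   the apparent skewness and kurtosis of their distributions; the sign
#'   convention is fixed so that PC1 increases with right (long-length) skew
#'   and PC2 with tail weight.
#' @name pca_distributions
NULL

.pca_lengths <- 5:26

#' Segment-by-length distribution matrix
#'
#' Builds the `n_segments x 22` matrix of cross-donor mean percentages for
#' CDR3 lengths 5-26 from averaged distributions. Lengths outside 5-26 are
#' dropped without renormalizing (rows are percentages of all sequences);
#' absent lengths are 0.
#'
#' @param averaged output of [average_across_donors] (one compartment).
#' @return matrix with segment row names and length column names (5..26).
#' @export
build_matrix <- function(averaged) {
  segs <- unique(averaged$group_key)
  if (length(segs) < 3L) stop("need >= 3 segments for a covariance analysis")
  X <- matrix(0, length(segs), length(.pca_lengths),
              dimnames = list(segs, .pca_lengths))
  keep <- averaged$length %in% .pca_lengths
  X[cbind(match(averaged$group_key[keep], segs),
          match(averaged$length[keep], .pca_lengths))] <- averaged$mean_pct[keep]
  X
}

#' Across-segment covariance of the distribution matrix
#'
#' `S[i, j]` is the covariance, across germline segments, of the percentages
#' at length columns i and j (denominator `n - 1`; eigenvectors and the
#' ordering of scores are invariant to this constant). All-equal rows give
#' the zero matrix with a warning.
#'
#' @param X matrix from [build_matrix].
#' @return symmetric positive semidefinite 22 x 22 matrix.
#' @export
cdr3_covariance <- function(X) {
  if (nrow(X) < 3L) stop("need >= 3 segments")
  S <- stats::cov(X)
  if (all(abs(S) < .Machine$double.eps * 100)) {
    warning("degenerate input: all segment distributions identical")
    S[] <- 0
  }
  S
}

# standardized third / fourth central moment of a percentage row read as a
# probability law over the length grid
.row_moment <- function(X, order) {
  grid <- as.numeric(colnames(X))
  apply(X, 1, function(p) {
    if (sum(p) <= 0) return(0)
    p <- p / sum(p)
    mu <- sum(grid * p)
    s2 <- sum((grid - mu)^2 * p)
    if (s2 <= 0) return(0)
    sum((grid - mu)^order * p) / s2^(order / 2)
  })
}

#' Eigendecomposition and PC scores of segment length distributions
#'
#' Eigendecomposes the covariance matrix and projects the mean-centered rows
#' of `X` onto the eigenvectors (sorted by decreasing eigenvalue).
#' Orientation convention: the PC1 eigenvector sign is chosen so that PC1
#' scores correlate positively with each row's third standardized moment
#' (right-skew high), PC2 with the fourth (heavy tails high); remaining
#' components get a deterministic largest-element-positive sign. Eigenvalue
#' ties within 1e-12 are broken by this same sign rule and noted.
#'
#' @param X matrix from [build_matrix].
#' @param S optional covariance from [cdr3_covariance] (computed if missing).
#' @return object of class `cdr3_pca`: `eigenvalues`, `eigenvectors`
#'   (columns, orthonormal), `scores` (segments x components), `center`,
#'   `orientation` (sign flips applied).
#' @export
pc_scores <- function(X, S = NULL) {
  if (is.null(S)) S <- cdr3_covariance(X)
  e <- eigen(S, symmetric = TRUE)
  vec <- e$vectors
  val <- pmax(e$values, 0)
  if (any(diff(val) > -1e-12 & diff(val) < 0)) {
    message("pc_scores: near-tied eigenvalues; deterministic sign rule applied")
  }
  center <- colMeans(X)
  scores <- sweep(X, 2, center) %*% vec
  skew <- .row_moment(X, 3)
  kurt <- .row_moment(X, 4)
  # default: largest-magnitude eigenvector element positive (deterministic,
  # row-order invariant); PC1/PC2 overridden by the moment convention
  flips <- vapply(seq_len(ncol(vec)), function(k) {
    if (vec[which.max(abs(vec[, k])), k] < 0) -1 else 1
  }, 0)
  orient <- function(k, target) {
    r <- suppressWarnings(stats::cor(scores[, k], target))
    if (is.na(r) || r == 0) flips[k] else sign(r)
  }
  flips[1] <- orient(1, skew)
  if (ncol(vec) >= 2L) flips[2] <- orient(2, kurt)
  vec <- sweep(vec, 2, flips, `*`)
  scores <- sweep(scores, 2, flips, `*`)
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  colnames(vec) <- colnames(scores)
  structure(list(eigenvalues = val, eigenvectors = vec, scores = scores,
                 center = center, orientation = flips),
            class = "cdr3_pca")
}

#' @export
print.cdr3_pca <- function(x, ...) {
  total <- sum(x$eigenvalues)
  cat("CDR3 length-distribution PCA (", nrow(x$scores), " segments)\n", sep = "")
  pv <- if (total > 0) 100 * x$eigenvalues[1:3] / total else rep(0, 3)
  cat(sprintf("  PC1-PC3 variance explained: %.1f%%, %.1f%%, %.1f%%\n",
              pv[1], pv[2], pv[3]))
  invisible(x)
}

#' @export
plot.cdr3_pca <- function(x, components = c(1, 2), ...) {
  s <- x$scores[, components, drop = FALSE]
  plot(s[, 1], s[, 2], xlab = colnames(s)[1], ylab = colnames(s)[2],
       main = "Germline segments in length-distribution PC space", ...)
  graphics::text(s[, 1], s[, 2], rownames(s), pos = 3, cex = 0.7)
  invisible(x)
}

#' Reconstruct the distribution matrix from PC scores
#'
#' Using all components this is exact to machine precision (rotation
#' completeness).
#'
#' @param pca a `cdr3_pca`.
#' @param k number of leading components to use (default all).
#' @return reconstructed matrix, same shape as the input of [pc_scores].
#' @export
pca_reconstruct <- function(pca, k = length(pca$eigenvalues)) {
  approx <- pca$scores[, seq_len(k), drop = FALSE] %*%
    t(pca$eigenvectors[, seq_len(k), drop = FALSE])
  approx <- sweep(approx, 2, pca$center, `+`)
  dimnames(approx) <- list(rownames(pca$scores), names(pca$center))
  approx
}
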