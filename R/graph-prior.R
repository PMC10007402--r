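# Graph prior over combination weights: k-NN adjacency among feature
# dimensions, Gaussian-kernel edge weights, graph Laplacian L = D - V, and the
# prior matrix B = lambda * t(X) %*% L %*% X.

#' Build a k-nearest-neighbour adjacency matrix over feature dimensions
#'
#' Each graph node is one feature dimension, represented by its row of the
#' training matrix (a vector of length N across training samples). An edge is
#' drawn between features i and j when j is among the k nearest neighbours of
#' i (Euclidean distance between rows) *or* vice versa (OR-symmetrization).
#' Edge weights use the Gaussian kernel
#' \eqn{V_{ij} = \exp(-\|x_i - x_j\|^2 / (2\sigma^2))}.
#'
#' @param x numeric matrix, p features x N samples; rows are the graph nodes.
#' @param k number of nearest neighbours, in `[1, p - 1]`.
#' @param bandwidth Gaussian kernel bandwidth sigma, a positive number, or
#'   `"auto"` (default): the median of the k-NN distances that define the
#'   graph. A scale-free default, standard in spectral methods; if all k-NN
#'   distances are zero the bandwidth falls back to 1.
#' @return a symmetric non-negative p x p matrix with zero diagonal.
#' @examples
#' x <- matrix(rnorm(40), nrow = 4)
#' V <- knn_adjacency(x, k = 2)
#' all(V == t(V))
#' @export
knn_adjacency <- function(x, k, bandwidth = "auto") {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("'x' must be finite (no NA/NaN/Inf)")
  p <- nrow(x)
  if (p < 2L) stop("need at least 2 features (rows) to build a graph")
  if (length(k) != 1L || !is.finite(k) || k < 1 || k > p - 1 || k != floor(k))
    stop("'k' must be an integer in [1, p - 1]; got ", k)
  k <- as.integer(k)

  d <- as.matrix(stats::dist(x))          # Euclidean distances between rows
  # k nearest neighbours of each node, self excluded; ties broken by index
  nn <- matrix(FALSE, p, p)
  for (i in seq_len(p)) {
    ord <- order(d[i, -i])                 # among the other p-1 nodes
    idx <- seq_len(p)[-i][ord[seq_len(k)]]
    nn[i, idx] <- TRUE
  }
  edge <- nn | t(nn)                       # OR-symmetrization

  if (identical(bandwidth, "auto")) {
    knn_d <- d[nn]
    sigma <- stats::median(knn_d)
    if (!is.finite(sigma) || sigma <= 0) sigma <- 1
  } else {
    sigma <- bandwidth
    if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
      stop("'bandwidth' must be a positive number or \"auto\"")
  }

  V <- matrix(0, p, p)
  V[edge] <- exp(-d[edge]^2 / (2 * sigma^2))
  diag(V) <- 0
  V
}

#' Graph Laplacian of a weighted adjacency matrix
#'
#' Returns `L = D - V` where `D` is the diagonal degree matrix of row sums
#' of `V`. For symmetric non-negative `V`, `L` is symmetric positive
#' semi-definite with zero row sums.
#'
#' @param V symmetric non-negative adjacency matrix with zero diagonal.
#' @param tol asymmetry tolerance.
#' @return the p x p Laplacian matrix.
#' @export
graph_laplacian <- function(V, tol = 1e-8) {
  V <- as.matrix(V)
  if (!all(is.finite(V))) stop("'V' must be finite")
  if (any(V < 0)) stop("'V' must be non-negative")
  if (max(abs(V - t(V))) > tol) stop("'V' must be symmetric")
  D <- diag(rowSums(V), nrow(V))
  D - V
}

#' Prior matrix over combination weights
#'
#' Computes `B = lambda * t(X) L X`, the quadratic-form matrix that penalizes
#' combinations `w` whose fitted signal `Xw` varies across strongly connected
#' feature nodes. The result is explicitly symmetrized to remove round-off
#' asymmetry.
#'
#' @param x numeric matrix, p x N (the training dictionary).
#' @param L graph Laplacian, p x p.
#' @param lambda non-negative trade-off parameter.
#' @return a symmetric positive semi-definite N x N matrix.
#' @export
prior_matrix <- function(x, L, lambda = 1) {
  x <- as.matrix(x); L <- as.matrix(L)
  if (length(lambda) != 1L || !is.finite(lambda) || lambda < 0)
    stop("'lambda' must be a non-negative number")
  if (nrow(x) != nrow(L) || nrow(L) != ncol(L))
    stop("non-conformable 'x' (", nrow(x), " features) and 'L' (", nrow(L), " x ", ncol(L), ")")
  B <- lambda * crossprod(x, L %*% x)
  (B + t(B)) / 2
}

#' Assemble the full graph prior for a training dictionary
#'
#' Convenience wrapper: builds the k-NN adjacency from the feature rows of
#' `x`, the Laplacian, and the prior matrix `B = lambda t(X) L X`.
#'
#' @inheritParams knn_adjacency
#' @inheritParams prior_matrix
#' @param k neighbour count; default `floor(p / 2)` (floored since p may be
#'   odd), with a floor of 1.
#' @return a list of class `"graph_prior"` with components `V`, `L`,
#'   `degree`, `B`, `lambda`, `k`, `bandwidth` (the resolved sigma).
#' @export
graph_prior <- function(x, lambda = 1, k = NULL, bandwidth = "auto") {
  x <- as.matrix(x)
  p <- nrow(x)
  if (is.null(k)) k <- max(1L, p %/% 2L)
  V <- knn_adjacency(x, k = k, bandwidth = bandwidth)
  L <- graph_laplacian(V)
  structure(
    list(V = V, L = L, degree = rowSums(V), B = prior_matrix(x, L, lambda),
         lambda = lambda, k = as.integer(k),
         bandwidth = if (identical(bandwidth, "auto")) attr_sigma(x, V) else bandwidth),
    class = "graph_prior")
}

# recover the effective sigma for reporting: refit from edge weights/distances
attr_sigma <- function(x, V) {
  d <- as.matrix(stats::dist(x))
  i <- which(V > 0 & V < 1 & upper.tri(V), arr.ind = TRUE)
  if (nrow(i) == 0L) return(1)
  w <- V[i]; dd <- d[i]
  sqrt(stats::median(dd^2 / (-2 * log(w))))
}

#' @export
print.graph_prior <- function(x, ...) {
  cat("Graph prior over combination weights\n")
  cat("  nodes (features):", nrow(x$V), "\n")
  cat("  edges:", sum(x$V > 0) / 2, " (k =", x$k, ", OR-symmetrized)\n")
  cat("  lambda:", x$lambda, "  kernel bandwidth:", format(x$bandwidth, digits = 4), "\n")
  cat("  B:", nrow(x$B), "x", ncol(x$B), "\n")
  invisible(x)
}
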