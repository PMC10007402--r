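# Sparse representation classification: the training samples are the
# dictionary (one column per "brain atom"); a test vector is expressed as a
# sparse linear combination of all atoms and assigned to the class whose
# atoms reconstruct it with the smallest residual.

#' Fit (assemble) a sparse representation classifier
#'
#' A lazy learner: fitting standardizes each feature using the training rows'
#' mean/sd (constant features are centered only), L2-normalizes each
#' dictionary column, and precomputes the graph prior; all solving is
#' deferred to [predict.src_model()].
#'
#' @param x numeric matrix of training feature vectors, p features x N
#'   samples (one column per sample). A samples-in-rows matrix is accepted
#'   via `t(x)` by the caller.
#' @param labels integer class labels of length N with values in `1..C`;
#'   every class must be represented.
#' @param variant `"graph_sbl"` (sparse Bayesian solver under the feature
#'   graph prior) or `"basic_l1"` (L1-penalized least squares baseline).
#' @param lambda graph-prior trade-off (default 1).
#' @param k neighbour count for the feature graph; default `floor(p/2)`.
#' @param bandwidth Gaussian kernel bandwidth for the graph, or `"auto"`.
#' @param rho L1 penalty weight for the `"basic_l1"` variant (default 0.01).
#' @param standardize logical; z-score features before normalization
#'   (default TRUE).
#' @param control an [sbl_control()] list for the Bayesian solver.
#' @return an object of class `"src_model"`.
#' @examples
#' d <- simulate_subspace_data(subspace_spec(p = 10, C = 2, d = 1,
#'                                           n_per_class = 6, seed = 1))
#' m <- src_model(d$x_train, d$labels_train)
#' pr <- predict(m, d$x_test)
#' mean(pr$class == d$labels_test)
#' @export
src_model <- function(x, labels, variant = c("graph_sbl", "basic_l1"),
                      lambda = 1, k = NULL, bandwidth = "auto", rho = 0.01,
                      standardize = TRUE, control = sbl_control()) {
  variant <- match.arg(variant)
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("'x' must be finite")
  labels <- as.integer(labels)
  n <- ncol(x); p <- nrow(x)
  if (length(labels) != n) stop("need one label per dictionary column")
  C <- max(labels)
  if (min(labels) < 1L) stop("labels must be positive integers 1..C")
  missing_cls <- setdiff(seq_len(C), unique(labels))
  if (length(missing_cls))
    stop("every class in 1..C needs at least one training column; missing: ",
         paste(missing_cls, collapse = ", "))
  if (rho <= 0) stop("'rho' must be positive")

  if (standardize) {
    mu <- rowMeans(x)
    sd_ <- apply(x, 1L, stats::sd)
    sd_[!is.finite(sd_) | sd_ == 0] <- 1   # constant feature: center only
  } else {
    mu <- rep(0, p); sd_ <- rep(1, p)
  }
  xs <- (x - mu) / sd_

  norms <- sqrt(colSums(xs^2))
  if (any(norms == 0))
    stop("dictionary column(s) ", paste(which(norms == 0), collapse = ", "),
         " are all-zero after standardization")
  xn <- sweep(xs, 2L, norms, "/")

  prior <- graph_prior(xn, lambda = lambda, k = k, bandwidth = bandwidth)

  structure(list(dictionary = xn, labels = labels, n_classes = C,
                 feature_mean = mu, feature_sd = sd_, column_norms = norms,
                 prior = prior, variant = variant, rho = rho,
                 standardize = standardize, control = control),
            class = "src_model")
}

#' Select the coefficients belonging to one class
#'
#' Returns a copy of the weight vector with every entry whose dictionary
#' column is not labeled `class` set to zero (the delta_c selector of the
#' SRC decision rule).
#'
#' @param w numeric weight vector, length N.
#' @param labels integer labels, length N.
#' @param class a class index in `1..max(labels)`.
#' @return numeric vector of length N.
#' @export
select_class_coefficients <- function(w, labels, class) {
  if (length(class) != 1L || !is.finite(class) || class < 1 ||
      class > max(labels) || class != floor(class))
    stop("'class' must be a single class index in 1..", max(labels))
  out <- w
  out[labels != class] <- 0
  out
}

#' L1-penalized least-squares weights by iterative soft thresholding
#'
#' Minimizes `||y - X w||_2^2 + rho * ||w||_1` by proximal gradient descent
#' (ISTA) from `w = 0`, with a fixed step of `1 / (2 * largest eigenvalue of
#' X'X)`, until the relative objective change drops below `tol` or `max_iter`
#' iterations. Deterministic.
#'
#' @param y response vector, length p.
#' @param x dictionary, p x N.
#' @param rho positive L1 weight.
#' @param tol relative objective-change tolerance.
#' @param max_iter iteration cap.
#' @return numeric weight vector of length N.
#' @export
l1_solve <- function(y, x, rho = 0.01, tol = 1e-8, max_iter = 5000L) {
  x <- as.matrix(x)
  n <- ncol(x)
  if (length(y) != nrow(x)) stop("length(y) must equal nrow(x)")
  if (rho <= 0) stop("'rho' must be positive")
  G <- crossprod(x)
  lip <- 2 * max(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  if (lip <= 0) return(numeric(n))
  step <- 1 / lip
  xty <- crossprod(x, y)
  w <- numeric(n)
  obj <- sum(y^2)
  soft <- function(z, t) sign(z) * pmax(abs(z) - t, 0)
  for (i in seq_len(max_iter)) {
    grad <- 2 * (G %*% w - xty)
    w <- drop(soft(w - step * grad, step * rho))
    r <- y - drop(x %*% w)
    obj_new <- sum(r^2) + rho * sum(abs(w))
    if (abs(obj - obj_new) <= tol * max(obj, 1e-12)) { obj <- obj_new; break }
    obj <- obj_new
  }
  w
}

#' Classify test vectors with a sparse representation model
#'
#' Each test vector is standardized with the stored training parameters and
#' L2-normalized (the same treatment the dictionary columns received), the
#' combination weights are solved (sparse Bayesian under the graph prior, or
#' the L1 baseline), per-class residuals `r_c = ||y - X delta_c(w)||_2` are
#' computed, and the class with the smallest residual wins (ties broken by
#' the lowest class index).
#'
#' @param object an [src_model()] fit.
#' @param newdata numeric matrix p x m (columns are test vectors) or a
#'   single vector of length p.
#' @param ... unused.
#' @return a list of class `"src_prediction"`: `class` (integer vector,
#'   length m), `residuals` (m x C matrix), `weights` (N x m matrix),
#'   `converged` (logical vector).
#' @export
predict.src_model <- function(object, newdata, ...) {
  y <- if (is.matrix(newdata)) newdata else matrix(newdata, ncol = 1L)
  p <- nrow(object$dictionary)
  if (nrow(y) != p)
    stop("test vectors have ", nrow(y), " features; the model expects ", p)
  m <- ncol(y)
  C <- object$n_classes
  X <- object$dictionary
  res <- matrix(NA_real_, m, C,
                dimnames = list(NULL, paste0("class", seq_len(C))))
  W <- matrix(NA_real_, ncol(X), m)
  cls <- integer(m)
  conv <- logical(m)
  for (j in seq_len(m)) {
    ys <- (y[, j] - object$feature_mean) / object$feature_sd
    nrm <- sqrt(sum(ys^2))
    if (nrm > 0) ys <- ys / nrm
    if (object$variant == "graph_sbl") {
      fit <- sbl_fit(ys, X, object$prior$B, control = object$control)
      w <- fit$w_hat; conv[j] <- fit$converged
    } else {
      w <- l1_solve(ys, X, rho = object$rho)
      conv[j] <- TRUE
    }
    for (c in seq_len(C)) {
      wc <- select_class_coefficients(w, object$labels, c)
      res[j, c] <- sqrt(sum((ys - drop(X %*% wc))^2))
    }
    cls[j] <- which.min(res[j, ])   # which.min takes the first (lowest index) on ties
    W[, j] <- w
  }
  structure(list(class = cls, residuals = res, weights = W, converged = conv),
            class = "src_prediction")
}

#' @export
print.src_model <- function(x, ...) {
  cat("Sparse representation classifier (", x$variant, ")\n", sep = "")
  cat("  dictionary:", nrow(x$dictionary), "features x", ncol(x$dictionary), "atoms;",
      x$n_classes, "classes\n")
  tab <- table(factor(x$labels, levels = seq_len(x$n_classes)))
  cat("  atoms per class:", paste(as.integer(tab), collapse = ", "), "\n")
  if (x$variant == "graph_sbl")
    cat("  graph prior: k =", x$prior$k, ", lambda =", x$prior$lambda, "\n")
  else
    cat("  L1 penalty rho =", x$rho, "\n")
  invisible(x)
}

#' @export
summary.src_model <- function(object, ...) {
  print(object)
  if (object$variant == "graph_sbl") print(object$prior)
  invisible(object)
}

#' @export
print.src_prediction <- function(x, ...) {
  cat("SRC predictions for", length(x$class), "test vector(s)\n")
  print(utils::head(data.frame(class = x$class, round(x$residuals, 4)), 10))
  if (length(x$class) > 10) cat("  ...\n")
  invisible(x)
}

#' Write a fitted SRC model to a single JSON archive
#'
#' Serializes the standardization vectors, normalized dictionary, labels,
#' graph matrices, and solver configuration so that classification can run
#' in a separate process. Numbers are stored at full precision.
#'
#' @param model an `src_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_src_model <- function(model, path) {
  stopifnot(inherits(model, "src_model"))
  payload <- list(
    format = "graphsrc-model", format_version = 1L,
    variant = model$variant, n_classes = model$n_classes,
    labels = model$labels, rho = model$rho, standardize = model$standardize,
    feature_mean = model$feature_mean, feature_sd = model$feature_sd,
    column_norms = model$column_norms,
    dictionary = model$dictionary,
    prior = list(V = model$prior$V, L = model$prior$L, B = model$prior$B,
                 degree = model$prior$degree, lambda = model$prior$lambda,
                 k = model$prior$k, bandwidth = model$prior$bandwidth),
    control = unclass(model$control))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read an SRC model archive written by [write_src_model()]
#'
#' @param path archive path.
#' @return an `src_model`.
#' @export
read_src_model <- function(path) {
  pl <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(pl$format, "graphsrc-model"))
    stop("'", path, "' is not a graphsrc model archive")
  ctl <- pl$control
  control <- sbl_control(max_iter = ctl$max_iter, tol = ctl$tol,
                         a_init = ctl$a_init, beta_init = ctl$beta_init,
                         a_max = ctl$a_max, jitter = ctl$jitter,
                         scale_mean_by_beta = ctl$scale_mean_by_beta)
  prior <- structure(list(V = as.matrix(pl$prior$V), L = as.matrix(pl$prior$L),
                          degree = pl$prior$degree, B = as.matrix(pl$prior$B),
                          lambda = pl$prior$lambda, k = as.integer(pl$prior$k),
                          bandwidth = pl$prior$bandwidth),
                     class = "graph_prior")
  structure(list(dictionary = as.matrix(pl$dictionary),
                 labels = as.integer(pl$labels), n_classes = as.integer(pl$n_classes),
                 feature_mean = pl$feature_mean, feature_sd = pl$feature_sd,
                 column_norms = pl$column_norms, prior = prior,
                 variant = pl$variant, rho = pl$rho,
                 standardize = isTRUE(pl$standardize), control = control),
            class = "src_model")
}
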