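#' Fit a pooled-covariance linear discriminant classifier
#'
#' Classic LDA as used in myoelectric pattern recognition: one mean vector
#' per class and a single within-class covariance pooled over all classes,
#' `S = sum_k sum_i (x_i - mu_k)(x_i - mu_k)' / (N - K)`. A small ridge
#' `lambda * I` (default `1e-6 * mean(diag(S))`) keeps the covariance
#' positive definite when features are collinear (e.g. duplicated
#' channels). Class priors default to uniform, matching a protocol with
#' balanced trials per class.
#'
#' @param x Numeric matrix, windows x features, all finite.
#' @param grouping Class label per row (factor or character); every class
#'   present must have at least 2 rows, and at least 2 classes are needed.
#' @param prior Optional prior probabilities (named by class or in the
#'   order of `sort(unique(grouping))`); must be non-negative and sum to 1.
#' @param lambda Optional ridge added to the diagonal of the pooled
#'   covariance.
#' @return An object of class `"pooled_lda"` with elements `classes`,
#'   `means` (K x D), `pooled_cov` (regularized, D x D), `lambda`, `prior`,
#'   and the precomputed discriminant weights `W` (D x K) and intercepts
#'   `b` (length K) such that the score of class k at x is
#'   `x' W[, k] + b[k]`.
#' @examples
#' x <- matrix(c(0, 2, 10, 12), ncol = 1)
#' fit <- fit_lda(x, c("a", "a", "b", "b"), lambda = 0)
#' fit$means
#' fit$pooled_cov
#' @export
fit_lda <- function(x, grouping, prior = NULL, lambda = NULL) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("non-finite feature values")
  g <- as.character(grouping)
  if (length(g) != nrow(x)) stop("grouping length must match rows of x")
  classes <- sort(unique(g))
  K <- length(classes)
  if (K < 2L) stop("need at least 2 classes")
  D <- ncol(x)
  counts <- table(factor(g, classes))
  if (any(counts < 2L)) {
    stop("every class needs at least 2 windows; offending: ",
         paste(classes[counts < 2L], collapse = ", "))
  }
  N <- nrow(x)
  means <- matrix(0, K, D, dimnames = list(classes, colnames(x)))
  scatter <- matrix(0, D, D)
  for (k in seq_len(K)) {
    xi <- x[g == classes[k], , drop = FALSE]
    means[k, ] <- colMeans(xi)
    cen <- sweep(xi, 2L, means[k, ])
    scatter <- scatter + crossprod(cen)
  }
  pooled <- scatter / (N - K)
  if (is.null(lambda)) lambda <- 1e-6 * mean(diag(pooled))
  if (lambda < 0) stop("lambda must be >= 0")
  sigma <- pooled + diag(lambda, D)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) {
    stop("pooled covariance is singular even after regularization ",
         "(lambda = ", format(lambda), ")")
  }
  if (is.null(prior)) {
    prior <- rep(1 / K, K)
    names(prior) <- classes
  } else {
    if (!is.null(names(prior))) prior <- prior[classes]
    if (length(prior) != K || any(!is.finite(prior)) || any(prior < 0) ||
        abs(sum(prior) - 1) > 1e-8) {
      stop("prior must be K non-negative values summing to 1")
    }
    names(prior) <- classes
  }
  # W = Sigma^{-1} mu_k via triangular solves; no explicit inverse
  W <- backsolve(ch, backsolve(ch, t(means), transpose = TRUE))
  b <- -0.5 * colSums(t(means) * W) + log(ifelse(prior > 0, prior, 1e-300))
  structure(list(classes = classes, means = means, pooled_cov = sigma,
                 lambda = lambda, prior = prior, W = W, b = b,
                 n = N, counts = as.integer(counts)),
            class = "pooled_lda")
}

#' Linear discriminant scores
#'
#' Score of class k at feature vector x:
#' `x' S^-1 mu_k - mu_k' S^-1 mu_k / 2 + log(prior_k)`, the log posterior
#' up to a class-independent term.
#'
#' @param model A [fit_lda()] model.
#' @param x Numeric vector of length D, or an n x D matrix.
#' @return An n x K matrix of scores (1 x K for a vector input), columns
#'   named by class.
#' @export
discriminant_scores <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != ncol(model$means)) {
    stop("feature dimension ", ncol(x), " does not match model (",
         ncol(model$means), ")")
  }
  scores <- x %*% model$W
  scores <- sweep(scores, 2L, model$b, "+")
  colnames(scores) <- model$classes
  scores
}

#' Predict task classes from features
#'
#' @param object A [fit_lda()] model.
#' @param newdata n x D feature matrix (or a `"feature_matrix"`).
#' @param type `"class"` for labels, `"scores"` for the full score matrix.
#' @param ... Unused.
#' @return Character vector of predicted classes (ties go to the first
#'   class in `object$classes`, deterministically), or the score matrix.
#' @export
predict.pooled_lda <- function(object, newdata, type = c("class", "scores"),
                               ...) {
  type <- match.arg(type)
  if (inherits(newdata, "feature_matrix")) newdata <- newdata$values
  scores <- discriminant_scores(object, newdata)
  if (type == "scores") return(scores)
  object$classes[max.col(scores, ties.method = "first")]
}

#' @export
print.pooled_lda <- function(x, ...) {
  cat("Pooled-covariance LDA:", length(x$classes), "classes,",
      ncol(x$means), "features,", x$n, "training windows\n")
  cat("classes:", paste(x$classes, collapse = ", "), "\n")
  cat("ridge lambda:", format(x$lambda), "\n")
  invisible(x)
}

#' @export
coef.pooled_lda <- function(object, ...) {
  rbind(`(intercept)` = object$b, object$W)
}

#' @export
summary.pooled_lda <- function(object, ...) {
  cat("Pooled-covariance linear discriminant model\n")
  cat("  classes (windows):",
      paste0(object$classes, " (", object$counts, ")", collapse = ", "), "\n")
  cat("  features:", ncol(object$means), "\n")
  cat("  ridge lambda:", format(object$lambda), "\n")
  cat("  priors:", paste(format(object$prior, digits = 3), collapse = ", "),
      "\n")
  ev <- eigen(object$pooled_cov, symmetric = TRUE, only.values = TRUE)$values
  cat("  pooled covariance condition number:",
      format(max(ev) / min(ev), digits = 4), "\n")
  invisible(object)
}

#' Serialize / restore a fitted LDA model as JSON
#'
#' Flat-text audit format holding classes, means, regularized pooled
#' covariance, ridge and priors.
#'
#' @param model A [fit_lda()] model.
#' @param path File path.
#' @return `write_lda` returns `path` invisibly; `read_lda` returns the
#'   restored `"pooled_lda"` object.
#' @export
write_lda <- function(model, path) {
  obj <- list(classes = model$classes,
              feature_names = colnames(model$means),
              means = unname(model$means),
              pooled_cov = unname(model$pooled_cov),
              lambda = model$lambda,
              prior = unname(model$prior))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_lda
#' @export
read_lda <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  means <- matrix(obj$means, length(obj$classes),
                  dimnames = list(obj$classes, obj$feature_names))
  sigma <- matrix(unlist(obj$pooled_cov), ncol(means), ncol(means))
  ch <- chol(sigma)
  prior <- obj$prior
  names(prior) <- obj$classes
  W <- backsolve(ch, backsolve(ch, t(means), transpose = TRUE))
  b <- -0.5 * colSums(t(means) * W) + log(prior)
  structure(list(classes = obj$classes, means = means, pooled_cov = sigma,
                 lambda = obj$lambda, prior = prior, W = W, b = b,
                 n = NA_integer_, counts = NA_integer_),
            class = "pooled_lda")
}
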