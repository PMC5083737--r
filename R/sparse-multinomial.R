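#' Fit a penalized multinomial regularization path
#'
#' Multinomial logistic regression in the symmetric (reference-free)
#' softmax parameterization, minimizing
#' `-(1/n) log-likelihood + lambda * penalty` with the lasso penalty
#' `sum_jk |beta_jk|` or the group-lasso penalty `sum_j ||beta_j.||_2`
#' (rows grouped across classes, so a feature is selected for all
#' classes jointly). Intercepts are unpenalized. Features are
#' standardized internally (centered, unit population sd); constant
#' features are dropped with a warning and coefficients are returned on
#' the original scale. The path is warm-started from `lambda_max` — the
#' smallest lambda at which all coefficients are exactly zero, obtained
#' analytically from the null-model gradient — down
#' `log10(1/lambda_min_ratio)` decades. The solver is proximal gradient
#' with backtracking, so the objective is non-increasing across
#' iterations.
#'
#' @param X Numeric matrix (n x p), rows = samples. No missing values.
#' @param y Class labels; a factor or character vector with at least
#'   two distinct values among `CP`, `IPMN`, `PC` (arbitrary 3-class
#'   label sets are accepted when not using the canonical names).
#' @param penalty `"lasso"` or `"group_lasso"`.
#' @param lambda Optional decreasing positive lambda sequence; computed
#'   from the data when `NULL`.
#' @param nlambda Path length when `lambda` is `NULL` (default 100).
#' @param lambda_min_ratio Ratio of the smallest to the largest lambda
#'   (default `1e-4`, i.e. 4 decades).
#' @param tol Relative objective-change convergence tolerance
#'   (default `1e-7`).
#' @param kkt_tol Additional stopping requirement: the maximum
#'   Karush-Kuhn-Tucker residual of the iterate (standardized scale)
#'   must fall below this bound (default `5e-6`); see
#'   [kkt_residuals()].
#' @param maxit Maximum proximal-gradient iterations per path point.
#' @param trace Record the per-iteration objective sequence for each
#'   path point (diagnostic; default `FALSE`).
#' @return Object of class `karyo_path`: list with `a0` (K x L
#'   intercepts, original scale), `beta` (p x K x L array, original
#'   scale), `beta_std` (standardized scale), `lambda`, `classes`,
#'   `penalty`, `df` (selected-feature count per path point),
#'   `center`, `scale`, `feature_names`, `objective`, `iterations`,
#'   and `trace` when requested.
#' @export
#' @examples
#' cohort <- gen_feature_cohort(cohort_config(seed = 1))
#' X <- as.matrix(cohort[, feature_names()])
#' fit <- fit_path(X, cohort$class, penalty = "lasso")
#' fit$df[c(1, 50, 100)]
fit_path <- function(X, y, penalty = c("lasso", "group_lasso"),
                     lambda = NULL, nlambda = 100,
                     lambda_min_ratio = 1e-4, tol = 1e-7, kkt_tol = 5e-6,
                     maxit = 5000, trace = FALSE) {
  penalty <- match.arg(penalty)
  X <- as.matrix(X)
  if (!is.numeric(X) || any(!is.finite(X))) stop("X must be finite numeric")
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("degenerate labels: need at least 2 classes")
  if (length(y) != nrow(X)) stop("X and y lengths differ")
  if (nrow(X) < 3) stop("need at least 3 samples")
  classes <- levels(y)
  K <- length(classes)
  n <- nrow(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("x%03d", seq_len(ncol(X)))
  fnames <- colnames(X)

  ctr <- colMeans(X)
  scl <- sqrt(colMeans(sweep(X, 2, ctr)^2))
  const <- scl <= 1e-12
  if (any(const)) {
    warning(sprintf("dropping %d constant feature(s): %s", sum(const),
                    paste(head(fnames[const], 5), collapse = ", ")))
  }
  keep <- which(!const)
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, ctr[keep]), 2, scl[keep], "/")
  Y <- matrix(0, n, K)
  Y[cbind(seq_len(n), as.integer(y))] <- 1

  if (is.null(lambda)) {
    lmax <- lambda_max(Xs, Y, penalty)
    lambda <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                      length.out = nlambda))
  } else {
    lambda <- as.numeric(lambda)
    if (any(diff(lambda) >= 0) || any(lambda < 0))
      stop("lambda must be strictly decreasing and non-negative")
    lambda[lambda == 0] <- 1e-12 * max(lambda[1], 1)
  }

  sol <- multinom_prox_path(Xs, Y, lambda, as.integer(penalty == "group_lasso"),
                            tol, as.integer(maxit), isTRUE(trace), kkt_tol)

  p <- length(fnames)
  L <- length(lambda)
  beta_std <- array(0, c(p, K, L), dimnames = list(fnames, classes, NULL))
  beta_std[keep, , ] <- sol$beta
  beta <- beta_std
  a0 <- sol$b0
  for (l in seq_len(L)) {
    beta[keep, , l] <- sol$beta[, , l] / scl[keep]
    a0[, l] <- sol$b0[, l] - colSums(sol$beta[, , l] * ctr[keep] / scl[keep])
  }
  rownames(a0) <- classes
  df <- apply(beta_std != 0, 3, function(b) sum(rowSums(abs(b)) > 0))

  structure(list(a0 = a0, beta = beta, beta_std = beta_std,
                 a0_std = sol$b0,
                 lambda = lambda, classes = classes, penalty = penalty,
                 df = df, center = ctr, scale = scl,
                 feature_names = fnames,
                 objective = sol$objective, iterations = sol$iterations,
                 trace = if (isTRUE(trace)) sol$trace else NULL),
            class = "karyo_path")
}

# smallest lambda with an all-zero solution, from the null-model gradient
lambda_max <- function(Xs, Y, penalty) {
  n <- nrow(Y)
  freq <- colMeans(Y)
  E <- (matrix(freq, n, length(freq), byrow = TRUE) - Y) / n
  G <- crossprod(Xs, E)
  if (penalty == "lasso") max(abs(G)) else max(sqrt(rowSums(G^2)))
}

#' @export
print.karyo_path <- function(x, ...) {
  cat(sprintf("karyo_path: %s penalty, %d path points, %d features, classes %s\n",
              x$penalty, length(x$lambda), length(x$feature_names),
              paste(x$classes, collapse = "/")))
  invisible(x)
}

#' Class probabilities from a fitted model
#'
#' Softmax of the affine scores of a fitted path (at a chosen lambda),
#' a cross-validated fit (at its selected lambda), or a deserialized
#' model. Rows sum to one.
#'
#' @param m A `karyo_path`, `karyo_cv`, or `karyo_model` object.
#' @param x Numeric vector (one sample) or matrix (samples x features);
#'   feature count must match the model.
#' @param lambda Path point to use for a `karyo_path` (nearest match;
#'   default: the smallest lambda on the path). Ignored for objects
#'   that carry their own selected lambda.
#' @return Matrix (samples x classes) of probabilities with class
#'   column names.
#' @export
predict_proba <- function(m, x, lambda = NULL) {
  if (inherits(m, "karyo_cv")) {
    return(predict_proba(m$fit, x, lambda = m$lambda_selected))
  }
  if (inherits(m, "karyo_model")) {
    a0 <- m$a0; beta <- m$beta; classes <- m$classes
  } else if (inherits(m, "karyo_path")) {
    l <- if (is.null(lambda)) length(m$lambda) else
      which.min(abs(m$lambda - lambda))
    a0 <- m$a0[, l]; beta <- m$beta[, , l, drop = TRUE]
    if (is.null(dim(beta))) beta <- matrix(beta, ncol = length(m$classes))
    classes <- m$classes
  } else stop("unsupported model object")
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != nrow(beta))
    stop(sprintf("feature dimension mismatch: model has %d, input has %d",
                 nrow(beta), ncol(x)))
  S <- sweep(x %*% beta, 2, -a0)
  S <- S - apply(S, 1, max)
  P <- exp(S)
  P <- P / rowSums(P)
  colnames(P) <- classes
  P
}

#' Features with nonzero coefficients
#'
#' @param m A `karyo_path` or `karyo_cv` object.
#' @param lambda Path point (nearest match); defaults to the selected
#'   lambda for `karyo_cv`, the last path point otherwise.
#' @return Character vector of selected feature names.
#' @export
selected_features <- function(m, lambda = NULL) {
  if (inherits(m, "karyo_cv")) {
    if (is.null(lambda)) lambda <- m$lambda_selected
    m <- m$fit
  }
  stopifnot(inherits(m, "karyo_path"))
  l <- if (is.null(lambda)) length(m$lambda) else
    which.min(abs(m$lambda - lambda))
  b <- m$beta_std[, , l, drop = TRUE]
  if (is.null(dim(b))) b <- matrix(b, ncol = length(m$classes))
  m$feature_names[rowSums(abs(b)) > 0]
}

#' Cross-validated selection of the regularization parameter
#'
#' Stratified K-fold cross-validation over the regularization path fit
#' on the full data. The criterion is either the mean held-out
#' multinomial deviance (`-2 * mean log p(true class)`) or the mean
#' held-out misclassification rate, both minimized; exact ties are
#' broken toward the larger lambda (the sparser model). If a training
#' fold ever loses a class entirely the folds are redrawn with a new
#' derived seed, up to 10 times.
#'
#' @inheritParams fit_path
#' @param criterion `"deviance"` or `"accuracy"`.
#' @param folds Number of folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @param ... Passed on to [fit_path()].
#' @return Object of class `karyo_cv`: list with `lambda`, `cvm`
#'   (mean criterion per path point), `cvsd`, `lambda_selected`,
#'   `criterion`, `penalty`, `fit` (the full-data `karyo_path`),
#'   `fold_id`, `seed`.
#' @export
cv_select_lambda <- function(X, y, penalty = c("lasso", "group_lasso"),
                             criterion = c("deviance", "accuracy"),
                             folds = 5, seed = 1L, ...) {
  penalty <- match.arg(penalty)
  criterion <- match.arg(criterion)
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  n <- nrow(X)
  if (folds < 2) stop("folds must be >= 2")
  if (n < folds) stop("need at least as many samples as folds")

  full <- fit_path(X, y, penalty = penalty, ...)
  lambda <- full$lambda

  fold_id <- NULL
  for (try in 0:10) {
    if (try == 10) stop("could not build folds covering all classes")
    fold_id <- stratified_folds(y, folds, seed + try * 1009L)
    ok <- all(vapply(seq_len(folds), function(k)
      nlevels(droplevels(y[fold_id != k])) == nlevels(y), logical(1)))
    if (ok) break
  }

  loss <- matrix(NA_real_, folds, length(lambda))
  for (k in seq_len(folds)) {
    tr <- fold_id != k
    fit_k <- suppressWarnings(
      fit_path(X[tr, , drop = FALSE], y[tr], penalty = penalty,
               lambda = lambda, ...))
    Xte <- X[!tr, , drop = FALSE]
    yte <- y[!tr]
    for (l in seq_along(lambda)) {
      P <- predict_proba(fit_k, Xte, lambda = lambda[l])
      # held-out fold may lack some training classes in fit_k's level set
      pt <- P[cbind(seq_len(nrow(P)), match(as.character(yte), colnames(P)))]
      if (criterion == "deviance") {
        loss[k, l] <- -2 * mean(log(pmax(pt, 1e-15)))
      } else {
        pred <- colnames(P)[max.col(P, ties.method = "first")]
        loss[k, l] <- mean(pred != as.character(yte))
      }
    }
  }
  cvm <- colMeans(loss)
  cvsd <- apply(loss, 2, sd) / sqrt(folds)
  sel <- which(cvm == min(cvm))[1]   # first index = largest lambda
  structure(list(lambda = lambda, cvm = cvm, cvsd = cvsd,
                 lambda_selected = lambda[sel], criterion = criterion,
                 penalty = penalty, fit = full, fold_id = fold_id,
                 seed = as.integer(seed)),
            class = "karyo_cv")
}

#' @export
print.karyo_cv <- function(x, ...) {
  cat(sprintf("karyo_cv: %s penalty, %s criterion, lambda_selected = %.5g (%d features)\n",
              x$penalty, x$criterion, x$lambda_selected,
              length(selected_features(x))))
  invisible(x)
}

# stratified fold assignment: shuffles within class, deals round-robin
stratified_folds <- function(y, k, seed) {
  withr::with_seed(seed, {
    id <- integer(length(y))
    for (cl in levels(y)) {
      i <- which(y == cl)
      id[i] <- sample(rep_len(sample.int(k), length(i)))
    }
    id
  })
}

#' Multinomial deviance of a model on data
#'
#' `-2 * mean(log p(true class))`, the held-out criterion used by
#' cross-validation, evaluated on an arbitrary data set.
#'
#' @param m Model accepted by [predict_proba()].
#' @param X Feature matrix.
#' @param y True labels.
#' @param lambda Optional path point.
#' @return Single numeric deviance value.
#' @export
multinomial_deviance <- function(m, X, y, lambda = NULL) {
  P <- predict_proba(m, X, lambda = lambda)
  pt <- P[cbind(seq_len(nrow(P)), match(as.character(y), colnames(P)))]
  -2 * mean(log(pmax(pt, 1e-15)))
}

#' Karush-Kuhn-Tucker residuals along a fitted path
#'
#' Optimality diagnostic on the standardized scale. For the lasso the
#' residual of a coefficient is `|g| - lambda` (positive part) at zero
#' coefficients and `|g + lambda * sign(beta)|` at nonzero ones, with
#' `g` the smooth-loss gradient; for the group lasso the analogous
#' row-norm conditions apply. The intercept gradient is included. At an
#' exact optimum all residuals vanish.
#'
#' @param m A `karyo_path` fit.
#' @param X,y The data the path was fit on.
#' @return Numeric vector: maximum KKT residual at each path point.
#' @export
kkt_residuals <- function(m, X, y) {
  stopifnot(inherits(m, "karyo_path"))
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  n <- nrow(X)
  keep <- which(m$scale > 1e-12)
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, m$center[keep]),
              2, m$scale[keep], "/")
  Y <- matrix(0, n, length(m$classes))
  Y[cbind(seq_len(n), as.integer(y))] <- 1
  out <- numeric(length(m$lambda))
  for (l in seq_along(m$lambda)) {
    B <- m$beta_std[keep, , l, drop = FALSE]
    dim(B) <- dim(B)[1:2]
    S <- Xs %*% B
    S <- sweep(S, 2, -m$a0_std[, l])
    S <- S - apply(S, 1, max)
    P <- exp(S); P <- P / rowSums(P)
    E <- (P - Y) / n
    G <- crossprod(Xs, E)
    lam <- m$lambda[l]
    if (m$penalty == "lasso") {
      r_zero <- pmax(abs(G[B == 0]) - lam, 0)
      r_nz <- abs(G[B != 0] + lam * sign(B[B != 0]))
      res <- max(c(0, r_zero, r_nz))
    } else {
      rn <- sqrt(rowSums(G^2))
      bn <- sqrt(rowSums(B^2))
      r_zero <- pmax(rn[bn == 0] - lam, 0)
      nz <- which(bn > 0)
      r_nz <- if (length(nz)) vapply(nz, function(j)
        sqrt(sum((G[j, ] + lam * B[j, ] / bn[j])^2)), numeric(1)) else numeric(0)
      res <- max(c(0, r_zero, r_nz))
    }
    out[l] <- max(res, max(abs(colSums(E))))
  }
  out
}
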