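#' @importFrom stats quantile sd var median cor
NULL

# Standardize columns to mean 0 and 1/n-variance 1; zero-variance columns
# are dropped (their coefficient is identically 0 at any penalty).
.standardize <- function(X) {
  center <- colMeans(X)
  Xc <- sweep(X, 2L, center)
  scale <- sqrt(colMeans(Xc^2))
  keep <- scale > 0
  Xs <- sweep(Xc[, keep, drop = FALSE], 2L, scale[keep], "/")
  list(Xs = Xs, center = center, scale = scale, keep = keep)
}

.lambda_max <- function(Xs, yc, alpha) {
  a <- max(alpha, 1e-3)  # alpha = 0 would put lambda_max at infinity
  max(abs(drop(crossprod(Xs, yc)))) / (nrow(Xs) * a)
}

#' Fit an elastic-net path
#'
#' Minimizes, for each penalty on a decreasing log-spaced path,
#' \deqn{\frac{1}{2n}\sum_i (y_i - \beta_0 - x_i^\top\beta)^2 +
#'   \lambda\left(\alpha\|\beta\|_1 +
#'   \frac{1-\alpha}{2}\|\beta\|_2^2\right)}
#' by cyclic coordinate descent with warm starts. Features are standardized
#' internally (mean 0, 1/n-variance 1) and coefficients are returned on the
#' original scale. The path starts at
#' \eqn{\lambda_{max} = \max_j |\tilde x_j^\top (y-\bar y)| / (n\alpha)},
#' the smallest penalty with an all-zero solution, and descends to
#' `lambda_max * lambda_min_ratio`. Convergence is declared per lambda only
#' once the KKT subgradient violation (standardized scale) is below
#' `kkt_tol`.
#'
#' @param X Samples x features numeric matrix.
#' @param y Numeric response.
#' @param alpha Elastic-net mixing parameter in \[0, 1\] (1 = lasso).
#' @param lambda Optional user path (decreasing); otherwise computed.
#' @param n_lambda,lambda_min_ratio Path length and depth.
#' @param kkt_tol Convergence tolerance on the KKT violation.
#' @param maxit Maximum coordinate sweeps per lambda.
#' @param fdev,devmax Path early-stopping controls: stop once in-sample
#'   R^2 exceeds `devmax` or improves by less than `fdev * R^2` between
#'   consecutive lambdas (the saturated tail of the path carries no
#'   information and dominates compute). Set `fdev = 0, devmax = 1` to
#'   force the full path.
#' @param truncate Drop the lambdas beyond the early stop (default);
#'   `FALSE` pads them with the last computed solution (used by
#'   cross-validation so every fold covers the master path).
#' @return List: `lambda`, `a0` (intercepts), `beta` (features x lambdas,
#'   original scale), `nonzero`, `kkt_violation`, `lambda_max`.
#' @seealso [fitElasticNetCV()], [kktViolation()]
#' @export
enetPath <- function(X, y, alpha = 0.5, lambda = NULL, n_lambda = 100,
                     lambda_min_ratio = 1e-3, kkt_tol = 1e-7,
                     maxit = 10000L, fdev = 1e-5, devmax = 0.999,
                     truncate = TRUE) {
  stopifnot(is.matrix(X), nrow(X) == length(y), alpha >= 0, alpha <= 1)
  n <- nrow(X); p <- ncol(X)
  ybar <- mean(y)
  yc <- y - ybar
  std <- .standardize(X)
  if (ncol(std$Xs) == 0L || var(y) == 0) {
    lam <- if (is.null(lambda)) c(1, 1e-3) else lambda
    return(list(lambda = lam, a0 = rep(ybar, length(lam)),
                beta = matrix(0, p, length(lam),
                              dimnames = list(colnames(X), NULL)),
                nonzero = rep(0L, length(lam)),
                kkt_violation = rep(0, length(lam)), lambda_max = NA_real_))
  }
  lmax <- .lambda_max(std$Xs, yc, alpha)
  if (is.null(lambda))
    lambda <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                      length.out = n_lambda))
  fit <- .cd_enet_path(std$Xs, yc, lambda, alpha, kkt_tol, as.integer(maxit),
                       fdev, devmax)
  sel <- if (truncate) seq_len(fit$n_used) else seq_along(lambda)
  beta <- matrix(0, p, length(sel), dimnames = list(colnames(X), NULL))
  beta[std$keep, ] <- fit$beta[, sel, drop = FALSE] / std$scale[std$keep]
  a0 <- ybar - drop(crossprod(beta, std$center))
  list(lambda = lambda[sel], a0 = a0, beta = beta,
       nonzero = colSums(fit$beta[, sel, drop = FALSE] != 0),
       kkt_violation = fit$kkt_violation[sel],
       lambda_max = lmax)
}

#' KKT stationarity violation of an elastic-net solution
#'
#' Independent check (pure R, no shared code with the solver) that a
#' proposed `(intercept, coefficients)` pair satisfies the elastic-net
#' subgradient conditions on the standardized problem: for active features
#' \eqn{\tilde x_j^\top r / n = \lambda(1-\alpha)\tilde\beta_j +
#' \lambda\alpha\,\mathrm{sign}(\tilde\beta_j)} and for inactive ones
#' \eqn{|\tilde x_j^\top r / n| \le \lambda\alpha}. Returns the largest
#' violation over features.
#'
#' @param X,y The training data the solution claims to solve.
#' @param intercept,coefficients Solution on the original scale;
#'   `coefficients` is a full-length or named sparse vector.
#' @param lambda,alpha The penalty the solution claims to minimize.
#' @return Maximum KKT violation (0 = exact stationarity).
#' @export
kktViolation <- function(X, y, intercept, coefficients, lambda, alpha) {
  b <- numeric(ncol(X))
  names(b) <- colnames(X)
  if (!is.null(names(coefficients))) {
    b[names(coefficients)] <- coefficients
  } else {
    stopifnot(length(coefficients) == ncol(X))
    b <- coefficients
  }
  n <- nrow(X)
  center <- colMeans(X)
  scl <- sqrt(colMeans(sweep(X, 2L, center)^2))
  keep <- scl > 0
  r <- y - intercept - drop(X %*% b)
  bt <- (b * scl)[keep]                      # standardized-scale coefficients
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2L, center[keep]), 2L,
              scl[keep], "/")
  g <- drop(crossprod(Xs, r)) / n
  l1 <- lambda * alpha
  l2 <- lambda * (1 - alpha)
  active <- bt != 0
  v <- numeric(length(g))
  v[active] <- abs(g[active] - l2 * bt[active] - l1 * sign(bt[active]))
  v[!active] <- pmax(abs(g[!active]) - l1, 0)
  if (length(v)) max(v) else 0
}

.make_folds <- function(y, n_folds) {
  # stratify on response quintiles to balance folds in age
  n <- length(y)
  breaks <- unique(quantile(y, probs = seq(0, 1, 0.2)))
  bins <- if (length(breaks) > 2)
    cut(y, breaks, include.lowest = TRUE, labels = FALSE)
  else rep(1L, n)
  folds <- integer(n)
  for (b in unique(bins)) {
    idx <- which(bins == b)
    folds[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  folds
}

#' Cross-validated elastic-net fit
#'
#' Fits the full regularization path (see [enetPath()]), estimates
#' out-of-fold mean squared error on the response scale by k-fold
#' cross-validation (folds stratified on response quintiles, assignment
#' keyed to `seed`), and selects the penalty by `selection_rule`:
#' `lambda_min` (CV-error minimizer) or `lambda_1se` (sparsest model within
#' one standard error of the minimum). A constant response short-circuits
#' to an intercept-only model with a warning.
#'
#' @param X Samples x features matrix (fully observed).
#' @param y Numeric response (already on the training scale).
#' @param alpha Elastic-net mixing parameter.
#' @param n_folds Number of CV folds (>= 2; n must be >= n_folds).
#' @param n_lambda,lambda_min_ratio Path parameters.
#' @param selection_rule `"lambda_min"` or `"lambda_1se"`.
#' @param seed Integer seed for fold assignment (optional).
#' @param kkt_tol,maxit Solver controls, as in [enetPath()].
#' @return List: `intercept`, `coefficients` (nonzero, named), `cv`
#'   ([ClockCV-class]), `path`, `kkt_violation` (at the chosen lambda).
#' @export
fitElasticNetCV <- function(X, y, alpha = 0.5, n_folds = 10, n_lambda = 100,
                            lambda_min_ratio = 1e-3,
                            selection_rule = c("lambda_min", "lambda_1se"),
                            seed = NULL, kkt_tol = 1e-7, maxit = 10000L) {
  selection_rule <- match.arg(selection_rule)
  stopifnot(is.matrix(X), nrow(X) == length(y), n_folds >= 2)
  if (nrow(X) < n_folds)
    stop("need at least as many samples as folds")
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (var(y) == 0) {
    warning("constant response: returning an intercept-only model")
    cv <- new("ClockCV", lambdaPath = numeric(), cvMean = numeric(),
              cvSE = numeric(), chosenLambda = NA_real_,
              selectionRule = selection_rule,
              foldAssignments = integer(length(y)), nonzero = integer())
    return(list(intercept = y[[1L]],
                coefficients = stats::setNames(numeric(), character()),
                cv = cv, path = NULL, kkt_violation = 0))
  }
  path <- enetPath(X, y, alpha = alpha, n_lambda = n_lambda,
                   lambda_min_ratio = lambda_min_ratio, kkt_tol = kkt_tol,
                   maxit = maxit)
  folds <- .make_folds(y, n_folds)
  nl <- length(path$lambda)
  fold_mse <- matrix(NA_real_, n_folds, nl)
  for (k in seq_len(n_folds)) {
    hold <- folds == k
    # fold fits only steer lambda selection; a looser tolerance does not
    # move the CV curve but cuts the fit cost substantially
    fit_k <- enetPath(X[!hold, , drop = FALSE], y[!hold], alpha = alpha,
                      lambda = path$lambda, kkt_tol = max(kkt_tol, 1e-5),
                      maxit = maxit, truncate = FALSE)
    pred <- sweep(X[hold, , drop = FALSE] %*% fit_k$beta, 2L, fit_k$a0, "+")
    fold_mse[k, ] <- colMeans((pred - y[hold])^2)
  }
  cvm <- colMeans(fold_mse)
  cvse <- apply(fold_mse, 2L, sd) / sqrt(n_folds)
  i_min <- which.min(cvm)
  i_sel <- if (selection_rule == "lambda_min") i_min
  else min(which(cvm <= cvm[i_min] + cvse[i_min]))  # largest qualifying lambda
  cv <- new("ClockCV", lambdaPath = path$lambda, cvMean = cvm, cvSE = cvse,
            chosenLambda = path$lambda[i_sel], selectionRule = selection_rule,
            foldAssignments = as.integer(folds),
            nonzero = as.integer(path$nonzero))
  b <- path$beta[, i_sel]
  b <- b[b != 0]
  list(intercept = path$a0[i_sel], coefficients = b, cv = cv, path = path,
       kkt_violation = path$kkt_violation[i_sel])
}
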