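# Directed cross-lagged panel networks: node-wise L1-penalized regression
# of every wave-(t+1) node on all wave-t nodes, on fully standardized
# scores. The coordinate-descent solver works on the Gram matrix
# (covariance updates), so fits are cheap even under bootstrap.

#' Lasso by cyclic coordinate descent on standardized data
#'
#' Minimizes \code{(1/2n) ||y - X beta||^2 + lam ||beta||_1} without an
#' intercept; columns of X and y must be centered and scaled. Convergence
#' is declared when the maximum coefficient change in a sweep falls below
#' \code{tol}.
#'
#' @param X standardized n x p predictor matrix.
#' @param y standardized response vector.
#' @param lam penalty, >= 0. \code{lam >= max_j |x_j'y|/n} gives an exact
#'   zero solution; \code{lam = 0} gives ordinary least squares.
#' @param tol convergence tolerance on coefficient change.
#' @param maxit maximum sweeps.
#' @return Named coefficient vector; entries below 1e-8 in magnitude are
#'   stored as exact zeros.
#' @export
lasso_solve <- function(X, y, lam, tol = 1e-7, maxit = 100000L) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  stopifnot(length(y) == n, lam >= 0)
  check_standardized(X, "X"); check_standardized(matrix(y), "y")
  G <- crossprod(X) / n
  cvec <- drop(crossprod(X, y)) / n
  fit <- cd_lasso_gram_cpp(G, cvec, lam, numeric(ncol(X)), tol, maxit)
  if (!fit$converged)
    stop("lasso did not converge after ", fit$iterations, " sweeps", call. = FALSE)
  beta <- fit$beta
  beta[abs(beta) < 1e-8] <- 0
  names(beta) <- colnames(X)
  beta
}

check_standardized <- function(m, name) {
  mu <- colMeans(m)
  s <- apply(m, 2, sd)
  # accept either the n or n-1 SD convention
  nn <- nrow(m)
  ok_sd <- abs(s - 1) < 0.02 | abs(s * sqrt((nn - 1) / nn) - 1) < 0.02
  if (max(abs(mu)) > 1e-6 || !all(ok_sd))
    stop("'", name, "' must be standardized (columns mean 0, SD 1)", call. = FALSE)
  invisible(m)
}

# Deterministic k-fold assignment from a seed.
cv_folds <- function(n, k, seed) {
  with_seed(seed, sample(rep_len(seq_len(k), n)))
}

# Per-response lambda path: glmnet-style, log-spaced from lambda_max.
lasso_lambda_path <- function(cvec, n_lambda = 100L, ratio = 1e-3) {
  lam_max <- max(abs(cvec))
  if (lam_max <= 0) lam_max <- 1e-3
  exp(seq(log(lam_max), log(ratio * lam_max), length.out = n_lambda))
}

# K-fold CV for one response; returns the CV-minimizing lambda.
cv_lasso_lambda <- function(X, y, folds, n_lambda = 100L, ratio = 1e-3,
                            tol = 1e-7, maxit = 10000L) {
  n <- nrow(X)
  lambdas <- lasso_lambda_path(drop(crossprod(X, y)) / n, n_lambda, ratio)
  k <- max(folds)
  mse <- matrix(NA_real_, k, length(lambdas))
  for (f in seq_len(k)) {
    tr <- folds != f
    Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
    G <- crossprod(Xtr) / sum(tr)
    cv <- drop(crossprod(Xtr, ytr)) / sum(tr)
    B <- cd_lasso_path_cpp(G, cv, lambdas, tol, maxit)
    pred <- X[!tr, , drop = FALSE] %*% B
    mse[f, ] <- colMeans((y[!tr] - pred)^2)
  }
  lambdas[which.min(colMeans(mse))]
}

#' Fit a cross-lagged panel network between two waves
#'
#' Z-scores all node columns within each wave, then regresses each
#' wave-\code{to} node on all wave-\code{from} nodes with an L1 penalty.
#' \code{lambda_mode = "fixed"} applies \code{lam} to every response;
#' \code{"cv"} (the default) selects each response's penalty by k-fold
#' cross-validation with a deterministic, seed-derived fold assignment.
#'
#' @param panel a complete \code{panel_dataset}.
#' @param wave_from,wave_to wave labels (predictor wave, response wave).
#' @param lambda_mode "cv" or "fixed".
#' @param lam penalty for fixed mode.
#' @param folds CV folds (default 10).
#' @param seed integer seed for fold assignment.
#' @return A \code{clpn_network}: list with \code{B_hat} (predictor x
#'   response coefficient matrix, diagonal = autoregressive paths),
#'   \code{wave_from}, \code{wave_to}, \code{lambda_mode},
#'   \code{lambda_used} (per response), \code{scheme}.
#' @export
fit_clpn <- function(panel, wave_from, wave_to,
                     lambda_mode = c("cv", "fixed"), lam = NULL,
                     folds = 10L, seed = NULL) {
  stopifnot(inherits(panel, "panel_dataset"))
  lambda_mode <- match.arg(lambda_mode)
  if (lambda_mode == "fixed" && is.null(lam))
    stop("fixed mode requires 'lam'", call. = FALSE)
  Xf <- wave_matrix(panel, wave_from)
  Xt <- wave_matrix(panel, wave_to)
  if (anyNA(Xf) || anyNA(Xt))
    stop("waves contain missing values; apply complete_case_filter() first",
         call. = FALSE)
  n <- nrow(Xf)
  if (n < 30) stop("need at least 30 participants", call. = FALSE)
  Z_from <- scale(Xf); Z_to <- scale(Xt)
  if (anyNA(Z_from) || anyNA(Z_to))
    stop("constant column in one of the waves", call. = FALSE)
  nodes <- colnames(Z_from)
  p <- length(nodes)

  core <- fit_clpn_core(Z_from, Z_to, lambda_mode, lam, folds, seed)
  new_clpn_network(core$B_hat, wave_from, wave_to, lambda_mode,
                   core$lambda_used, panel$scheme)
}

# Node-wise lasso on already-standardized wave matrices; shared by
# fit_clpn() and the bootstrap machinery.
fit_clpn_core <- function(Z_from, Z_to, lambda_mode, lam, folds, seed,
                          n_lambda = 100L, ratio = 1e-3) {
  n <- nrow(Z_from)
  nodes <- colnames(Z_from)
  p <- length(nodes)
  if (lambda_mode == "cv") {
    fold_id <- cv_folds(n, folds, seed)
    fit <- clpn_cv_cpp(Z_from, Z_to, as.integer(fold_id),
                       as.integer(n_lambda), ratio, 1e-7, 100000L, 1e-4)
    B_hat <- fit$B_hat
    B_hat[abs(B_hat) < 1e-8] <- 0
    dimnames(B_hat) <- list(nodes, nodes)
    return(list(B_hat = B_hat,
                lambda_used = setNames(as.numeric(fit$lambda_used), nodes)))
  }
  G <- crossprod(Z_from) / n
  B_hat <- matrix(0, p, p, dimnames = list(nodes, nodes))
  lambda_used <- setNames(numeric(p), nodes)
  for (j in seq_len(p)) {
    y <- Z_to[, j]
    cvec <- drop(crossprod(Z_from, y)) / n
    fit <- cd_lasso_gram_cpp(G, cvec, lam, numeric(p), 1e-7, 100000L)
    if (!fit$converged)
      stop("lasso did not converge for response ", nodes[j], call. = FALSE)
    b <- fit$beta
    b[abs(b) < 1e-8] <- 0
    B_hat[, j] <- b
    lambda_used[j] <- lam
  }
  list(B_hat = B_hat, lambda_used = lambda_used)
}

#' Construct a clpn_network from a coefficient matrix
#'
#' Mainly for synthetic truths and tests; \code{B[i, j]} is the effect of
#' predictor node i on response node j.
#' @param B square coefficient matrix with dimnames.
#' @param wave_from,wave_to wave labels.
#' @param scheme optional node scheme (needed for cross-construct and
#'   bridge centralities).
#' @export
clpn_network <- function(B, wave_from = "T1", wave_to = "T2", scheme = NULL) {
  check_square(B)
  if (is.null(rownames(B)))
    dimnames(B) <- list(paste0("V", seq_len(nrow(B))),
                        paste0("V", seq_len(nrow(B))))
  new_clpn_network(B, wave_from, wave_to, "fixed",
                   setNames(rep(NA_real_, ncol(B)), colnames(B)), scheme)
}

new_clpn_network <- function(B, wave_from, wave_to, lambda_mode, lambda_used,
                             scheme) {
  if (any(!is.finite(B))) stop("B_hat entries must be finite", call. = FALSE)
  structure(list(B_hat = B, wave_from = wave_from, wave_to = wave_to,
                 lambda_mode = lambda_mode, lambda_used = lambda_used,
                 scheme = scheme),
            class = "clpn_network")
}

#' @export
print.clpn_network <- function(x, ...) {
  cat(sprintf("CLPN %s -> %s: %d nodes, %d nonzero cross-lagged edges (%s lambda)\n",
              x$wave_from, x$wave_to, nrow(x$B_hat),
              count_nonzero_cross_lagged(x), x$lambda_mode))
  invisible(x)
}

#' Number of nonzero cross-lagged (off-diagonal) edges
#'
#' Autoregressive paths (the diagonal) are excluded.
#' @param network a \code{clpn_network}.
#' @export
count_nonzero_cross_lagged <- function(network) {
  B <- network$B_hat
  sum(B[row(B) != col(B)] != 0)
}

#' Directed edge list of a CLPN
#'
#' @param network a \code{clpn_network}.
#' @param all include zero-weight pairs?
#' @return data.frame(from_node, to_node, weight, is_autoregressive).
#' @export
clpn_edge_list <- function(network, all = FALSE) {
  B <- network$B_hat
  idx <- which(B != 0 | all, arr.ind = TRUE)
  out <- data.frame(from_node = rownames(B)[idx[, 1]],
                    to_node = colnames(B)[idx[, 2]],
                    weight = B[idx],
                    is_autoregressive = idx[, 1] == idx[, 2],
                    stringsAsFactors = FALSE)
  out <- out[order(out$from_node, out$to_node), ]
  rownames(out) <- NULL
  out
}
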