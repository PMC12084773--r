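# Cross-sectional Gaussian graphical model estimation: correlation input,
# graphical-lasso path, EBIC model selection, partial-correlation output.

#' Correlation matrix of a participants x nodes score matrix
#'
#' @param data numeric matrix or data.frame, participants in rows.
#' @param method "pearson" (default) or "spearman".
#' @return A \code{corr_matrix}: list(values, n, method).
#' @export
compute_correlations <- function(data, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  x <- as.matrix(data)
  if (nrow(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (anyNA(x))
    stop("data contain missing values; apply the complete-case filter first",
         call. = FALSE)
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    nm <- colnames(x) %||% as.character(seq_len(ncol(x)))
    stop("constant column(s): ", paste(nm[sds == 0], collapse = ", "),
         call. = FALSE)
  }
  vals <- cor(x, method = method)
  structure(list(values = vals, n = nrow(x), method = method),
            class = "corr_matrix")
}

as_corr_values <- function(S) {
  if (inherits(S, "corr_matrix")) S$values else check_symmetric(as.matrix(S))
}

#' Default penalty path for the graphical lasso
#'
#' 100 log-spaced values from the largest absolute off-diagonal
#' correlation down to 1/100 of it.
#' @param S correlation matrix (or \code{corr_matrix}).
#' @param n_lambda path length.
#' @param ratio min/max penalty ratio.
#' @export
default_lambda_path <- function(S, n_lambda = 100L, ratio = 0.01) {
  v <- as_corr_values(S)
  lam_max <- max(abs(v[upper.tri(v)]))
  if (lam_max <= 0) lam_max <- 0.1
  exp(seq(log(lam_max), log(ratio * lam_max), length.out = n_lambda))
}

#' Graphical-lasso solution path
#'
#' For each penalty, maximizes \code{log det(Theta) - tr(S Theta) -
#' lambda * sum_offdiag |Theta_ij|} (L1 on off-diagonal entries only) by
#' block coordinate descent with warm starts along the decreasing path.
#'
#' @param S a \code{corr_matrix} or a symmetric correlation/covariance
#'   matrix.
#' @param lambdas decreasing positive penalty values; default
#'   \code{default_lambda_path(S)}.
#' @param tol convergence tolerance on the maximum element change of the
#'   working covariance per sweep.
#' @param maxit maximum outer sweeps per penalty.
#' @return A \code{glasso_path}: list with \code{Theta} (list of precision
#'   estimates), \code{W} (covariance estimates), \code{lambdas},
#'   \code{S}, \code{n} (if known).
#' @export
graphical_lasso_path <- function(S, lambdas = NULL, tol = 1e-6, maxit = 200L) {
  v <- as_corr_values(S)
  n <- if (inherits(S, "corr_matrix")) S$n else NA_integer_
  p <- nrow(v)
  lambdas <- lambdas %||% default_lambda_path(v)
  if (any(lambdas <= 0)) stop("lambdas must be positive", call. = FALSE)
  if (is.unsorted(rev(lambdas))) lambdas <- sort(lambdas, decreasing = TRUE)

  W <- v
  Bmat <- matrix(0, p, p)
  thetas <- vector("list", length(lambdas))
  ws <- vector("list", length(lambdas))
  for (i in seq_along(lambdas)) {
    fit <- glasso_cpp(v, lambdas[i], W, Bmat, tol, maxit, tol * 0.1, 500L)
    if (!fit$converged)
      stop(sprintf("graphical lasso did not converge at lambda=%.4g after %d sweeps",
                   lambdas[i], fit$iterations), call. = FALSE)
    W <- fit$W; Bmat <- fit$B
    Th <- fit$Theta
    dimnames(Th) <- dimnames(v)
    thetas[[i]] <- Th
    ws[[i]] <- fit$W
  }
  structure(list(Theta = thetas, W = ws, lambdas = lambdas, S = v, n = n),
            class = "glasso_path")
}

#' Convert a precision matrix to partial correlations
#'
#' \code{w_ij = -Theta_ij / sqrt(Theta_ii * Theta_jj)}, diagonal forced to
#' zero.
#' @param precision positive-definite precision matrix.
#' @export
precision_to_partial <- function(precision) {
  check_symmetric(precision, tol = 1e-6, name = "precision")
  d <- diag(precision)
  if (any(d <= 0)) stop("precision diagonal must be positive", call. = FALSE)
  s <- 1 / sqrt(d)
  w <- -(s %o% s) * precision
  diag(w) <- 0
  dimnames(w) <- dimnames(precision)
  w
}

#' EBIC model selection over a graphical-lasso path
#'
#' Computes, for each estimate on the path,
#' \code{EBIC = -2 l(Theta) + E log(n) + 4 E gamma log(p)} with
#' \code{l = n/2 (log det Theta - tr(S Theta))} and E the number of
#' nonzero unique off-diagonal edges, and returns the minimizer as a
#' partial-correlation network.
#'
#' @param path a \code{glasso_path}.
#' @param n sample size (taken from the path if recorded there).
#' @param gamma EBIC hyperparameter, >= 0; default 0.5.
#' @param scheme optional node scheme attached to the result.
#' @param edge_tol entries below this magnitude count as absent edges.
#' @return A \code{ggm_network}: list with \code{weights} (partial
#'   correlations), \code{precision_hat}, \code{lambda_selected},
#'   \code{ebic_value}, \code{ebic_path}, \code{lambda_path},
#'   \code{gamma}, \code{n}, \code{nodes}, \code{node_scheme}.
#' @export
select_ebic <- function(path, n = NULL, gamma = 0.5, scheme = NULL,
                        edge_tol = 1e-8) {
  stopifnot(inherits(path, "glasso_path"))
  n <- n %||% path$n
  if (is.null(n) || is.na(n))
    stop("sample size 'n' is required for EBIC", call. = FALSE)
  if (gamma < 0) stop("gamma must be >= 0", call. = FALSE)
  p <- nrow(path$S)
  ebic <- vapply(path$Theta, function(Th) {
    E <- sum(abs(Th[upper.tri(Th)]) > edge_tol)
    ll <- n / 2 * (determinant(Th, logarithm = TRUE)$modulus - sum(path$S * Th))
    -2 * as.numeric(ll) + E * log(n) + 4 * E * gamma * log(p)
  }, numeric(1))
  best <- which.min(ebic)
  Th <- path$Theta[[best]]
  Th[abs(Th) <= edge_tol & row(Th) != col(Th)] <- 0
  w <- precision_to_partial(Th)
  nodes <- colnames(path$S) %||% paste0("V", seq_len(p))
  dimnames(w) <- dimnames(Th) <- list(nodes, nodes)
  structure(list(weights = w, precision_hat = Th,
                 lambda_selected = path$lambdas[best],
                 ebic_value = ebic[best], ebic_path = ebic,
                 lambda_path = path$lambdas, gamma = gamma, n = n,
                 nodes = nodes, node_scheme = scheme),
            class = "ggm_network")
}

#' Estimate a regularized partial-correlation network
#'
#' Convenience wrapper: correlation matrix, graphical-lasso path, EBIC
#' selection.
#' @param data participants x nodes matrix.
#' @param method correlation method.
#' @param gamma EBIC hyperparameter.
#' @param lambdas optional penalty path.
#' @param scheme optional node scheme.
#' @return A \code{ggm_network}.
#' @export
estimate_ggm <- function(data, method = "pearson", gamma = 0.5,
                         lambdas = NULL, scheme = NULL) {
  S <- compute_correlations(data, method)
  path <- graphical_lasso_path(S, lambdas)
  select_ebic(path, n = S$n, gamma = gamma, scheme = scheme)
}

#' @export
print.ggm_network <- function(x, ...) {
  E <- sum(x$weights[upper.tri(x$weights)] != 0)
  cat(sprintf("GGM network: %d nodes, %d edges, lambda=%.4g (gamma=%.2f), EBIC=%.1f\n",
              length(x$nodes), E, x$lambda_selected, x$gamma, x$ebic_value))
  invisible(x)
}

#' Global strength of an undirected network
#'
#' Sum of absolute edge weights over unique node pairs.
#' @param network a \code{ggm_network} or symmetric weights matrix.
#' @export
global_strength <- function(network) {
  w <- if (inherits(network, "ggm_network")) network$weights
       else check_symmetric(as.matrix(network))
  sum(abs(w[upper.tri(w)]))
}

#' Edge list of an undirected network
#'
#' @param network a \code{ggm_network}.
#' @param all include absent (zero) edges?
#' @return data.frame(node_i, node_j, weight).
#' @export
ggm_edge_list <- function(network, all = FALSE) {
  w <- network$weights
  idx <- which(upper.tri(w), arr.ind = TRUE)
  out <- data.frame(node_i = rownames(w)[idx[, 1]],
                    node_j = colnames(w)[idx[, 2]],
                    weight = w[idx], stringsAsFactors = FALSE)
  if (!all) out <- out[out$weight != 0, ]
  rownames(out) <- NULL
  out
}
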