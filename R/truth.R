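# Ground-truth network generators: sparse Gaussian graphical models for
# cross-sectional structure and sparse lag-1 coefficient matrices for the
# longitudinal process. These are the "true networks" against which
# estimator recovery and power are measured.

#' Sample a sparse ground-truth Gaussian graphical model
#'
#' Draws a random sparse partial-correlation structure over the nodes of a
#' scheme. Edges are placed uniformly at random in the upper triangle at
#' the requested density; nonzero partial correlations have magnitudes
#' uniform in \code{weight_range}, with sign positive with probability
#' \code{prob_positive} (symptom networks are predominantly positive).
#' The precision matrix is \code{I - P} (unit diagonal, off-diagonal
#' \code{-p_ij}); if that matrix is not positive definite the partial
#' correlations are shrunk by a constant factor until the smallest
#' eigenvalue exceeds \code{1e-4}, and the draw is rejected if shrinkage
#' pushes any nonzero weight below \code{weight_range[1]} (the weight
#' range was too aggressive for the density).
#'
#' @param scheme a \code{node_scheme}, or an integer node count for
#'   generic use.
#' @param edge_density fraction of node pairs carrying an edge, in (0, 1].
#'   Zero gives the empty graph.
#' @param weight_range length-2 numeric, magnitudes of nonzero partial
#'   correlations; \code{0 < lo <= hi < 1}.
#' @param prob_positive probability a nonzero edge is positive.
#' @param seed integer seed; same seed gives identical truth.
#' @param min_eigen conditioning floor: a draw is accepted only if the
#'   smallest eigenvalue of the precision matrix is at least this value.
#'   Near-singular truths imply marginal correlations close to 1, which
#'   bounded Likert-type symptom scores cannot exhibit; the floor keeps
#'   the implied covariance in a realistic regime.
#' @param max_tries redraws allowed before giving up on positive
#'   definiteness.
#' @return A \code{true_ggm}: list with \code{partial_corr},
#'   \code{precision}, \code{adjacency}, \code{sigma} (implied
#'   covariance), and \code{nodes}.
#' @export
sample_true_ggm <- function(scheme, edge_density, weight_range = c(0.15, 0.4),
                            prob_positive = 0.8, seed = NULL,
                            min_eigen = 0.1, max_tries = 200L) {
  nodes <- if (inherits(scheme, "node_scheme")) scheme$node_ids
           else paste0("V", seq_len(as.integer(scheme)))
  p <- length(nodes)
  stopifnot(edge_density >= 0, edge_density <= 1,
            length(weight_range) == 2L,
            weight_range[1] > 0 || edge_density == 0,
            weight_range[1] <= weight_range[2], weight_range[2] < 1)

  with_seed(seed, {
    n_pairs <- p * (p - 1L) / 2L
    n_edges <- round(edge_density * n_pairs)
    for (try in seq_len(max_tries)) {
      P <- matrix(0, p, p)
      if (n_edges > 0) {
        sel <- sample.int(n_pairs, n_edges)
        w <- runif(n_edges, weight_range[1], weight_range[2]) *
          ifelse(runif(n_edges) < prob_positive, 1, -1)
        ut <- which(upper.tri(P))
        P[ut[sel]] <- w
        P <- P + t(P)
      }
      Theta <- diag(p) - P
      ev_min <- min(eigen(Theta, symmetric = TRUE, only.values = TRUE)$values)
      shrink <- 1
      while (ev_min <= max(min_eigen, 1e-4) && shrink > 1e-3) {
        shrink <- shrink * 0.9
        Theta <- diag(p) - shrink * P
        ev_min <- min(eigen(Theta, symmetric = TRUE, only.values = TRUE)$values)
      }
      if (ev_min <= max(min_eigen, 1e-4)) next
      if (shrink < 1 && n_edges > 0 &&
          min(abs(shrink * P[P != 0])) < weight_range[1]) next
      P <- shrink * P
      dimnames(P) <- dimnames(Theta) <- list(nodes, nodes)
      sigma <- solve(Theta)
      return(structure(list(partial_corr = P,
                            precision = Theta,
                            adjacency = P != 0,
                            sigma = sigma,
                            nodes = nodes),
                       class = "true_ggm"))
    }
    stop("could not build a positive-definite truth at this density/weight range; ",
         "reduce edge_density or weight_range", call. = FALSE)
  })
}

#' Sample a sparse ground-truth cross-lagged coefficient matrix
#'
#' Builds the lag-1 transition matrix B of a stationary VAR(1)-type
#' process: entry \code{B[i, j]} is the effect of node i at wave t on node
#' j at wave t+1. Diagonal (autoregressive) entries are uniform in
#' \code{ar_range}; off-diagonal cross-lagged effects are placed at
#' \code{cross_density} with magnitudes in \code{cross_weight_range} and
#' sign positive with probability \code{prob_positive}. Specific edges
#' (e.g. a planted distress-to-IA path) can be forced exactly via
#' \code{forced_edges}. If the spectral radius reaches 0.95, non-forced
#' entries are shrunk; forced weights that still break stationarity are
#' rejected.
#'
#' @param scheme node_scheme or node count.
#' @param ar_range autoregressive range, subset of (0, 1).
#' @param cross_density fraction of ordered off-diagonal pairs with a
#'   cross-lagged effect.
#' @param cross_weight_range magnitudes of cross-lagged effects.
#' @param forced_edges data.frame with columns from, to, weight (or NULL).
#' @param prob_positive probability a cross effect is positive.
#' @param innovation_cov optional positive-definite innovation covariance;
#'   defaults to the identity.
#' @param seed integer seed.
#' @return A \code{true_clpn}: list with \code{B}, \code{pattern}
#'   (logical nonzero pattern), \code{innovation_cov}, \code{nodes}.
#' @export
sample_true_clpn <- function(scheme, ar_range = c(0.4, 0.6),
                             cross_density = 0.05,
                             cross_weight_range = c(0.15, 0.3),
                             forced_edges = NULL, prob_positive = 0.9,
                             innovation_cov = NULL, seed = NULL) {
  nodes <- if (inherits(scheme, "node_scheme")) scheme$node_ids
           else paste0("V", seq_len(as.integer(scheme)))
  p <- length(nodes)
  stopifnot(ar_range[1] > 0, ar_range[2] < 1, ar_range[1] <= ar_range[2],
            cross_density >= 0, cross_density <= 1)
  if (!is.null(forced_edges)) {
    stopifnot(is.data.frame(forced_edges),
              all(c("from", "to", "weight") %in% names(forced_edges)))
    bad <- setdiff(c(forced_edges$from, forced_edges$to), nodes)
    if (length(bad))
      stop("forced_edges reference unknown nodes: ", paste(bad, collapse = ", "),
           call. = FALSE)
  }

  with_seed(seed, {
    B <- matrix(0, p, p, dimnames = list(nodes, nodes))
    diag(B) <- runif(p, ar_range[1], ar_range[2])
    off <- which(row(B) != col(B))
    n_cross <- round(cross_density * length(off))
    if (n_cross > 0) {
      sel <- sample(off, n_cross)
      B[sel] <- runif(n_cross, cross_weight_range[1], cross_weight_range[2]) *
        ifelse(runif(n_cross) < prob_positive, 1, -1)
    }
    forced_mask <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
    if (!is.null(forced_edges) && nrow(forced_edges)) {
      for (k in seq_len(nrow(forced_edges))) {
        B[forced_edges$from[k], forced_edges$to[k]] <- forced_edges$weight[k]
        forced_mask[forced_edges$from[k], forced_edges$to[k]] <- TRUE
      }
    }
    sr <- function(m) max(abs(eigen(m, only.values = TRUE)$values))
    tries <- 0L
    while (sr(B) >= 0.95 && tries < 200L) {
      B[!forced_mask] <- B[!forced_mask] * 0.95
      tries <- tries + 1L
    }
    if (sr(B) >= 0.95)
      stop("forced edge weights incompatible with a stationary process ",
           "(spectral radius >= 0.95 after rescaling)", call. = FALSE)
    psi <- innovation_cov %||% diag(p)
    check_symmetric(psi, name = "innovation_cov")
    if (!is_pd(psi)) stop("innovation_cov must be positive definite", call. = FALSE)
    dimnames(psi) <- list(nodes, nodes)
    structure(list(B = B, pattern = B != 0, innovation_cov = psi, nodes = nodes),
              class = "true_clpn")
  })
}
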