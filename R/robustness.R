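# Robustness machinery: nonparametric bootstrap of edges and
# centralities, bootstrapped difference tests, case-drop stability (CS
# coefficient), permutation network-comparison test, and simulation-based
# power analysis.

# Sample from N(0, sigma) via the Cholesky factor.
rmvn <- function(n, sigma) {
  matrix(rnorm(n * nrow(sigma)), n, nrow(sigma)) %*% chol(sigma)
}

clpn_offdiag_names <- function(nodes) {
  idx <- which(row(diag(length(nodes))) != col(diag(length(nodes))),
               arr.ind = TRUE)
  paste(nodes[idx[, 1]], nodes[idx[, 2]], sep = "->")
}

# One estimator evaluation -> list(edges = named vector, centrality =
# named vector). `data` is a matrix (ggm) or list(from, to) (clpn).
estimate_once <- function(data, estimator, gamma, method, lambda_mode, lam,
                          folds, fit_seed, communities, centrality_index) {
  if (estimator == "ggm") {
    net <- estimate_ggm(data, method = method, gamma = gamma)
    ed <- setNames(upper_tri_vec(net$weights), edge_names_upper(net$nodes))
    cent <- centrality_values(net, centrality_index, communities)
    list(edges = ed, centrality = cent)
  } else {
    Z_from <- scale(data$from); Z_to <- scale(data$to)
    if (anyNA(Z_from) || anyNA(Z_to)) stop("constant column in resample")
    core <- fit_clpn_core(Z_from, Z_to, lambda_mode, lam, folds, fit_seed)
    net <- clpn_network(core$B_hat)
    nodes <- colnames(core$B_hat)
    B <- core$B_hat
    ed <- setNames(B[row(B) != col(B)], clpn_offdiag_names(nodes))
    cent <- centrality_values(net, centrality_index, communities)
    list(edges = ed, centrality = cent)
  }
}

# Extract one centrality index as a named vector.
centrality_values <- function(network, index, communities = NULL) {
  tab <- switch(index,
    EI1 = , EI2 = expected_influence(network, steps = as.integer(substr(index, 3, 3))),
    IEI = , OEI = in_out_expected_influence(
      network,
      scope = if (is.null(communities) && is.null(network$scheme)) "all"
              else "cross_construct",
      communities = communities),
    BEI1 = , BEI2 = bridge_expected_influence(
      network, steps = as.integer(substr(index, 4, 4)),
      communities = communities),
    stop("unknown centrality index '", index, "'", call. = FALSE))
  setNames(tab[[index]], tab$node)
}

#' Nonparametric bootstrap of network edges and centralities
#'
#' Resamples participants with replacement, re-estimates the network each
#' draw with a frozen estimator configuration, and collects edge weights
#' and one node-centrality index. Edge confidence bounds are the
#' empirical percentiles at \code{level}.
#'
#' @param data for \code{estimator = "ggm"} a participants x nodes
#'   matrix; for \code{"clpn"} a list with elements \code{from} and
#'   \code{to} (aligned wave matrices).
#' @param estimator "ggm" or "clpn".
#' @param iterations bootstrap draws, >= 100 (default 1200).
#' @param seed integer seed; the whole result is a deterministic function
#'   of (data, configuration, seed).
#' @param gamma,method GGM options.
#' @param lambda_mode,lam,folds CLPN options.
#' @param communities community labels for bridge/cross-construct
#'   centralities.
#' @param centrality_index which index to track ("EI1" default for ggm,
#'   "OEI" for clpn).
#' @param level CI level (default 0.95).
#' @param max_failure_rate estimator failures tolerated before erroring.
#' @return A \code{bootstrap_result}: list with \code{edge_samples},
#'   \code{edge_ci}, \code{centrality_samples}, \code{observed},
#'   \code{iterations}, \code{seed}, \code{failures}.
#' @export
bootstrap_edges <- function(data, estimator = c("ggm", "clpn"),
                            iterations = 1200L, seed = NULL,
                            gamma = 0.5, method = "pearson",
                            lambda_mode = "cv", lam = NULL, folds = 10L,
                            communities = NULL, centrality_index = NULL,
                            level = 0.95, max_failure_rate = 0.05) {
  estimator <- match.arg(estimator)
  if (iterations < 100) stop("iterations must be >= 100", call. = FALSE)
  centrality_index <- centrality_index %||%
    if (estimator == "ggm") "EI1" else "OEI"
  n <- if (estimator == "ggm") nrow(data) else nrow(data$from)

  observed <- estimate_once(data, estimator, gamma, method, lambda_mode, lam,
                            folds, fit_seed = seed, communities = communities,
                            centrality_index = centrality_index)
  E <- length(observed$edges)

  with_seed(seed, {
    idx_mat <- matrix(sample.int(n, n * iterations, replace = TRUE),
                      nrow = iterations)
    fit_seeds <- sample.int(.Machine$integer.max, iterations)
    edge_samples <- matrix(NA_real_, iterations, E,
                           dimnames = list(NULL, names(observed$edges)))
    cent_samples <- matrix(NA_real_, iterations, length(observed$centrality),
                           dimnames = list(NULL, names(observed$centrality)))
    failures <- 0L
    for (b in seq_len(iterations)) {
      idx <- idx_mat[b, ]
      d <- if (estimator == "ggm") data[idx, , drop = FALSE]
           else list(from = data$from[idx, , drop = FALSE],
                     to = data$to[idx, , drop = FALSE])
      res <- tryCatch(
        estimate_once(d, estimator, gamma, method, lambda_mode, lam, folds,
                      fit_seed = fit_seeds[b], communities = communities,
                      centrality_index = centrality_index),
        error = function(e) NULL)
      if (is.null(res)) { failures <- failures + 1L; next }
      edge_samples[b, ] <- res$edges
      cent_samples[b, ] <- res$centrality
    }
    if (failures > max_failure_rate * iterations)
      stop(sprintf("estimator failed in %d of %d bootstrap draws",
                   failures, iterations), call. = FALSE)
    ok <- !is.na(edge_samples[, 1])
    alpha <- (1 - level) / 2
    edge_ci <- t(apply(edge_samples[ok, , drop = FALSE], 2, quantile,
                       probs = c(alpha, 1 - alpha), names = FALSE))
    colnames(edge_ci) <- c("lower", "upper")
    structure(list(edge_samples = edge_samples[ok, , drop = FALSE],
                   edge_ci = edge_ci,
                   centrality_samples = cent_samples[ok, , drop = FALSE],
                   observed = observed,
                   estimator = estimator,
                   centrality_index = centrality_index,
                   iterations = iterations, level = level,
                   failures = failures, seed = seed),
              class = "bootstrap_result")
  })
}

#' Bootstrapped difference tests for edges and centralities
#'
#' For every pair of edges (and every pair of node centralities), the
#' bootstrap distribution of their difference is formed; a pair is
#' flagged significantly different iff the level-CI of the difference
#' excludes zero.
#'
#' @param result a \code{bootstrap_result}.
#' @param level CI level.
#' @return list(edge_significant, centrality_significant): symmetric
#'   logical matrices.
#' @export
bootstrap_difference_test <- function(result, level = 0.95) {
  stopifnot(inherits(result, "bootstrap_result"))
  alpha <- (1 - level) / 2
  sig_mat <- function(samples) {
    k <- ncol(samples)
    out <- matrix(FALSE, k, k, dimnames = list(colnames(samples),
                                               colnames(samples)))
    if (k < 2) return(out)
    for (i in seq_len(k - 1)) {
      di <- samples[, (i + 1):k, drop = FALSE] - samples[, i]
      ci <- apply(di, 2, quantile, probs = c(alpha, 1 - alpha), names = FALSE)
      sig <- ci[1, ] > 0 | ci[2, ] < 0
      out[i, (i + 1):k] <- sig
      out[(i + 1):k, i] <- sig
    }
    out
  }
  list(edge_significant = sig_mat(result$edge_samples),
       centrality_significant = sig_mat(result$centrality_samples))
}

#' Case-drop stability of a centrality index (CS coefficient)
#'
#' For each drop proportion, participants are subsampled without
#' replacement, the network re-estimated, and the chosen centrality
#' correlated with its full-sample values. The CS coefficient is the
#' largest drop proportion at which at least 95% of draws correlate at
#' least 0.7 with the full sample (and all smaller proportions also
#' qualify). By convention, CS >= 0.25 is read as acceptable stability
#' and CS >= 0.5 as good stability.
#'
#' @inheritParams bootstrap_edges
#' @param drop_grid proportions to drop, subset of (0, 0.75].
#' @param iterations subsamples per proportion.
#' @param cor_threshold,prob_level the 0.7 / 0.95 conventions.
#' @return A \code{stability_result}: list with \code{cs_coefficient},
#'   \code{drop_proportions}, \code{retained_correlations} (matrix
#'   iterations x proportions), \code{qualified}.
#' @export
case_drop_stability <- function(data, estimator = c("ggm", "clpn"),
                                centrality_index = NULL,
                                drop_grid = seq(0.05, 0.75, by = 0.05),
                                iterations = 100L, seed = NULL,
                                gamma = 0.5, method = "pearson",
                                lambda_mode = "cv", lam = NULL, folds = 10L,
                                communities = NULL,
                                cor_threshold = 0.7, prob_level = 0.95) {
  estimator <- match.arg(estimator)
  if (any(drop_grid <= 0) || any(drop_grid > 0.75))
    stop("drop_grid must lie in (0, 0.75]", call. = FALSE)
  drop_grid <- sort(drop_grid)
  centrality_index <- centrality_index %||%
    if (estimator == "ggm") "EI1" else "OEI"
  n <- if (estimator == "ggm") nrow(data) else nrow(data$from)
  p <- if (estimator == "ggm") ncol(data) else ncol(data$from)

  full <- estimate_once(data, estimator, gamma, method, lambda_mode, lam,
                        folds, fit_seed = seed, communities = communities,
                        centrality_index = centrality_index)$centrality

  with_seed(seed, {
    cors <- matrix(NA_real_, iterations, length(drop_grid),
                   dimnames = list(NULL, paste0("drop_", drop_grid)))
    for (g in seq_along(drop_grid)) {
      m <- round((1 - drop_grid[g]) * n)
      if (m < 2 * p) {
        warning(sprintf("drop proportion %.2f leaves %d < 2p cases; skipped",
                        drop_grid[g], m))
        next
      }
      for (b in seq_len(iterations)) {
        idx <- sample.int(n, m)
        d <- if (estimator == "ggm") data[idx, , drop = FALSE]
             else list(from = data$from[idx, , drop = FALSE],
                       to = data$to[idx, , drop = FALSE])
        res <- tryCatch(
          estimate_once(d, estimator, gamma, method, lambda_mode, lam, folds,
                        fit_seed = sample.int(.Machine$integer.max, 1),
                        communities = communities,
                        centrality_index = centrality_index)$centrality,
          error = function(e) NULL)
        if (is.null(res)) next
        cors[b, g] <- suppressWarnings(cor(full, res))
      }
    }
    qualified <- apply(cors, 2, function(cc) {
      cc <- cc[!is.na(cc)]
      length(cc) > 0 && mean(cc >= cor_threshold) >= prob_level
    })
    cs <- 0
    for (g in seq_along(drop_grid)) {
      if (isTRUE(qualified[g])) cs <- drop_grid[g] else break
    }
    structure(list(cs_coefficient = cs,
                   drop_proportions = drop_grid,
                   retained_correlations = cors,
                   qualified = qualified,
                   centrality_index = centrality_index,
                   cor_threshold = cor_threshold, prob_level = prob_level,
                   iterations = iterations, seed = seed),
              class = "stability_result")
  })
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("CS coefficient (%s): %.2f  (>= 0.25 acceptable, >= 0.5 good)\n",
              x$centrality_index, x$cs_coefficient))
  invisible(x)
}

#' Permutation network-comparison test
#'
#' Compares two estimated networks on (i) network structure invariance,
#' M = the maximum absolute edge difference, (ii) global strength,
#' S = the absolute difference of the summed absolute edge weights, and
#' (iii) individual edges. The null distribution is built by permutation:
#' unpaired, group labels are reshuffled across the pooled participants;
#' paired (repeated measures of one cohort, the default for wave
#' comparisons), each participant's two records are swapped independently
#' with probability 1/2. P-values use the add-one permutation estimator;
#' per-edge p-values are referred to the null distribution of the maximum
#' difference and Holm-corrected.
#'
#' @param data_a,data_b participants x nodes matrices over the same
#'   nodes; for \code{paired = TRUE} rows must be aligned (same
#'   participants).
#' @param paired logical; see above.
#' @param iterations permutations (default 1000).
#' @param seed integer seed.
#' @param gamma,method GGM estimator options (frozen across
#'   permutations).
#' @return An \code{nct_result}: list with \code{m_statistic},
#'   \code{s_statistic}, \code{p_invariance}, \code{p_global},
#'   \code{per_edge_p} (Holm-corrected, symmetric matrix),
#'   \code{global_strength} (both groups), \code{iterations},
#'   \code{paired}.
#' @export
network_comparison_test <- function(data_a, data_b, paired = TRUE,
                                    iterations = 1000L, seed = NULL,
                                    gamma = 0.5, method = "pearson") {
  data_a <- as.matrix(data_a); data_b <- as.matrix(data_b)
  if (ncol(data_a) != ncol(data_b) ||
      !identical(colnames(data_a), colnames(data_b)))
    stop("both datasets must share the same node set", call. = FALSE)
  if (paired && nrow(data_a) != nrow(data_b))
    stop("paired comparison requires the same participants in both datasets",
         call. = FALSE)
  p <- ncol(data_a)
  nodes <- colnames(data_a) %||% paste0("V", seq_len(p))

  stat_fun <- function(xa, xb) {
    wa <- estimate_ggm(xa, method = method, gamma = gamma)$weights
    wb <- estimate_ggm(xb, method = method, gamma = gamma)$weights
    d <- upper_tri_vec(wa - wb)
    list(edge_diff = abs(d), M = max(abs(d)),
         S = abs(sum(abs(upper_tri_vec(wa))) - sum(abs(upper_tri_vec(wb)))),
         gs = c(global_strength(wa), global_strength(wb)))
  }
  obs <- stat_fun(data_a, data_b)

  with_seed(seed, {
    m_null <- s_null <- numeric(iterations)
    for (it in seq_len(iterations)) {
      if (paired) {
        swap <- runif(nrow(data_a)) < 0.5
        xa <- data_a; xb <- data_b
        xa[swap, ] <- data_b[swap, ]
        xb[swap, ] <- data_a[swap, ]
      } else {
        pool <- rbind(data_a, data_b)
        lab <- sample.int(nrow(pool))
        xa <- pool[lab[seq_len(nrow(data_a))], , drop = FALSE]
        xb <- pool[lab[-seq_len(nrow(data_a))], , drop = FALSE]
      }
      st <- stat_fun(xa, xb)
      m_null[it] <- st$M
      s_null[it] <- st$S
    }
    p_inv <- (1 + sum(m_null >= obs$M)) / (1 + iterations)
    p_glob <- (1 + sum(s_null >= obs$S)) / (1 + iterations)
    per_edge_raw <- vapply(obs$edge_diff, function(d)
      (1 + sum(m_null >= d)) / (1 + iterations), numeric(1))
    per_edge_adj <- stats::p.adjust(per_edge_raw, method = "holm")
    pm <- matrix(1, p, p, dimnames = list(nodes, nodes))
    pm[upper.tri(pm)] <- per_edge_adj
    pm[lower.tri(pm)] <- t(pm)[lower.tri(pm)]
    diag(pm) <- NA_real_
    structure(list(m_statistic = obs$M, s_statistic = obs$S,
                   p_invariance = p_inv, p_global = p_glob,
                   per_edge_p = pm,
                   global_strength = setNames(obs$gs, c("a", "b")),
                   iterations = iterations, paired = paired, seed = seed),
              class = "nct_result")
  })
}

#' @export
print.nct_result <- function(x, ...) {
  cat(sprintf("Network comparison (%s): M=%.3f (p=%.3f), S=%.3f (p=%.3f); GS %.3f vs %.3f\n",
              if (x$paired) "paired" else "unpaired",
              x$m_statistic, x$p_invariance, x$s_statistic, x$p_global,
              x$global_strength[1], x$global_strength[2]))
  invisible(x)
}

#' Simulation-based power analysis for GGM estimation
#'
#' For each sample size, repeatedly simulates Gaussian data from a
#' ground-truth network, re-estimates it, and scores edge-detection
#' sensitivity TP/(TP+FN), specificity TN/(TN+FP), and the correlation
#' between true and estimated edge weights over all unique pairs.
#'
#' @param truth a \code{true_ggm}.
#' @param n_grid sample sizes to probe.
#' @param reps replications per sample size (>= 10).
#' @param seed integer seed.
#' @param gamma EBIC hyperparameter of the re-estimator.
#' @return A \code{power_result}: list with \code{summary} (per-n means
#'   and quartiles of the three metrics) and \code{samples} (long
#'   data.frame of every replication).
#' @export
power_simulation <- function(truth, n_grid, reps = 20L, seed = NULL,
                             gamma = 0.5) {
  stopifnot(inherits(truth, "true_ggm"))
  if (reps < 10) stop("reps must be >= 10", call. = FALSE)
  true_w <- upper_tri_vec(truth$partial_corr)
  true_adj <- true_w != 0
  no_edges <- !any(true_adj)

  with_seed(seed, {
    rows <- list()
    for (n in n_grid) for (r in seq_len(reps)) {
      x <- rmvn(n, truth$sigma)
      colnames(x) <- truth$nodes
      est <- estimate_ggm(x, gamma = gamma)
      est_w <- upper_tri_vec(est$weights)
      est_adj <- est_w != 0
      tp <- sum(est_adj & true_adj); fn <- sum(!est_adj & true_adj)
      tn <- sum(!est_adj & !true_adj); fp <- sum(est_adj & !true_adj)
      rows[[length(rows) + 1L]] <- data.frame(
        n = n, rep = r,
        sensitivity = if (no_edges) NA_real_ else tp / (tp + fn),
        specificity = if (tn + fp == 0) NA_real_ else tn / (tn + fp),
        correlation = suppressWarnings(cor(true_w, est_w)))
    }
    samples <- do.call(rbind, rows)
    agg <- function(v) c(mean = mean(v, na.rm = TRUE),
                         q25 = unname(quantile(v, 0.25, na.rm = TRUE)),
                         q75 = unname(quantile(v, 0.75, na.rm = TRUE)))
    summ <- do.call(rbind, lapply(split(samples, samples$n), function(d) {
      data.frame(n = d$n[1],
                 t(c(sensitivity = agg(d$sensitivity),
                     specificity = agg(d$specificity),
                     correlation = agg(d$correlation))))
    }))
    rownames(summ) <- NULL
    structure(list(summary = summ, samples = samples, n_grid = n_grid,
                   reps = reps, seed = seed),
              class = "power_result")
  })
}
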