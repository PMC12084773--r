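# Three-wave ordinal panel simulation. Wave 1 is multivariate normal with
# the covariance implied by a true GGM; later waves follow the lag-1
# process X_{t+1} = B' X_t + eps. In ordinal mode each latent column is
# discretized to its node's integer score range with marginal moments
# matched to a calibration table.

#' Default marginal calibration for the synthetic cohort
#'
#' Target means and SDs per node per wave emulating a large Chinese
#' college-student cohort assessed with the IAT and the DASS-21 over three
#' waves (baseline, 12 and 24 months). IA subscale targets are subscale
#' sums; the 21 distress items share a common per-item target derived from
#' the scale totals: mean = total mean / 21, and SD from the total SD via
#' the equal-correlation identity Var(total) = k * sigma^2 * (1 + (k-1) *
#' rho) with rho implied by the scale's Cronbach alpha
#' (rho = alpha / (k - (k-1) * alpha)).
#'
#' @return data.frame with columns node, wave, mean, sd.
#' @export
default_calibration <- function() {
  waves <- c("T1", "T2", "T3")
  ia <- data.frame(
    node = rep(c("A1", "A2", "A3", "A4", "A5", "A6"), times = 3),
    wave = rep(waves, each = 6),
    mean = c(11.42, 10.87, 7.26, 4.28, 7.19, 3.94,
             10.96, 10.64, 6.85, 4.32, 6.66, 3.97,
             11.04, 10.85, 6.87, 4.47, 6.71, 3.94),
    sd   = c(4.08, 3.78, 2.69, 1.83, 2.99, 1.78,
             4.13, 3.89, 2.79, 1.84, 2.87, 1.68,
             4.22, 3.99, 2.79, 1.93, 2.86, 1.69),
    stringsAsFactors = FALSE)

  dass_total_mean <- c(T1 = 11.27, T2 = 9.00, T3 = 9.13)
  dass_total_sd   <- c(T1 = 9.49,  T2 = 9.44, T3 = 9.80)
  alpha           <- c(T1 = 0.93,  T2 = 0.95, T3 = 0.95)
  k <- 21
  rho <- alpha / (k - (k - 1) * alpha)
  item_sd <- dass_total_sd / sqrt(k * (1 + (k - 1) * rho))
  distress_nodes <- make_node_scheme()$node_ids[-(1:6)]
  di <- do.call(rbind, lapply(waves, function(w) {
    data.frame(node = distress_nodes, wave = w,
               mean = dass_total_mean[[w]] / k, sd = item_sd[[w]],
               stringsAsFactors = FALSE)
  }))
  rbind(ia, di)
}

#' Discretize a latent column to an integer Likert-type score range
#'
#' Monotone rank binning: the empirical quantiles of the latent column are
#' cut at the thresholds of a discretized normal on the integer levels
#' \code{bounds[1]..bounds[2]} whose parameters are moment-matched to
#' \code{target_mean} and \code{target_sd} (with a final one-dimensional
#' refinement so the implied mean hits the target). Larger latent values
#' never map to smaller levels; tied latent values map to the same level.
#'
#' @param latent numeric vector.
#' @param bounds integer (min, max) score bounds.
#' @param target_mean target sample mean, strictly inside bounds.
#' @param target_sd target sample SD (> 0).
#' @return Integer vector of the same length, values in
#'   \code{bounds[1]:bounds[2]}; the realized mean is within
#'   \code{0.05 * target_sd} of the target (up to small-sample
#'   granularity, warned about otherwise).
#' @export
discretize_likert <- function(latent, bounds, target_mean, target_sd) {
  lo <- bounds[1]; hi <- bounds[2]
  stopifnot(length(latent) >= 1, hi > lo, target_sd > 0)
  if (target_mean <= lo || target_mean >= hi)
    stop("target_mean must lie strictly inside the score bounds", call. = FALSE)
  levels <- seq.int(lo, hi)

  if (length(unique(latent)) == 1L)
    return(rep.int(as.integer(levels[which.min(abs(levels - target_mean))]),
                   length(latent)))

  disc <- function(mu, sigma) {
    cuts <- pnorm((levels[-1] - 0.5 - mu) / sigma)
    probs <- diff(c(0, cuts, 1))
    m <- sum(levels * probs)
    list(m = m, s = sqrt(max(sum(levels^2 * probs) - m^2, 0)), cuts = cuts)
  }
  obj <- function(par) {
    d <- disc(par[1], exp(par[2]))
    (d$m - target_mean)^2 + (d$s - target_sd)^2
  }
  fit <- optim(c(target_mean, log(target_sd)), obj,
               control = list(maxit = 3000, reltol = 1e-14))
  mu <- fit$par[1]; sigma <- exp(fit$par[2])
  # refine mu so the implied mean matches the target exactly
  root <- tryCatch(
    uniroot(function(m) disc(m, sigma)$m - target_mean,
            interval = mu + c(-4, 4) * sigma, extendInt = "upX", tol = 1e-10),
    error = function(e) NULL)
  if (!is.null(root)) mu <- root$root
  cuts <- disc(mu, sigma)$cuts

  u <- (rank(latent, ties.method = "average") - 0.5) / length(latent)
  out <- as.integer(levels[findInterval(u, cuts) + 1L])
  # achievable precision is limited by sample granularity at small n
  slack <- max(0.05 * target_sd, (hi - lo) / length(latent))
  if (abs(mean(out) - target_mean) > slack)
    warning(sprintf("realized mean %.3f misses target %.3f by more than 0.05*SD",
                    mean(out), target_mean))
  out
}

#' Simulate a three-wave panel dataset from known network truth
#'
#' Wave-1 latent scores are drawn from the zero-mean Gaussian with
#' covariance implied by \code{truth_ggm}; subsequent waves follow
#' \code{X[t+1] = t(B) X[t] + eps} with innovations from
#' \code{truth_clpn$innovation_cov}. With \code{ordinal = TRUE} each
#' latent column is discretized to its node's score bounds with marginal
#' moments from \code{calibration}.
#'
#' @param truth_ggm a \code{true_ggm} over the scheme's nodes.
#' @param truth_clpn a \code{true_clpn} over the same nodes.
#' @param n number of participants (>= 2).
#' @param seed integer seed.
#' @param ordinal discretize to integer scores? Default TRUE.
#' @param scheme node scheme; defaults to \code{make_node_scheme()}.
#' @param waves wave labels (length >= 1).
#' @param calibration data.frame(node, wave, mean, sd); default
#'   \code{default_calibration()}.
#' @return A \code{panel_dataset}.
#' @export
simulate_panel <- function(truth_ggm, truth_clpn, n, seed = NULL,
                           ordinal = TRUE, scheme = make_node_scheme(),
                           waves = c("T1", "T2", "T3"),
                           calibration = default_calibration()) {
  stopifnot(inherits(truth_ggm, "true_ggm"), inherits(truth_clpn, "true_clpn"))
  if (n < 2) stop("n must be at least 2", call. = FALSE)
  nodes <- scheme$node_ids
  if (!identical(truth_ggm$nodes, nodes) || !identical(truth_clpn$nodes, nodes))
    stop("truth objects must be defined on the scheme's nodes", call. = FALSE)
  B <- truth_clpn$B
  if (max(abs(eigen(B, only.values = TRUE)$values)) >= 1)
    stop("non-stationary truth: spectral radius of B >= 1", call. = FALSE)
  p <- length(nodes); W <- length(waves)

  with_seed(seed, {
    ch_sigma <- chol(truth_ggm$sigma)
    ch_psi <- chol(truth_clpn$innovation_cov)
    lat <- array(NA_real_, dim = c(n, p, W))
    lat[, , 1] <- matrix(rnorm(n * p), n, p) %*% ch_sigma
    if (W > 1) for (w in 2:W)
      lat[, , w] <- lat[, , w - 1] %*% B + matrix(rnorm(n * p), n, p) %*% ch_psi

    ids <- sprintf("P%05d", seq_len(n))
    dimnames(lat) <- list(ids, nodes, waves)
    if (!ordinal)
      return(panel_dataset(lat, scheme))

    stopifnot(all(c("node", "wave", "mean", "sd") %in% names(calibration)))
    vals <- lat
    for (w in waves) for (nd in nodes) {
      row <- calibration[calibration$node == nd & calibration$wave == w, ]
      if (nrow(row) != 1L)
        stop("calibration must have exactly one row for node ", nd,
             ", wave ", w, call. = FALSE)
      vals[, nd, w] <- discretize_likert(lat[, nd, w],
                                         scheme$score_bounds[nd, ],
                                         row$mean, row$sd)
    }
    panel_dataset(vals, scheme)
  })
}

#' Inject missing-completely-at-random cells into a panel dataset
#'
#' Each cell is masked independently with probability \code{rate};
#' underlying values are preserved so the filter's effect can be studied
#' on synthetic data.
#'
#' @param panel a \code{panel_dataset}.
#' @param rate missingness probability in [0, 1).
#' @param seed integer seed.
#' @export
inject_missingness <- function(panel, rate, seed = NULL) {
  stopifnot(inherits(panel, "panel_dataset"))
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)", call. = FALSE)
  with_seed(seed, {
    mask <- array(runif(length(panel$values)) < rate, dim = dim(panel$values),
                  dimnames = dimnames(panel$values))
    panel_dataset(panel$values, panel$scheme, missing_mask = mask)
  })
}
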