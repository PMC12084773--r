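sch <- make_node_scheme()

test_that("true GGM sampler honors density, determinism and PD invariants", {
  g0 <- sample_true_ggm(sch, 0, c(0.1, 0.2), seed = 1)
  expect_true(all(g0$partial_corr == 0))
  expect_true(all(g0$precision == diag(27)))

  g1 <- sample_true_ggm(sch, 0.1, c(0.15, 0.4), seed = 7)
  g2 <- sample_true_ggm(sch, 0.1, c(0.15, 0.4), seed = 7)
  expect_identical(g1$partial_corr, g2$partial_corr)

  n_edges <- sum(g1$partial_corr[upper.tri(g1$partial_corr)] != 0)
  expect_lte(abs(n_edges - round(0.1 * 351)), 2)

  ev <- eigen(g1$precision, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  # partial correlation identity w_ij = -theta_ij/sqrt(theta_ii theta_jj)
  th <- g1$precision
  w <- -th / sqrt(diag(th) %o% diag(th)); diag(w) <- 0
  expect_equal(w, g1$partial_corr, tolerance = 1e-12)
  expect_true(all(abs(g1$partial_corr) < 1))
  expect_equal(diag(g1$partial_corr), setNames(rep(0, 27), sch$node_ids))
  # round trip: sigma is the inverse of the precision
  expect_lt(max(abs(g1$sigma %*% g1$precision - diag(27))), 1e-10)
  # nonzero weights within the requested magnitude band
  nz <- abs(g1$partial_corr[g1$partial_corr != 0])
  expect_true(all(nz >= 0.15 - 1e-12 & nz <= 0.4 + 1e-12))
})

test_that("true CLPN sampler plants forced edges exactly and stays stationary", {
  cl0 <- sample_true_clpn(sch, cross_density = 0, seed = 3)
  expect_true(all(cl0$B[row(cl0$B) != col(cl0$B)] == 0))
  expect_true(all(diag(cl0$B) >= 0.4 & diag(cl0$B) <= 0.6))

  forced <- data.frame(from = "D4", to = "A2", weight = 0.22)
  cl <- sample_true_clpn(sch, forced_edges = forced, seed = 4)
  expect_identical(cl$B["D4", "A2"], 0.22)
  expect_lt(max(abs(eigen(cl$B, only.values = TRUE)$values)), 1)
  expect_identical(unname(cl$pattern), unname(cl$B != 0))

  # a reciprocal pair of huge forced weights makes the process explosive
  expect_error(
    sample_true_clpn(sch, forced_edges = data.frame(from = c("D4", "A2"),
                                                    to = c("A2", "D4"),
                                                    weight = c(2.5, 2.5)),
                     seed = 5),
    "stationary")
  expect_error(
    sample_true_clpn(sch, forced_edges = data.frame(from = "bogus", to = "A2",
                                                    weight = 0.1), seed = 5),
    "unknown nodes")
})

test_that("ordinal panels respect bounds, counts and integrality", {
  pan <- small_panel(n = 300, seed = 11)
  expect_length(pan$participant_ids, 300L)
  expect_true(all(pan$values == round(pan$values)))
  for (nd in sch$node_ids) {
    b <- sch$score_bounds[nd, ]
    expect_true(all(pan$values[, nd, ] >= b[1] & pan$values[, nd, ] <= b[2]))
  }
  expect_error(simulate_panel(sample_true_ggm(sch, 0, c(0.1, 0.2), seed = 1),
                              sample_true_clpn(sch, seed = 1), n = 1),
               "at least 2")
})

test_that("wave-1 sample partial correlations reproduce the truth", {
  g <- sample_true_ggm(sch, 0.1, c(0.15, 0.4), seed = 21)
  cl <- sample_true_clpn(sch, seed = 22)
  pan <- simulate_panel(g, cl, n = 50000, seed = 23, ordinal = FALSE)
  x <- wave_matrix(pan, "T1")
  emp <- precision_to_partial(solve(cov(x)))
  expect_lt(max(abs(emp - g$partial_corr)), 0.02)
})

test_that("a null lag structure leaves cross-wave correlations at noise level", {
  g <- sample_true_ggm(sch, 0, c(0.1, 0.2), seed = 31)
  cl <- sample_true_clpn(sch, cross_density = 0, seed = 32)
  cl$B[] <- 0  # fully decoupled waves
  pan <- simulate_panel(g, cl, n = 5000, seed = 33, ordinal = FALSE)
  cc <- cor(wave_matrix(pan, "T1"), wave_matrix(pan, "T2"))
  # 729 null correlations, each ~ N(0, 1/n): check the tail behaves,
  # allowing the handful of 3-sigma exceedances expected at this count
  expect_lt(mean(abs(cc) > 3 / sqrt(5000)), 0.01)
  expect_lt(max(abs(cc)), 4.5 / sqrt(5000))
})

test_that("a single planted lag edge is recovered by unpenalized regression", {
  cl <- sample_true_clpn(sch, ar_range = c(0.5, 0.5), cross_density = 0,
                         forced_edges = data.frame(from = "D4", to = "A2",
                                                   weight = 0.3),
                         seed = 41)
  g <- sample_true_ggm(sch, 0, c(0.1, 0.2), seed = 42)
  pan <- simulate_panel(g, cl, n = 20000, seed = 43, ordinal = FALSE)
  x1 <- wave_matrix(pan, "T1"); a2 <- wave_matrix(pan, "T2")[, "A2"]
  fit <- lm(a2 ~ x1)
  expect_lt(abs(coef(fit)[["x1D4"]] - 0.3), 0.03)
})

test_that("likert discretization matches target moments monotonically", {
  set.seed(5)
  z <- rnorm(10000)
  out <- discretize_likert(z, c(1, 5), target_mean = 3, target_sd = 1)
  expect_true(all(out %in% 1:5))
  expect_lt(abs(mean(out) - 3), 0.05)
  # monotone: sorting the latent leaves the output sorted
  expect_identical(out[order(z)], sort(out))
  # skewed target (distress-like marginal on 0-3)
  out2 <- discretize_likert(rnorm(5000), c(0, 3), 0.54, 0.70)
  expect_lt(abs(mean(out2) - 0.54), 0.05 * 0.70)
  # constant latent collapses to the level nearest the target
  expect_identical(unique(discretize_likert(rep(1.7, 50), c(1, 5), 3, 1)), 3L)
  expect_error(discretize_likert(z, c(1, 5), 7, 1), "inside")
})

test_that("MCAR injection hits the requested rate and is reproducible", {
  pan <- small_panel(n = 2497, seed = 51)
  p0 <- inject_missingness(pan, 0, seed = 1)
  expect_equal(sum(p0$missing_mask), 0L)
  p1 <- inject_missingness(pan, 0.1, seed = 2)
  expect_lt(abs(mean(p1$missing_mask) - 0.1), 0.01)
  p2 <- inject_missingness(pan, 0.1, seed = 2)
  expect_identical(p1$missing_mask, p2$missing_mask)
  # values preserved under the mask; complete cases recover them
  expect_identical(p1$values, pan$values)
  expect_error(inject_missingness(pan, 1), "rate")
})
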