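test_that("correlation layer computes product-moment values and validates input", {
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 4)
  S <- compute_correlations(cbind(a = x, b = y))
  expect_equal(S$values["a", "b"], 0.8)
  expect_equal(diag(S$values), c(a = 1, b = 1))
  S2 <- compute_correlations(cbind(a = x, b = -x))
  expect_equal(S2$values["a", "b"], -1)
  expect_error(compute_correlations(cbind(a = x, flat = rep(2, 4))), "flat")
  xm <- cbind(a = x, b = y); xm[2, 1] <- NA
  expect_error(compute_correlations(xm), "complete-case")
  expect_error(compute_correlations(cbind(a = 1:2, b = 2:1)), "at least 3")
})

test_that("precision-to-partial transform is the definitional map", {
  th <- matrix(c(2, -1, -1, 2), 2)
  expect_equal(precision_to_partial(th)[1, 2], 0.5)
  expect_equal(precision_to_partial(diag(3)), matrix(0, 3, 3))
  set.seed(1)
  a <- crossprod(matrix(rnorm(25), 5))  + diag(5)
  w <- precision_to_partial(a)
  expect_equal(w, t(w))
  expect_equal(diag(w), rep(0, 5))
  expect_error(precision_to_partial(matrix(c(-1, 0, 0, 1), 2)), "positive")
})

test_that("graphical lasso reproduces closed-form and inverse oracles", {
  S <- matrix(c(1, 0.5, 0.5, 1), 2)
  # full shrinkage at lambda >= max |s_ij|
  th_big <- graphical_lasso_path(S, lambdas = 0.6)$Theta[[1]]
  expect_identical(th_big[1, 2], 0)
  # analytic 2x2 solution: covariance off-diagonal soft-thresholded
  fit <- graphical_lasso_path(S, lambdas = 0.2)
  expect_equal(fit$W[[1]][1, 2], 0.3, tolerance = 1e-7)
  expect_equal(precision_to_partial(fit$Theta[[1]])[1, 2], 0.3,
               tolerance = 1e-6)
  # lambda -> 0 recovers the matrix inverse (p = 3, well-conditioned)
  set.seed(2)
  x <- matrix(rnorm(3000), 1000, 3); x[, 2] <- x[, 2] + 0.5 * x[, 1]
  S3 <- cor(x)
  th0 <- graphical_lasso_path(S3, lambdas = 1e-10)$Theta[[1]]
  expect_lt(max(abs(th0 - solve(S3))), 1e-4)
})

test_that("edge count is non-increasing along the penalty path", {
  set.seed(3)
  sch <- make_node_scheme()
  g <- sample_true_ggm(sch, 0.15, c(0.15, 0.35), seed = 3)
  x <- panelnet:::rmvn(400, g$sigma)
  path <- graphical_lasso_path(compute_correlations(x))
  n_edges <- vapply(path$Theta,
                    function(th) sum(abs(th[upper.tri(th)]) > 1e-8), numeric(1))
  # graphical-lasso edge sets are not exactly nested along the path: single
  # edges can drop out as lambda falls; the trend must still be monotone
  expect_true(all(diff(n_edges) >= -3))
  expect_equal(n_edges[1], 0)
  expect_gt(n_edges[length(n_edges)], n_edges[1])
})

test_that("EBIC selection minimizes the criterion and recovers simple truths", {
  S <- matrix(c(1, 0.5, 0.5, 1), 2)
  one <- graphical_lasso_path(S, lambdas = 0.2)
  sel <- select_ebic(one, n = 100)
  expect_equal(sel$lambda_selected, 0.2)

  # empty model: penalty term is exactly zero, EBIC = -2 * loglik
  th_d <- graphical_lasso_path(S, lambdas = 0.6)
  sel_d <- select_ebic(th_d, n = 100, gamma = 0.5)
  ll <- 100 / 2 * (determinant(sel_d$precision_hat)$modulus[1] -
                     sum(S * sel_d$precision_hat))
  expect_equal(sel_d$ebic_value, -2 * ll)

  # 4-node truth with 2 strong edges: selected edge set equals truth, and
  # the selection agrees with an independently computed EBIC argmin
  p4 <- diag(4)
  p4[1, 2] <- p4[2, 1] <- -0.35
  p4[3, 4] <- p4[4, 3] <- -0.4
  sigma <- solve(p4)
  set.seed(4)
  x <- panelnet:::rmvn(2000, sigma)
  S4 <- compute_correlations(x)
  path <- graphical_lasso_path(S4)
  net <- select_ebic(path, n = 2000)
  expect_identical(unname(net$weights != 0),
                   unname(p4 != 0 & row(p4) != col(p4)))
  ebic_oracle <- vapply(path$Theta, function(th) {
    E <- sum(abs(th[upper.tri(th)]) > 1e-8)
    ll <- 2000 / 2 * (determinant(th)$modulus[1] - sum(S4$values * th))
    -2 * ll + E * log(2000) + 4 * E * 0.5 * log(4)
  }, numeric(1))
  expect_equal(net$lambda_selected, path$lambdas[which.min(ebic_oracle)])
  expect_equal(net$ebic_value, min(ebic_oracle))
})

test_that("network weights and precision share a sparsity pattern", {
  pan <- small_panel(n = 400, seed = 61)
  x <- wave_matrix(pan, "T1")
  net <- estimate_ggm(x)
  off <- row(net$weights) != col(net$weights)
  expect_identical(net$weights[off] != 0, net$precision_hat[off] != 0)
  expect_true(all(abs(net$weights[off]) < 1))
})

test_that("global strength sums absolute unique edge weights", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.1
  w[1, 3] <- w[3, 1] <- 0.2
  w[2, 3] <- w[3, 2] <- -0.4
  expect_equal(global_strength(w), 0.7)
  expect_equal(global_strength(matrix(0, 4, 4)), 0)
})
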