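# Shared small fixtures: a 2-node and a 4-node truth with known edges.
truth2 <- local({
  th <- matrix(c(1, -0.5, -0.5, 1), 2,
               dimnames = list(c("V1", "V2"), c("V1", "V2")))
  structure(list(partial_corr = precision_to_partial(th), precision = th,
                 adjacency = precision_to_partial(th) != 0,
                 sigma = solve(th), nodes = c("V1", "V2")),
            class = "true_ggm")
})

test_that("bootstrap is deterministic and covers a known partial correlation", {
  set.seed(1)
  x <- panelnet:::rmvn(600, truth2$sigma)
  colnames(x) <- truth2$nodes
  b1 <- bootstrap_edges(x, "ggm", iterations = 150, seed = 5)
  b2 <- bootstrap_edges(x, "ggm", iterations = 150, seed = 5)
  expect_identical(b1$edge_samples, b2$edge_samples)
  expect_identical(b1$edge_ci, b2$edge_ci)
  # the (single) edge CI straddles the true partial correlation 0.5
  expect_lt(b1$edge_ci[1, "lower"], 0.5)
  expect_gt(b1$edge_ci[1, "upper"], 0.5)
  # default iteration count contract
  expect_equal(eval(formals(bootstrap_edges)$iterations), 1200L)
  expect_error(bootstrap_edges(x, "ggm", iterations = 50, seed = 1), ">= 100")
})

test_that("bootstrap propagates estimator preconditions", {
  x <- cbind(V1 = rnorm(200), V2 = rep(1, 200))
  expect_error(bootstrap_edges(x, "ggm", iterations = 100, seed = 1))
})

test_that("difference tests flag separated edges and spare identical ones", {
  set.seed(2)
  base <- rnorm(400)
  samples <- cbind(e1 = base, e2 = base,          # identical distributions
                   e3 = base + 5)                 # disjoint from e1/e2
  fake <- structure(list(edge_samples = samples,
                         centrality_samples = samples),
                    class = "bootstrap_result")
  sig <- bootstrap_difference_test(fake)
  expect_false(sig$edge_significant["e1", "e2"])
  expect_true(sig$edge_significant["e1", "e3"])
  expect_true(sig$edge_significant["e2", "e3"])
  expect_identical(sig$edge_significant, t(sig$edge_significant))
})

test_that("clearly different edges are detected on estimated networks", {
  p4 <- diag(4)
  p4[1, 2] <- p4[2, 1] <- -0.4   # strong edge ~ 0.4
  p4[3, 4] <- p4[4, 3] <- -0.05  # weak edge ~ 0.05
  sigma <- solve(p4)
  set.seed(3)
  x <- panelnet:::rmvn(2000, sigma)
  colnames(x) <- paste0("V", 1:4)
  b <- bootstrap_edges(x, "ggm", iterations = 200, seed = 7)
  sig <- bootstrap_difference_test(b)
  expect_true(sig$edge_significant["V1--V2", "V3--V4"])
})

test_that("edge CIs tighten as the sample grows", {
  p4 <- diag(4)
  p4[1, 2] <- p4[2, 1] <- -0.3
  p4[2, 3] <- p4[3, 2] <- -0.2
  sigma <- solve(p4)
  width <- vapply(c(500, 4000), function(n) {
    set.seed(11)
    x <- panelnet:::rmvn(n, sigma)
    colnames(x) <- paste0("V", 1:4)
    b <- bootstrap_edges(x, "ggm", iterations = 150, seed = 13)
    # width at the true edges (null-edge CIs degenerate at 0 under shrinkage)
    ci <- b$edge_ci[c("V1--V2", "V2--V3"), , drop = FALSE]
    median(ci[, "upper"] - ci[, "lower"])
  }, numeric(1))
  expect_lt(width[2], width[1])
})

test_that("case-drop stability reports 0 when no proportion qualifies", {
  set.seed(4)
  x <- matrix(rnorm(60 * 5), 60, 5)  # pure noise, tiny n: unstable
  colnames(x) <- paste0("V", 1:5)
  s <- suppressWarnings(
    case_drop_stability(x, "ggm", drop_grid = c(0.25, 0.5, 0.75),
                        iterations = 40, seed = 9))
  expect_true(s$cs_coefficient %in% c(0, s$drop_proportions))
  expect_true(all(is.na(s$retained_correlations) |
                    abs(s$retained_correlations) <= 1))
})

test_that("network comparison is null on identical data and validates input", {
  set.seed(5)
  xa <- matrix(rnorm(300 * 4), 300, 4)
  colnames(xa) <- paste0("V", 1:4)
  r <- network_comparison_test(xa, xa, paired = TRUE, iterations = 100,
                               seed = 15)
  expect_equal(r$m_statistic, 0)
  expect_equal(r$s_statistic, 0)
  expect_gt(r$p_global, 0.9)
  expect_true(all(r$per_edge_p[upper.tri(r$per_edge_p)] >= 0 &
                    r$per_edge_p[upper.tri(r$per_edge_p)] <= 1))

  xb <- xa[, c(2, 1, 3, 4)]
  expect_error(network_comparison_test(xa, xb, iterations = 100), "node set")
  expect_error(network_comparison_test(xa, xa[1:100, ], paired = TRUE,
                                       iterations = 100), "same participants")
})

test_that("unpaired comparison runs and detects a gross difference", {
  p4a <- diag(4); p4a[1, 2] <- p4a[2, 1] <- -0.45
  p4b <- diag(4)  # empty network
  set.seed(6)
  xa <- panelnet:::rmvn(800, solve(p4a)); colnames(xa) <- paste0("V", 1:4)
  xb <- panelnet:::rmvn(800, solve(p4b)); colnames(xb) <- paste0("V", 1:4)
  r <- network_comparison_test(xa, xb, paired = FALSE, iterations = 200,
                               seed = 17)
  expect_lt(r$p_invariance, 0.05)
  expect_lt(r$p_global, 0.05)
})

test_that("power simulation scores detection metrics against the truth", {
  g <- sample_true_ggm(6, 0.3, c(0.25, 0.45), seed = 21)
  pw <- power_simulation(g, n_grid = c(150, 1200), reps = 10, seed = 23)
  expect_true(all(pw$samples$sensitivity >= 0 & pw$samples$sensitivity <= 1))
  expect_true(all(pw$samples$specificity >= 0 & pw$samples$specificity <= 1))
  s <- pw$summary
  # larger samples detect more of the truth (up to Monte-Carlo noise)
  expect_gte(s$sensitivity.mean[s$n == 1200],
             s$sensitivity.mean[s$n == 150] - 0.02)
  expect_gte(s$correlation.mean[s$n == 1200],
             s$correlation.mean[s$n == 150] - 0.02)

  # empty truth: sensitivity undefined, specificity high under shrinkage
  g0 <- sample_true_ggm(6, 0, c(0.2, 0.3), seed = 25)
  pw0 <- power_simulation(g0, n_grid = 300, reps = 10, seed = 27)
  expect_true(all(is.na(pw0$samples$sensitivity)))
  expect_gt(mean(pw0$samples$specificity), 0.9)
})
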