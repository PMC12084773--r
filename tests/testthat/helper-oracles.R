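# Brute-force centrality oracles (independent of the package's matrix
# implementations) and small fixture builders.

bf_ei1 <- function(w) {
  vapply(seq_len(nrow(w)), function(i) sum(w[i, -i]), numeric(1))
}

bf_ei2 <- function(w) {
  e1 <- bf_ei1(w)
  vapply(seq_len(nrow(w)),
         function(i) e1[i] + sum(w[i, -i] * e1[-i]), numeric(1))
}

# Directed sums; comm = community label per node; scope "all" or "cross".
bf_oei <- function(B, comm = NULL, scope = "all") {
  p <- nrow(B)
  vapply(seq_len(p), function(i) {
    s <- 0
    for (j in seq_len(p)) {
      if (j == i) next
      if (scope == "cross" && comm[i] == comm[j]) next
      s <- s + B[i, j]
    }
    s
  }, numeric(1))
}

bf_iei <- function(B, comm = NULL, scope = "all") {
  bf_oei(t(B), comm, scope)
}

bf_bei1 <- function(B, comm, direction = "out") {
  p <- nrow(B)
  vapply(seq_len(p), function(i) {
    s <- 0
    for (j in seq_len(p)) {
      if (j == i || comm[i] == comm[j]) next
      s <- s + switch(direction, out = B[i, j], `in` = B[j, i],
                      both = B[i, j] + B[j, i])
    }
    s
  }, numeric(1))
}

bf_bei2 <- function(B, comm, direction = "out") {
  b1 <- bf_bei1(B, comm, direction)
  p <- nrow(B)
  vapply(seq_len(p), function(i) {
    s <- b1[i]
    for (k in seq_len(p)) if (k != i) s <- s + B[i, k] * b1[k]
    s
  }, numeric(1))
}

rand_und_net <- function(p, seed) {
  set.seed(seed)
  w <- matrix(0, p, p)
  w[upper.tri(w)] <- runif(p * (p - 1) / 2, -0.3, 0.3) *
    rbinom(p * (p - 1) / 2, 1, 0.5)
  w <- w + t(w)
  dimnames(w) <- list(paste0("V", 1:p), paste0("V", 1:p))
  w
}

rand_dir_net <- function(p, seed) {
  set.seed(seed)
  B <- matrix(runif(p * p, -0.3, 0.3) * rbinom(p * p, 1, 0.4), p, p)
  dimnames(B) <- list(paste0("V", 1:p), paste0("V", 1:p))
  B
}

# A small calibrated three-wave synthetic panel.
small_panel <- function(n = 200, seed = 1, ordinal = TRUE,
                        edge_density = 0.1, cross_density = 0.05) {
  sch <- make_node_scheme()
  g <- sample_true_ggm(sch, edge_density, c(0.15, 0.35), seed = seed)
  cl <- sample_true_clpn(sch, cross_density = cross_density, seed = seed + 1)
  simulate_panel(g, cl, n = n, seed = seed + 2, ordinal = ordinal)
}
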