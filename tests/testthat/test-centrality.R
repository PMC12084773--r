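test_that("expected influence reproduces hand-computed star and dyad values", {
  w <- matrix(c(0, 0.4, 0.4, 0), 2)
  tab <- expected_influence(w)
  expect_equal(tab$EI1, c(0.4, 0.4))

  star <- matrix(0, 4, 4)
  star[1, 2:4] <- star[2:4, 1] <- 0.2
  tab <- expected_influence(star)
  expect_equal(tab$EI1, c(0.6, 0.2, 0.2, 0.2))
  expect_equal(tab$EI2[1], 0.6 + 3 * (0.2 * 0.2))
})

test_that("directed and bridge indices reproduce forced configurations", {
  sch <- make_node_scheme()
  B <- matrix(0, 27, 27, dimnames = list(sch$node_ids, sch$node_ids))
  B["D4", "A2"] <- 0.22
  net <- clpn_network(B, scheme = sch)
  io <- in_out_expected_influence(net)
  expect_equal(io$OEI[io$node == "D4"], 0.22)
  expect_equal(io$IEI[io$node == "A2"], 0.22)
  expect_equal(sum(abs(io$IEI)) + sum(abs(io$OEI)), 0.44)

  # IA->IA paths vanish under cross-construct scope
  B2 <- matrix(0, 27, 27, dimnames = list(sch$node_ids, sch$node_ids))
  B2["A1", "A2"] <- 0.3; B2["A5", "A3"] <- 0.2
  io2 <- in_out_expected_influence(clpn_network(B2, scheme = sch))
  expect_true(all(io2$IEI == 0) && all(io2$OEI == 0))

  # bridge: single cross edge, outgoing convention
  bei <- bridge_expected_influence(net, direction = "out")
  expect_equal(bei$BEI1[bei$node == "D4"], 0.22)
  expect_equal(bei$BEI1[bei$node == "A2"], 0)

  # chain D -> S (within-community 0.5), S -> A (cross 0.2)
  B3 <- matrix(0, 27, 27, dimnames = list(sch$node_ids, sch$node_ids))
  B3["D1", "S1"] <- 0.5; B3["S1", "A1"] <- 0.2
  bei3 <- bridge_expected_influence(clpn_network(B3, scheme = sch),
                                    direction = "out")
  expect_equal(bei3$BEI1[bei3$node == "S1"], 0.2)
  expect_equal(bei3$BEI2[bei3$node == "D1"], 0 + 0.5 * 0.2)

  zero <- bridge_expected_influence(
    clpn_network(matrix(0, 27, 27, dimnames = list(sch$node_ids, sch$node_ids)),
                 scheme = sch))
  expect_true(all(zero$BEI1 == 0) && all(zero$BEI2 == 0))
})

test_that("all indices match brute-force enumeration on random networks", {
  comm <- rep(c("IA", "distress"), each = 4)
  for (r in 1:50) {
    w <- rand_und_net(8, seed = r); diag(w) <- 0
    tab <- expected_influence(w)
    expect_equal(tab$EI1, bf_ei1(w))
    expect_equal(tab$EI2, bf_ei2(w))

    B <- rand_dir_net(8, seed = 1000 + r)
    io_all <- in_out_expected_influence(B, scope = "all", communities = comm)
    expect_equal(io_all$IEI, bf_iei(B))
    expect_equal(io_all$OEI, bf_oei(B))
    io_cr <- in_out_expected_influence(B, scope = "cross_construct",
                                       communities = comm)
    expect_equal(io_cr$IEI, bf_iei(B, comm, "cross"))
    expect_equal(io_cr$OEI, bf_oei(B, comm, "cross"))
    for (dir in c("out", "in", "both")) {
      bei <- bridge_expected_influence(B, direction = dir, communities = comm)
      expect_equal(bei$BEI1, bf_bei1(B, comm, dir))
      expect_equal(bei$BEI2, bf_bei2(B, comm, dir))
    }
  }
})

test_that("EI1 is additive over edge-disjoint decompositions", {
  w <- rand_und_net(9, seed = 5)
  mask <- upper.tri(w) & (row(w) + col(w)) %% 2 == 0
  w1 <- w; w1[mask | t(mask)] <- 0
  w2 <- w - w1
  expect_equal(expected_influence(w, 1)$EI1,
               expected_influence(w1, 1)$EI1 + expected_influence(w2, 1)$EI1)
})

test_that("centralities are equivariant under node relabeling", {
  comm <- rep(c("IA", "distress"), each = 4)
  B <- rand_dir_net(8, seed = 6)
  perm <- sample(8)
  Bp <- B[perm, perm]
  io <- in_out_expected_influence(B, scope = "all", communities = comm)
  iop <- in_out_expected_influence(Bp, scope = "all", communities = comm[perm])
  expect_equal(iop$OEI, io$OEI[perm])
  expect_equal(iop$IEI, io$IEI[perm])
  w <- rand_und_net(8, seed = 7)
  expect_equal(expected_influence(w[perm, perm], 1)$EI1,
               expected_influence(w, 1)$EI1[perm])
})

test_that("raw and standardized tables interconvert by the z transform", {
  w <- rand_und_net(8, seed = 8)
  tab <- expected_influence(w)
  z <- standardize_centrality(tab)
  expect_equal(z$EI1, (tab$EI1 - mean(tab$EI1)) / sd(tab$EI1))
  expect_true(attr(z, "standardized"))
})
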