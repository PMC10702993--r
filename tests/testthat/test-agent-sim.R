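test_that("neighborhood summaries count neighbor degrees by state", {
  # path 1-2, 2-3, 2-4: node 2 has degree 3; leaves have degree 1
  g <- igraph::graph_from_edgelist(rbind(c(1, 2), c(2, 3), c(2, 4)),
                                   directed = FALSE)
  net <- contagion_network(g)
  net$state <- factor(c("Ip", "S", "In", "S"), levels = c("S", "Ip", "In", "R"))
  s2 <- neighborhood_summary(net, 2)
  expect_equal(s2$d_Ip, 1)
  expect_equal(s2$d_In, 1)
  expect_equal(s2$d_S, 1)
  expect_equal(s2$A, 0)
  s1 <- neighborhood_summary(net, 1)   # sole neighbor is S of degree 3
  expect_equal(s1$d_S, 3)
  expect_equal(s1$A, 0)

  iso <- contagion_network(igraph::make_empty_graph(2, directed = FALSE))
  si <- neighborhood_summary(iso, 1)
  expect_equal(unlist(si), c(d_S = 0, d_Ip = 0, d_In = 0, d_R = 0, A = 0))
  expect_error(neighborhood_summary(net, 99), "unknown node")
})

test_that("transition probabilities match hand-evaluated formulas", {
  p <- ref_params()
  # Ip-dominant neighborhood of a degree-2 node
  tp <- transition_probabilities(list(d_S = 0, d_Ip = 3, d_In = 1, d_R = 0),
                                 k_i = 2, p)
  expect_equal(tp$F_SIp, 0.45 * (2 * 2 * 3) / (2 * 4))  # 0.675
  expect_equal(tp$F_SIn, 0)
  expect_equal(tp$F_InIp, 0.05 * 2 / 2)
  expect_equal(tp$F_IpIn, 0)
  # balanced neighborhood neutralizes infection and conversion
  tb <- transition_probabilities(list(d_S = 4, d_Ip = 3, d_In = 3, d_R = 2),
                                 k_i = 4, p)
  expect_equal(tb$F_SIp, 0)
  expect_equal(tb$F_SIn, 0)
  expect_equal(tb$F_InIp, 0)
  expect_equal(tb$F_SR, p$gamma)
  expect_equal(tb$F_IpR, min(1, 2 * p$beta1))
  # degree-1 node facing a hub: raw value 4.5 must clamp to 1
  tc <- transition_probabilities(list(d_S = 0, d_Ip = 5, d_In = 0, d_R = 0),
                                 k_i = 1, p)
  expect_equal(tc$F_SIp, 1)
  expect_gte(attr(tc, "n_clamped"), 1)
})

test_that("transition probabilities are always valid probabilities", {
  set.seed(31)
  p <- ref_params()
  for (i in 1:100) {
    d <- as.list(stats::setNames(sample(0:40, 4, replace = TRUE),
                                 c("d_S", "d_Ip", "d_In", "d_R")))
    tp <- transition_probabilities(d, k_i = sample(0:12, 1), p)
    vals <- unlist(tp)
    expect_true(all(vals >= 0 & vals <= 1))
    # the dominance gates are mutually exclusive
    expect_true(tp$F_SIp == 0 || tp$F_SIn == 0)
    expect_true(tp$F_InIp == 0 || tp$F_IpIn == 0)
    if (d$d_Ip <= d$d_In) expect_equal(tp$F_SIp, 0)
    if (d$d_In <= d$d_Ip) expect_equal(tp$F_SIn, 0)
  }
  expect_error(transition_probabilities(
    list(d_S = -1, d_Ip = 0, d_In = 0, d_R = 0), 2, p), "non-negative")
})

test_that("state seeding hits exact counts and honors degree strategies", {
  net <- generate_ba(100, 2, seed = 8)
  seeded <- seed_states(net, c(S = 0.96, Ip = 0.02, In = 0.02, R = 0),
                        seed = 14)
  expect_equal(unname(state_counts(seeded)), c(96, 2, 2, 0))
  again <- seed_states(net, c(S = 0.96, Ip = 0.02, In = 0.02, R = 0),
                       seed = 14)
  expect_identical(seeded$state, again$state)

  star <- contagion_network(igraph::make_star(50, mode = "undirected"))
  hubbed <- seed_states(star, c(S = 0.96, Ip = 0.02, In = 0.02, R = 0),
                        seeding = "top_degree_negative", seed = 1)
  expect_equal(as.character(hubbed$state[1]), "In")   # hub carries negativity
  pos <- seed_states(star, c(S = 0.96, Ip = 0.02, In = 0.02, R = 0),
                     seeding = "top_degree_positive", seed = 1)
  expect_equal(as.character(pos$state[1]), "Ip")
  # banker's rounding can push per-state counts past n on tiny networks
  tiny <- contagion_network(igraph::make_ring(3))
  expect_error(seed_states(tiny, c(S = 0, Ip = 0.5, In = 0.5, R = 0), seed = 1),
               "exceed")
})

test_that("degenerate update cases are absorbing where they must be", {
  p <- sipinrs_params(epsilon = 0)
  net <- generate_ws(50, 4, 0.2, seed = 3)
  net$state <- factor(rep("R", 50), levels = c("S", "Ip", "In", "R"))
  set.seed(1)
  out <- step_contagion(net, p)
  expect_equal(unname(out$counts), c(0, 0, 0, 50))

  p2 <- sipinrs_params(gamma = 0)
  net$state <- factor(rep("S", 50), levels = c("S", "Ip", "In", "R"))
  set.seed(1)
  out2 <- step_contagion(net, p2)
  expect_equal(unname(out2$counts), c(50, 0, 0, 0))
})

test_that("vectorized round agrees exactly with a per-node reference", {
  p <- ref_params()
  net <- generate_ws(60, 6, 0.3, seed = 17)
  net <- seed_states(net, c(S = 0.8, Ip = 0.1, In = 0.1, R = 0), seed = 18)
  fast <- net; slow <- net
  for (round in 1:15) {
    set.seed(500 + round)
    fast <- step_contagion(fast, p)$network
    set.seed(500 + round)
    slow <- naive_step(slow, p)
    expect_identical(fast$state, slow$state)
  }
  # also on a graph with isolated nodes and a hub
  g <- igraph::add_vertices(igraph::make_star(20, mode = "undirected"), 3)
  net2 <- seed_states(contagion_network(g),
                      c(S = 0.6, Ip = 0.2, In = 0.1, R = 0.1), seed = 4)
  fast2 <- net2; slow2 <- net2
  for (round in 1:10) {
    set.seed(900 + round)
    fast2 <- step_contagion(fast2, p)$network
    set.seed(900 + round)
    slow2 <- naive_step(slow2, p)
    expect_identical(fast2$state, slow2$state)
  }
})

test_that("simulations conserve nodes and reproduce exactly from the seed", {
  net <- generate_ba(400, 3, seed = 21)
  cfg <- simulation_config(rounds = 12, replicates = 4, seed = 77)
  traj <- simulate_contagion(net, ref_params(), cfg)
  sums <- apply(traj$counts, c(1, 2), sum)
  expect_true(all(sums == 400))
  traj2 <- simulate_contagion(net, ref_params(), cfg)
  expect_identical(traj$counts, traj2$counts)
  # long format export
  df <- as.data.frame(traj)
  expect_equal(nrow(df), 4 * 13)
  expect_true(all(df$S + df$Ip + df$In + df$R == 400))
})

test_that("peak detection takes the earliest argmax of the median", {
  fake <- structure(list(
    counts = array(0L, c(1, 4, 4)),
    median = matrix(c(1, 1, 1, 1,  0, 0, 0, 0,  2, 5, 9, 4,  0, 0, 0, 0),
                    nrow = 4),
    n_nodes = 10), class = "count_trajectory")
  expect_equal(detect_peak(fake, "In"), list(round = 2L, count = 9))
  expect_equal(detect_peak(fake, "S")$round, 0L)   # constant: earliest
})
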