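# The closed-form examples are checked against independent oracles:
# numeric integration for the disparity null, urn enumeration for the Polya
# filter, binomial mass enumeration for MLF/NC, and direct counting for
# LANS/GloSS.

test_that("disparity p-values match the uniform order-statistic null", {
  # one-sided p for (k, s, w) by numeric integration of the null density
  df_oracle <- function(w, s, k) {
    1 - (k - 1) * integrate(function(x) (1 - x)^(k - 2), 0, w / s,
                            rel.tol = 1e-12)$value
  }
  # hub with k = 3, s = 10, one edge of weight 5 -> one-sided p = 0.25
  star <- weighted_network(data.frame(from = "h", to = c("l1", "l2", "l3"),
                                      weight = c(5, 3, 2)))
  pv <- disparity_pvalues(star)
  expect_equal(pv$p_side_from[pv$weight == 5], 0.25, tolerance = 1e-12)
  for (w in c(5, 3, 2)) {
    expect_equal(pv$p_side_from[pv$weight == w], df_oracle(w, 10, 3),
                 tolerance = 1e-10)
  }
  # k = 2 with equal weights: both one-sided p = 0.5
  path <- weighted_network(data.frame(from = c("a", "b"), to = c("b", "c"),
                                      weight = 1))
  pvp <- disparity_pvalues(path)
  hub_side <- ifelse(pvp$from == "b", pvp$p_side_from, pvp$p_side_to)
  expect_equal(hub_side, c(0.5, 0.5))
  # both endpoints degree 1 -> p = 1
  single <- weighted_network(data.frame(from = "a", to = "b", weight = 7))
  expect_equal(disparity_pvalues(single)$p, 1)
})

test_that("Polya urn p-values match exhaustive urn enumeration", {
  # a = 1, k = 2, s = 2: W uniform on {0, 1, 2}, so P(W >= 2) = 1/3
  probs <- polya_urn_enumerate(s = 2, k = 2, a = 1)
  expect_equal(probs, rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(netbackbone:::betabinom_survival(2, 2, 1, 1), 1 / 3,
               tolerance = 1e-12)
  # full distribution agreement for several (s, k, a)
  for (cfg in list(c(6, 3, 1), c(5, 2, 2), c(8, 4, 0.5))) {
    s <- cfg[1]; k <- cfg[2]; a <- cfg[3]
    probs <- polya_urn_enumerate(s, k, a)
    for (w in 0:s) {
      expect_equal(netbackbone:::betabinom_survival(w, s, 1 / a, (k - 1) / a),
                   sum(probs[(w + 1):(s + 1)]), tolerance = 1e-10)
    }
  }
  # survival at 0 is 1
  expect_equal(netbackbone:::betabinom_survival(0, 10, 1, 4), 1)
  # degree-1 endpoints contribute 1
  single <- weighted_network(data.frame(from = "a", to = "b", weight = 3))
  expect_equal(polya_pvalues(single)$p, 1)
  # non-integer weights rejected with guidance
  frac <- weighted_network(data.frame(from = c("a", "b"), to = c("b", "c"),
                                      weight = c(0.5, 1.2)))
  expect_error(polya_pvalues(frac), "validate_for_method")
})

test_that("PF with a = 1 approaches the disparity null at large strength", {
  s <- 10000
  for (k in c(2, 5, 10)) {
    ws <- seq(1, s, by = 397)
    pf <- vapply(ws, function(w) {
      netbackbone:::betabinom_survival(w, s, 1, k - 1)
    }, numeric(1))
    df <- (1 - ws / s)^(k - 1)
    expect_lt(max(abs(pf - df)), 0.02)
  }
})

test_that("MLF p-values match binomial enumeration", {
  tri <- fixture("triangle_unit")
  # T = 3, q = 2/9: enumeration of the binomial mass over x in 0..3
  q <- 2 / 9
  p_enum <- sum(choose(3, 1:3) * q^(1:3) * (1 - q)^(3 - (1:3)))
  expect_equal(p_enum, 386 / 729, tolerance = 1e-14)
  expect_equal(mlf_pvalues(tri)$p, rep(386 / 729, 3), tolerance = 1e-12)
  # two-node single edge: q = 1/2, p = 2^-w
  for (w in 1:10) {
    net <- weighted_network(data.frame(from = "a", to = "b", weight = w))
    expect_equal(mlf_pvalues(net)$p, 2^(-w), tolerance = 1e-12)
  }
})

test_that("NC p-values match binomial enumeration and share the MLF mean", {
  tri <- fixture("triangle_unit")
  # N_t = 6, q = 1/9: survival at w = 1 is 1 - (8/9)^6
  q <- 1 / 9
  p_enum <- sum(choose(6, 1:6) * q^(1:6) * (1 - q)^(6 - (1:6)))
  expect_equal(p_enum, 1 - (8 / 9)^6, tolerance = 1e-14)
  expect_equal(nc_pvalues(tri)$p, rep(1 - (8 / 9)^6, 3), tolerance = 1e-12)
  # null means agree edgewise: T * s_i s_j / (2 T^2) = N_t * s_i s_j / N_t^2
  for (seed in 1:50) {
    net <- toy_random_network(10, 0.35, 6, seed)
    s <- node_strengths(net)
    et <- edge_table(net)
    T_ <- total_weight(net)
    mlf_mean <- T_ * s[et$from] * s[et$to] / (2 * T_^2)
    nc_mean <- 2 * T_ * s[et$from] * s[et$to] / (2 * T_)^2
    expect_equal(unname(mlf_mean), unname(nc_mean), tolerance = 1e-12)
  }
})

test_that("MLF/NC null conserves total weight on large networks", {
  net <- gen_heterogeneous(150, mean_degree = 6, seed = 11)
  s <- node_strengths(net)
  T_ <- total_weight(net)
  # sum over unordered pairs of n * q_ij; deviation reflects excluded i = j
  exp_total <- (sum(s)^2 - sum(s^2)) / (4 * T_)
  expect_lt(abs(exp_total - T_) / T_, 0.02)
})

test_that("LANS counts strictly heavier incident edges", {
  star <- weighted_network(data.frame(from = "h", to = c("l1", "l2", "l3"),
                                      weight = c(1, 2, 3)))
  pv <- lans_pvalues(star)
  expect_equal(pv$p_side_from[pv$weight == 3], 0)
  expect_equal(pv$p_side_from[pv$weight == 1], 2 / 3)
  # leaves have degree 1 -> one-sided p = 0, so every edge p = 0
  expect_equal(pv$p, c(0, 0, 0))
  # ties: incident weights {2, 2} -> both 0
  path <- weighted_network(data.frame(from = c("a", "b"), to = c("b", "c"),
                                      weight = 2))
  pvp <- lans_pvalues(path)
  hub_side <- ifelse(pvp$from == "b", pvp$p_side_from, pvp$p_side_to)
  expect_equal(hub_side, c(0, 0))
})

test_that("GloSS marginal mode is the empirical weight survival", {
  net <- weighted_network(data.frame(from = c("a", "a", "b", "c"),
                                     to = c("b", "c", "c", "d"),
                                     weight = c(1, 1, 2, 4)))
  pv <- gloss_pvalues(net, mode = "marginal")
  expect_equal(pv$p[pv$weight == 2], 0.5)
  expect_equal(pv$p[pv$weight == 4], 0.25)
  expect_equal(pv$p[pv$weight == 1], c(1, 1))
  # all weights equal -> p = 1 in both modes
  tri <- fixture("triangle_unit")
  expect_equal(gloss_pvalues(tri, "marginal")$p, rep(1, 3))
  expect_equal(gloss_pvalues(tri, "conditional")$p, rep(1, 3))
})

test_that("GloSS conditional mode matches hand-computed convolution null", {
  # triangle with weights ab = 1, ac = 2, bc = 1; empirical pmf
  # f(1) = 2/3, f(2) = 1/3. Conditioning pins ab and bc entirely (p = 1);
  # for ac: g(1) = f(1)f(2)f(2) = 2/27, g(2) = f(2)f(1)f(1) = 4/27,
  # so p(ac) = (4/27) / (6/27) = 2/3.
  tri <- weighted_network(data.frame(from = c("a", "a", "b"),
                                     to = c("b", "c", "c"),
                                     weight = c(1, 2, 1)))
  pv <- gloss_pvalues(tri, "conditional")
  expect_equal(pv$p[pv$from == "a" & pv$to == "b"], 1)
  expect_equal(pv$p[pv$from == "b" & pv$to == "c"], 1)
  expect_equal(pv$p[pv$from == "a" & pv$to == "c"], 2 / 3, tolerance = 1e-9)
  # non-integer weights only allowed in marginal mode
  frac <- weighted_network(data.frame(from = c("a", "b"), to = c("b", "c"),
                                      weight = c(0.5, 1.2)))
  expect_error(gloss_pvalues(frac, "conditional"), "integer")
  expect_silent(gloss_pvalues(frac, "marginal"))
})

test_that("all filters give p in [0, 1] on seeded random networks", {
  cheap <- c("df", "mlf", "nc", "lans")
  for (seed in 1:100) {
    net <- toy_random_network(10, 0.35, 8, seed)
    for (m in cheap) {
      p <- edge_pvalues(net, m)$p
      expect_true(all(p >= 0 & p <= 1), label = paste(m, "seed", seed))
    }
  }
  for (seed in 1:15) {
    net <- toy_random_network(10, 0.35, 8, seed + 200)
    for (m in c("pf", "gloss")) {
      p <- suppressWarnings(edge_pvalues(net, m))$p
      expect_true(all(p >= 0 & p <= 1), label = paste(m, "seed", seed))
    }
  }
})

test_that("edge p-values are invariant to endpoint order and row order", {
  net <- toy_random_network(12, 0.3, 10, 42)
  et <- edge_table(net)
  perm <- rev(seq_len(nrow(et)))
  flipped <- weighted_network(data.frame(from = et$to[perm], to = et$from[perm],
                                         weight = et$weight[perm]))
  for (m in c("df", "pf", "mlf", "nc", "lans", "gloss")) {
    a <- edge_pvalues(net, m)
    b <- edge_pvalues(flipped, m)
    expect_equal(a$p, b$p, tolerance = 1e-12, label = m)
  }
})

test_that("one-sided p-values decrease with weight at fixed (k, s)", {
  # within one node all incident edges share its (k, s); the heavier edge
  # must never look less significant from that node's viewpoint
  for (seed in 1:10) {
    net <- toy_random_network(10, 0.4, 12, seed)
    for (m in c("df", "pf", "lans")) {
      pv <- edge_pvalues(net, m)
      for (v in names(node_degrees(net))) {
        sel_from <- pv$from == v
        sel_to <- pv$to == v
        w <- c(pv$weight[sel_from], pv$weight[sel_to])
        p <- c(pv$p_side_from[sel_from], pv$p_side_to[sel_to])
        ord <- order(w)
        # sorted by weight, the one-sided p never increases (ties share p)
        expect_true(all(diff(p[ord]) <= 1e-12), label = paste(m, v))
      }
    }
  }
  # symmetric filters: alternating 4-cycle has equal strengths everywhere,
  # so only the weight differs between edges
  cyc <- weighted_network(data.frame(from = c("a", "b", "c", "d"),
                                     to = c("b", "c", "d", "a"),
                                     weight = c(1, 4, 1, 4)))
  for (m in c("mlf", "nc")) {
    pv <- edge_pvalues(cyc, m)
    expect_true(all(pv$p[pv$weight == 4] < pv$p[pv$weight == 1]), label = m)
  }
})
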