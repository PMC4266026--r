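# The code selection algorithm's individual steps (frozen expected values
# from direct arithmetic) and its invariants: ranges, per-CM normalization,
# softmax consistency, familiarity correctness, fixed operation count.

test_that("input normalization clamps to [0, 1] with the lower-bound divisor", {
  expect_equal(normalize_input(762, lo = 5), 1)           # 762/635 clamped
  expect_equal(normalize_input(762, lo = 9), 762 / (9 * 127))
  expect_equal(normalize_input(0, lo = 5), 0)
  # level > 1: denominator min(lo, star) * Q * w_max
  expect_equal(normalize_input(1143, lo = 1, star = 2, Q = 9, level = 2), 1)
  expect_equal(normalize_input(600, lo = 2, star = 1, Q = 9, level = 2),
               600 / (1 * 9 * 127))
  # no active non-muddled features: everything is zero
  expect_equal(normalize_input(c(500, 100), lo = 1, star = 0, Q = 9, level = 2),
               c(0, 0))
})

test_that("local support multiplies available evidence and respects t = 0", {
  p <- csa_params()
  expect_equal(local_support(U = 1, H = 1, D = 1, t = 1, params = p), 1)
  expect_equal(local_support(U = 1, H = 0, D = 1, t = 1, params = p), 0)
  expect_equal(local_support(U = 0.8, t = 0, params = p), 0.8)
  expect_equal(local_support(U = 0.9, H = 0.5, t = 1, params = p), 0.45)
  p2 <- csa_params(lambda_U = function(t) ifelse(t == 0, 1, 2))
  expect_equal(local_support(U = 0.5, H = 1, t = 3, params = p2), 0.25)
})

test_that("competing-hypothesis tally uses a strict threshold and rounds", {
  cm <- rep(1:4, each = 4)
  V <- rep(0, 16)
  V[c(1, 2, 5, 6, 9, 10, 13, 14)] <- 1    # two maximal cells per CM
  expect_identical(count_mch(V, cm)$zeta, 2L)
  V2 <- rep(0, 16); V2[c(1, 5, 9, 13)] <- 1
  expect_identical(count_mch(V2, cm)$zeta, 1L)
  # zeta_q = (3,2,2,2): mean 2.25 rounds to 2
  V3 <- rep(0, 16); V3[c(1, 2, 3, 5, 6, 9, 10, 13, 14)] <- 1
  res <- count_mch(V3, cm)
  expect_identical(res$zeta_q, c(3L, 2L, 2L, 2L))
  expect_identical(res$zeta, 2L)
  # strictly-at-threshold cells do not count
  expect_identical(count_mch(rep(csa_params()$V_zeta, 16), cm)$zeta, 0L)
})

test_that("MCH factor boosts small tie counts and mutes muddled macs", {
  expect_equal(mch_factor(1), 1)
  expect_equal(mch_factor(2), 2 ^ 0.7)
  expect_equal(mch_factor(5), 0)          # beyond the default cutoff B = 4
  expect_equal(mch_factor(0), 0)          # no signal from an inactive source
  expect_equal(mch_factor(2, csa_params(mch_boost = FALSE)), 1)
})

test_that("per-CM hard max preserves ties and the familiarity is their mean", {
  cm <- rep(1:2, each = 3)
  hm <- cm_hard_max(c(0.2, 0.9, 0.4, 1, 1, 0.3), cm)
  expect_equal(hm$V_hat, c(0.9, 1))
  expect_identical(hm$argmax[[1]], 2L)
  expect_identical(hm$argmax[[2]], c(4L, 5L))
  hm0 <- cm_hard_max(rep(0, 6), cm)
  expect_identical(hm0$argmax[[1]], 1:3)
  expect_equal(familiarity_G(c(1, 1, 0.5, 0.5)), 0.75)
  expect_equal(familiarity_G(rep(0, 9)), 0)
})

test_that("sigmoid range and shape follow the familiarity modulation", {
  p <- csa_params(G_floor = 0.2, gamma = 2, chi = 1)
  expect_equal(sigmoid_range(0.1, K = 100, p), 1)     # below the floor
  expect_equal(sigmoid_range(0.2, K = 100, p), 1)
  expect_equal(sigmoid_range(0.6, K = 100, p), 26)    # 1 + 0.25 * 100
  expect_equal(sigmoid_range(1, K = 100, p), 101)     # 1 + chi * K
  # eta = 1 collapses psi to the constant function
  expect_equal(v_to_psi(c(0, 0.5, 1), eta = 1), rep(1, 3))
  # logistic midpoint: V at the inflection gives (eta + 1) / 2
  p3 <- csa_params()
  expect_equal(v_to_psi(p3$sigma3, eta = 11, p3), 6)
  # saturation toward eta
  p4 <- csa_params(sigma2 = 1000)
  expect_equal(v_to_psi(1, eta = 50, p4), 50, tolerance = 1e-6)
  expect_true(all(diff(v_to_psi(seq(0, 1, 0.1), eta = 20)) >= 0))
})

test_that("psi normalizes to win probabilities that sum to one per CM", {
  cm7 <- rep(1L, 7)
  expect_equal(psi_to_rho(rep(3, 7), cm7), rep(1 / 7, 7))
  expect_equal(psi_to_rho(c(300, rep(1, 6)), cm7)[1], 300 / 306)
  expect_equal(psi_to_rho(c(30, rep(1, 6)), cm7)[1], 5 / 6)
  # property: sums are exactly 1 in every CM for random psi
  set.seed(4)
  for (i in 1:20) {
    Q <- sample(2:8, 1); K <- sample(2:9, 1)
    cm <- rep(seq_len(Q), each = K)
    rho <- psi_to_rho(1 + runif(Q * K) * 100, cm)
    expect_equal(as.numeric(tapply(rho, cm, sum)), rep(1, Q), tolerance = 1e-12)
  }
})

test_that("softmax draws match their distribution and are seed-reproducible", {
  cm <- rep(1:2, each = 4)
  one_hot <- c(0, 0, 1, 0, 0, 1, 0, 0)
  expect_identical(draw_winners(one_hot, cm, rng = 1), c(3L, 6L))
  expect_identical(draw_winners(one_hot, cm, rng = 99), c(3L, 6L))
  # empirical frequencies within 3 standard errors of rho
  rho <- psi_to_rho(c(8, 4, 2, 1, 1, 1, 1, 1), rep(1L, 8))
  set.seed(10)
  n <- 6000
  draws <- replicate(n, draw_winners(rho, rep(1L, 8)))
  freq <- tabulate(draws, 8) / n
  se <- sqrt(rho * (1 - rho) / n)
  expect_true(all(abs(freq - rho) <= 3 * se + 1e-9))
  # identical seed, identical code
  expect_identical(draw_winners(rho, rep(1L, 8), rng = 7),
                   draw_winners(rho, rep(1L, 8), rng = 7))
})

test_that("familiarity is 1 on a stored moment and 0 on a disjoint one", {
  items <- make_items(3, seed = 9)
  cfg <- item_config(Q = 9, K = 4)
  fit <- seq_memory(make_seq(items, c(1, 2)), cfg, seed = 3)
  net <- fit$network
  # re-present the stored first moment
  tr <- recognize_sequence(net, make_seq(items, 1), mode = "simple", seed = 1)
  expect_equal(tr$frames[[1]][[1]]$G, 1)
  # disjoint input in a blank-crosstalk mac: familiarity 0
  tr2 <- recognize_sequence(net, make_seq(items, 3), mode = "simple", seed = 1)
  expect_equal(tr2$frames[[1]][[1]]$G, 0)
  # exact repeat of the stored two-frame moment sequence reinstates both codes
  tr3 <- recognize_sequence(net, make_seq(items, c(1, 2)), mode = "simple",
                            seed = 1)
  expect_identical(trace_code(tr3, 1), trace_code(fit$traces[[1]], 1))
  expect_identical(trace_code(tr3, 2), trace_code(fit$traces[[1]], 2))
})

test_that("the first frame of a blank network draws uniformly at random", {
  cfg <- single_mac_config(Q = 9, K = 4)
  seqs <- gen_random_sequences(1, 1, seed = 21)
  net <- build_network(cfg)
  reset_state(net)
  net$prev <- lapply(net$macs, function(m) list(active = FALSE))
  tick_persistence(net)
  st <- csa_step(net, net$macs[[1]], seqs[[1]]$frames[[1]], 0,
                 mode = "learning", rng = 3)
  expect_equal(st$G, 0)
  expect_equal(st$eta, 1)
  expect_equal(st$rho, rep(1 / 4, 36))   # uniform over every CM
  st2 <- csa_step(net, net$macs[[1]], seqs[[1]]$frames[[1]], 0,
                  mode = "learning", rng = 3)
  expect_identical(st$code, st2$code)    # reproducibility contract
})

test_that("ranges hold throughout learning: U,H,V,G in [0,1], psi in [1,eta]", {
  cfg <- single_mac_config(Q = 9, K = 8)
  seqs <- gen_random_sequences(3, 10, seed = 31)
  fit <- seq_memory(seqs, cfg, seed = 31)
  net <- fit$network
  probe <- gen_random_sequences(1, 5, seed = 77)[[1]]
  reset_state(net)
  net$prev <- lapply(net$macs, function(m) list(active = FALSE))
  for (t1 in seq_along(probe$frames)) {
    prev <- lapply(net$macs, function(m)
      list(active = m$active, code = m$code, zeta = m$zeta))
    net$prev <- prev
    tick_persistence(net)
    st <- csa_step(net, net$macs[[1]], probe$frames[[t1]], t1 - 1L,
                   mode = "learning", prev = prev, rng = t1)
    expect_true(all(st$U >= 0 & st$U <= 1))
    if (!is.null(st$H)) expect_true(all(st$H >= 0 & st$H <= 1))
    expect_true(all(st$V >= 0 & st$V <= 1))
    expect_true(st$G >= 0 && st$G <= 1)
    expect_true(st$eta >= 1)
    psi <- v_to_psi(st$V, st$eta)
    expect_true(all(psi >= 1 - 1e-12 & psi <= st$eta + 1e-12))
    m <- net$macs[[1]]
    m$active <- TRUE; m$code <- st$code; m$age <- 0L; m$zeta <- st$zeta
  }
})

test_that("operation count is identical after storing 1 vs 50 codes", {
  ops_after <- function(S) {
    seqs <- gen_random_sequences(S, 10, seed = 3)
    fit <- seq_memory(seqs, single_mac_config(Q = 9, K = 8), seed = 3)
    net <- fit$network
    probe <- gen_random_sequences(1, 1, seed = 99)[[1]]
    reset_state(net)
    net$prev <- lapply(net$macs, function(m) list(active = FALSE))
    tick_persistence(net)
    csa_step(net, net$macs[[1]], probe$frames[[1]], 0,
             mode = "learning", rng = 1)$ops
  }
  expect_identical(ops_after(1), ops_after(5))   # 10 vs 50 stored codes
})

test_that("codes assigned to similar inputs intersect more (SISC trend)", {
  b <- bench_sisc(n_levels = 6, n_reps = 12, seed = 5)
  # intersection should fall as the ladder level rises (overlap falls)
  ct <- suppressWarnings(stats::cor.test(b$level, b$intersection,
                                         method = "spearman"))
  expect_lt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
  agg <- aggregate(intersection ~ overlap, b, mean)
  expect_gt(agg$intersection[nrow(agg)], agg$intersection[1])  # 100% vs 0% overlap
})
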