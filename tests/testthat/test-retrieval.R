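# Retrieval: exact-match completeness, the back-off policy walk, time-warp
# catch-up through a persisting higher-level code, and multiple-competing-
# hypothesis disambiguation.

test_that("back-off walks the variant precedence and stops at its threshold", {
  pol <- backoff_policy()
  cm <- rep(1:2, each = 2)
  perfect <- c(1, 0, 1, 0)
  weak <- c(0.1, 0, 0.1, 0)
  # full 3-way match: a single evaluation suffices
  sel <- backoff_select(list(U = perfect, H = perfect, D = perfect), pol, 1, cm)
  expect_identical(sel$variant, "HUD")
  expect_identical(sel$n_evaluated, 1L)
  expect_equal(sel$G, 1)
  # H disagrees (a deleted frame): 2-way U-D match is accepted next
  sel2 <- backoff_select(list(U = perfect, H = weak, D = perfect), pol, 1, cm)
  expect_identical(sel2$variant, "UD")
  expect_equal(sel2$G, 1)
  # everything weak: the terminal U-only variant is used
  sel3 <- backoff_select(list(U = weak, H = weak, D = weak), pol, 1, cm)
  expect_identical(sel3$variant, "U")
  # evaluations are bounded by the fixed policy length
  expect_lte(sel3$n_evaluated, length(pol$order))
  # unavailable sources restrict the usable variants (first frame: U only)
  sel4 <- backoff_select(list(U = perfect, H = NULL, D = NULL), pol, 0, cm)
  expect_identical(sel4$variant, "U")
  expect_identical(sel4$n_evaluated, 1L)
  expect_error(evaluate_G_variant(list(U = perfect), character(0), 0, cm),
               "empty")
})

test_that("exact-match recall of stored sequences is perfect in simple mode", {
  # single stored sequence: always perfect
  seqs <- gen_random_sequences(1, 10, seed = 13)
  fit <- seq_memory(seqs, single_mac_config(Q = 9, K = 4), seed = 13)
  pred <- predict(fit, mode = "simple")
  expect_equal(pred$accuracy$R_star, 100)
  expect_equal(pred$accuracy$R_omega, 100)
  # the whole trace matches frame by frame, deterministically
  tr <- predict(fit, mode = "simple")$traces[[1]]
  for (t1 in seq_along(tr$frames)) {
    expect_identical(trace_code(tr, t1), trace_code(fit$traces[[1]], t1))
  }
})

test_that("a deleted frame is caught up via back-off under a persisting chunk", {
  items <- make_items(4, seed = 42)
  both <- make_seq(items, 1:4, label = "BOTH")
  bth <- make_seq(items, c(1, 3, 4), label = "BTH")   # second frame deleted
  fit <- seq_memory(both, two_level_config(), seed = 5)
  lt <- fit$traces[[1]]
  # exact duplicate: the whole two-level trace replays without back-off
  dup <- recognize_sequence(fit$network, both, mode = "simple", seed = 9)
  for (t1 in 1:4) for (mac in 1:2) {
    expect_identical(trace_code(dup, t1, mac), trace_code(lt, t1, mac))
    expected_variant <- if (t1 == 1) "U" else if (mac == 1) "HUD" else "HU"
    expect_identical(dup$frames[[t1]][[mac]]$variant, expected_variant)
  }
  # warped instance: at the deleted position the level-1 mac backs off from
  # the 3-way to the 2-way U-D criterion and the entire internal state
  # advances to the learning trace's next frame
  tr <- recognize_sequence(fit$network, bth, mode = "simple", seed = 9)
  expect_identical(tr$frames[[2]][[1]]$variant, "UD")
  for (mac in 1:2) {
    expect_identical(trace_code(tr, 1, mac), trace_code(lt, 1, mac))
    expect_identical(trace_code(tr, 2, mac), trace_code(lt, 3, mac))  # caught up
    expect_identical(trace_code(tr, 3, mac), trace_code(lt, 4, mac))
  }
  # final-frame accuracy of the warped presentation is perfect
  expect_equal(frame_accuracy(lt$frames[[4]], tr$frames[[3]]), 100)
})

test_that("an ambiguous prompt is disambiguated by the next item", {
  # two contexts share their middle item; prompting with it alone activates
  # a blend of both stored codes (an MCH state), and the following item
  # settles the mac on the right stored code.
  # simple retrieval: reinstatement with certainty, and the MCH state is
  # detected at the prompt frame
  runs <- lapply(1:5, mch_run, boost = TRUE, mode = "simple")
  for (r in runs) expect_equal(r$sim, 1)
  # the MCH state is detected at the prompt frame in most runs (chance code
  # overlap between the two stored contexts occasionally collapses the tie)
  expect_gte(sum(vapply(runs, `[[`, numeric(1), "zeta") >= 2), 4)
  # the boost strictly improves accuracy under the stochastic (learning-mode)
  # competition, where the H evidence actually enters the draw
  sims_on <- vapply(1:40, function(s) mch_run(s, TRUE, "learning")$sim,
                    numeric(1))
  sims_off <- vapply(1:40, function(s) mch_run(s, FALSE, "learning")$sim,
                     numeric(1))
  expect_gt(mean(sims_on), mean(sims_off))
})

test_that("retrieval rejects mismatched input geometry", {
  fit <- seq_memory(gen_random_sequences(1, 3, seed = 1),
                    single_mac_config(), seed = 1)
  bad <- gen_random_sequences(1, 3, grid = c(6, 6), active_range = c(3, 5),
                              seed = 1)[[1]]
  expect_error(recognize_sequence(fit$network, bad), "input error")
})
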