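# Effectively binary synapses: the age/permanence weight table, correlation
# and decay dynamics, saturation accounting, and the critical-period freeze.

test_that("weight table honours the plateau/decay/permanence constraints", {
  ws <- weight_schedule()
  # age zero always maps to the maximum weight
  expect_true(all(weight_lookup(rep(0L, 3), 0:2, ws) == 127L))
  # maximum permanence pins the weight at the maximum forever
  expect_equal(weight_lookup(ws$sigma_max, ws$theta_max, ws), 127L)
  # monotone non-increasing in age for every permanence row
  for (th in 0:ws$theta_max) {
    expect_true(all(diff(ws$table[, th + 1L]) <= 0))
  }
  # plateau window strictly increases with permanence
  expect_true(all(diff(ws$T_sigma) > 0))
  # full decay reaches zero for non-permanent synapses
  expect_equal(weight_lookup(ws$sigma_max, 0L, ws), 0L)
  expect_equal(weight_lookup(ws$T_sigma[1] + 1L, 0L, ws) < 127L, TRUE)
  expect_error(weight_lookup(ws$sigma_max + 1L, 0L, ws), "range")
  # CSV export/import round trip
  f <- tempfile(fileext = ".csv")
  write_weight_schedule_csv(ws, f)
  expect_identical(unname(read_weight_schedule_csv(f)), unname(t(ws$table)))
})

test_that("correlations reset age and escalate permanence within the window", {
  ws <- weight_schedule()
  p <- sdcmem:::new_projection(2, 2, ws)
  # first-ever correlation from the blank state: weight jumps to 127,
  # permanence untouched
  apply_correlation(p, 1, 1, ws)
  expect_identical(p$sigma[1, 1], 0L)
  expect_identical(p$theta[1, 1], 0L)
  expect_identical(weight_lookup(p$sigma[1, 1], p$theta[1, 1], ws), 127L)
  # repeat within the window: permanence 0 -> 1
  p$sigma[1, 1] <- ws$T_sigma[1]
  apply_correlation(p, 1, 1, ws)
  expect_identical(p$theta[1, 1], 1L)
  expect_identical(p$sigma[1, 1], 0L)
  # repeat after the window: age resets but permanence unchanged
  p$sigma[1, 1] <- ws$T_sigma[2] + 1L
  apply_correlation(p, 1, 1, ws)
  expect_identical(p$theta[1, 1], 1L)
  expect_identical(p$sigma[1, 1], 0L)
  # permanence never decreases and caps at theta_max
  p$theta[1, 1] <- ws$theta_max
  p$sigma[1, 1] <- 5L
  apply_correlation(p, 1, 1, ws)
  expect_identical(p$theta[1, 1], ws$theta_max)
  # frozen projection is a no-op
  before <- p$sigma
  p$sigma[2, 2] <- 50L
  apply_correlation(p, 2, 2, ws, frozen = TRUE)
  expect_identical(p$sigma[2, 2], 50L)
})

test_that("ages advance once per frame and permanent synapses stay young", {
  ws <- weight_schedule()
  p <- sdcmem:::new_projection(2, 1, ws)
  p$sigma[] <- c(0L, ws$sigma_max)
  age_tick(p, ws)
  expect_identical(as.vector(p$sigma), c(1L, ws$sigma_max))  # +1 and capped
  expect_identical(weight_lookup(p$sigma[1, 1], 0L, ws), 127L)  # still on plateau
  p$theta[2, 1] <- ws$theta_max
  p$sigma[2, 1] <- 3L
  age_tick(p, ws)
  expect_identical(p$sigma[2, 1], 0L)  # pinned at age zero
})

test_that("saturation counts potentiated weights over existing synapses", {
  cfg <- memory_config(input = c(12, 12),
                       levels = list(level_spec(Q = 9, K = 4, pi_u = c(6, 6))))
  net <- build_network(cfg)
  ws <- cfg$schedule
  expect_equal(saturation(net$macs[[1]]$proj_U, ws), 0)
  # one stored code with 6 active pixels: 6*9 potentiated of 144*36
  fr <- sdcmem:::new_frame_sequence(c(12, 12), list(sort(sample(144, 6))), "f")
  fit <- seq_memory(fr, network = net, seed = 1)
  expect_equal(saturation(net$macs[[1]]$proj_U, ws), 54 / 5184)
  p <- sdcmem:::new_projection(3, 3, ws)
  p$sigma[] <- 0L
  expect_equal(saturation(p, ws), 1)
})

test_that("freezing is any-matrix, irreversible, and stops all afferent change", {
  ws <- weight_schedule()
  cfg <- item_config(Q = 9, K = 4)
  net <- build_network(cfg)
  m <- net$macs[[1]]
  expect_false(check_freeze(m, 0.8, ws))
  # saturate one H matrix above threshold: the whole mac freezes
  m$proj_H[[1]]$sigma[] <- 0L
  expect_true(check_freeze(m, 0.8, ws))
  expect_true(m$frozen)
  m$proj_H[[1]]$sigma[] <- ws$sigma_max  # even if saturation later drops...
  expect_true(check_freeze(m, 0.8, ws))  # ...freezing is permanent
})

test_that("afferent synapses are bitwise unchanged by training after freeze", {
  cfg <- single_mac_config(Q = 9, K = 4, freeze_threshold = 0.0005)
  seqs <- gen_random_sequences(3, 10, seed = 2)
  fit <- seq_memory(seqs[1], cfg, seed = 2)
  expect_true(fit$network$macs[[1]]$frozen)
  synap <- function(net) lapply(network_state(net)$macs,
                                function(m) m[c("U", "H", "D")])
  snap <- synap(fit$network)
  invisible(seq_memory(seqs[2:3], network = fit$network, seed = 3))
  expect_identical(synap(fit$network), snap)
})

test_that("weights are effectively binary after a training run", {
  fit <- seq_memory(gen_random_sequences(2, 10, seed = 5),
                    single_mac_config(Q = 9, K = 4), seed = 5)
  w <- coef(fit)[[1]]
  ws <- fit$network$config$schedule
  # short run: every weight is either still blank (0) or freshly potentiated
  # (on the 127 plateau); a correlation always leaves the weight at exactly 127
  expect_true(all(w$U %in% c(0L, 127L)))
  expect_true(all(w$H[[1]] %in% c(0L, 127L)))
})
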