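# Shared fixtures: item alphabets with controlled overlap, small letter-style
# sequences, and the two-level configuration used for the time-warp studies.

# n_items disjoint items of n_px pixels each on the grid
make_items <- function(n_items, n_px = 9, grid = c(12, 12), seed = 1) {
  set.seed(seed)
  px <- sample(prod(grid), n_items * n_px)
  lapply(split(px, rep(seq_len(n_items), each = n_px)), sort)
}

make_seq <- function(items, idx, grid = c(12, 12), label = "") {
  sdcmem:::new_frame_sequence(grid, lapply(idx, function(i) items[[i]]), label)
}

# single mac over the full 12x12 input, gate bounds equal to the item size
item_config <- function(Q, K, n_px = 9, ...) {
  memory_config(input = c(12, 12),
                levels = list(level_spec(Q = Q, K = K, pi_u = c(n_px, n_px))),
                ...)
}

# two internal levels, one mac each, persistence 1 then 2 (chunking)
two_level_config <- function(n_px = 9, ...) {
  memory_config(input = c(12, 12),
                levels = list(level_spec(Q = 9, K = 4, pi_u = c(n_px, n_px)),
                              level_spec(Q = 6, K = 4, pi_u = c(1, 1))),
                ...)
}

trace_code <- function(trace, t1, mac = 1) trace$frames[[t1]][[mac]]$code

# ambiguous-prompt scenario: two stored contexts share their middle item;
# prompt with [middle, third] and score the second frame against the code of
# the matching stored moment
mch_run <- function(s, boost, mode) {
  items <- make_items(5, seed = s * 7 + 1)
  abc <- make_seq(items, c(1, 2, 3), label = "ABC")
  dbe <- make_seq(items, c(4, 2, 5), label = "DBE")
  bc <- make_seq(items, c(2, 3), label = "BC")
  cfg <- item_config(Q = 9, K = 8, csa = csa_params(mch_boost = boost))
  fit <- seq_memory(list(abc, dbe), cfg, seed = s)
  phi_abc <- trace_code(fit$traces[[1]], 3)
  net <- clone_network(fit$network)
  tr <- recognize_sequence(net, bc, mode = mode, seed = s + 5000)
  list(sim = code_similarity(phi_abc, trace_code(tr, 2)),
       zeta = tr$frames[[1]][[1]]$zeta)
}
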