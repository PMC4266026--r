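# Study drivers: repeated seeded runs of the noisy best-match retrieval
# protocol (train S random 10-frame sequences once each, test pixel-relocated
# versions in simple retrieval mode) and of the similar-inputs-to-similar-codes
# overlap-ladder protocol.

#' Single-mac model configuration for the retrieval studies
#'
#' One internal level with one mac of Q CMs by K cells over a pixel grid; the
#' activation bounds equal the generator's active-pixel range so every frame
#' gates the mac on and the lower bound is the normalizer.
#'
#' @param Q,K Mac geometry.
#' @param grid Input pixel grid.
#' @param active_range Per-frame active-pixel range of the input protocol.
#' @param ... Passed to [memory_config()].
#' @return A [memory_config()].
#' @export
single_mac_config <- function(Q = 9, K = 4, grid = c(12, 12),
                              active_range = c(9, 12), ...) {
  memory_config(input = grid,
                levels = list(level_spec(Q = Q, K = K, pi_u = active_range)),
                ...)
}

#' Noisy best-match retrieval benchmark
#'
#' For each replicate: build a fresh blank single-mac model, generate S random
#' sequences (10 frames, 9-12 active pixels by default), store each once in
#' learning mode, relocate `noise_pixels` pixels in every frame, and recognize
#' the noisy versions in simple retrieval mode with back-off. Reports the
#' whole-trace accuracy R* and final-frame accuracy R^Omega (percent, averaged
#' over sequences) per replicate.
#'
#' @param K Cells per CM.
#' @param S Sequences stored per replicate.
#' @param noise_pixels Pixels relocated per test frame.
#' @param n_reps Replicates.
#' @param seed Integer base seed.
#' @param Q CMs per mac.
#' @param n_frames Frames per sequence.
#' @param grid Pixel grid.
#' @param active_range Active pixels per frame.
#' @param mode Retrieval mode.
#' @return A data frame (one row per replicate) with columns `rep`, `R_star`,
#'   `R_omega`, plus a `"summary"` attribute with means and standard
#'   deviations.
#' @export
#' @examples
#' \donttest{
#' b <- bench_noisy_recall(K = 4, S = 2, noise_pixels = 1, n_reps = 5, seed = 1)
#' attr(b, "summary")
#' }
bench_noisy_recall <- function(K = 4, S = 2, noise_pixels = 1, n_reps = 25,
                               seed = 1L, Q = 9, n_frames = 10,
                               grid = c(12, 12), active_range = c(9, 12),
                               mode = "simple") {
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    rep_seed <- substream_seed(seed, r, 0L, 0L)
    seqs <- gen_random_sequences(S, n_frames, grid = grid,
                                 active_range = active_range, seed = rep_seed)
    fit <- seq_memory(seqs, single_mac_config(Q = Q, K = K, grid = grid,
                                              active_range = active_range),
                      seed = rep_seed)
    noisy <- lapply(seq_along(seqs), function(i) {
      perturb_sequence(seqs[[i]], noise_pixels,
                       seed = substream_seed(rep_seed, i, 1L, 0L))
    })
    pred <- predict(fit, newdata = noisy, mode = mode,
                    seed = substream_seed(rep_seed, 0L, 2L, 0L))
    rows[[r]] <- data.frame(rep = r, R_star = mean(pred$accuracy$R_star),
                            R_omega = mean(pred$accuracy$R_omega))
  }
  out <- do.call(rbind, rows)
  if (n_reps > 0) {
    attr(out, "summary") <- data.frame(
      K = K, S = S, noise_pixels = noise_pixels, n_reps = n_reps,
      R_star_mean = mean(out$R_star), R_star_sd = stats::sd(out$R_star),
      R_omega_mean = mean(out$R_omega), R_omega_sd = stats::sd(out$R_omega))
  }
  out
}

#' Similar-inputs-to-similar-codes benchmark
#'
#' For each replicate and each overlap level: build a fresh single-mac model
#' (Q = 25, K = 9 by default), store the reference sequence [A, X], then store
#' the ladder sequence [A_i, X] whose first frame overlaps A by a decreasing
#' fraction, and record the per-CM intersection of the code assigned to the
#' second frame with the code originally assigned to [A, X]'s second frame.
#' More similar spatiotemporal inputs should receive more similar codes.
#'
#' @param n_levels Overlap levels in the ladder.
#' @param n_reps Replicates.
#' @param seed Integer base seed.
#' @param Q,K Mac geometry.
#' @param grid Pixel grid.
#' @param n_active Active pixels per frame.
#' @return A data frame with one row per (replicate, level): columns `rep`,
#'   `level`, `overlap` (input overlap fraction), `intersection` (code cells
#'   in common with the reference, of Q). Attribute `"spearman"` holds the
#'   Spearman rank correlation test of intersection against overlap.
#' @export
bench_sisc <- function(n_levels = 6, n_reps = 50, seed = 1L, Q = 25, K = 9,
                       grid = c(12, 12), n_active = 12) {
  cfg <- single_mac_config(Q = Q, K = K, grid = grid,
                           active_range = c(n_active, n_active))
  rows <- list()
  for (r in seq_len(n_reps)) {
    rep_seed <- substream_seed(seed, r, 0L, 1L)
    ladder <- gen_overlap_ladder(grid, n_levels, n_active, seed = rep_seed)
    overlaps <- attr(ladder, "overlap")
    for (i in seq_len(n_levels)) {
      fit <- seq_memory(ladder[[1]], cfg, seed = rep_seed)        # learn [A,X]
      ref_code <- fit$traces[[1]]$frames[[2]][[1]]$code
      fit2 <- seq_memory(ladder[[i]], network = fit$network,      # then [Ai,X]
                         seed = substream_seed(rep_seed, i, 7L, 0L))
      code_i <- fit2$traces[[1]]$frames[[2]][[1]]$code
      rows[[length(rows) + 1L]] <- data.frame(
        rep = r, level = i - 1L, overlap = overlaps[i],
        intersection = sum(ref_code == code_i))
    }
  }
  out <- do.call(rbind, rows)
  if (length(unique(out$overlap)) > 1) {
    attr(out, "spearman") <- suppressWarnings(
      stats::cor.test(out$overlap, out$intersection, method = "spearman"))
  }
  out
}
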