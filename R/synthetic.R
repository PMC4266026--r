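# Synthetic input generators for the study protocols: random binary-frame
# sequences with controlled active-pixel counts, pixel-relocation noise,
# time-warp (deletion/repetition) variants, overlap ladders for the
# similar-inputs-to-similar-codes study, and multi-aperture frames for
# hierarchical models. Every generator is deterministic given its seed.

new_frame_sequence <- function(grid, frames, label = "") {
  structure(list(grid = as.integer(grid), frames = frames,
                 label = as.character(label)),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  cat(sprintf("frame_sequence '%s': %d frame(s) on a %dx%d grid, %s active pixels/frame\n",
              x$label, length(x$frames), x$grid[1], x$grid[2],
              paste(range(lengths(x$frames)), collapse = "-")))
  invisible(x)
}

#' Generate random binary frame sequences
#'
#' Each frame activates a uniformly drawn number of pixels (without
#' replacement) in the given range -- the random-sequence protocol of the
#' best-match retrieval study (12x12 grids, 9-12 active pixels per frame).
#'
#' @param n_seq Number of sequences.
#' @param n_frames Frames per sequence.
#' @param grid `c(rows, cols)` pixel grid.
#' @param active_range `c(lo, hi)` active pixels per frame.
#' @param seed Integer seed.
#' @return List of `frame_sequence` objects (frames are integer vectors of
#'   1-based row-major active-pixel indices).
#' @export
gen_random_sequences <- function(n_seq, n_frames, grid = c(12, 12),
                                 active_range = c(9, 12), seed = 1L) {
  n_px <- prod(grid)
  if (active_range[2] > n_px) {
    stop("input error: active_range exceeds the grid capacity", call. = FALSE)
  }
  set.seed(as.integer(seed))
  lapply(seq_len(n_seq), function(s) {
    frames <- lapply(seq_len(n_frames), function(t1) {
      n_on <- if (active_range[1] == active_range[2]) active_range[1] else
        sample(active_range[1]:active_range[2], 1L)
      if (n_on == 0) integer(0) else sort(sample.int(n_px, n_on))
    })
    new_frame_sequence(grid, frames, label = sprintf("rand-%d", s))
  })
}

#' Relocate pixels in every frame (noise model)
#'
#' "Changing" a pixel relocates it: one active pixel is switched off and one
#' inactive pixel switched on, so each changed pixel yields two pixel-level
#' differences while the active count is preserved exactly.
#'
#' @param fseq A `frame_sequence`.
#' @param n_changed Pixels relocated per frame.
#' @param seed Integer seed.
#' @return A perturbed `frame_sequence`.
#' @export
#' @examples
#' s <- gen_random_sequences(1, 3, seed = 1)[[1]]
#' p <- perturb_sequence(s, 1, seed = 2)
#' length(setdiff(union(s$frames[[1]], p$frames[[1]]),
#'                intersect(s$frames[[1]], p$frames[[1]])))  # 2
perturb_sequence <- function(fseq, n_changed, seed = 1L) {
  stopifnot(inherits(fseq, "frame_sequence"))
  if (n_changed == 0) return(fseq)
  n_px <- prod(fseq$grid)
  set.seed(as.integer(seed))
  frames <- lapply(fseq$frames, function(fr) {
    off_pool <- setdiff(seq_len(n_px), fr)
    if (length(fr) < n_changed || length(off_pool) < n_changed) {
      stop("input error: frame too small to relocate ", n_changed, " pixel(s)",
           call. = FALSE)
    }
    drop <- fr[sample.int(length(fr), n_changed)]
    add <- off_pool[sample.int(length(off_pool), n_changed)]
    sort(c(setdiff(fr, drop), add))
  })
  new_frame_sequence(fseq$grid, frames,
                     label = paste0(fseq$label, sprintf("+noise%d", n_changed)))
}

#' Time-warp a sequence by frame deletion / repetition
#'
#' @param fseq A `frame_sequence`.
#' @param schedule Integer vector, one multiplicity per frame: 0 deletes the
#'   frame (speed-up), 1 keeps it, `n > 1` presents it `n` times (slow-down).
#'   `NULL` is the identity.
#' @return The warped `frame_sequence`.
#' @export
#' @examples
#' s <- gen_random_sequences(1, 4, seed = 1)[[1]]
#' length(warp_sequence(s, c(1, 0, 1, 1))$frames)   # 3: second frame deleted
#' length(warp_sequence(s, rep(2, 4))$frames)       # 8: uniform half speed
warp_sequence <- function(fseq, schedule = NULL) {
  stopifnot(inherits(fseq, "frame_sequence"))
  if (is.null(schedule)) return(fseq)
  if (length(schedule) != length(fseq$frames)) {
    stop("input error: schedule length must equal the frame count", call. = FALSE)
  }
  frames <- fseq$frames[rep(seq_along(fseq$frames), times = schedule)]
  new_frame_sequence(fseq$grid, frames, label = paste0(fseq$label, "+warp"))
}

#' Overlap ladder for the similar-inputs-to-similar-codes study
#'
#' Builds 2-frame sequences that all share the same second frame while the
#' first frame's pixel overlap with the first sequence's opening frame
#' decreases strictly from 100% to 0% across the ladder.
#'
#' @param grid `c(rows, cols)` pixel grid.
#' @param n_levels Number of overlap levels (>= 2).
#' @param n_active Active pixels per frame.
#' @param seed Integer seed.
#' @return List of `frame_sequence` objects with attribute `"overlap"` (the
#'   realized pairwise overlap fractions with the first item).
#' @export
gen_overlap_ladder <- function(grid = c(12, 12), n_levels = 6, n_active = 12,
                               seed = 1L) {
  stopifnot(n_levels >= 2)
  n_px <- prod(grid)
  set.seed(as.integer(seed))
  A <- sort(sample.int(n_px, n_active))
  X <- sort(sample.int(n_px, n_active))
  fracs <- seq(1, 0, length.out = n_levels)
  seqs <- vector("list", n_levels)
  realized <- numeric(n_levels)
  for (i in seq_len(n_levels)) {
    n_keep <- round(fracs[i] * n_active)
    keep <- if (n_keep > 0) sample(A, n_keep) else integer(0)
    pool <- setdiff(seq_len(n_px), A)
    fresh <- if (n_keep < n_active) sample(pool, n_active - n_keep) else integer(0)
    item <- sort(c(keep, fresh))
    realized[i] <- length(intersect(item, A)) / n_active
    seqs[[i]] <- new_frame_sequence(grid, list(item, X),
                                    label = sprintf("ladder-%d", i - 1L))
  }
  attr(seqs, "overlap") <- realized
  seqs
}

#' Multi-aperture frames for hierarchical models
#'
#' Builds frames on an aperture-tiled grid in which a chosen number of
#' apertures carry a gate-eligible pixel count and the rest carry too few to
#' activate their level-1 mac.
#'
#' @param n_frames Number of frames.
#' @param grid `c(rows, cols)` pixel grid (default 24x24).
#' @param aperture `c(rows, cols)` aperture shape (default 6x6).
#' @param n_eligible Apertures per frame given an eligible count (scalar or
#'   vector over frames).
#' @param eligible_range `c(lo, hi)` active pixels in an eligible aperture.
#' @param ineligible_max Maximum active pixels in an ineligible aperture
#'   (drawn from `0:ineligible_max`, always below `eligible_range[1]`).
#' @param seed Integer seed.
#' @return A `frame_sequence`.
#' @export
gen_hierarchical_frames <- function(n_frames, grid = c(24, 24),
                                    aperture = c(6, 6), n_eligible,
                                    eligible_range = c(5, 7),
                                    ineligible_max = eligible_range[1] - 1L,
                                    seed = 1L) {
  if (any(grid %% aperture != 0)) {
    stop("input error: apertures must tile the grid exactly", call. = FALSE)
  }
  ag <- grid %/% aperture
  n_ap <- prod(ag)
  n_eligible <- rep_len(n_eligible, n_frames)
  stopifnot(all(n_eligible <= n_ap), ineligible_max < eligible_range[1])
  # 1-based row-major pixel indices of each aperture
  ap_pixels <- list()
  for (r in seq_len(ag[1])) for (cc in seq_len(ag[2])) {
    rows <- ((r - 1L) * aperture[1] + 1L):(r * aperture[1])
    cols <- ((cc - 1L) * aperture[2] + 1L):(cc * aperture[2])
    ap_pixels[[length(ap_pixels) + 1L]] <-
      as.integer(outer((rows - 1L) * grid[2], cols, "+"))
  }
  set.seed(as.integer(seed))
  frames <- lapply(seq_len(n_frames), function(t1) {
    elig <- sample.int(n_ap, n_eligible[t1])
    px <- integer(0)
    for (a in seq_len(n_ap)) {
      n_on <- if (a %in% elig) {
        sample(eligible_range[1]:eligible_range[2], 1L)
      } else if (ineligible_max > 0) {
        sample(0:ineligible_max, 1L)
      } else 0L
      if (n_on > 0) px <- c(px, sample(ap_pixels[[a]], n_on))
    }
    sort(px)
  })
  new_frame_sequence(grid, frames, label = "hier")
}

#' Read / write sequences in the JSON interchange format
#'
#' The file holds `{"grid": [rows, cols], "sequences": [{"label": ...,
#' "frames": [[i, ...], ...]}, ...]}` with 0-based row-major pixel indices
#' (the in-memory representation is 1-based).
#'
#' @param x A `frame_sequence` or list of them (for writing).
#' @param path File path.
#' @return `write_sequences` returns `path` invisibly; `read_sequences`
#'   returns a list of `frame_sequence` objects.
#' @export
write_sequences <- function(x, path) {
  if (inherits(x, "frame_sequence")) x <- list(x)
  grid <- x[[1]]$grid
  obj <- list(grid = grid,
              sequences = lapply(x, function(s) {
                list(label = s$label,
                     frames = lapply(s$frames, function(f) as.integer(f - 1L)))
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sequences
#' @export
read_sequences <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  grid <- as.integer(unlist(obj$grid))
  lapply(obj$sequences, function(s) {
    frames <- lapply(s$frames, function(f) sort(as.integer(unlist(f)) + 1L))
    new_frame_sequence(grid, frames, label = s$label)
  })
}
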