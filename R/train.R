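# Sequence processing driver and the user-facing model interface.
# seq_memory() stores a set of binary frame sequences with single-trial
# Hebbian learning; predict() recognizes test sequences against the stored
# learning traces.

frame_pixels <- function(fseq, t1) fseq$frames[[t1]]

# process one frame through the whole hierarchy (bottom-up), updating mac
# activation state in place; returns the per-mac trace records
process_frame <- function(net, active_pixels, t, mode, seed, seq_idx) {
  learn <- mode == "learning"
  prev <- lapply(net$macs, function(m)
    list(active = m$active, code = m$code, zeta = m$zeta))
  net$prev <- prev
  tick_persistence(net)

  records <- vector("list", length(net$macs))
  for (l in seq_len(net$L)) {
    for (gi in as.integer(net$level_index[[l]])) {
      m <- net$macs[[gi]]
      pi_u <- if (m$u_type == "pixels") {
        sum(m$u_src %in% active_pixels)
      } else {
        sum(vapply(m$u_src, function(i) net$macs[[i]]$active, logical(1)))
      }
      in_bounds <- pi_u >= m$pi_u[1] && pi_u <= m$pi_u[2]
      if (learn && m$persisting) {
        # persistence trumps the activation criteria during learning:
        # the code is held unchanged for its full duration
        records[[gi]] <- list(active = TRUE, code = m$code, G = m$G,
                              zeta = m$zeta, eta = NA_real_,
                              variant = m$variant, new = FALSE, ops = 0L)
        next
      }
      eligible <- in_bounds || (!learn && m$persisting)
      if (!eligible) {
        m$active <- FALSE; m$code <- NULL; m$age <- 0L; m$zeta <- 0L
        m$G <- NA_real_; m$variant <- NA_character_
        records[[gi]] <- list(active = FALSE)
        next
      }
      st <- csa_step(net, m, active_pixels, t, mode = mode,
                     prev = prev, rng = substream_seed(seed, seq_idx, t, gi))
      m$active <- TRUE; m$code <- st$code; m$age <- 0L
      m$zeta <- st$zeta; m$G <- st$G; m$variant <- st$variant
      if (learn && !m$frozen) m$stored_code_count <- m$stored_code_count + 1L
      records[[gi]] <- list(active = TRUE, code = st$code, G = st$G,
                            zeta = st$zeta, eta = st$eta, variant = st$variant,
                            new = TRUE, ops = st$ops)
    }
  }

  if (learn) {
    sched <- net$config$schedule
    for (m in net$macs) {
      if (m$frozen) next
      age_tick(m$proj_U, sched)
      for (p in m$proj_H) age_tick(p, sched)
      for (p in m$proj_D) age_tick(p, sched)
    }
    for (m in net$macs) {
      if (!m$active || m$frozen) next
      pre_u <- if (m$u_type == "pixels") {
        which(m$u_src %in% active_pixels)
      } else {
        unlist(lapply(seq_along(m$u_src), function(k) {
          src <- net$macs[[m$u_src[k]]]
          if (src$active) m$u_offsets[k] + src$code else integer(0)
        }))
      }
      apply_correlation(m$proj_U, pre_u, m$code, sched)
      for (k in seq_along(m$h_src)) {
        ps <- prev[[m$h_src[k]]]
        if (!is.null(ps) && ps$active) {
          apply_correlation(m$proj_H[[k]], ps$code, m$code, sched)
        }
      }
      for (k in seq_along(m$d_src)) {
        ps <- prev[[m$d_src[k]]]
        if (!is.null(ps) && ps$active) {
          apply_correlation(m$proj_D[[k]], ps$code, m$code, sched)
        }
      }
    }
    for (m in net$macs) {
      if (!m$frozen && check_freeze(m, net$config$freeze_threshold, sched)) {
        net$freeze_log <- c(net$freeze_log,
                            sprintf("mac %d frozen at global frame %d",
                                    m$idx, net$global_frame))
      }
    }
  }
  records
}

#' Process one sequence through the network
#'
#' Presents the frames of one sequence in order, running the code selection
#' algorithm in every eligible mac at every frame. In `"learning"` mode the
#' chosen codes are stored by Hebbian correlation and persistence holds codes
#' for their full duration; in the retrieval modes (`"probabilistic"` with
#' back-off softmax, `"simple"` with back-off hard max) plasticity is off and
#' codes are re-selected every frame so the internal state can keep pace with
#' time-warped inputs.
#'
#' @param net A built network (modified in place in learning mode).
#' @param fseq A frame sequence (see [gen_random_sequences()]).
#' @param mode One of "learning", "probabilistic", "simple".
#' @param seed Integer run seed.
#' @param seq_idx Index of this sequence within the run (feeds the per-mac
#'   random substreams).
#' @return An object of class `sdc_trace`: per-frame, per-mac records of the
#'   chosen code, familiarity G, the variant used, and the MCH count.
#' @export
recognize_sequence <- function(net, fseq, mode = c("simple", "probabilistic",
                                                   "learning"),
                               seed = 1L, seq_idx = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(fseq, "frame_sequence"))
  if (!all(fseq$grid == net$input_grid)) {
    stop("input error: frame grid ", paste(fseq$grid, collapse = "x"),
         " does not match the network input grid", call. = FALSE)
  }
  reset_state(net)
  if (is.null(net$global_frame)) net$global_frame <- 0L
  frames <- vector("list", length(fseq$frames))
  for (t1 in seq_along(fseq$frames)) {
    net$global_frame <- net$global_frame + 1L
    frames[[t1]] <- process_frame(net, fseq$frames[[t1]], t = t1 - 1L,
                                  mode = mode, seed = seed, seq_idx = seq_idx)
  }
  structure(list(label = fseq$label, frames = frames,
                 n_macs = length(net$macs), mode = mode),
            class = "sdc_trace")
}

#' Store binary frame sequences in a sparse-coding memory
#'
#' The fitting function: builds the network described by `config` (or takes an
#' already-built one) and presents each sequence once, in order, in learning
#' mode -- single-trial storage. The returned object carries the trained
#' network and the learning traces (the sequence of codes assigned to every
#' mac at every frame), against which later recognitions are scored.
#'
#' @param x A frame sequence or list of frame sequences (see
#'   [gen_random_sequences()], [read_sequences()]).
#' @param config A [memory_config()]; ignored if `network` is supplied.
#' @param network Optionally, an existing network to continue training.
#' @param seed Integer seed governing all winner draws.
#' @return An object of class `seq_memory` with components `network`,
#'   `traces` (list of `sdc_trace`), `sequences`, `seed`.
#' @seealso [predict.seq_memory()], [bench_noisy_recall()]
#' @export
#' @examples
#' cfg <- memory_config(input = c(12, 12),
#'                      levels = list(level_spec(Q = 9, K = 4, pi_u = c(9, 12))))
#' seqs <- gen_random_sequences(2, 10, grid = c(12, 12),
#'                              active_range = c(9, 12), seed = 7)
#' fit <- seq_memory(seqs, cfg, seed = 7)
#' pred <- predict(fit)
#' pred$accuracy
seq_memory <- function(x, config = NULL, network = NULL, seed = 1L) {
  if (inherits(x, "frame_sequence")) x <- list(x)
  stopifnot(all(vapply(x, inherits, logical(1), "frame_sequence")))
  net <- if (!is.null(network)) network else build_network(config)
  net$global_frame <- if (is.null(net$global_frame)) 0L else net$global_frame
  traces <- vector("list", length(x))
  for (i in seq_along(x)) {
    traces[[i]] <- recognize_sequence(net, x[[i]], mode = "learning",
                                      seed = seed, seq_idx = i)
  }
  structure(list(network = net, traces = traces, sequences = x,
                 seed = as.integer(seed), call = match.call()),
            class = "seq_memory")
}

#' Recognize sequences against a trained memory
#'
#' Runs each test sequence through the trained network in a retrieval mode and
#' scores the resulting memory trace against the corresponding learning trace
#' frame by frame (normalized code intersection, averaged over the macs active
#' during learning).
#'
#' @param object A fitted [seq_memory()].
#' @param newdata Test sequences; defaults to the training sequences
#'   (exact-match recognition). When scoring, `newdata[[i]]` is compared to
#'   the learning trace of training sequence `i`.
#' @param mode `"simple"` (back-off hard max, deterministic given the seed) or
#'   `"probabilistic"` (back-off softmax).
#' @param ref Reference traces to score against (default: the stored learning
#'   traces). `NULL` skips scoring.
#' @param seed Integer seed for retrieval draws/tie-breaks.
#' @param ... Unused.
#' @return An object of class `seq_memory_pred`: `traces`, `accuracy` (data
#'   frame with per-sequence whole-trace accuracy `R_star` and final-frame
#'   accuracy `R_omega`, in percent), and `R_t` (per-frame percent accuracies,
#'   sequences in rows).
#' @export
predict.seq_memory <- function(object, newdata = object$sequences,
                               mode = c("simple", "probabilistic"),
                               ref = object$traces, seed = object$seed, ...) {
  mode <- match.arg(mode)
  if (inherits(newdata, "frame_sequence")) newdata <- list(newdata)
  net <- object$network
  traces <- vector("list", length(newdata))
  for (i in seq_along(newdata)) {
    traces[[i]] <- recognize_sequence(net, newdata[[i]], mode = mode,
                                      seed = seed, seq_idx = i)
  }
  out <- list(traces = traces, mode = mode, seed = seed)
  if (!is.null(ref)) {
    if (length(ref) != length(traces)) {
      stop("number of test sequences does not match the reference traces",
           call. = FALSE)
    }
    acc <- lapply(seq_along(traces), function(i)
      trace_accuracy(ref[[i]], traces[[i]]))
    out$accuracy <- data.frame(
      seq = seq_along(traces),
      R_star = vapply(acc, `[[`, numeric(1), "R_star"),
      R_omega = vapply(acc, `[[`, numeric(1), "R_omega"))
    nt <- max(vapply(acc, function(a) length(a$R_t), integer(1)))
    out$R_t <- t(vapply(acc, function(a) {
      c(a$R_t, rep(NA_real_, nt - length(a$R_t)))
    }, numeric(nt)))
  }
  class(out) <- "seq_memory_pred"
  out
}

#' @export
print.seq_memory <- function(x, ...) {
  net <- x$network
  cw <- count_weights(net)
  cat("Sparse distributed coding sequence memory\n")
  cat(sprintf("  input grid: %dx%d pixels; %d internal level(s), %d mac(s)\n",
              net$input_grid[1], net$input_grid[2], net$L, length(net$macs)))
  cat(sprintf("  units: %d   synapses: %d\n", count_units(net), cw$total))
  cat(sprintf("  stored: %d sequence(s), %d frame(s)\n",
              length(x$sequences),
              sum(vapply(x$sequences, function(s) length(s$frames), integer(1)))))
  invisible(x)
}

#' @export
print.seq_memory_pred <- function(x, ...) {
  cat(sprintf("Recognition (%s retrieval mode)\n", x$mode))
  if (!is.null(x$accuracy)) {
    print(x$accuracy, row.names = FALSE)
    cat(sprintf("  mean R* = %.1f%%   mean R^Omega = %.1f%%\n",
                mean(x$accuracy$R_star), mean(x$accuracy$R_omega)))
  }
  invisible(x)
}

#' @export
summary.seq_memory <- function(object, ...) {
  net <- object$network
  sched <- net$config$schedule
  macs <- lapply(net$macs, function(m) {
    data.frame(mac = m$idx, level = m$level,
               Q = m$Q, K = m$K,
               stored_codes = m$stored_code_count,
               sat_U = saturation(m$proj_U, sched),
               sat_H = max(vapply(m$proj_H, saturation, numeric(1),
                                  schedule = sched)),
               frozen = m$frozen)
  })
  G_vals <- unlist(lapply(object$traces, function(tr)
    lapply(tr$frames, function(fr)
      lapply(fr, function(r) if (isTRUE(r$active)) r$G else NULL))))
  out <- list(macs = do.call(rbind, macs), G = summary(G_vals),
              n_sequences = length(object$sequences),
              freeze_log = net$freeze_log)
  class(out) <- "summary.seq_memory"
  out
}

#' @export
print.summary.seq_memory <- function(x, ...) {
  cat("Per-mac storage state:\n")
  print(x$macs, row.names = FALSE, digits = 3)
  cat("\nFamiliarity G over all learning frames:\n")
  print(x$G)
  if (length(x$freeze_log)) cat("\nFreeze events:\n ",
                                paste(x$freeze_log, collapse = "\n  "), "\n")
  invisible(x)
}

#' Extract derived synaptic weight matrices
#'
#' @param object A fitted [seq_memory()].
#' @param ... Unused.
#' @return A list, one element per mac, each with the `U` weight matrix and
#'   lists of `H` and `D` weight matrices (integer, 0-127).
#' @export
coef.seq_memory <- function(object, ...) {
  net <- object$network
  sched <- net$config$schedule
  lapply(net$macs, function(m) {
    list(U = proj_weights(m$proj_U, sched),
         H = lapply(m$proj_H, proj_weights, schedule = sched),
         D = lapply(m$proj_D, proj_weights, schedule = sched))
  })
}

#' Plot pairwise code intersections of a mac's learning trace
#'
#' Shows the pairwise per-CM intersection counts of all codes assigned to one
#' mac over all stored frames -- the block structure reveals how distinct the
#' stored moments are (diagonal = Q).
#'
#' @param x A fitted [seq_memory()].
#' @param mac Global mac index (default 1).
#' @param ... Passed to [graphics::image()].
#' @return The intersection matrix, invisibly.
#' @export
plot.seq_memory <- function(x, mac = 1L, ...) {
  codes <- list()
  for (tr in x$traces) for (fr in tr$frames) {
    r <- fr[[mac]]
    if (isTRUE(r$active)) codes[[length(codes) + 1L]] <- r$code
  }
  if (length(codes) < 2) stop("mac has fewer than two stored codes", call. = FALSE)
  im <- intersection_matrix(codes)
  n <- nrow(im)
  graphics::image(seq_len(n), seq_len(n), im[, n:1, drop = FALSE],
                  xlab = "code (storage order)", ylab = "code",
                  main = sprintf("Pairwise code intersections, mac %d", mac),
                  ...)
  invisible(im)
}

#' Simulate recognition draws from a trained memory
#'
#' Repeatedly runs probabilistic retrieval with fresh seeds, returning one set
#' of memory traces per simulation -- the model's stochastic response
#' distribution to the given inputs.
#'
#' @param object A fitted [seq_memory()].
#' @param nsim Number of simulated recognition runs.
#' @param seed Base seed.
#' @param newdata Sequences to present (default: training sequences).
#' @param ... Unused.
#' @return A list of length `nsim` of `seq_memory_pred` objects.
#' @export
simulate.seq_memory <- function(object, nsim = 1, seed = object$seed,
                                newdata = object$sequences, ...) {
  lapply(seq_len(nsim), function(i) {
    predict(object, newdata = newdata, mode = "probabilistic",
            seed = seed + i - 1L)
  })
}

#' Write a memory trace as JSON lines
#'
#' One JSON object per (frame, mac) with the familiarity G, the MCH count,
#' the sigmoid range, the familiarity variant used, and the winning cells.
#'
#' @param trace An `sdc_trace` (or list of them).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trace_jsonl <- function(trace, path) {
  if (inherits(trace, "sdc_trace")) trace <- list(trace)
  con <- file(path, "w")
  on.exit(close(con))
  for (si in seq_along(trace)) {
    tr <- trace[[si]]
    for (t1 in seq_along(tr$frames)) {
      for (mi in seq_along(tr$frames[[t1]])) {
        r <- tr$frames[[t1]][[mi]]
        rec <- list(seq = si, frame = t1 - 1L, mac = mi,
                    active = isTRUE(r$active))
        if (isTRUE(r$active)) {
          rec <- c(rec, list(G = r$G, zeta = r$zeta, eta = r$eta,
                             variant = r$variant, winners = r$code))
        }
        writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                    null = "null"), con)
      }
    }
  }
  invisible(path)
}
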