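# Network construction: levels of macs, each a grid of Q competitive modules
# (CMs) of K cells, wired with bottom-up (U), horizontal (H) and top-down (D)
# projections. Synapse state (age sigma, permanence theta) lives in
# environments so learning can update it in place; use network_state() for a
# plain-data snapshot and clone_network() for an independent copy.

new_projection <- function(n_pre, n_post, schedule, mask = NULL) {
  e <- new.env(parent = emptyenv())
  e$sigma <- matrix(schedule$sigma_max, n_pre, n_post)
  e$theta <- matrix(0L, n_pre, n_post)
  storage.mode(e$sigma) <- "integer"
  e$mask <- mask  # NULL = all pairs exist; else logical n_pre x n_post
  e
}

proj_n_synapses <- function(proj) {
  if (is.null(proj$mask)) length(proj$sigma) else sum(proj$mask)
}

proj_weights <- function(proj, schedule) {
  w <- weight_lookup(proj$sigma, proj$theta, schedule)
  if (!is.null(proj$mask)) w[!proj$mask] <- 0L
  w
}

# aperture tiling: dims of the subjacent layer divided by this level's grid
infer_aperture <- function(sub_dims, grid, what) {
  if (any(sub_dims %% grid != 0)) {
    stop("configuration error: ", what, " (", sub_dims[1], "x", sub_dims[2],
         ") is not tiled exactly by a ", grid[1], "x", grid[2], " mac grid",
         call. = FALSE)
  }
  as.integer(sub_dims %/% grid)
}

#' Build a hierarchical sparse-coding memory network
#'
#' Instantiates every mac, competitive module and projection described by the
#' configuration. U projections are all-to-all from every source unit in a
#' mac's aperture to every one of its cells (all cells of a mac share the same
#' receptive fields); recurrent H projections connect every cell to every cell
#' in *other* CMs of each neighborhood mac (within-CM pairs of the same mac are
#' excluded unless configured otherwise); D projections are all-to-all from
#' every cell of each superjacent parent mac. All synapses start blank
#' (age `sigma_max`, permanence 0, i.e. weight 0). The structure is a
#' deterministic function of the configuration.
#'
#' @param config A [memory_config()].
#' @return An object of class `sdc_network`. Note the synapse state is held by
#'   reference: training functions modify it in place.
#' @seealso [count_units()], [count_weights()], [network_state()]
#' @export
#' @examples
#' cfg <- memory_config(input = c(12, 12),
#'                      levels = list(level_spec(Q = 9, K = 4, pi_u = c(9, 12))))
#' net <- build_network(cfg)
#' count_units(net)   # 144 pixels + 36 cells
build_network <- function(config) {
  stopifnot(inherits(config, "memory_config"))
  L <- length(config$levels)
  schedule <- config$schedule
  in_rows <- config$input[1]; in_cols <- config$input[2]
  n_pixels <- in_rows * in_cols

  macs <- list()
  level_index <- vector("list", L)  # matrix of global mac indices per level
  gidx <- 0L
  for (l in seq_len(L)) {
    spec <- config$levels[[l]]
    gr <- spec$grid
    idxmat <- matrix(0L, gr[1], gr[2])
    for (r in seq_len(gr[1])) for (cc in seq_len(gr[2])) {
      gidx <- gidx + 1L
      idxmat[r, cc] <- gidx
      m <- new.env(parent = emptyenv())
      m$level <- l; m$row <- r - 1L; m$col <- cc - 1L; m$idx <- gidx
      m$Q <- spec$Q; m$K <- spec$K; m$Z <- spec$Q * spec$K
      m$delta <- spec$delta; m$pi_u <- spec$pi_u
      m$pi_h_lo <- spec$pi_h_lo; m$pi_d_lo <- spec$pi_d_lo
      m$cm_of <- rep(seq_len(spec$Q), each = spec$K)  # CM of each cell
      m$frozen <- FALSE
      m$stored_code_count <- 0L
      macs[[gidx]] <- m
    }
    level_index[[l]] <- idxmat
  }

  # wiring
  for (l in seq_len(L)) {
    spec <- config$levels[[l]]
    gr <- spec$grid
    if (l == 1L) {
      ap <- if (is.null(spec$u_rf)) infer_aperture(config$input, gr, "input grid") else spec$u_rf
      if (!all(ap * gr == config$input)) {
        stop("configuration error: aperture ", ap[1], "x", ap[2],
             " does not tile the input grid", call. = FALSE)
      }
    } else {
      sub_grid <- config$levels[[l - 1L]]$grid
      ap <- if (is.null(spec$u_rf)) infer_aperture(sub_grid, gr, "subjacent mac grid") else spec$u_rf
      if (!all(ap * gr == sub_grid)) {
        stop("configuration error: U-RF ", ap[1], "x", ap[2],
             " does not tile the subjacent level", call. = FALSE)
      }
    }
    for (r in seq_len(gr[1])) for (cc in seq_len(gr[2])) {
      m <- macs[[level_index[[l]][r, cc]]]
      if (l == 1L) {
        rows <- ((r - 1L) * ap[1] + 1L):(r * ap[1])
        cols <- ((cc - 1L) * ap[2] + 1L):(cc * ap[2])
        # row-major pixel indices
        m$u_type <- "pixels"
        m$u_src <- as.integer(outer((rows - 1L) * in_cols, cols, "+"))
        m$proj_U <- new_projection(length(m$u_src), m$Z, schedule)
      } else {
        rows <- ((r - 1L) * ap[1] + 1L):(r * ap[1])
        cols <- ((cc - 1L) * ap[2] + 1L):(cc * ap[2])
        m$u_type <- "macs"
        m$u_src <- as.integer(t(level_index[[l - 1L]][rows, cols, drop = FALSE]))
        n_pre <- sum(vapply(m$u_src, function(i) macs[[i]]$Z, integer(1)))
        m$proj_U <- new_projection(n_pre, m$Z, schedule)
        # offsets of each source mac's cells within the projection rows
        zs <- vapply(m$u_src, function(i) macs[[i]]$Z, integer(1))
        m$u_offsets <- c(0L, cumsum(zs))[seq_along(zs)]
      }
      # horizontal neighborhood: own mac plus macs within Manhattan radius
      hr <- spec$h_radius
      hs <- integer(0)
      for (r2 in seq_len(gr[1])) for (c2 in seq_len(gr[2])) {
        if (abs(r2 - r) + abs(c2 - cc) <= hr) hs <- c(hs, level_index[[l]][r2, c2])
      }
      hs <- c(m$idx, setdiff(hs, m$idx))  # self first
      m$h_src <- hs
      m$proj_H <- lapply(hs, function(s) {
        src <- macs[[s]]
        mask <- NULL
        if (s == m$idx && !config$h_include_own_cm) {
          mask <- outer(src$cm_of, m$cm_of, "!=")
        }
        new_projection(src$Z, m$Z, schedule, mask = mask)
      })
      m$d_src <- integer(0)
      m$proj_D <- list()
    }
  }
  # top-down: parents are the superjacent macs whose U-RF contains this mac
  for (l in seq_len(L)) {
    if (l == L) next
    for (gi in as.integer(level_index[[l]])) {
      m <- macs[[gi]]
      parents <- Filter(function(p) gi %in% macs[[p]]$u_src,
                        as.integer(level_index[[l + 1L]]))
      m$d_src <- as.integer(parents)
      m$proj_D <- lapply(m$d_src, function(s) {
        new_projection(macs[[s]]$Z, m$Z, schedule)
      })
    }
  }

  net <- new.env(parent = emptyenv())
  net$config <- config
  net$macs <- macs
  net$level_index <- level_index
  net$L <- L
  net$n_pixels <- n_pixels
  net$input_grid <- config$input
  reset_state(net)
  class(net) <- "sdc_network"
  net
}

# clear all dynamic (per-sequence) activation state; synapses untouched
reset_state <- function(net) {
  for (m in net$macs) {
    m$active <- FALSE
    m$code <- NULL       # integer vector length Q of cell indices
    m$age <- 0L          # code age (frames since activation)
    m$zeta <- 0L
    m$G <- NA_real_
    m$variant <- NA_character_
    m$persisting <- FALSE
  }
  invisible(net)
}

#' Count units in a network
#'
#' Input pixels plus all internal cells.
#'
#' @param net An [build_network()] result (or `NULL`, counting 0).
#' @return Integer unit count.
#' @export
count_units <- function(net) {
  if (is.null(net) || length(net$macs) == 0) return(0L)
  net$n_pixels + sum(vapply(net$macs, function(m) m$Z, integer(1)))
}

#' Count synapses in a network
#'
#' Sums synapse counts over every U, H and D projection (masked within-CM
#' horizontal pairs are not counted). For a single-mac, single-internal-level
#' model this equals `P*Z + Z*(Z - K)` with `P` input pixels and `Z = Q*K`.
#'
#' @param net A built network.
#' @return A list with `by_projection` (data frame: mac, kind, source, n) and
#'   `total`.
#' @export
count_weights <- function(net) {
  rows <- list()
  for (m in net$macs) {
    rows[[length(rows) + 1L]] <- data.frame(
      mac = m$idx, kind = "U", source = 0L, n = proj_n_synapses(m$proj_U))
    for (k in seq_along(m$h_src)) {
      rows[[length(rows) + 1L]] <- data.frame(
        mac = m$idx, kind = "H", source = m$h_src[k],
        n = proj_n_synapses(m$proj_H[[k]]))
    }
    for (k in seq_along(m$d_src)) {
      rows[[length(rows) + 1L]] <- data.frame(
        mac = m$idx, kind = "D", source = m$d_src[k],
        n = proj_n_synapses(m$proj_D[[k]]))
    }
  }
  by <- do.call(rbind, rows)
  list(by_projection = by, total = sum(by$n))
}

#' Advance persistence clocks
#'
#' Increments the code age of every active mac; codes whose age reaches the
#' level's persistence expire (the mac becomes eligible for new code
#' selection), while younger codes persist unchanged. During learning,
#' persistence trumps the activation bounds: a persisting mac stays active
#' regardless of how many features are in its receptive field.
#'
#' @param net A built network with activation state.
#' @return The network, invisibly. Each mac's `persisting` flag tells whether
#'   its current code is being held for this frame.
#' @export
tick_persistence <- function(net) {
  for (m in net$macs) {
    if (m$active) {
      m$age <- m$age + 1L
      m$persisting <- m$age < m$delta
    } else {
      m$persisting <- FALSE
    }
  }
  invisible(net)
}

#' Snapshot the full synaptic state of a network
#'
#' Returns a plain-data (copy) representation: the per-projection age and
#' permanence matrices, freeze flags and a configuration echo. Two builds from
#' the same configuration produce identical snapshots; [save_network()] writes
#' this structure to JSON.
#'
#' @param net A built network.
#' @return A nested list.
#' @export
network_state <- function(net) {
  list(
    format = "sdcmem-network-v1",
    config = config_to_list(net$config),
    macs = lapply(net$macs, function(m) {
      list(level = m$level, row = m$row, col = m$col,
           frozen = m$frozen, stored_code_count = m$stored_code_count,
           U = list(sigma = m$proj_U$sigma, theta = m$proj_U$theta),
           H = lapply(m$proj_H, function(p) list(sigma = p$sigma, theta = p$theta)),
           D = lapply(m$proj_D, function(p) list(sigma = p$sigma, theta = p$theta)))
    })
  )
}

#' Deep-copy a network
#'
#' @param net A built network.
#' @return An independent network with identical synaptic state.
#' @export
clone_network <- function(net) {
  net2 <- build_network(net$config)
  restore_synapses(net2, network_state(net))
  net2
}

restore_synapses <- function(net, state) {
  as_int_mat <- function(x, like) {
    m <- as.matrix(x); storage.mode(m) <- "integer"; dim(m) <- dim(like); m
  }
  for (i in seq_along(net$macs)) {
    m <- net$macs[[i]]; s <- state$macs[[i]]
    m$frozen <- isTRUE(s$frozen)
    m$stored_code_count <- as.integer(s$stored_code_count)
    m$proj_U$sigma <- as_int_mat(s$U$sigma, m$proj_U$sigma)
    m$proj_U$theta <- as_int_mat(s$U$theta, m$proj_U$theta)
    for (k in seq_along(m$proj_H)) {
      m$proj_H[[k]]$sigma <- as_int_mat(s$H[[k]]$sigma, m$proj_H[[k]]$sigma)
      m$proj_H[[k]]$theta <- as_int_mat(s$H[[k]]$theta, m$proj_H[[k]]$theta)
    }
    for (k in seq_along(m$proj_D)) {
      m$proj_D[[k]]$sigma <- as_int_mat(s$D[[k]]$sigma, m$proj_D[[k]]$sigma)
      m$proj_D[[k]]$theta <- as_int_mat(s$D[[k]]$theta, m$proj_D[[k]]$theta)
    }
  }
  invisible(net)
}

#' Save / load a network's synaptic state as JSON
#'
#' Weights are never stored: they are always derived from the age and
#' permanence integers via the weight schedule, so the round trip is exact.
#'
#' @param net A built network.
#' @param path File path (plain-text JSON).
#' @return `save_network` returns `path` invisibly; `load_network` returns a
#'   rebuilt network.
#' @export
save_network <- function(net, path) {
  jsonlite::write_json(network_state(net), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  state <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = TRUE,
                               simplifyDataFrame = FALSE)
  config <- config_from_list(state$config)
  net <- build_network(config)
  restore_synapses(net, state)
  net
}

config_to_list <- function(config) {
  if (is.function(config$csa$lambda_U)) {
    stop("a configuration with a lambda_U schedule function cannot be serialized",
         call. = FALSE)
  }
  list(
    input = config$input,
    levels = lapply(config$levels, function(s) {
      list(grid = s$grid, Q = s$Q, K = s$K, delta = s$delta, pi_u = s$pi_u,
           pi_h_lo = s$pi_h_lo, pi_d_lo = s$pi_d_lo, u_rf = s$u_rf,
           h_radius = s$h_radius)
    }),
    csa = unclass(config$csa),
    schedule = list(table = config$schedule$table,
                    T_sigma = config$schedule$T_sigma,
                    sigma_max = config$schedule$sigma_max,
                    theta_max = config$schedule$theta_max,
                    w_max = config$schedule$w_max),
    backoff = list(order = config$backoff$order,
                   thresholds = as.list(config$backoff$thresholds)),
    freeze_threshold = config$freeze_threshold,
    h_include_own_cm = config$h_include_own_cm
  )
}

config_from_list <- function(x) {
  csa <- do.call(csa_params, x$csa[setdiff(names(x$csa), "w_max")])
  sched_tab <- as.matrix(x$schedule$table)
  storage.mode(sched_tab) <- "integer"
  schedule <- structure(list(table = sched_tab,
                             T_sigma = as.integer(x$schedule$T_sigma),
                             sigma_max = as.integer(x$schedule$sigma_max),
                             theta_max = as.integer(x$schedule$theta_max),
                             w_max = as.integer(x$schedule$w_max)),
                        class = "weight_schedule")
  thr <- unlist(x$backoff$thresholds)
  backoff <- backoff_policy(order = unlist(x$backoff$order), thresholds = thr)
  levels <- lapply(x$levels, function(s) {
    # jsonlite round-trips Inf as the string "Inf"; as.numeric recovers it
    pu <- as.numeric(unlist(s$pi_u)); if (length(pu) == 0) pu <- c(1, Inf)
    level_spec(grid = unlist(s$grid), Q = s$Q, K = s$K, delta = s$delta,
               pi_u = pu, pi_h_lo = s$pi_h_lo, pi_d_lo = s$pi_d_lo,
               u_rf = if (is.null(s$u_rf)) NULL else unlist(s$u_rf),
               h_radius = s$h_radius)
  })
  memory_config(input = unlist(x$input), levels = levels, csa = csa,
                schedule = schedule, backoff = backoff,
                freeze_threshold = x$freeze_threshold,
                h_include_own_cm = isTRUE(x$h_include_own_cm))
}
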