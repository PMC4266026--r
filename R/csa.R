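# The code selection algorithm (CSA): each frame, each active mac converts its
# bottom-up (U), horizontal (H) and top-down (D) inputs into a sparse
# distributed code -- one winner per competitive module (CM) -- in a fixed
# number of operations, independent of how many codes the mac has stored.
# Phase 1 (steps 1-7) computes the familiarity G of the mac's overall input;
# phase 2 (steps 8-12) runs a G-modulated softmax competition in each CM.

#' Mac activation gate
#'
#' A mac becomes (or stays) active if its current code is still within its
#' persistence window, or if the number of active features in its bottom-up
#' receptive field lies within the activation bounds.
#'
#' @param pi_u Number of active features in the mac's U receptive field
#'   (pixels at level 1, active macs at higher levels).
#' @param bounds `c(lo, hi)` activation bounds (hi may be `Inf`).
#' @param age Code age in frames (frames since the current code activated,
#'   after this frame's persistence tick).
#' @param delta Persistence in frames.
#' @return Logical.
#' @export
#' @examples
#' gate_mac(6, c(5, 7))          # in bounds -> TRUE
#' gate_mac(8, c(5, 7))          # out of bounds -> FALSE
#' gate_mac(0, c(5, 7), age = 1, delta = 2)  # persisting code -> TRUE
gate_mac <- function(pi_u, bounds, age = Inf, delta = 1) {
  (age < delta) || (pi_u >= bounds[1] && pi_u <= bounds[2])
}

#' Normalize a raw input summation to [0, 1]
#'
#' The denominator uses the *lower* feature-count bound so that inputs with
#' different numbers of active features compete on an equal footing; values are
#' hard-limited (clamped) to 1. At level 1 the afferent features are single
#' pixels; at higher levels each feature is a mac represented by Q co-active
#' cells, so the denominator scales by Q, and muddled source macs are excluded
#' from the effective feature count (`star`).
#'
#' @param x Raw summation vector (one entry per cell).
#' @param lo Lower activation bound on the feature count.
#' @param star Number of active, non-muddled features (levels > 1).
#' @param Q Cells per afferent feature (levels > 1).
#' @param level Level of the receiving mac (1 = first internal level).
#' @param w_max Maximum synaptic weight.
#' @return Normalized values in `[0, 1]`; all zero when `star == 0`.
#' @export
#' @examples
#' normalize_input(762, lo = 5)                    # clamped to 1
#' normalize_input(1143, lo = 1, star = 2, Q = 9, level = 2)
normalize_input <- function(x, lo, star = NULL, Q = NULL, level = 1,
                            w_max = 127L) {
  if (level == 1) {
    denom <- lo * w_max
  } else {
    if (is.null(star) || star == 0) return(rep(0, length(x)))
    denom <- min(lo, star) * Q * w_max
  }
  if (denom <= 0) return(rep(0, length(x)))
  pmin(1, x / denom)
}

#' Local evidential support V for each cell
#'
#' Multiplies the (exponentiated) normalized inputs that are available at this
#' moment. On the first frame of a sequence only the bottom-up input exists;
#' an omitted source (`NULL`) contributes a factor of 1, which is how the
#' retrieval back-off relaxes the match criterion.
#'
#' @param U,H,D Normalized input vectors (H and/or D may be `NULL`).
#' @param t Frame index within the sequence (0-based).
#' @param params [csa_params()].
#' @return Support values `V` in `[0, 1]` per cell.
#' @export
local_support <- function(U, H = NULL, D = NULL, t = 0, params = csa_params()) {
  if (t == 0) return(U ^ lambda_U_at(params, 0))
  V <- U ^ lambda_U_at(params, t)
  if (!is.null(H)) V <- V * H ^ params$lambda_H
  if (!is.null(D)) V <- V * D ^ params$lambda_D
  V
}

# round to nearest integer, halves up (deterministic, unlike round())
rni <- function(x) floor(x + 0.5)

#' Count maximally competing hypotheses
#'
#' Tallies, per competitive module, the cells whose support strictly exceeds
#' the tolerance threshold `V_zeta`, and averages (rounded to the nearest
#' integer) over the mac's CMs to give the number of tied hypotheses zeta.
#'
#' @param V Support vector over the mac's cells.
#' @param cm_of Integer vector giving each cell's CM.
#' @param params [csa_params()].
#' @return List with `zeta_q` (per-CM counts) and `zeta` (mac-level count).
#' @export
count_mch <- function(V, cm_of, params = csa_params()) {
  zeta_q <- as.integer(tapply(V > params$V_zeta, cm_of, sum))
  list(zeta_q = zeta_q, zeta = as.integer(rni(mean(zeta_q))))
}

#' Multiple-competing-hypotheses correction factor
#'
#' Efferent signals from a mac with `zeta` tied hypotheses are boosted by
#' `zeta^A` while `1 <= zeta <= B`; a "muddled" mac (`zeta > B`) is ignored
#' entirely (factor 0). `zeta = 0` (no signal) also yields 0.
#'
#' @param zeta Number of maximally active hypotheses in the source mac.
#' @param params [csa_params()].
#' @return The factor `F(zeta)`.
#' @export
#' @examples
#' mch_factor(1)  # 1
#' mch_factor(2)  # 2^0.7
#' mch_factor(5)  # 0 with the default cutoff B = 4
mch_factor <- function(zeta, params = csa_params()) {
  if (zeta < 1) return(0)
  if (zeta > params$B) return(0)
  if (!params$mch_boost) return(1)
  zeta ^ params$A
}

#' Hard max per competitive module
#'
#' @param V Support vector over the mac's cells.
#' @param cm_of Integer vector giving each cell's CM.
#' @return List with `V_hat` (per-CM maximum) and `argmax` (list of the cell
#'   indices attaining it; ties preserved).
#' @export
cm_hard_max <- function(V, cm_of) {
  Q <- max(cm_of)
  V_hat <- as.numeric(tapply(V, cm_of, max))
  argmax <- lapply(seq_len(Q), function(q) {
    idx <- which(cm_of == q)
    idx[V[idx] == V_hat[q]]
  })
  list(V_hat = V_hat, argmax = argmax)
}

#' Familiarity of the mac's overall input
#'
#' The mean of the per-CM maximum supports. G = 1 means the current moment
#' exactly matches a stored moment; G near 0 means a completely novel moment.
#'
#' @param V_hat Per-CM maximum support (length Q).
#' @return Familiarity in `[0, 1]`.
#' @export
familiarity_G <- function(V_hat) mean(V_hat)

#' Expansivity of the V-to-psi map
#'
#' As familiarity G approaches 1 the sigmoid becomes maximally expansive
#' (range `1 + chi * K`), concentrating win probability on the most implicated
#' cell of each CM; at or below the floor `G^-` it collapses to the constant
#' function (uniform draw).
#'
#' @param G Familiarity.
#' @param K Cells per CM.
#' @param params [csa_params()].
#' @return Sigmoid range `eta >= 1`.
#' @export
sigmoid_range <- function(G, K, params = csa_params()) {
  z <- max(0, (G - params$G_floor) / (1 - params$G_floor))
  1 + z ^ params$gamma * params$chi * K
}

#' Apply the familiarity-modulated sigmoid
#'
#' @param V Support vector.
#' @param eta Sigmoid range from [sigmoid_range()].
#' @param params [csa_params()].
#' @param sigma3 Optional override of the inflection point (used by the
#'   stored-code-count schedule; see [csa_params()]).
#' @return Relative win probabilities `psi` in `[1, eta]`.
#' @export
v_to_psi <- function(V, eta, params = csa_params(), sigma3 = NULL) {
  if (is.null(sigma3)) sigma3 <- params$sigma3
  (eta - 1) / (1 + params$sigma1 * exp(-params$sigma2 * (V - sigma3))) ^
    params$sigma4 + 1
}

#' Normalize relative win probabilities within each CM
#'
#' @param psi Relative probabilities (>= 1) per cell.
#' @param cm_of Integer vector giving each cell's CM.
#' @return Probabilities `rho` summing to 1 within each CM.
#' @export
#' @examples
#' cm <- rep(1, 7)
#' psi_to_rho(c(300, 1, 1, 1, 1, 1, 1), cm)[1]  # 300/306
psi_to_rho <- function(psi, cm_of) {
  totals <- tapply(psi, cm_of, sum)
  psi / as.numeric(totals[cm_of])
}

#' Draw one winner per competitive module (softmax)
#'
#' @param rho Win probabilities per cell (summing to 1 within each CM).
#' @param cm_of Integer vector giving each cell's CM.
#' @param rng Optional integer seed for a reproducible draw.
#' @return Integer vector (length Q) of winning cell indices, one per CM.
#' @export
draw_winners <- function(rho, cm_of, rng = NULL) {
  if (!is.null(rng)) set.seed(as.integer(rng))
  Q <- max(cm_of)
  vapply(seq_len(Q), function(q) {
    idx <- which(cm_of == q)
    if (length(idx) == 1L) return(idx)
    idx[sample.int(length(idx), 1L, prob = rho[idx])]
  }, integer(1))
}

#' Evaluate one familiarity variant
#'
#' Computes the support V restricted to the listed evidence sources (omitted
#' factors contribute 1) and the resulting familiarity G.
#'
#' @param inputs List with normalized vectors `U`, and optionally `H`, `D`.
#' @param sources Character vector, a subset of `c("U", "H", "D")`.
#' @param t Frame index within the sequence (0-based).
#' @param cm_of Integer vector giving each cell's CM.
#' @param params [csa_params()].
#' @return List with `G`, `V`, `V_hat`.
#' @export
evaluate_G_variant <- function(inputs, sources, t, cm_of,
                               params = csa_params()) {
  if (length(sources) == 0) stop("empty evidence source set", call. = FALSE)
  V <- rep(1, length(inputs$U))
  if ("U" %in% sources) V <- V * inputs$U ^ lambda_U_at(params, t)
  if ("H" %in% sources) {
    if (is.null(inputs$H)) stop("H evidence requested but unavailable", call. = FALSE)
    V <- V * inputs$H ^ params$lambda_H
  }
  if ("D" %in% sources) {
    if (is.null(inputs$D)) stop("D evidence requested but unavailable", call. = FALSE)
    V <- V * inputs$D ^ params$lambda_D
  }
  hm <- cm_hard_max(V, cm_of)
  list(G = familiarity_G(hm$V_hat), V = V, V_hat = hm$V_hat)
}

variant_sources <- function(name) strsplit(name, "")[[1]]

#' Walk the back-off policy and choose a familiarity variant
#'
#' Evaluates variants in precedence order, restricted to those whose evidence
#' sources are available at this moment, and stops at the first whose
#' familiarity meets its threshold; if none does, the terminal (U-only)
#' variant is used. The number of variant evaluations is bounded by the fixed
#' policy length regardless of how many codes are stored.
#'
#' @param inputs List with normalized vectors `U` and optionally `H`, `D`
#'   (`NULL` = unavailable at this moment).
#' @param policy A [backoff_policy()].
#' @param t Frame index within the sequence (0-based).
#' @param cm_of Integer vector giving each cell's CM.
#' @param params [csa_params()].
#' @return List with `variant` (name), `G`, `V`, `V_hat`, `n_evaluated`.
#' @export
backoff_select <- function(inputs, policy, t, cm_of, params = csa_params()) {
  avail <- c("U", if (!is.null(inputs$H)) "H", if (!is.null(inputs$D)) "D")
  usable <- Filter(function(v) all(variant_sources(v) %in% avail), policy$order)
  if (length(usable) == 0) usable <- "U"
  n_eval <- 0L
  res <- NULL
  for (v in usable) {
    res <- evaluate_G_variant(inputs, variant_sources(v), t, cm_of, params)
    n_eval <- n_eval + 1L
    if (res$G >= policy$thresholds[[v]]) {
      return(c(res, list(variant = v, n_evaluated = n_eval)))
    }
  }
  c(res, list(variant = usable[length(usable)], n_evaluated = n_eval))
}

# deterministic substream seed < 2^31 from the run seed and position,
# so mac evaluation order never changes results
substream_seed <- function(seed, seq_idx, t, mac_idx) {
  h <- as.double(seed) %% 2147483563
  for (x in c(seq_idx, t, mac_idx)) {
    h <- (h * 69069 + x + 1) %% 2147483563
  }
  as.integer(h)
}

# -- raw summations ----------------------------------------------------------

#' Raw weighted input summations for a mac
#'
#' Sums the synaptic weights from active pre-synaptic units into each cell,
#' each source mac's signals scaled by its MCH correction factor. U signals
#' come from the current frame; H and D signals from codes active on the
#' previous frame.
#'
#' @param weights Weight matrix (pre x cells), e.g. from the weight schedule.
#' @param pre_rows Integer indices of active pre-synaptic rows.
#' @param factor MCH correction factor applied to these signals.
#' @return Numeric summation vector over the mac's cells.
#' @export
raw_summation <- function(weights, pre_rows, factor = 1) {
  if (length(pre_rows) == 0 || factor == 0) return(numeric(ncol(weights)))
  factor * colSums(weights[pre_rows, , drop = FALSE])
}

# gather the three raw summations + feature counts for mac m at frame t.
# prev = snapshot of all macs' state at t-1.
mac_inputs <- function(net, m, active_pixels, t, prev) {
  params <- net$config$csa
  sched <- net$config$schedule
  w_max <- sched$w_max
  Z <- m$Z

  # --- U ---
  if (m$u_type == "pixels") {
    rows <- which(m$u_src %in% active_pixels)
    pi_u <- length(rows)
    pi_u_star <- pi_u
    WU <- proj_weights(m$proj_U, sched)
    u <- raw_summation(WU, rows, 1)
    U <- normalize_input(u, lo = m$pi_u[1], level = 1, w_max = w_max)
    Q_sub <- 1L
    n_pre_u <- nrow(WU)
  } else {
    WU <- proj_weights(m$proj_U, sched)
    u <- numeric(Z); pi_u <- 0L; pi_u_star <- 0L
    Q_sub <- net$macs[[m$u_src[1]]]$Q
    for (k in seq_along(m$u_src)) {
      src <- net$macs[[m$u_src[k]]]
      if (!src$active) next
      pi_u <- pi_u + 1L
      f <- mch_factor(max(1L, src$zeta), params)
      if (f == 0) next  # muddled source: excluded from the summation
      pi_u_star <- pi_u_star + 1L
      rows <- m$u_offsets[k] + src$code
      u <- u + raw_summation(WU, rows, f)
    }
    U <- normalize_input(u, lo = m$pi_u[1], star = pi_u_star, Q = Q_sub,
                         level = 2, w_max = w_max)
    n_pre_u <- nrow(WU)
  }

  # --- H (previous-frame codes in the horizontal neighborhood) ---
  h <- numeric(Z); pi_h <- 0L; pi_h_star <- 0L
  self_counted <- FALSE
  n_pre_h <- 0L
  for (k in seq_along(m$h_src)) {
    ps <- prev[[m$h_src[k]]]
    n_pre_h <- n_pre_h + nrow(m$proj_H[[k]]$sigma)
    if (is.null(ps) || !ps$active) next
    pi_h <- pi_h + 1L
    f <- mch_factor(max(1L, ps$zeta), params)
    if (f == 0) next
    pi_h_star <- pi_h_star + 1L
    if (m$h_src[k] == m$idx && !net$config$h_include_own_cm) self_counted <- TRUE
    WH <- proj_weights(m$proj_H[[k]], sched)
    h <- h + raw_summation(WH, ps$code, f)
  }
  H <- NULL
  if (pi_h > 0L) {
    if (pi_h_star == 0L) {
      H <- numeric(Z)
    } else {
      Q_h <- net$macs[[m$h_src[1]]]$Q
      # a cell cannot receive from the winner of its own CM, so a perfectly
      # familiar recurrent moment has Q-1 reachable pre-synaptic cells
      reach <- min(m$pi_h_lo, pi_h_star) * Q_h - as.integer(self_counted)
      H <- pmin(1, h / (reach * w_max))
    }
  }

  # --- D (previous-frame codes in superjacent parents) ---
  d <- numeric(Z); pi_d <- 0L; pi_d_star <- 0L
  n_pre_d <- 0L
  if (length(m$d_src) > 0) {
    for (k in seq_along(m$d_src)) {
      ps <- prev[[m$d_src[k]]]
      n_pre_d <- n_pre_d + nrow(m$proj_D[[k]]$sigma)
      if (is.null(ps) || !ps$active) next
      pi_d <- pi_d + 1L
      f <- mch_factor(max(1L, ps$zeta), params)
      if (f == 0) next
      pi_d_star <- pi_d_star + 1L
      WD <- proj_weights(m$proj_D[[k]], sched)
      d <- d + raw_summation(WD, ps$code, f)
    }
  }
  D <- NULL
  if (pi_d > 0L) {
    if (pi_d_star == 0L) {
      D <- numeric(Z)
    } else {
      Q_d <- net$macs[[m$d_src[1]]]$Q
      D <- normalize_input(d, lo = m$pi_d_lo, star = pi_d_star, Q = Q_d,
                           level = 2, w_max = w_max)
    }
  }

  list(u = u, h = h, d = d, U = U, H = H, D = D,
       pi_u = pi_u, pi_u_star = pi_u_star, pi_h = pi_h, pi_d = pi_d,
       n_pre = c(U = n_pre_u, H = n_pre_h, D = n_pre_d))
}

#' Run the code selection algorithm for one mac at one frame
#'
#' Orchestrates the full per-frame competition: raw summations, normalization,
#' local support (with back-off over familiarity variants in the retrieval
#' modes), the MCH tally, familiarity G, and winner selection -- softmax in
#' learning and probabilistic-retrieval modes, hard max (with seeded
#' tie-break) in simple retrieval mode. The operation count depends only on
#' the network structure and the (bounded) number of back-off evaluations,
#' never on how many codes are stored.
#'
#' @param net A built network (current-frame subjacent codes already set).
#' @param mac The mac (element of `net$macs`).
#' @param active_pixels Active pixel indices of the current input frame.
#' @param t Frame index within the sequence (0-based).
#' @param mode One of "learning", "probabilistic", "simple".
#' @param prev Snapshot list of all macs' previous-frame state
#'   (`list(active, code, zeta)` each); defaults to the stored snapshot.
#' @param rng Optional integer seed for this mac's draw.
#' @return A list (the mac frame state): `code`, `G`, `zeta`, `zeta_q`, `eta`,
#'   `variant`, `V`, `V_hat`, `rho` (softmax modes), `ops` (elementary
#'   operation count), and the normalized inputs.
#' @export
csa_step <- function(net, mac, active_pixels, t, mode = "learning",
                     prev = net$prev, rng = NULL) {
  mode <- match.arg(mode, c("learning", "probabilistic", "simple"))
  params <- net$config$csa
  cm_of <- mac$cm_of
  inp <- mac_inputs(net, mac, active_pixels, t, prev)
  n_eval <- 1L

  if (mode == "learning") {
    V <- local_support(inp$U, inp$H, inp$D, t = t, params = params)
    hm <- cm_hard_max(V, cm_of)
    G <- familiarity_G(hm$V_hat)
    variant <- paste0(c(if (!is.null(inp$H)) "H", "U", if (!is.null(inp$D)) "D"),
                      collapse = "")
  } else {
    sel <- backoff_select(inp[c("U", "H", "D")], net$config$backoff, t, cm_of,
                          params)
    V <- sel$V; G <- sel$G; variant <- sel$variant
    hm <- cm_hard_max(V, cm_of)
    n_eval <- sel$n_evaluated
  }

  mch <- count_mch(V, cm_of, params)
  if (!is.null(rng)) set.seed(as.integer(rng))

  if (mode == "simple") {
    eta <- 1
    rho <- NULL
    code <- vapply(hm$argmax, function(idx) {
      if (length(idx) == 1L) idx else idx[sample.int(length(idx), 1L)]
    }, integer(1))
  } else {
    eta <- sigmoid_range(G, mac$K, params)
    s3 <- min(params$sigma3_max,
              params$sigma3 + params$sigma3_rate * mac$stored_code_count)
    psi <- v_to_psi(V, eta, params, sigma3 = s3)
    rho <- psi_to_rho(psi, cm_of)
    code <- draw_winners(rho, cm_of)
  }

  # structural operation count: full-RF multiply-adds plus the per-cell
  # normalization/sigmoid work and per-CM draws, times back-off evaluations
  ops <- sum(inp$n_pre) * mac$Z + n_eval * (6L * mac$Z + 2L * mac$Q)

  list(code = code, G = G, zeta = max(1L, mch$zeta), zeta_q = mch$zeta_q,
       eta = eta, variant = variant, V = V, V_hat = hm$V_hat, rho = rho,
       U = inp$U, H = inp$H, D = inp$D, pi_u = inp$pi_u, ops = ops)
}
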