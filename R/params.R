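#' Code-selection parameters
#'
#' Parameters of the per-frame code selection algorithm (CSA): the exponents
#' applied to the normalized bottom-up (U), horizontal (H) and top-down (D)
#' inputs, the multiple-competing-hypotheses (MCH) machinery, and the shape of
#' the familiarity-modulated sigmoid that turns local support V into relative
#' win probabilities.
#'
#' @param lambda_U Exponent on the normalized U input. Either a single number
#'   or a function of the frame index `t` (0-based within a sequence).
#' @param lambda_H,lambda_D Exponents on the normalized H and D inputs.
#' @param V_zeta Threshold above which a cell counts as maximally implicated
#'   when tallying competing hypotheses (strict inequality `V > V_zeta`).
#' @param A MCH boost discount exponent (< 1); efferent signals from a mac with
#'   `zeta` tied hypotheses are multiplied by `zeta^A`.
#' @param B MCH cutoff: a mac with `zeta > B` is "muddled" and its efferent
#'   signals are ignored entirely.
#' @param G_floor Familiarity floor `G^-`; for `G <= G_floor` the sigmoid
#'   collapses to the constant function (uniform winner draw).
#' @param gamma Sigmoid expansion exponent (>= 1).
#' @param chi Sigmoid expansion factor; the sigmoid range at `G = 1` is
#'   `eta = 1 + chi * K`.
#' @param sigma1,sigma2,sigma3,sigma4 Sigmoid shape parameters. The defaults
#'   give a plain logistic with inflection at `V = 0.5`.
#' @param sigma3_rate Rightward shift of the sigmoid inflection point per code
#'   stored in the mac (a linear schedule that counteracts mounting crosstalk
#'   as more codes are stored in superposition); 0 disables the schedule.
#' @param sigma3_max Upper cap on the shifted inflection point.
#' @param w_max Maximum synaptic weight (127).
#' @param mch_boost If `FALSE`, the boost is disabled: `F(zeta) = 1` for
#'   `zeta <= B` (the muddled cutoff still applies). Used for ablation.
#' @return An object of class `csa_params` (a list).
#' @export
#' @examples
#' p <- csa_params()
#' p$V_zeta
csa_params <- function(lambda_U = 1, lambda_H = 1, lambda_D = 1,
                       V_zeta = 0.95, A = 0.7, B = 4,
                       G_floor = 0, gamma = 2, chi = 100,
                       sigma1 = 1, sigma2 = 10, sigma3 = 0.5, sigma4 = 1,
                       sigma3_rate = 0.008, sigma3_max = 0.9,
                       w_max = 127L, mch_boost = TRUE) {
  stopifnot(V_zeta > 0, V_zeta <= 1, A < 1, B >= 1, G_floor >= 0, G_floor < 1,
            gamma >= 1, w_max == 127L)
  p <- list(lambda_U = lambda_U, lambda_H = lambda_H, lambda_D = lambda_D,
            V_zeta = V_zeta, A = A, B = B,
            G_floor = G_floor, gamma = gamma, chi = chi,
            sigma1 = sigma1, sigma2 = sigma2, sigma3 = sigma3, sigma4 = sigma4,
            sigma3_rate = sigma3_rate, sigma3_max = sigma3_max,
            w_max = as.integer(w_max), mch_boost = isTRUE(mch_boost))
  class(p) <- "csa_params"
  p
}

lambda_U_at <- function(params, t) {
  if (is.function(params$lambda_U)) params$lambda_U(t) else params$lambda_U
}

#' Synaptic weight schedule (age/permanence table)
#'
#' Synapses are effectively binary: a pre-post correlation drives the weight to
#' `w_max = 127` immediately; thereafter the weight decays passively with age
#' `sigma` at a rate set by the permanence level `theta`. For each permanence
#' the weight stays on a plateau at 127 for `T_sigma(theta)` steps and then
#' decays linearly to 0 over a further `decay_span(theta)` steps. At the
#' maximum permanence the weight is pinned at 127 forever.
#'
#' @param theta_max Maximum permanence (default 2: a weight becomes permanent
#'   on the third within-window pre-post correlation).
#' @param plateau Function of `theta` giving the plateau length `T_sigma(theta)`
#'   in frames; default `100 * 2^theta`.
#' @param decay_span Function of `theta` giving the linear-decay span; default
#'   equal to the plateau.
#' @param w_max Maximum weight (127).
#' @return An object of class `weight_schedule` with the tabulated weights
#'   (`table`: `(sigma_max+1) x (theta_max+1)` integer matrix), the per-theta
#'   window lengths `T_sigma`, and `sigma_max`.
#' @seealso [weight_lookup()]
#' @export
weight_schedule <- function(theta_max = 2L,
                            plateau = function(theta) 100L * 2L^theta,
                            decay_span = plateau,
                            w_max = 127L) {
  theta_max <- as.integer(theta_max)
  stopifnot(theta_max >= 1L)
  thetas <- 0:theta_max
  T_sigma <- vapply(thetas, function(th) as.integer(plateau(th)), integer(1))
  spans <- vapply(thetas, function(th) as.integer(decay_span(th)), integer(1))
  stopifnot(all(diff(T_sigma) > 0))
  sigma_max <- max(T_sigma[thetas < theta_max] + spans[thetas < theta_max])
  tab <- matrix(0L, nrow = sigma_max + 1L, ncol = theta_max + 1L)
  for (th in thetas) {
    sig <- 0:sigma_max
    if (th == theta_max) {
      w <- rep.int(as.integer(w_max), sigma_max + 1L)
    } else {
      w <- ifelse(sig <= T_sigma[th + 1L], w_max,
                  pmax(0, w_max * (1 - (sig - T_sigma[th + 1L]) / spans[th + 1L])))
      w <- as.integer(round(w))
    }
    tab[, th + 1L] <- w
  }
  structure(list(table = tab, T_sigma = T_sigma, sigma_max = sigma_max,
                 theta_max = theta_max, w_max = as.integer(w_max)),
            class = "weight_schedule")
}

#' Look up synaptic weights by age and permanence
#'
#' @param sigma Integer vector/matrix of synapse ages in `[0, sigma_max]`.
#' @param theta Integer vector/matrix of permanences in `[0, theta_max]`,
#'   recycled against `sigma`.
#' @param schedule A [weight_schedule()].
#' @return Integer weights in `[0, 127]`, with the shape of `sigma`.
#' @export
#' @examples
#' ws <- weight_schedule()
#' weight_lookup(0L, 0L, ws)    # a fresh correlation -> 127
#' weight_lookup(ws$sigma_max, ws$theta_max, ws)  # permanent -> 127
weight_lookup <- function(sigma, theta, schedule) {
  if (any(sigma < 0L) || any(sigma > schedule$sigma_max) ||
      any(theta < 0L) || any(theta > schedule$theta_max)) {
    stop("sigma/theta out of the schedule's range", call. = FALSE)
  }
  w <- schedule$table[cbind(as.vector(sigma) + 1L, as.vector(theta) + 1L)]
  if (is.matrix(sigma)) dim(w) <- dim(sigma)
  w
}

#' Export / import a weight schedule as CSV
#'
#' Writes the tabulated weights with permanence levels as rows and ages as
#' columns, for inspection.
#'
#' @param schedule A [weight_schedule()].
#' @param path File path.
#' @return `write_weight_schedule_csv` returns `path` invisibly;
#'   `read_weight_schedule_csv` returns the weight matrix (theta rows x sigma
#'   columns).
#' @export
write_weight_schedule_csv <- function(schedule, path) {
  m <- t(schedule$table)
  rownames(m) <- paste0("theta", 0:schedule$theta_max)
  colnames(m) <- paste0("sigma", 0:schedule$sigma_max)
  utils::write.csv(m, path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_weight_schedule_csv
#' @export
read_weight_schedule_csv <- function(path) {
  m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  storage.mode(m) <- "integer"
  m
}

#' Back-off match policy for retrieval
#'
#' In retrieval mode a mac first evaluates the most stringent familiarity
#' variant available (all of U, H, D); only if that familiarity falls below its
#' threshold does it relax the match criterion to lower-order variants,
#' finishing at the U-only terminal variant (threshold 0). This is what makes
#' recognition tolerant to nonlinear time warping of test sequences.
#'
#' @param order Variant precedence, a character vector of subsets of "HUD".
#' @param thresholds Named numeric vector of per-variant acceptance thresholds.
#'   The terminal variant must have threshold 0.
#' @return An object of class `backoff_policy`.
#' @export
backoff_policy <- function(order = c("HUD", "UD", "HU", "HD", "U"),
                           thresholds = c(HUD = 0.9, UD = 0.95, HU = 0.95,
                                          HD = 0.95, U = 0)) {
  stopifnot(all(order %in% names(thresholds)))
  terminal <- order[length(order)]
  if (thresholds[[terminal]] != 0) {
    stop("the terminal back-off variant must have threshold 0", call. = FALSE)
  }
  structure(list(order = order, thresholds = thresholds), class = "backoff_policy")
}

#' Specify one internal level of the network
#'
#' @param grid `c(rows, cols)` of macs at this level.
#' @param Q Competitive modules (minicolumns) per mac.
#' @param K Cells per competitive module (>= 2).
#' @param delta Persistence: number of frames a chosen code stays active during
#'   learning. Defaults double with level when built via [memory_config()].
#' @param pi_u `c(lo, hi)` bounds on the number of active features in a mac's
#'   bottom-up receptive field for the mac to activate (`hi` may be `Inf`).
#' @param pi_h_lo,pi_d_lo Lower feature-count bounds used as H/D normalizers.
#' @param u_rf `c(rows, cols)` of the bottom-up receptive-field aperture, in
#'   pixels for level 1 and in subjacent macs for higher levels. `NULL` means
#'   the aperture is inferred by exact tiling.
#' @param h_radius Horizontal neighborhood radius in macs: 0 = own mac only,
#'   1 = own mac plus the N/S/E/W neighbors (the default).
#' @return An object of class `level_spec`.
#' @export
level_spec <- function(grid = c(1, 1), Q, K, delta = NULL,
                       pi_u = c(1, Inf), pi_h_lo = 1, pi_d_lo = 1,
                       u_rf = NULL, h_radius = 1) {
  stopifnot(length(grid) == 2, all(grid >= 1), Q >= 1, K >= 2,
            length(pi_u) == 2, pi_u[1] >= 1, pi_u[1] <= pi_u[2])
  structure(list(grid = as.integer(grid), Q = as.integer(Q), K = as.integer(K),
                 delta = if (is.null(delta)) NULL else as.integer(delta),
                 pi_u = pi_u, pi_h_lo = as.integer(pi_h_lo),
                 pi_d_lo = as.integer(pi_d_lo),
                 u_rf = if (is.null(u_rf)) NULL else as.integer(u_rf),
                 h_radius = as.integer(h_radius)),
            class = "level_spec")
}

#' Full model configuration
#'
#' Bundles the input grid, the internal levels, the code-selection parameters,
#' the synaptic weight schedule, the back-off policy, and the learning-freeze
#' (critical period) threshold.
#'
#' @param input `c(rows, cols)` of the binary input grid (level 0).
#' @param levels List of [level_spec()] objects, bottom level first.
#' @param csa A [csa_params()] object.
#' @param schedule A [weight_schedule()] object.
#' @param backoff A [backoff_policy()] object.
#' @param freeze_threshold Fraction of potentiated weights in any one afferent
#'   projection at which all of a mac's afferent projections freeze permanently.
#' @param h_include_own_cm If `TRUE`, recurrent horizontal projections also
#'   connect cells within the same competitive module (off by default: the
#'   within-CM pairs are excluded).
#' @return An object of class `memory_config`.
#' @export
#' @examples
#' cfg <- memory_config(input = c(12, 12),
#'                      levels = list(level_spec(Q = 9, K = 4, pi_u = c(9, 12))))
memory_config <- function(input, levels, csa = csa_params(),
                          schedule = weight_schedule(),
                          backoff = backoff_policy(),
                          freeze_threshold = 0.8,
                          h_include_own_cm = FALSE) {
  if (length(levels) == 0) stop("configuration error: at least one internal level is required",
                                call. = FALSE)
  stopifnot(length(input) == 2, all(input >= 1),
            freeze_threshold > 0, freeze_threshold <= 1)
  if (!all(vapply(levels, inherits, logical(1), "level_spec"))) {
    stop("`levels` must be a list of level_spec objects", call. = FALSE)
  }
  # default persistence doubles with level: 1, 2, 4, ...
  for (i in seq_along(levels)) {
    if (is.null(levels[[i]]$delta)) levels[[i]]$delta <- as.integer(2^(i - 1))
  }
  deltas <- vapply(levels, `[[`, integer(1), "delta")
  if (any(diff(deltas) < 0)) {
    stop("configuration error: persistence must be non-decreasing with level",
         call. = FALSE)
  }
  structure(list(input = as.integer(input), levels = levels, csa = csa,
                 schedule = schedule, backoff = backoff,
                 freeze_threshold = freeze_threshold,
                 h_include_own_cm = isTRUE(h_include_own_cm)),
            class = "memory_config")
}
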