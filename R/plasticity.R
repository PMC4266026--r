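# Hebbian learning with effectively binary synapses. A pre-post correlation
# resets a synapse's age to 0 (weight jumps to 127); a repeat correlation
# within the permanence-dependent window T_sigma(theta) increments permanence.
# Ages advance once per global frame; weights decay passively via the weight
# schedule. Once any afferent projection of a mac is sufficiently saturated,
# all its afferent projections freeze permanently (critical period).

#' Apply a pre-post correlation to a projection
#'
#' For every (active pre, winning post) pair: if this is a repeat correlation
#' (the synapse has been potentiated before, i.e. its age is below the blank
#' state) occurring within the window `T_sigma(theta)`, permanence is
#' incremented (capped at `theta_max`); in all cases the age resets to 0,
#' driving the weight to `w_max`. Masked (non-existent) pairs are skipped.
#'
#' @param proj A projection (as held by a built network).
#' @param pre Integer indices of active pre-synaptic units.
#' @param post Integer indices of the winning post-synaptic cells.
#' @param schedule The [weight_schedule()].
#' @param frozen If `TRUE` the call is a no-op (critical period closed).
#' @return Invisibly, the number of synapses whose permanence was incremented.
#' @export
apply_correlation <- function(proj, pre, post, schedule, frozen = FALSE) {
  if (frozen || length(pre) == 0 || length(post) == 0) return(invisible(0L))
  sig <- proj$sigma[pre, post, drop = FALSE]
  th <- proj$theta[pre, post, drop = FALSE]
  ok <- if (is.null(proj$mask)) TRUE else proj$mask[pre, post, drop = FALSE]
  win <- schedule$T_sigma[th + 1L]
  dim(win) <- dim(th)
  inc <- ok & (sig < schedule$sigma_max) & (sig <= win) & (th < schedule$theta_max)
  th[inc] <- th[inc] + 1L
  sig[ok] <- 0L
  proj$sigma[pre, post] <- sig
  proj$theta[pre, post] <- th
  invisible(sum(inc))
}

#' Advance synapse ages by one frame
#'
#' Ages increase by one (capped at `sigma_max`) for synapses without a
#' correlation this frame; fully permanent synapses (`theta = theta_max`) stay
#' at age 0 so their weight is pinned at `w_max`. The training driver calls
#' this once per global frame *before* applying the frame's correlations, so
#' correlated synapses end the frame at age 0 either way.
#'
#' @param proj A projection.
#' @param schedule The [weight_schedule()].
#' @param frozen If `TRUE` the call is a no-op.
#' @return The projection, invisibly.
#' @export
age_tick <- function(proj, schedule, frozen = FALSE) {
  if (frozen) return(invisible(proj))
  sig <- proj$sigma
  sig <- pmin(sig + 1L, schedule$sigma_max)
  sig[proj$theta == schedule$theta_max] <- 0L
  dim(sig) <- dim(proj$sigma)
  proj$sigma <- sig
  invisible(proj)
}

#' Fraction of potentiated synapses in a projection
#'
#' @param proj A projection.
#' @param schedule The [weight_schedule()].
#' @param high Weight at or above which a synapse counts as potentiated
#'   (default `w_max = 127`).
#' @return Fraction in `[0, 1]` of existing (unmasked) synapses at high weight.
#' @export
saturation <- function(proj, schedule, high = schedule$w_max) {
  w <- weight_lookup(proj$sigma, proj$theta, schedule)
  if (is.null(proj$mask)) mean(w >= high) else mean(w[proj$mask] >= high)
}

#' Critical-period check for a mac
#'
#' If the saturation of *any one* of the mac's afferent projections (U, or any
#' H or D matrix) reaches the threshold, all afferent projections freeze
#' permanently; efferent projections (stored as other macs' afferents) are
#' unaffected. Freezing is irreversible.
#'
#' @param mac A mac environment from a built network.
#' @param threshold Saturation fraction in `(0, 1]`.
#' @param schedule The [weight_schedule()].
#' @return Logical: the mac's (possibly updated) frozen flag.
#' @export
check_freeze <- function(mac, threshold, schedule) {
  if (mac$frozen) return(TRUE)
  sats <- c(saturation(mac$proj_U, schedule),
            vapply(mac$proj_H, saturation, numeric(1), schedule = schedule),
            if (length(mac$proj_D))
              vapply(mac$proj_D, saturation, numeric(1), schedule = schedule))
  if (any(sats >= threshold)) mac$frozen <- TRUE
  mac$frozen
}
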