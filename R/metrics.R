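# Accuracy and similarity measures over codes and memory traces.
# The core quantity is the normalized per-CM intersection of two codes;
# frame and whole-trace accuracies average it over macs and frames and are
# reported in percent, matching how such results are usually tabulated.

#' Normalized intersection of two codes
#'
#' Counts the CMs in which the two codes picked the same winner, normalized by
#' the code size Q. Symmetric, 1 for identical codes, 0 for disjoint ones.
#'
#' @param code_a,code_b Integer vectors of winning cell indices (length Q,
#'   one per CM, from the same mac geometry). `NULL` counts as no overlap.
#' @param Q Code size; defaults to `length(code_a)`.
#' @return Similarity in `[0, 1]`.
#' @export
#' @examples
#' code_similarity(c(1, 5, 9), c(1, 5, 9))  # 1
#' code_similarity(c(1, 5, 9), c(2, 5, 9))  # 2/3
code_similarity <- function(code_a, code_b, Q = length(code_a)) {
  if (is.null(code_a) || is.null(code_b)) return(0)
  sum(code_a == code_b) / Q
}

#' Whole-network accuracy on one frame
#'
#' Averages the normalized code intersection over all macs that were active in
#' the learning trace at this frame; a mac inactive at test (or with a
#' different code) contributes its (possibly zero) intersection. Returned in
#' percent.
#'
#' @param learn_frame,test_frame Per-mac record lists for one frame of a
#'   learning and a test trace (elements of `sdc_trace$frames`).
#' @return Accuracy `R_t` in percent; `NA` if no mac was active at learning.
#' @export
frame_accuracy <- function(learn_frame, test_frame) {
  gammas <- c()
  for (mi in seq_along(learn_frame)) {
    lr <- learn_frame[[mi]]
    if (!isTRUE(lr$active)) next
    tr <- test_frame[[mi]]
    g <- if (isTRUE(tr$active)) code_similarity(lr$code, tr$code) else 0
    gammas <- c(gammas, g)
  }
  if (length(gammas) == 0) return(NA_real_)
  100 * mean(gammas)
}

#' Whole-trace and final-frame accuracy
#'
#' `R_star` is the mean over frames of the per-frame accuracy; `R_omega` is
#' the accuracy on the final frame alone. Both in percent. The traces must
#' have equal frame counts (exact-match protocol).
#'
#' @param learn_trace,test_trace `sdc_trace` objects.
#' @return List with `R_t` (per-frame percents), `R_star`, `R_omega`.
#' @export
trace_accuracy <- function(learn_trace, test_trace) {
  if (length(learn_trace$frames) != length(test_trace$frames)) {
    stop("traces have different frame counts", call. = FALSE)
  }
  R_t <- vapply(seq_along(learn_trace$frames), function(t1) {
    frame_accuracy(learn_trace$frames[[t1]], test_trace$frames[[t1]])
  }, numeric(1))
  list(R_t = R_t, R_star = mean(R_t, na.rm = TRUE),
       R_omega = R_t[length(R_t)])
}

#' Pairwise code intersection matrix
#'
#' @param codes List of codes (integer vectors, same mac geometry).
#' @return Symmetric integer matrix of per-CM intersection counts; diagonal
#'   equals Q.
#' @export
intersection_matrix <- function(codes) {
  n <- length(codes)
  m <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    m[i, j] <- m[j, i] <- sum(codes[[i]] == codes[[j]])
  }
  m
}
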