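# Adaptive least-mean-squares artifact cancellation. The filter predicts the
# artifact in a PPG channel from a tap-delay vector of the motion reference
# and subtracts the prediction; tap weights follow the stochastic-gradient
# update that descends the mean squared error, w <- w + mu * e * a_vec.

#' LMS adaptive artifact removal
#'
#' Runs an order-`order` LMS filter over `y` with reference `a`:
#' at each step `l`, the artifact estimate is
#' `m'(l) = w' \%*\% [a(l), a(l-1), ..., a(l-order+1)]` (zero-padded history),
#' the cleansed output is `e(l) = y(l) - m'(l)`, and the weights update by
#' `w <- w + mu * e(l) * a_vec`. A zero reference therefore passes `y`
#' through untouched.
#'
#' @param y observed series (PPG channel).
#' @param a reference motion-artifact series, same length.
#' @param order number of taps (default 25).
#' @param mu step size (default 0.005).
#' @param state optional `lms_state` from a previous call; its weights and
#'   reference history seed this run, so chunked processing is bit-identical
#'   to one continuous run across successive windows of a session.
#' @return list of class `lms_state`: `cleansed` (the error series `e`),
#'   `artifact_estimate` (`m'`), `weights` (final tap vector), `order`, `mu`.
#' @export
lms_denoise <- function(y, a, order = 25L, mu = 0.005, state = NULL) {
  n <- length(y)
  if (length(a) != n) stop("y and a must have the same length")
  if (n < 1L) stop("empty input")
  order <- as.integer(order)
  if (!is.null(state)) {
    stopifnot(inherits(state, "lms_state"), length(state$weights) == order)
    w <- state$weights
    hist <- state$ref_tail
  } else {
    w <- numeric(order)
    hist <- numeric(order - 1L)
  }
  apad <- c(hist, a)                   # apad[l + order - 1] == a[l]
  e <- numeric(n)
  mhat <- numeric(n)
  for (l in seq_len(n)) {
    avec <- apad[(l + order - 1L):l]   # a(l), a(l-1), ..., a(l-order+1)
    mhat[l] <- sum(w * avec)
    e[l] <- y[l] - mhat[l]
    w <- w + mu * e[l] * avec
    if (!all(is.finite(w))) {
      stop("LMS diverged at step ", l,
           "; consider a smaller step size mu (current mu=", mu, ")")
    }
  }
  structure(list(cleansed = e, artifact_estimate = mhat, weights = w,
                 ref_tail = tail(apad, order - 1L), order = order, mu = mu),
            class = "lms_state")
}
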