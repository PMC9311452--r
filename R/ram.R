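# Robust adaptive Metropolis (RAM): a random-walk Metropolis whose
# lower-triangular proposal scale adapts towards a target acceptance rate.

#' One robust-adaptive-Metropolis step
#'
#' Proposes `z' = z + S u` with `u ~ N(0, I)`, accepts with probability
#' `min(1, exp(logpost(z') - logpost(z)))`, and (while adapting) updates the
#' lower-triangular scale `S` by
#' \deqn{S_t S_t' = S_{t-1}\bigl(I + \gamma_t(\alpha - \alpha^*)
#'  uu'/\|u\|^2\bigr)S_{t-1}'}
#' with adaptation weight \eqn{\gamma_t = t^{-\gamma}} and target acceptance
#' \eqn{\alpha^* = 0.234}.  Proposals outside `[z_lower, z_upper]` are
#' rejected outright (with \eqn{\alpha = 0} still driving the adaptation).
#'
#' @param z current state (transformed scale).
#' @param logpost function of `z` returning the log target density.
#' @param ld current value `logpost(z)` (to avoid recomputation).
#' @param S lower-triangular proposal scale.
#' @param iter adaptation step counter (1-based).
#' @param adapt logical: update `S`?
#' @param target target acceptance rate.
#' @param gamma_exp adaptation decay exponent.
#' @param z_lower,z_upper optional box bounds on the transformed scale.
#' @return List with `z`, `ld`, `accepted`, `alpha`, `S`.
#' @export
ram_step <- function(z, logpost, ld, S, iter, adapt = TRUE, target = 0.234,
                     gamma_exp = 0.7, z_lower = NULL, z_upper = NULL) {
  d <- length(z)
  u <- stats::rnorm(d)
  zp <- z + as.numeric(S %*% u)
  inside <- TRUE
  if (!is.null(z_lower)) inside <- inside && all(zp >= z_lower)
  if (!is.null(z_upper)) inside <- inside && all(zp <= z_upper)
  if (inside) {
    ldp <- logpost(zp)
    alpha <- min(1, exp(ldp - ld))
    accepted <- stats::runif(1) < alpha
  } else {
    ldp <- -Inf
    alpha <- 0
    accepted <- FALSE
  }
  if (accepted) {
    z <- zp
    ld <- ldp
  }
  if (adapt) {
    gam <- min(1, d * iter^(-gamma_exp))
    M <- S %*% (diag(d) + gam * (alpha - target) * tcrossprod(u) / sum(u^2)) %*%
      t(S)
    M <- 0.5 * (M + t(M))
    S <- t(chol(M))
  }
  list(z = z, ld = ld, accepted = accepted, alpha = alpha, S = S)
}
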