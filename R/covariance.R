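#' Expanded locations on the domain D x Xi
#'
#' A q-variate spatial process on a domain `D` can be recast as a univariate
#' process on the expanded domain `D x Xi`, where `Xi` is a latent domain
#' holding one coordinate per variable.  An `expanded_locs` object stores the
#' spatial coordinates together with the variable index of every point of
#' that expanded domain.
#'
#' @param coords numeric matrix (n x d) of spatial coordinates; by convention
#'   the unit square for d = 2.
#' @param var integer vector of length n with entries in `1..q`, the position
#'   of each point in the latent variable domain.
#' @param q number of variables; defaults to `max(var)`.
#' @return An object of class `expanded_locs`.
#' @export
expanded_locs <- function(coords, var, q = max(var)) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  var <- as.integer(var)
  if (nrow(coords) != length(var)) {
    stop("`coords` and `var` must have matching lengths")
  }
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (any(var < 1L) || any(var > q)) stop("`var` must lie in 1..q")
  structure(list(coords = coords, var = var, q = as.integer(q)),
            class = "expanded_locs")
}

#' @export
print.expanded_locs <- function(x, ...) {
  cat(sprintf("<expanded_locs> %d points, %d spatial dims, q = %d variables\n",
              nrow(x$coords), ncol(x$coords), x$q))
  invisible(x)
}

#' @export
length.expanded_locs <- function(x) nrow(x$coords)

subset_locs <- function(x, idx) {
  expanded_locs(x$coords[idx, , drop = FALSE], x$var[idx], q = x$q)
}

#' Cross-covariance parameters
#'
#' Parameter vector of the non-separable multivariate cross-covariance on the
#' expanded domain: for variables i, j at spatial distance h,
#' \deqn{Cov = \sigma_{i1}^2 C(h, 0) + \sigma_{i2}^2 e^{-\phi_i h}} when
#' i = j, and \eqn{\sigma_{i1}\sigma_{j1} C(h, \delta_{ij})} otherwise, with
#' the base correlation
#' \deqn{C(h,\Delta) = (1+\alpha\Delta)^{-\beta}
#'   \exp\{-\phi h (1+\alpha\Delta)^{-\beta/2}\}.}
#' The free parameters number `3q + q(q-1)/2 + 3`.
#'
#' @param sigma1 length-q vector of shared-component scales (sign free).
#' @param sigma2 length-q nonnegative vector of independent-component scales.
#' @param phi_i length-q positive vector of independent-component decays.
#' @param delta q x q symmetric nonnegative latent-distance table with zero
#'   diagonal; a scalar is accepted when q = 2.
#' @param alpha,beta_cov,phi positive scalars of the base correlation
#'   (`beta_cov` is the latent-dimension exponent, named to avoid a clash
#'   with regression coefficients).
#' @return An object of class `cov_params`.
#' @export
cov_params <- function(sigma1, sigma2, phi_i, delta, alpha, beta_cov, phi) {
  q <- length(sigma1)
  if (is.null(dim(delta))) {
    if (q == 2L && length(delta) == 1L) {
      delta <- matrix(c(0, delta, delta, 0), 2, 2)
    } else if (length(delta) == q * (q - 1) / 2) {
      m <- matrix(0, q, q)
      m[lower.tri(m)] <- delta
      delta <- m + t(m)
    } else stop("`delta` must be a q x q matrix or the j < i free entries")
  }
  stopifnot(length(sigma2) == q, length(phi_i) == q,
            nrow(delta) == q, ncol(delta) == q)
  if (any(sigma2 < 0)) stop("sigma2 must be nonnegative")
  if (any(phi_i <= 0) || phi <= 0) stop("spatial decays must be positive")
  if (alpha <= 0 || beta_cov <= 0) stop("alpha and beta_cov must be positive")
  if (any(abs(delta - t(delta)) > 1e-12) || any(diag(delta) != 0) ||
      any(delta < 0)) {
    stop("`delta` must be symmetric, nonnegative, with zero diagonal")
  }
  structure(list(sigma1 = as.numeric(sigma1), sigma2 = as.numeric(sigma2),
                 phi_i = as.numeric(phi_i), delta = delta,
                 alpha = as.numeric(alpha), beta_cov = as.numeric(beta_cov),
                 phi = as.numeric(phi), q = q),
            class = "cov_params")
}

#' @export
print.cov_params <- function(x, ...) {
  cat(sprintf("<cov_params> q = %d (%d free parameters)\n", x$q,
              3L * x$q + (x$q * (x$q - 1L)) %/% 2L + 3L))
  cat(" sigma1:", signif(x$sigma1, 4), "\n sigma2:", signif(x$sigma2, 4),
      "\n phi_i: ", signif(x$phi_i, 4), "\n delta: ",
      signif(x$delta[lower.tri(x$delta)], 4),
      sprintf("\n alpha = %.4g, beta_cov = %.4g, phi = %.4g\n",
              x$alpha, x$beta_cov, x$phi))
  invisible(x)
}

#' Flatten / restore a parameter vector
#'
#' Serialization order: `sigma1[1..q]`, `sigma2[1..q]`, `phi_i[1..q]`,
#' `delta[i, j]` for j < i row-major, `alpha`, `beta_cov`, `phi`.
#'
#' @param params a [cov_params()] object.
#' @return `flatten_params` returns a named numeric vector;
#'   `unflatten_params` its inverse.
#' @export
flatten_params <- function(params) {
  q <- params$q
  dl <- numeric(0)
  nm <- character(0)
  if (q > 1) {
    for (i in 2:q) for (j in 1:(i - 1)) {
      dl <- c(dl, params$delta[i, j])
      nm <- c(nm, sprintf("delta_%d%d", i, j))
    }
  }
  out <- c(params$sigma1, params$sigma2, params$phi_i, dl,
           params$alpha, params$beta_cov, params$phi)
  names(out) <- c(paste0("sigma1_", seq_len(q)), paste0("sigma2_", seq_len(q)),
                  paste0("phi_", seq_len(q)), nm, "alpha", "beta_cov", "phi")
  out
}

#' @rdname flatten_params
#' @param x numeric vector in serialization order.
#' @param q number of variables.
#' @export
unflatten_params <- function(x, q) {
  nfree <- 3L * q + (q * (q - 1L)) %/% 2L + 3L
  if (length(x) != nfree) stop("parameter vector has wrong length")
  k <- 0L
  take <- function(n) {
    out <- x[(k + 1L):(k + n)]
    k <<- k + n
    out
  }
  s1 <- take(q); s2 <- take(q); pi_ <- take(q)
  dl <- if (q > 1) take((q * (q - 1L)) %/% 2L) else numeric(0)
  delta <- matrix(0, q, q)
  if (q > 1) {
    kk <- 0L
    for (i in 2:q) for (j in 1:(i - 1)) {
      kk <- kk + 1L
      delta[i, j] <- delta[j, i] <- dl[kk]
    }
  }
  al <- take(1)
  bc <- take(1)
  ph <- take(1)
  cov_params(s1, s2, pi_, delta, alpha = al, beta_cov = bc, phi = ph)
}

#' Base correlation on the expanded domain
#'
#' `corr_base()` evaluates
#' \eqn{C(h,\Delta) = (1+\alpha\Delta)^{-\beta}\exp\{-\phi h
#' (1+\alpha\Delta)^{-\beta/2}\}}: an exponential spatial correlation whose
#' effective range is stretched by the latent distance \eqn{\Delta} between
#' variables, scaled by a Cauchy-type decay in \eqn{\Delta}.  It is
#' nonincreasing in both arguments and equals 1 only at h = 0, \eqn{\Delta}
#' = 0.
#'
#' @param h nonnegative spatial distance (vectorised).
#' @param Delta nonnegative latent distance (vectorised).
#' @param alpha,beta_cov,phi positive scalars.
#' @return Correlation values in (0, 1].
#' @export
corr_base <- function(h, Delta, alpha, beta_cov, phi) {
  if (alpha <= 0 || beta_cov <= 0 || phi <= 0) {
    stop("alpha, beta_cov and phi must be positive")
  }
  if (any(h < 0) || any(Delta < 0)) stop("h and Delta must be nonnegative")
  g <- (1 + alpha * Delta)^(-beta_cov)
  g * exp(-phi * h * sqrt(g))
}

#' Cross-covariance between two expanded locations
#'
#' @param l1,l2 [expanded_locs()] objects of length 1 (or equal length for
#'   elementwise evaluation).
#' @param params a [cov_params()] object.
#' @return Numeric covariance value(s).
#' @export
cross_cov <- function(l1, l2, params) {
  h <- sqrt(rowSums((l1$coords - l2$coords)^2))
  i <- l1$var
  j <- l2$var
  out <- numeric(length(h))
  same <- i == j
  if (any(same)) {
    ii <- i[same]
    out[same] <- params$sigma1[ii]^2 * exp(-params$phi * h[same]) +
      params$sigma2[ii]^2 * exp(-params$phi_i[ii] * h[same])
  }
  if (any(!same)) {
    ii <- i[!same]; jj <- j[!same]
    out[!same] <- params$sigma1[ii] * params$sigma1[jj] *
      corr_base(h[!same], params$delta[cbind(ii, jj)],
                params$alpha, params$beta_cov, params$phi)
  }
  out
}

#' Covariance matrix between two sets of expanded locations
#'
#' Entry (r, s) is the cross-covariance between `A[r]` and `B[s]`.  When `B`
#' is `A` itself, a relative jitter (`1e-9` times the mean diagonal) is added
#' before any factorisation downstream, since coincident or near-coincident
#' expanded locations arise by construction on gridded multivariate data.
#'
#' @param A,B [expanded_locs()] objects (`B` defaults to `A`).
#' @param params a [cov_params()] object.
#' @param jitter relative diagonal jitter used in self-covariance mode.
#' @return A `length(A)` x `length(B)` matrix.
#' @export
cov_matrix <- function(A, B = A, params, jitter = 1e-9) {
  self <- identical(A, B)
  out <- .cov_block_arma(A$coords, A$var, B$coords, B$var,
                         unclass(params))
  if (self) {
    out <- 0.5 * (out + t(out))
    diag(out) <- diag(out) + jitter * mean(diag(out))
  }
  out
}
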