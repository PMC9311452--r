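# Prior specification for the Bayesian spatial regression: Gaussian prior on
# fixed effects, inverse-gamma on nuggets, and flat (box) priors on the
# transformed covariance parameters.

#' Default transformed-scale prior for the covariance parameters
#'
#' Each free component of the covariance parameter vector gets a transform
#' (identity for the sign-free shared scales `sigma1`, log for positive
#' components), box bounds on the transformed scale, and an initial value
#' (the box midpoint on the transformed scale, i.e. the prior median).  The
#' prior is flat on the transformed scale inside the box.
#'
#' @param q number of variables.
#' @return A `theta_prior` list with `names`, `transform`, `lower`, `upper`
#'   (natural scale), `init` (natural scale).
#' @export
default_theta_prior <- function(q) {
  nm <- names(flatten_params(cov_params(rep(1, q), rep(1, q), rep(1, q),
                                        matrix(0, q, q), 1, 1, 1)))
  k <- length(nm)
  tr <- rep("log", k)
  lo <- numeric(k); hi <- numeric(k)
  is_s1 <- grepl("^sigma1_", nm)
  tr[is_s1] <- "identity"
  lo[is_s1] <- -5; hi[is_s1] <- 5
  lo[grepl("^sigma2_", nm)] <- 1e-2; hi[grepl("^sigma2_", nm)] <- 10
  lo[grepl("^phi_", nm)] <- 1e-2;   hi[grepl("^phi_", nm)] <- 10
  lo[grepl("^delta_", nm)] <- 1e-3; hi[grepl("^delta_", nm)] <- 20
  lo[nm == "alpha"] <- 1e-2; hi[nm == "alpha"] <- 10
  lo[nm == "beta_cov"] <- 1e-2; hi[nm == "beta_cov"] <- 10
  lo[nm == "phi"] <- 1e-2; hi[nm == "phi"] <- 50
  theta_prior_box(nm, tr, lo, hi)
}

#' Box prior for covariance parameters, matched to the synthetic benchmark
#'
#' Box supports aligned with the sampling distributions of the synthetic
#' study design (shared scales uniform on \[-3, 3\], spatial decays within
#' their sampled ranges), so that fitting a generated dataset uses a prior
#' consistent with how its parameters were drawn.
#'
#' @param q number of variables (2 for the shipped design).
#' @return A `theta_prior` list.
#' @export
sim_theta_prior <- function(q = 2L) {
  nm <- names(flatten_params(cov_params(rep(1, q), rep(1, q), rep(1, q),
                                        matrix(0, q, q), 1, 1, 1)))
  k <- length(nm)
  tr <- rep("log", k)
  lo <- numeric(k); hi <- numeric(k)
  is_s1 <- grepl("^sigma1_", nm)
  tr[is_s1] <- "identity"
  lo[is_s1] <- -3; hi[is_s1] <- 3
  lo[grepl("^sigma2_", nm)] <- 0.05; hi[grepl("^sigma2_", nm)] <- 5
  lo[grepl("^phi_", nm)] <- 0.1; hi[grepl("^phi_", nm)] <- 3
  lo[grepl("^delta_", nm)] <- 0.01; hi[grepl("^delta_", nm)] <- 10
  lo[nm == "alpha"] <- 0.1; hi[nm == "alpha"] <- 10
  lo[nm == "beta_cov"] <- 0.1; hi[nm == "beta_cov"] <- 10
  lo[nm == "phi"] <- 0.1; hi[nm == "phi"] <- 30
  theta_prior_box(nm, tr, lo, hi)
}

theta_prior_box <- function(nm, tr, lo, hi) {
  z_lo <- ifelse(tr == "log", log(pmax(lo, 1e-300)), lo)
  z_hi <- ifelse(tr == "log", log(pmax(hi, 1e-300)), hi)
  z_init <- (z_lo + z_hi) / 2
  init <- ifelse(tr == "log", exp(z_init), z_init)
  structure(list(names = nm, transform = tr, lower = lo, upper = hi,
                 z_lower = z_lo, z_upper = z_hi, init = init),
            class = "theta_prior")
}

theta_to_z <- function(params, tp) {
  x <- flatten_params(params)
  lg <- tp$transform == "log"
  x[lg] <- log(x[lg])
  x
}

z_to_theta <- function(z, tp, q) {
  unflatten_params(ifelse(tp$transform == "log", exp(z), z), q)
}

#' Prior specification for the spatial regression model
#'
#' @param q number of variables.
#' @param v_beta prior variance of the fixed effects (scalar for `v_beta *
#'   I`, or a PD matrix).
#' @param a_tau,b_tau inverse-gamma shape/rate for the nuggets.
#' @param theta_prior a `theta_prior` (see [default_theta_prior()]).
#' @return A `prior_spec` list.
#' @export
prior_spec <- function(q, v_beta = 100, a_tau = 2, b_tau = 1,
                       theta_prior = default_theta_prior(q)) {
  stopifnot(a_tau > 0, b_tau > 0)
  structure(list(q = as.integer(q), v_beta = v_beta, a_tau = a_tau,
                 b_tau = b_tau, theta = theta_prior),
            class = "prior_spec")
}
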