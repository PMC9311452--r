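# Structured run configuration (YAML): tree settings, MCMC settings,
# priors, simulation design and file paths, validated against the module
# preconditions before any computation.  Unknown keys are rejected.

config_defaults <- function() {
  list(
    tree = list(M = 3L, depth = 3L, branching = 4L, per_level_size = 20L,
                n_roots = 1L, root_bias_var = NULL, bias_weight = 5,
                cherry_pick_same_variable = FALSE,
                all_outcomes_colocated = FALSE,
                leaf_granularity = "terminal", preset = NULL),
    mcmc = list(n_iter = 1000L, burn = 500L, thin = 1L, seed = 1L,
                theta_update = "conditional"),
    priors = list(v_beta = 100, a_tau = 2, b_tau = 1,
                  theta_prior = "default"),
    simulation = list(grid_side = 30L, nuggets = c(0.01, 0.1),
                      retention = c(0.5, 0.1),
                      holes = list(count = 2L, radius = 0.1,
                                   missing_frac = 0.99),
                      seed = 1L, n_datasets = 1L),
    paths = list(data = NULL, truth = NULL, manifest = NULL, out = NULL,
                 model = NULL, locations = NULL)
  )
}

merge_checked <- function(def, usr, where) {
  if (is.null(usr)) return(def)
  unknown <- setdiff(names(usr), names(def))
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s) in ", where, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (nm in names(usr)) {
    if (is.list(def[[nm]]) && is.list(usr[[nm]]) &&
        !is.null(names(def[[nm]]))) {
      def[[nm]] <- merge_checked(def[[nm]], usr[[nm]],
                                 paste0(where, "$", nm))
    } else {
      def[[nm]] <- usr[[nm]]
    }
  }
  def
}

#' Read and validate a run configuration
#'
#' Reads a YAML file with (any of the) sections `tree`, `mcmc`, `priors`,
#' `simulation`, `paths`; unknown keys raise an error naming the key, and
#' the values are checked against the module preconditions (`depth` in
#' `1..M`, positive sizes, valid `theta_update`).
#'
#' @param path YAML file path, or a list already parsed.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  usr <- if (is.character(path)) yaml::read_yaml(path) else path
  cfg <- merge_checked(config_defaults(), usr, "config")
  with(cfg$tree, {
    if (depth < 1L || depth > M) stop("tree$depth must lie in 1..tree$M")
    if (per_level_size[1] < 1L) stop("tree$per_level_size must be >= 1")
  })
  if (!cfg$mcmc$theta_update %in% c("conditional", "integrated")) {
    stop("mcmc$theta_update must be 'conditional' or 'integrated'")
  }
  if (cfg$mcmc$n_iter < 0L) stop("mcmc$n_iter must be nonnegative")
  structure(cfg, class = "run_config")
}

config_tree_args <- function(cfg) {
  tr <- cfg$tree
  if (!is.null(tr$preset)) return(benchmark_tree(tr$preset))
  list(M = as.integer(tr$M), depth = as.integer(tr$depth),
       branching = as.integer(tr$branching),
       per_level_size = as.integer(tr$per_level_size),
       n_roots = as.integer(tr$n_roots),
       root_bias_var = if (is.null(tr$root_bias_var)) NULL
                       else as.integer(tr$root_bias_var),
       bias_weight = tr$bias_weight,
       same_variable_first = isTRUE(tr$cherry_pick_same_variable),
       all_outcomes_colocated = isTRUE(tr$all_outcomes_colocated),
       granularity = tr$leaf_granularity)
}

config_prior <- function(cfg, q) {
  tp <- if (identical(cfg$priors$theta_prior, "benchmark")) sim_theta_prior(q)
        else default_theta_prior(q)
  prior_spec(q, v_beta = cfg$priors$v_beta, a_tau = cfg$priors$a_tau,
             b_tau = cfg$priors$b_tau, theta_prior = tp)
}

config_mcmc <- function(cfg) {
  mcmc_config(n_iter = cfg$mcmc$n_iter, burn = cfg$mcmc$burn,
              thin = cfg$mcmc$thin, seed = cfg$mcmc$seed,
              theta_update = cfg$mcmc$theta_update)
}
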