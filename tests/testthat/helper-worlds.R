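# shared fixtures, all generated in code

quick_mcmc <- function(seed = 1, n_iter = 2000L, burn_in = 500L,
                       n_chains = 2L) {
  mcmc_config(n_chains = n_chains, n_iter = n_iter, burn_in = burn_in,
              target_ess = 0, seed = seed)
}

small_world <- function(n_mountains = 6, n_species = 40, seed = 1, ...) {
  generate_world(world_config(n_mountains = n_mountains,
                              n_species_per_mountain = n_species,
                              singleton_fraction = 0.1, seed = seed, ...),
                 true_parameters())
}

# records data.frame shorthand
rec_df <- function(min_elev, max_elev, mountain_id = "m1",
                   species_id = NULL) {
  n <- length(min_elev)
  data.frame(species_id = species_id %||% sprintf("sp%03d", seq_len(n)),
             mountain_id = rep_len(mountain_id, n),
             min_elev = min_elev, max_elev = max_elev)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal hand-built fit object for evaluation unit tests
fake_local_fit <- function(beta_draws_by_site, sigma2 = 0.5) {
  ids <- names(beta_draws_by_site)
  nd <- length(beta_draws_by_site[[1]])
  m <- cbind(matrix(5, nd, length(ids),
                    dimnames = list(NULL, sprintf("alpha[%s]", ids))),
             do.call(cbind, setNames(beta_draws_by_site,
                                     sprintf("beta[%s]", ids))),
             sigma2 = rep(sigma2, nd))
  structure(list(model = "local", draws = list(m), par_names = colnames(m),
                 site_ids = ids,
                 data = list(y = numeric(0), site = integer(0),
                             v = numeric(0)),
                 diagnostics = data.frame(parameter = colnames(m),
                                          rhat = NA, ess = NA),
                 n_extensions = 0L),
            class = "rsq_fit")
}
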