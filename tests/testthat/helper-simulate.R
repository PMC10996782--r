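# shared fixtures, built in code

default_trials <- function(seed = 3) build_choice_set(task_design(seed = seed))

# choices for a set of agents with given true parameters on shared trials
make_choices <- function(logk, trials, alpha = 3, eps = 0.02, seed = 1) {
  alpha <- rep_len(alpha, length(logk))
  eps <- rep_len(eps, length(logk))
  purrr::map_dfr(seq_along(logk), function(i) {
    tibble::tibble(
      participant_id = i,
      trial_id = trials$trial_id,
      choice = simulate_agent_choices(
        list(log_k = logk[i], alpha = alpha[i], epsilon = eps[i]),
        trials, seed = seed * 1000 + i)
    )
  })
}

quick_mcmc <- function(seed = 1) {
  mcmc_settings(n_chains = 2, n_samples = 1500, n_burnin = 500, n_thin = 2,
                seed = seed)
}
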