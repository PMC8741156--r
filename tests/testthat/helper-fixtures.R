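# shared fixtures: small simulated datasets built in code at test time

tiny_design <- function(n = 2, blocks = 1, tasks = "motion_coherence") {
  study_design(n_per_group = n, blocks_per_task = blocks, tasks = tasks)
}

tiny_sim <- function(n = 2, blocks = 1, seed = 1, config = generator_config(),
                     tasks = "motion_coherence") {
  simulate_behaviour(tiny_design(n, blocks, tasks), config, seed = seed)
}

default_params <- function(...) {
  args <- list(a = 0.1, z_rel = 0.5, ter = 0.3, v = 0.2, s = 0.1)
  args[names(list(...))] <- list(...)
  do.call(diffusion_params, args)
}

# quick lookup of a participant's true parameter values
truth_of <- function(sim, id, task = "motion_coherence") {
  sim$subjects[sim$subjects$participant_id == id &
                 sim$subjects$task == task, ]
}
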