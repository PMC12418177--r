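# Desk-scale trained models are expensive, so they are trained lazily once
# per test run and shared across test files.

.trained <- new.env(parent = emptyenv())

desk_train_config <- function(steps, seed) {
  training_config(batch_size = 4L, max_steps_per_stage = steps,
                  eval_every = 40L, n_val = 8L, lambda_rho = 2, seed = seed)
}

desk_stage1 <- function() {
  if (is.null(.trained$s1)) {
    stages <- default_curriculum(desk_scale = TRUE)
    m <- init_model(model_config(hidden_dim = 32L, n_blocks = 2L, t_max = 2L),
                    seed = 1L)
    .trained$s1 <- run_stage(m, stages[[1]], desk_train_config(400L, 11L))
  }
  .trained$s1
}

desk_stage2 <- function() {
  if (is.null(.trained$s2)) {
    stages <- default_curriculum(desk_scale = TRUE)
    .trained$s2 <- run_stage(desk_stage1()$model, stages[[2]],
                             desk_train_config(600L, 12L))
  }
  .trained$s2
}

desk_logr <- function() {
  if (is.null(.trained$lr)) {
    .trained$lr <- fine_tune_logr(desk_stage2()$model,
                                  train_config = desk_train_config(300L, 21L))
  }
  .trained$lr
}

stage_genome <- function(stage, seed, base_sim = NULL) {
  aracna:::simulate_stage_genome(stage, base_sim, seed)
}

locus_accuracy <- function(model, genome, states = NULL) {
  y <- profile_index(genome$truth$a_major, genome$truth$a_minor,
                     model$catalog)
  if (is.null(states)) {
    out <- model_forward(model, genome$observations)
    states <- max.col(out$class_probs)
  }
  mean(states == y)
}
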