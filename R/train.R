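#' A curriculum stage
#'
#' @param name Stage label.
#' @param t_max Maximum simulated total copy number for the stage.
#' @param length Simulated sequence length.
#' @param purity_sampling Sample purity from the configured range? When
#'   `FALSE` purity is fixed at 1.
#' @param noise_sampling Enable the simulator noise channels?
#' @param mode `"reads"` or `"logr"`.
#' @return A `curriculum_stage` list.
#' @export
curriculum_stage <- function(name, t_max, length, purity_sampling,
                             noise_sampling, mode = "reads") {
  structure(list(name = name, t_max = as.integer(t_max),
                 length = as.integer(length),
                 purity_sampling = isTRUE(purity_sampling),
                 noise_sampling = isTRUE(noise_sampling), mode = mode),
            class = "curriculum_stage")
}

#' Default curriculum
#'
#' The warmup schedule: start with pure noiseless diploid-regime genomes
#' (t_max 2), then add purity and noise sampling, then raise the maximum
#' total copy number step by step, then grow the sequence length by
#' doubling. The full-scale schedule ends at t_max 8 and length 650,000; desk scale —
#' what a single CPU trains in minutes — ends at t_max 4 and length 8,000.
#'
#' @param desk_scale Use the desk-scale schedule?
#' @return List of [curriculum_stage()]s.
#' @export
default_curriculum <- function(desk_scale = TRUE) {
  if (desk_scale) {
    list(
      curriculum_stage("stage1_diploid", 2, 2000, FALSE, FALSE),
      curriculum_stage("stage2_purity_noise", 2, 2000, TRUE, TRUE),
      curriculum_stage("stage3_tmax4", 4, 2000, TRUE, TRUE),
      curriculum_stage("stage4_len4000", 4, 4000, TRUE, TRUE),
      curriculum_stage("stage5_len8000", 4, 8000, TRUE, TRUE)
    )
  } else {
    stages <- list(
      curriculum_stage("stage1_diploid", 2, 10000, FALSE, FALSE),
      curriculum_stage("stage2_purity_noise", 2, 10000, TRUE, TRUE),
      curriculum_stage("stage3_tmax4", 4, 10000, TRUE, TRUE),
      curriculum_stage("stage3_tmax6", 6, 10000, TRUE, TRUE),
      curriculum_stage("stage3_tmax8", 8, 10000, TRUE, TRUE)
    )
    for (len in c(20000, 40000, 80000, 160000, 320000, 650000)) {
      stages[[length(stages) + 1L]] <-
        curriculum_stage(paste0("stage4_len", len), 8, len, TRUE, TRUE)
    }
    stages
  }
}

#' Training configuration
#'
#' @param batch_size Genomes per optimisation step (gradients averaged).
#' @param learning_rate Adam learning rate.
#' @param max_steps_per_stage Step cap per stage.
#' @param eval_every Steps between held-out evaluations.
#' @param patience Evaluations without improvement before stopping.
#' @param tolerance Minimum validation-loss improvement that counts.
#' @param n_val Number of fixed held-out validation genomes.
#' @param clip Global gradient-norm clip.
#' @param lambda_r,lambda_rho Loss weights used during optimisation. The
#'   default down-weights the reads-per-copy term to 0.1 so its absolute
#'   error (on the scale of tens of reads) does not swamp the cross entropy
#'   at desk scale.
#' @param lr_min_frac Linear learning-rate decay floor, as a fraction of
#'   `learning_rate`, reached at the step cap.
#' @param seed Base seed; training and validation genome seeds derive from it.
#' @param verbose Print progress lines?
#' @return A `training_config` list.
#' @export
training_config <- function(batch_size = 4L, learning_rate = 1e-3,
                            max_steps_per_stage = 400L, eval_every = 40L,
                            patience = 10L, tolerance = 1e-3, n_val = 8L,
                            clip = 1, lambda_r = 0.1, lambda_rho = 1,
                            lr_min_frac = 0.1, seed = 1L, verbose = FALSE) {
  stopifnot(batch_size >= 1, learning_rate > 0, max_steps_per_stage >= 1,
            eval_every >= 1, patience >= 1, tolerance >= 0, n_val >= 1,
            lambda_r >= 0, lambda_rho >= 0, lr_min_frac > 0, lr_min_frac <= 1)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 max_steps_per_stage = as.integer(max_steps_per_stage),
                 eval_every = as.integer(eval_every),
                 patience = as.integer(patience), tolerance = tolerance,
                 n_val = as.integer(n_val), clip = clip,
                 lambda_r = lambda_r, lambda_rho = lambda_rho,
                 lr_min_frac = lr_min_frac,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "training_config")
}

stage_sim_config <- function(stage, base_sim = NULL, seed = 1L) {
  if (is.null(base_sim)) base_sim <- sim_config()
  noise <- base_sim$noise
  noise$enabled <- stage$noise_sampling
  sim_config(length = stage$length, t_max = stage$t_max,
             max_segments = base_sim$max_segments,
             swap_prob = base_sim$swap_prob,
             poisson_rate = base_sim$poisson_rate,
             min_segment_len = base_sim$min_segment_len,
             purity_range = if (stage$purity_sampling) base_sim$purity_range
                            else c(1, 1),
             rd_range = base_sim$rd_range, noise = noise, ibd = base_sim$ibd,
             n_chrom = base_sim$n_chrom, seed = seed)
}

simulate_stage_genome <- function(stage, base_sim, seed) {
  cfg <- stage_sim_config(stage, base_sim, seed)
  gen <- simulate_genome(cfg)
  if (stage$mode == "logr") gen <- to_logr_inputs(gen)
  gen
}

adam_init <- function(par) {
  list(m = lapply(par, function(x) x * 0), v = lapply(par, function(x) x * 0),
       t = 0L)
}

adam_step <- function(par, grads, state, lr, clip = 1, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  gn <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
  scale <- if (is.finite(gn) && gn > clip) clip / gn else 1
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(par)) {
    gr <- grads[[nm]] * scale
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr * gr
    par[[nm]] <- par[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(par = par, state = state)
}

eval_model <- function(model, genomes, lambda_r = 1, lambda_rho = 1) {
  mean(vapply(genomes, function(g) {
    out <- model_forward(model, g$observations)
    total_loss(out, g, mode = model$mode, lambda_r = lambda_r,
               lambda_rho = lambda_rho, catalog = model$catalog)$total
  }, numeric(1)))
}

#' Train a model on one curriculum stage
#'
#' Streams freshly simulated genomes (never a fixed dataset), optimises the
#' composite loss with Adam under global gradient-norm clipping, evaluates
#' on a fixed set of seeded held-out genomes every `eval_every` steps, and
#' returns the parameters with the best validation loss. Stops when the
#' validation loss fails to improve by `tolerance` for `patience`
#' consecutive evaluations or at the step cap.
#'
#' @param model An `aracna_model` (its `mode` must match the stage mode).
#' @param stage A [curriculum_stage()].
#' @param train_config A [training_config()].
#' @param base_sim Optional base [sim_config()] giving ranges and noise
#'   defaults that the stage specialises.
#' @return List with `model` (best parameters), `history` (data.frame of
#'   evaluations) and `val_genomes`.
#' @export
run_stage <- function(model, stage, train_config = training_config(),
                      base_sim = NULL) {
  stopifnot(inherits(stage, "curriculum_stage"))
  if (stage$length > model$config$max_length)
    stop("stage length exceeds the model's max_length")
  if (stage$t_max > model$config$t_max)
    stop("stage t_max exceeds the model's t_max")
  model$mode <- stage$mode
  tc <- train_config
  val_genomes <- lapply(seq_len(tc$n_val), function(i) {
    simulate_stage_genome(stage, base_sim,
                          derive_seed(tc$seed, 900000L + i))
  })
  st <- adam_init(model$par)
  best_par <- model$par
  best_val <- eval_model(model, val_genomes, tc$lambda_r, tc$lambda_rho)
  start_val <- best_val
  bad <- 0L
  hist <- list(list(step = 0L, val_loss = best_val))
  counter <- 0L
  for (step in seq_len(tc$max_steps_per_stage)) {
    gacc <- NULL
    for (k in seq_len(tc$batch_size)) {
      counter <- counter + 1L
      gen <- simulate_stage_genome(stage, base_sim,
                                   derive_seed(tc$seed, counter))
      lg <- loss_and_grad(model, gen, tc$lambda_r, tc$lambda_rho)
      if (!is.finite(lg$loss$total))
        stop(sprintf("training diverged at step %d (non-finite loss)", step))
      gacc <- if (is.null(gacc)) lg$grads else
        mapply(`+`, gacc, lg$grads, SIMPLIFY = FALSE)
    }
    gacc <- lapply(gacc, function(g) g / tc$batch_size)
    lr_t <- tc$learning_rate *
      (1 - (1 - tc$lr_min_frac) * (step - 1) / tc$max_steps_per_stage)
    upd <- adam_step(model$par, gacc, st, lr_t, tc$clip)
    model$par <- upd$par
    st <- upd$state
    if (step %% tc$eval_every == 0L) {
      v <- eval_model(model, val_genomes, tc$lambda_r, tc$lambda_rho)
      hist[[length(hist) + 1L]] <- list(step = step, val_loss = v)
      if (tc$verbose)
        message(sprintf("[%s] step %d val %.4f", stage$name, step, v))
      if (v < best_val - tc$tolerance) {
        best_val <- v
        best_par <- model$par
        bad <- 0L
      } else {
        if (v < best_val) { best_val <- v; best_par <- model$par }
        bad <- bad + 1L
        if (bad >= tc$patience) break
      }
    }
  }
  model$par <- best_par
  history <- do.call(rbind, lapply(hist, as.data.frame))
  attr(history, "start_val") <- start_val
  attr(history, "best_val") <- best_val
  list(model = model, history = history, val_genomes = val_genomes)
}

#' Run a full curriculum
#'
#' Runs the stages sequentially, each initialised from the previous stage's
#' best parameters; optionally writes one checkpoint per stage plus a run
#' manifest (stage configs, seeds and package version).
#'
#' @param model An `aracna_model`.
#' @param stages List of [curriculum_stage()]s.
#' @param train_config A [training_config()].
#' @param base_sim Optional base [sim_config()].
#' @param checkpoint_dir Optional directory for per-stage checkpoints.
#' @return List with the final `model` and per-stage `history`.
#' @export
run_curriculum <- function(model, stages, train_config = training_config(),
                           base_sim = NULL, checkpoint_dir = NULL) {
  histories <- list()
  for (i in seq_along(stages)) {
    res <- run_stage(model, stages[[i]], train_config, base_sim)
    model <- res$model
    histories[[stages[[i]]$name]] <- res$history
    if (!is.null(checkpoint_dir)) {
      dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
      save_checkpoint(model, file.path(
        checkpoint_dir, paste0("ckpt_", i, "_", stages[[i]]$name, ".rds")))
    }
  }
  if (!is.null(checkpoint_dir)) {
    manifest <- list(
      package_version = as.character(utils::packageVersion("aracna")),
      seed = train_config$seed,
      stages = lapply(stages, unclass),
      training = unclass(train_config)
    )
    jsonlite::write_json(manifest, file.path(checkpoint_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(model = model, histories = histories)
}

#' Fine-tune a pretrained reads-mode model on logR inputs
#'
#' Swaps the read-depth input channel for the log ratio `l_r`, replaces the
#' reads-per-copy loss with the sample-ploidy loss `|Phi_s - Phi_hat|`, and
#' trains from the pretrained weights until convergence on logR simulations.
#' No architecture change is needed since only the depth channel is
#' replaced.
#'
#' @param model A pretrained `aracna_model` in reads mode.
#' @param stage Optional [curriculum_stage()] with `mode = "logr"`; defaults
#'   to a desk-scale stage with purity and noise sampling at the model's
#'   diploid-regime settings.
#' @param train_config A [training_config()].
#' @param base_sim Optional base [sim_config()].
#' @return The fine-tuned model (mode `"logr"`).
#' @export
fine_tune_logr <- function(model, stage = NULL,
                           train_config = training_config(),
                           base_sim = NULL) {
  if (!inherits(model, "aracna_model") || model$mode != "reads")
    stop("fine_tune_logr requires a reads-mode pretrained checkpoint")
  if (is.null(stage)) {
    stage <- curriculum_stage("logr_finetune", min(2L, model$config$t_max),
                              2000L, TRUE, TRUE, mode = "logr")
  }
  if (stage$mode != "logr") stop("stage mode must be 'logr'")
  res <- run_stage(model, stage, train_config, base_sim)
  res$model
}
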