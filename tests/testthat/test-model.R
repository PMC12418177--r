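tiny_model <- function(d = 6, blocks = 2, seed = 3) {
  init_model(model_config(hidden_dim = d, n_blocks = blocks, t_max = 2),
             seed = seed)
}

test_that("global placeholder is appended with zero features and flag 1", {
  obs <- make_obs(c(10, 20, 30), c(0.5, NA, 1))
  gp <- append_global_placeholder(obs)
  expect_identical(dim(gp$features), c(4L, 2L))
  expect_identical(gp$flags, c(0L, 0L, 0L, 1L))
  expect_identical(unname(gp$features[4, ]), c(0, 0))
  # removing the appended element recovers the raw channels bitwise
  expect_identical(unname(gp$features[1:3, 1]), obs$reads)
  expect_identical(unname(gp$features[1:3, 2]), obs$baf)
})

test_that("encoder is positionwise and rejects non-finite features", {
  m <- tiny_model()
  obs <- make_obs(rpois(5, 50), runif(5))
  gp <- append_global_placeholder(obs)
  X <- aracna:::prepare_features(gp$features, "reads")
  H <- encode(X, gp$flags, m)
  expect_identical(dim(H), c(6L, 6L))
  # changing locus 3 only changes row 3
  X2 <- X
  X2[3, 1] <- X2[3, 1] + 1
  H2 <- encode(X2, gp$flags, m)
  delta <- rowSums(abs(H2 - H))
  expect_true(delta[3] > 0)
  expect_true(all(delta[-3] == 0))
  X2[2, 1] <- NA
  expect_error(encode(X2, gp$flags, m), "finite")
})

test_that("backbone output at every position depends on every input position", {
  m <- tiny_model(d = 8, blocks = 1, seed = 5)
  set.seed(1)
  H <- matrix(rnorm(31 * 8), 31, 8)
  out <- backbone_forward(H, m)
  expect_identical(dim(out), dim(H))
  # first -> last (single-channel perturbation; a constant shift across
  # channels would be removed by layer normalisation)
  Hp <- H; Hp[1, 2] <- Hp[1, 2] + 1
  expect_gt(max(abs(backbone_forward(Hp, m)[31, ] - out[31, ])), 0)
  # last -> first
  Hq <- H; Hq[31, 2] <- Hq[31, 2] + 1
  expect_gt(max(abs(backbone_forward(Hq, m)[1, ] - out[1, ])), 0)
})

test_that("a strictly causal operator fails the reverse receptive-field test", {
  set.seed(2)
  U <- matrix(rnorm(20 * 4), 20, 4)
  a <- rep(0.9, 4)
  S <- ema_scan(U, a)
  Up <- U; Up[20, ] <- Up[20, ] + 5
  Sp <- ema_scan(Up, a)
  # perturbing the last position changes nothing upstream
  expect_identical(Sp[1:19, ], S[1:19, ])
  expect_gt(max(abs(Sp[20, ] - S[20, ])), 0)
})

test_that("decoder produces a simplex per locus and a purity in (0,1)", {
  m <- tiny_model()
  set.seed(3)
  obs <- make_obs(rpois(40, 60), runif(40))
  out <- model_forward(m, obs)
  expect_identical(dim(out$class_probs), c(40L, 4L))
  expect_true(all(abs(rowSums(out$class_probs) - 1) < 1e-5))
  expect_true(all(out$class_probs >= 0))
  expect_gt(out$purity_estimate, 0)
  expect_lt(out$purity_estimate, 1)
  # deterministic forward
  expect_identical(out$class_probs, model_forward(m, obs)$class_probs)
  # length flexibility without re-instantiation
  obs2 <- make_obs(rpois(77, 60), runif(77))
  expect_identical(nrow(model_forward(m, obs2)$class_probs), 77L)
  # overlong input is refused
  m_small <- init_model(model_config(hidden_dim = 4, n_blocks = 1, t_max = 2,
                                     max_length = 10), seed = 1)
  expect_error(model_forward(m_small, obs), "max_length")
})

test_that("cross entropy matches closed forms", {
  P <- matrix(0.25, 3, 4)
  expect_equal(sequence_loss(P, c(1, 2, 3)), log(4))
  Pone <- diag(4)[c(2, 4), ]
  expect_equal(sequence_loss(Pone, c(2, 4)), 0)
  # hand-computed 2-locus case
  P2 <- rbind(c(0.5, 0.5, 0, 0), c(0.25, 0.25, 0.25, 0.25))
  expect_equal(sequence_loss(P2, c(1, 3)), -(log(0.5) + log(0.25)) / 2,
               tolerance = 1e-12)
  expect_error(sequence_loss(P2, c(1, 9)), "outside")
})

test_that("reads-per-copy estimate follows the expected sample ploidy", {
  catalog <- enumerate_profiles(2)
  i11 <- profile_index(1, 1, catalog)
  P <- matrix(0, 50, 4); P[, i11] <- 1
  reads <- rep(60, 50)
  expect_equal(estimate_rd(reads, P, 1, catalog), 30)
  # sample ploidy is 2 regardless of purity when CN = 2
  expect_equal(estimate_rd(reads, P, 0.5, catalog), 30)
  expect_equal(estimate_rd(2 * reads, P, 1, catalog), 60)
  expect_error(estimate_rd(numeric(0), P, 1, catalog), "empty")
})

test_that("total loss composes its terms and vanishes for perfect predictions", {
  g <- make_fixture("diploid", seed = 4, length = 300)
  catalog <- enumerate_profiles(2)
  i11 <- profile_index(1, 1, catalog)
  P <- matrix(0, 300, 4); P[, i11] <- 1
  out <- list(class_probs = P, purity_estimate = 1 - 1e-12)
  lv <- total_loss(out, g, mode = "reads", catalog = catalog)
  expect_equal(lv$l_ss, 0)
  expect_equal(lv$l_srho, 0, tolerance = 1e-9)
  # l_sr = |r_d - mu_robust(R)/2|; with Poisson reads this is small but not 0
  expect_equal(lv$total, lv$l_ss + lv$lambda_r * lv$l_sr +
                 lv$lambda_rho * lv$l_srho)
  expect_equal(total_loss(out, g, mode = "reads", lambda_r = 0,
                          lambda_rho = 0, catalog = catalog)$total, 0)
  # logr mode with perfect classes and purity has zero ploidy loss
  set.seed(5)
  glr <- to_logr_inputs(g)
  lvl <- total_loss(out, glr, mode = "logr", catalog = catalog)
  expect_equal(lvl$l_sphi, 0, tolerance = 1e-9)
})

test_that("analytic gradients match finite differences on a tiny model", {
  g <- simulate_genome(sim_config(length = 20, t_max = 2, min_segment_len = 3,
                                  seed = 7))
  for (mode in c("reads", "logr")) {
    m <- tiny_model(d = 4, blocks = 2, seed = 3)
    gen <- g
    if (mode == "logr") {
      m$mode <- "logr"
      set.seed(5)
      gen <- to_logr_inputs(g)
    }
    base <- loss_and_grad(m, gen)
    eps <- 1e-6
    set.seed(1)
    worst <- 0
    for (nm in names(m$par)) {
      for (i in sample(length(m$par[[nm]]), min(3, length(m$par[[nm]])))) {
        m2 <- m
        m2$par[[nm]][i] <- m2$par[[nm]][i] + eps
        lp <- loss_and_grad(m2, gen)$loss$total
        m2$par[[nm]][i] <- m2$par[[nm]][i] - 2 * eps
        lm <- loss_and_grad(m2, gen)$loss$total
        num <- (lp - lm) / (2 * eps)
        ana <- base$grads[[nm]][i]
        worst <- max(worst, abs(num - ana) / max(1e-6, abs(num), abs(ana)))
      }
    }
    expect_lt(worst, 1e-4)
  }
})

test_that("checkpoints round-trip bit-identically", {
  m <- tiny_model(seed = 9)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_identical(m2$par, m$par)
  expect_identical(m2$config, m$config)
  expect_identical(m2$mode, m$mode)
  obs <- make_obs(rpois(10, 40), runif(10))
  expect_identical(model_forward(m, obs), model_forward(m2, obs))
  bad <- tempfile(fileext = ".rds")
  saveRDS(list(x = 1), bad)
  expect_error(load_checkpoint(bad), "format")
})
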