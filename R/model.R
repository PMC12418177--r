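#' Model configuration
#'
#' Defines the sequence-labelling network: a positionwise encoder into
#' dimension `hidden_dim`, `n_blocks` bidirectional long-range blocks, and a
#' two-stream decoder (per-locus class probabilities over the `t_max`
#' catalogue plus a global purity estimate read off an appended global
#' token).
#'
#' The `reference_bidirectional` backbone stacks gated multi-scale linear
#' recurrence (exponential-moving-average) operators run forward and over
#' the reversed sequence, their projections combined by elementwise sum with
#' a residual connection — a diagonal state-space-style operator whose
#' compute is linear in sequence length. Other long-range operators can be
#' plugged in via [register_backbone()] under the same contract: every
#' output position must depend on every input position.
#'
#' @param hidden_dim Hidden width d.
#' @param n_blocks Number of bidirectional blocks.
#' @param backbone_kind `"reference_bidirectional"` or the name of a
#'   registered external operator.
#' @param t_max Maximum modelled total copy number (fixes the class count J).
#' @param max_length Maximum accepted sequence length.
#' @param n_global_tokens Number of appended global tokens (only 1 supported).
#' @param mlp_mult Width multiplier of the positionwise feed-forward layer.
#' @return A `model_config` list.
#' @export
model_config <- function(hidden_dim = 32L, n_blocks = 2L,
                         backbone_kind = "reference_bidirectional",
                         t_max = 2L, max_length = 20000L,
                         n_global_tokens = 1L, mlp_mult = 2L) {
  stopifnot(hidden_dim >= 1, n_blocks >= 1, t_max >= 2, max_length >= 2)
  if (n_global_tokens != 1L) stop("only a single global token is supported")
  structure(list(hidden_dim = as.integer(hidden_dim),
                 n_blocks = as.integer(n_blocks),
                 backbone_kind = backbone_kind,
                 t_max = as.integer(t_max),
                 max_length = as.integer(max_length),
                 n_global_tokens = 1L,
                 mlp_mult = as.integer(mlp_mult),
                 n_features = 4L),
            class = "model_config")
}

.backbones <- new.env(parent = emptyenv())

#' Register an external long-range backbone operator
#'
#' The function must map `(hidden, params, config)` to a hidden matrix of
#' identical shape and give every output position a receptive field covering
#' the whole input.
#'
#' @param name Backbone identifier used in `model_config(backbone_kind=)`.
#' @param forward_fn The operator function.
#' @export
register_backbone <- function(name, forward_fn) {
  stopifnot(is.character(name), is.function(forward_fn))
  assign(name, forward_fn, envir = .backbones)
  invisible(name)
}

# column-broadcast helpers: v has one entry per column of M
bcast_mul <- function(M, v) M * rep(v, each = nrow(M))
bcast_add <- function(M, v) M + rep(v, each = nrow(M))

relu <- function(x) pmax(x, 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Initialise a model
#'
#' He-scaled Gaussian weights; recurrence decay logits are spread
#' deterministically from -1 to 8 across channels (decays ~0.27 to ~0.9997)
#' so the randomly initialised backbone already mixes local and near-global
#' time scales.
#'
#' @param config A [model_config()].
#' @param seed Integer seed for the weight draw.
#' @return An `aracna_model`: list with `config`, `catalog`, `par` (named
#'   list of arrays), `mode` (`"reads"` or `"logr"`).
#' @export
init_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  set.seed(seed)
  d <- config$hidden_dim
  m <- d * config$mlp_mult
  catalog <- enumerate_profiles(config$t_max)
  J <- catalog$j
  he <- function(nin, nout) matrix(rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
  par <- list(
    # small nonzero bias keeps the all-zero global-token features off the
    # ReLU kink
    enc_W1 = he(config$n_features, d), enc_b1 = rep(0.01, d),
    enc_W2 = he(d, d), enc_b2 = numeric(d),
    tok_E = matrix(rnorm(2 * d, 0, 0.1), 2, d)
  )
  for (b in seq_len(config$n_blocks)) {
    p <- function(nm) paste0("blk", b, "_", nm)
    decay_logits <- seq(-1, 8, length.out = d) + rnorm(d, 0, 0.05)
    par[[p("ln1_g")]] <- rep(1, d); par[[p("ln1_b")]] <- numeric(d)
    par[[p("Wf")]] <- he(d, d);     par[[p("bf")]] <- numeric(d)
    par[[p("Wr")]] <- he(d, d);     par[[p("br")]] <- numeric(d)
    par[[p("pf")]] <- decay_logits
    par[[p("pr")]] <- rev(decay_logits)
    par[[p("Of")]] <- he(d, d) * 0.5
    par[[p("Or")]] <- he(d, d) * 0.5
    par[[p("bo")]] <- numeric(d)
    par[[p("ln2_g")]] <- rep(1, d); par[[p("ln2_b")]] <- numeric(d)
    par[[p("Wm1")]] <- he(d, m);    par[[p("bm1")]] <- numeric(m)
    par[[p("Wm2")]] <- he(m, d) * 0.5; par[[p("bm2")]] <- numeric(d)
  }
  par$dec_Wc1 <- he(d, d); par$dec_bc1 <- numeric(d)
  par$dec_Wc2 <- he(d, J); par$dec_bc2 <- numeric(J)
  par$dec_Wg1 <- he(d, d); par$dec_bg1 <- numeric(d)
  par$dec_wg2 <- matrix(rnorm(d, 0, sqrt(1 / d)), d, 1)
  par$dec_bg2 <- 0
  structure(list(config = config, catalog = catalog, par = par,
                 mode = "reads"),
            class = "aracna_model")
}

#' @export
print.aracna_model <- function(x, ...) {
  np <- sum(vapply(x$par, length, integer(1)))
  cat(sprintf(paste0("aracna model: d=%d, %d block(s), t_max=%d (J=%d), ",
                     "mode=%s, %d parameters\n"),
              x$config$hidden_dim, x$config$n_blocks, x$config$t_max,
              x$catalog$j, x$mode, np))
  invisible(x)
}

#' Append the global placeholder element
#'
#' The global purity estimate is read off an extra element appended to the
#' end of the sequence with zero values in both observation channels; a
#' token flag distinguishes it (0 for the L data elements, 1 for the
#' appended one).
#'
#' @param obs Observation track data.frame with `reads` (or `logr`) and
#'   `baf` columns.
#' @param mode `"reads"` or `"logr"` — which depth channel is used.
#' @return List with `features` ((L+1) x 2 matrix of the raw channels, NA
#'   preserved) and `flags` (length L+1 integer 0/1).
#' @export
append_global_placeholder <- function(obs, mode = "reads") {
  L <- nrow(obs)
  if (is.null(L) || L < 1) stop("observation track must have at least 1 locus")
  depth <- if (mode == "logr") obs$logr else obs$reads
  features <- cbind(depth = c(depth, 0), baf = c(obs$baf, 0))
  list(features = features, flags = c(rep(0L, L), 1L))
}

# Raw channels -> finite model features:
#  reads mode: x1 = log1p(reads)/4; logr mode: x1 = l_r (0 where missing).
#  x2 = BAF with missing imputed at 0.5; x3 = missing-data indicator;
#  x4 = folded BAF |x2 - 0.5|, the heterozygous band offset that carries the
#  purity signal directly.
prepare_features <- function(raw, mode) {
  depth <- raw[, 1L]
  baf <- raw[, 2L]
  miss <- as.numeric(is.na(baf) | is.na(depth))
  x1 <- if (mode == "logr") ifelse(is.na(depth), 0, depth) else log1p(depth) / 4
  x2 <- ifelse(is.na(baf), 0.5, baf)
  cbind(x1, x2, miss, abs(x2 - 0.5))
}

layernorm_fwd <- function(H, g, b, eps = 1e-5) {
  mu <- rowMeans(H)
  Hc <- H - mu
  sd <- sqrt(rowMeans(Hc * Hc) + eps)
  N <- Hc / sd
  list(out = bcast_add(bcast_mul(N, g), b), N = N, sd = sd)
}

layernorm_bwd <- function(dY, cacheln, g) {
  N <- cacheln$N
  dg <- colSums(dY * N)
  db <- colSums(dY)
  dZ <- bcast_mul(dY, g)
  dH <- (dZ - rowMeans(dZ) - N * rowMeans(dZ * N)) / cacheln$sd
  list(dH = dH, dg = dg, db = db)
}

#' Encode features and token flags into the hidden space
#'
#' The observation channels pass through a two-layer perceptron with ReLU
#' into dimension d; the token flag indexes a learned two-entry embedding;
#' the two are combined by elementwise addition.
#'
#' @param features Finite (L+1) x 3 feature matrix (see
#'   [append_global_placeholder()]; missing values must already be imputed).
#' @param flags Length L+1 token flags (0 data / 1 global).
#' @param model An `aracna_model`.
#' @return Hidden matrix (L+1) x d (invisibly also used internally with a
#'   cache).
#' @export
encode <- function(features, flags, model) {
  if (!all(is.finite(features))) stop("encoder features must be finite")
  encode_cache(features, flags, model$par)$out
}

encode_cache <- function(X, flags, par) {
  E1pre <- bcast_add(X %*% par$enc_W1, par$enc_b1)
  E1 <- relu(E1pre)
  H <- bcast_add(E1 %*% par$enc_W2, par$enc_b2) + par$tok_E[flags + 1L, , drop = FALSE]
  list(out = H, X = X, flags = flags, E1pre = E1pre, E1 = E1)
}

block_forward <- function(H0, par, b) {
  p <- function(nm) par[[paste0("blk", b, "_", nm)]]
  n <- nrow(H0)
  ln1 <- layernorm_fwd(H0, p("ln1_g"), p("ln1_b"))
  Z1 <- ln1$out
  Uf <- bcast_add(Z1 %*% p("Wf"), p("bf"))
  Ur <- bcast_add(Z1 %*% p("Wr"), p("br"))
  af <- sigmoid(p("pf"))
  ar <- sigmoid(p("pr"))
  Sf <- ema_scan(Uf, af)
  Ur_rev <- Ur[n:1, , drop = FALSE]
  Sr_rev <- ema_scan(Ur_rev, ar)
  Sr <- Sr_rev[n:1, , drop = FALSE]
  A <- bcast_add(Sf %*% p("Of") + Sr %*% p("Or"), p("bo"))
  H1 <- H0 + A
  ln2 <- layernorm_fwd(H1, p("ln2_g"), p("ln2_b"))
  Z2 <- ln2$out
  Mpre <- bcast_add(Z2 %*% p("Wm1"), p("bm1"))
  Mh <- relu(Mpre)
  H2 <- H1 + bcast_add(Mh %*% p("Wm2"), p("bm2"))
  list(out = H2, H0 = H0, ln1 = ln1, Z1 = Z1, Uf = Uf, Ur = Ur,
       af = af, ar = ar, Sf = Sf, Ur_rev = Ur_rev, Sr_rev = Sr_rev, Sr = Sr,
       H1 = H1, ln2 = ln2, Z2 = Z2, Mpre = Mpre, Mh = Mh)
}

#' Run the bidirectional backbone
#'
#' Applies `n_blocks` blocks, each running a causal linear-recurrence
#' operator forward and a second operator over the reversed sequence,
#' combining their output projections by elementwise sum with a residual
#' connection, followed by a positionwise feed-forward sublayer. Output
#' position i depends on every input position.
#'
#' @param hidden (L+1) x d hidden matrix.
#' @param model An `aracna_model`.
#' @return Hidden matrix of the same shape.
#' @export
backbone_forward <- function(hidden, model) {
  cfg <- model$config
  if (nrow(hidden) > cfg$max_length + 1L)
    stop("sequence longer than the model's max_length")
  if (cfg$backbone_kind != "reference_bidirectional") {
    fn <- get0(cfg$backbone_kind, envir = .backbones)
    if (is.null(fn)) stop("unknown backbone kind: ", cfg$backbone_kind)
    return(fn(hidden, model$par, cfg))
  }
  H <- hidden
  for (b in seq_len(cfg$n_blocks)) H <- block_forward(H, model$par, b)$out
  H
}

#' Decode hidden states into class probabilities and purity
#'
#' The copy-number stream applies a positionwise perceptron and a softmax
#' over the J catalogue classes at the first L positions; the global stream
#' applies a perceptron and sigmoid at the appended global position to give
#' the purity estimate.
#'
#' @param hidden (L+1) x d hidden matrix.
#' @param model An `aracna_model`.
#' @return List with `class_probs` (L x J) and `purity_estimate`.
#' @export
decode <- function(hidden, model) {
  dc <- decode_cache(hidden, model$par)
  list(class_probs = dc$P, purity_estimate = dc$rho_hat)
}

decode_cache <- function(H, par) {
  n <- nrow(H)
  Hc <- H[-n, , drop = FALSE]
  A1pre <- bcast_add(Hc %*% par$dec_Wc1, par$dec_bc1)
  A1 <- relu(A1pre)
  G <- bcast_add(A1 %*% par$dec_Wc2, par$dec_bc2)
  Gm <- G - apply(G, 1L, max)
  E <- exp(Gm)
  P <- E / rowSums(E)
  hg <- H[n, ]
  A2pre <- drop(hg %*% par$dec_Wg1) + par$dec_bg1
  A2 <- relu(A2pre)
  zg <- sum(A2 * par$dec_wg2) + par$dec_bg2
  rho_hat <- sigmoid(zg)
  list(P = P, rho_hat = rho_hat, Hc = Hc, A1pre = A1pre, A1 = A1,
       hg = hg, A2pre = A2pre, A2 = A2)
}

#' Full forward pass on an observation track
#'
#' @param model An `aracna_model`.
#' @param obs Observation track data.frame.
#' @param cache Keep intermediates for the backward pass?
#' @return List with `class_probs` (L x J rows summing to 1),
#'   `purity_estimate` in (0, 1) and (if requested) `cache`.
#' @export
model_forward <- function(model, obs, cache = FALSE) {
  gp <- append_global_placeholder(obs, model$mode)
  X <- prepare_features(gp$features, model$mode)
  if (!all(is.finite(X))) stop("non-finite model features")
  cfg <- model$config
  if (nrow(X) > cfg$max_length + 1L)
    stop("sequence longer than the model's max_length")
  enc <- encode_cache(X, gp$flags, model$par)
  H <- enc$out
  blocks <- vector("list", cfg$n_blocks)
  if (cfg$backbone_kind == "reference_bidirectional") {
    for (b in seq_len(cfg$n_blocks)) {
      blocks[[b]] <- block_forward(H, model$par, b)
      H <- blocks[[b]]$out
    }
  } else {
    H <- backbone_forward(H, model)
  }
  dc <- decode_cache(H, model$par)
  out <- list(class_probs = dc$P, purity_estimate = dc$rho_hat)
  if (cache) out$cache <- list(enc = enc, blocks = blocks, dec = dc)
  out
}
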