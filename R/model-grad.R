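# Reverse-mode gradients of the composite training loss with respect to
# every model parameter, hand-derived for the reference backbone and
# verified against finite differences in the test suite.

#' Training loss and analytic parameter gradients for one genome
#'
#' @param model An `aracna_model` with the reference backbone.
#' @param genome A `simulated_genome` (with a `logr` column when the model
#'   is in logR mode).
#' @param lambda_r,lambda_rho Loss weights.
#' @return List with `loss` (a `loss_values`), `output` (forward result) and
#'   `grads` (named list matching `model$par`).
#' @export
loss_and_grad <- function(model, genome, lambda_r = 1, lambda_rho = 1) {
  if (model$config$backbone_kind != "reference_bidirectional")
    stop("analytic gradients are implemented for the reference backbone")
  par <- model$par
  cfg <- model$config
  catalog <- model$catalog
  mode <- model$mode

  out <- model_forward(model, genome$observations, cache = TRUE)
  cache <- out$cache
  P <- out$class_probs
  rho_hat <- out$purity_estimate
  L <- nrow(P)
  J <- ncol(P)
  y <- profile_index(genome$truth$a_major, genome$truth$a_minor, catalog)

  tvec <- catalog$profiles$total
  e <- drop(P %*% tvec)
  phi_hat <- rho_hat * mean(e) + 2 * (1 - rho_hat)

  p_at <- P[cbind(seq_len(L), y)]
  l_ss <- -mean(log(pmax(p_at, LOG_EPS)))
  l_srho <- abs(genome$params$rho - rho_hat)
  l_sphi <- NULL
  if (mode == "reads") {
    muR <- robust_mean(genome$observations$reads, 0.05)
    rd_hat <- muR / phi_hat
    l_sr <- abs(genome$params$r_d - rd_hat)
    dL_dphi <- lambda_r * sign(rd_hat - genome$params$r_d) *
      (-muR / phi_hat^2)
    total <- l_ss + lambda_r * l_sr + lambda_rho * l_srho
  } else {
    st <- sample_copy_track(genome$truth, genome$params$rho)
    phi_s <- sample_ploidy(st$c_s_total)
    l_sphi <- abs(phi_s - phi_hat)
    l_sr <- 0
    dL_dphi <- lambda_r * sign(phi_hat - phi_s)
    total <- l_ss + lambda_r * l_sphi + lambda_rho * l_srho
  }
  loss <- structure(list(l_ss = l_ss, l_sr = l_sr, l_srho = l_srho,
                         l_sphi = l_sphi, total = total,
                         lambda_r = lambda_r, lambda_rho = lambda_rho),
                    class = "loss_values")

  # --- gradients on the class logits -------------------------------------
  Y <- matrix(0, L, J)
  Y[cbind(seq_len(L), y)] <- 1
  dG <- (P - Y) / L
  # ploidy pathway through the softmax: d phi / d logit_{i,k}
  #   = rho_hat/L * P_{i,k} (t_k - e_i)
  cph <- dL_dphi * rho_hat / L
  if (cph != 0) {
    TV <- matrix(tvec, L, J, byrow = TRUE)
    dG <- dG + cph * P * (TV - e)
  }
  dL_drho <- lambda_rho * sign(rho_hat - genome$params$rho) +
    dL_dphi * (mean(e) - 2)

  g <- list()
  dec <- cache$dec

  # --- decoder: copy number stream ---------------------------------------
  g$dec_Wc2 <- t(dec$A1) %*% dG
  g$dec_bc2 <- colSums(dG)
  dA1 <- dG %*% t(par$dec_Wc2)
  dA1pre <- dA1 * (dec$A1pre > 0)
  g$dec_Wc1 <- t(dec$Hc) %*% dA1pre
  g$dec_bc1 <- colSums(dA1pre)
  dHc <- dA1pre %*% t(par$dec_Wc1)

  # --- decoder: global stream --------------------------------------------
  dzg <- dL_drho * rho_hat * (1 - rho_hat)
  g$dec_wg2 <- matrix(dzg * dec$A2, ncol = 1)
  g$dec_bg2 <- dzg
  dA2 <- dzg * drop(par$dec_wg2)
  dA2pre <- dA2 * (dec$A2pre > 0)
  g$dec_Wg1 <- outer(dec$hg, dA2pre)
  g$dec_bg1 <- dA2pre
  dhg <- drop(par$dec_Wg1 %*% dA2pre)

  dH <- rbind(dHc, dhg)

  # --- backbone blocks in reverse ----------------------------------------
  for (b in rev(seq_len(cfg$n_blocks))) {
    ck <- cache$blocks[[b]]
    pn <- function(x) paste0("blk", b, "_", x)
    p <- function(x) par[[pn(x)]]
    dM <- dH
    g[[pn("Wm2")]] <- t(ck$Mh) %*% dM
    g[[pn("bm2")]] <- colSums(dM)
    dMh <- dM %*% t(p("Wm2"))
    dMpre <- dMh * (ck$Mpre > 0)
    g[[pn("Wm1")]] <- t(ck$Z2) %*% dMpre
    g[[pn("bm1")]] <- colSums(dMpre)
    dZ2 <- dMpre %*% t(p("Wm1"))
    lb2 <- layernorm_bwd(dZ2, ck$ln2, p("ln2_g"))
    g[[pn("ln2_g")]] <- lb2$dg
    g[[pn("ln2_b")]] <- lb2$db
    dH1 <- dH + lb2$dH

    dA <- dH1
    g[[pn("Of")]] <- t(ck$Sf) %*% dA
    g[[pn("Or")]] <- t(ck$Sr) %*% dA
    g[[pn("bo")]] <- colSums(dA)
    dSf <- dA %*% t(p("Of"))
    dSr <- dA %*% t(p("Or"))
    ef <- ema_scan_grad(ck$Uf, ck$af, ck$Sf, dSf)
    dUf <- ef$gu
    g[[pn("pf")]] <- ef$ga * ck$af * (1 - ck$af)
    nr <- nrow(dSr)
    dSr_rev <- dSr[nr:1, , drop = FALSE]
    er <- ema_scan_grad(ck$Ur_rev, ck$ar, ck$Sr_rev, dSr_rev)
    dUr <- er$gu[nr:1, , drop = FALSE]
    g[[pn("pr")]] <- er$ga * ck$ar * (1 - ck$ar)
    g[[pn("Wf")]] <- t(ck$Z1) %*% dUf
    g[[pn("bf")]] <- colSums(dUf)
    g[[pn("Wr")]] <- t(ck$Z1) %*% dUr
    g[[pn("br")]] <- colSums(dUr)
    dZ1 <- dUf %*% t(p("Wf")) + dUr %*% t(p("Wr"))
    lb1 <- layernorm_bwd(dZ1, ck$ln1, p("ln1_g"))
    g[[pn("ln1_g")]] <- lb1$dg
    g[[pn("ln1_b")]] <- lb1$db
    dH <- dH1 + lb1$dH
  }

  # --- encoder ------------------------------------------------------------
  enc <- cache$enc
  g$enc_W2 <- t(enc$E1) %*% dH
  g$enc_b2 <- colSums(dH)
  dE1 <- dH %*% t(par$enc_W2)
  dE1pre <- dE1 * (enc$E1pre > 0)
  g$enc_W1 <- t(enc$X) %*% dE1pre
  g$enc_b1 <- colSums(dE1pre)
  gE <- matrix(0, 2, cfg$hidden_dim)
  f1 <- enc$flags == 1L
  gE[1, ] <- colSums(dH[!f1, , drop = FALSE])
  gE[2, ] <- colSums(dH[f1, , drop = FALSE])
  g$tok_E <- gE

  list(loss = loss, output = list(class_probs = P, purity_estimate = rho_hat),
       grads = g)
}
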