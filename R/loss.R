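LOG_EPS <- 1e-12

#' Supervised sequence loss (cross entropy)
#'
#' `-(1/L) sum_i log p_{y_i, i}` with probabilities clamped at 1e-12 for
#' numerical safety.
#'
#' @param class_probs L x J matrix of per-locus class probabilities.
#' @param target_classes Length-L integer vector of 1-based class indices.
#' @return Scalar loss.
#' @export
sequence_loss <- function(class_probs, target_classes) {
  L <- nrow(class_probs)
  stopifnot(length(target_classes) == L)
  if (any(target_classes < 1 | target_classes > ncol(class_probs)))
    stop("target class index outside the catalogue")
  p <- class_probs[cbind(seq_len(L), target_classes)]
  -mean(log(pmax(p, LOG_EPS)))
}

#' Estimate reads per copy from model output
#'
#' `r_d_hat = robust_mean(reads) / Phi_hat` where `Phi_hat` is the expected
#' sample ploidy under the output distribution:
#' `(1/L) sum_i [rho_hat * sum_k p_{k,i} (A_M(k) + A_m(k)) + 2 (1 - rho_hat)]`.
#' Using the probability-weighted expectation keeps the estimate
#' differentiable through both the class probabilities and the purity
#' estimate during training; at inference the smoothed hard states are used
#' instead (see [call_genome()]).
#'
#' @param reads Per-locus read counts.
#' @param class_probs L x J class probability matrix.
#' @param purity_estimate Scalar purity estimate in \[0, 1\].
#' @param catalog The class catalogue.
#' @param trim Trim fraction of the robust mean.
#' @return Scalar reads-per-copy estimate.
#' @export
estimate_rd <- function(reads, class_probs, purity_estimate, catalog,
                        trim = 0.05) {
  if (!length(reads)) stop("empty reads vector")
  tvec <- catalog$profiles$total
  phi <- purity_estimate * mean(class_probs %*% tvec) +
    2 * (1 - purity_estimate)
  if (phi <= 1e-9) stop("degenerate sample ploidy estimate")
  robust_mean(reads, trim) / phi
}

#' Composite training loss
#'
#' Reads mode: `L_ss + lambda_r |r_d - r_d_hat| + lambda_rho |rho - rho_hat|`.
#' LogR mode replaces the reads-per-copy term with the sample ploidy term
#' `L_sPhi = |Phi_s - Phi_hat|`, which links the purity estimate to the
#' output copy numbers when no absolute read scale is available.
#'
#' @param output List with `class_probs` and `purity_estimate` (a
#'   [model_forward()] result).
#' @param genome A `simulated_genome` providing targets, true parameters and
#'   observed reads.
#' @param mode `"reads"` or `"logr"`.
#' @param lambda_r,lambda_rho Loss weights (default 1).
#' @param catalog Catalogue matching the columns of `class_probs`.
#' @return A `loss_values` list with `l_ss`, `l_sr`, `l_srho`, `l_sphi`,
#'   `total`, `lambda_r`, `lambda_rho`.
#' @export
total_loss <- function(output, genome, mode = c("reads", "logr"),
                       lambda_r = 1, lambda_rho = 1, catalog = NULL) {
  mode <- match.arg(mode)
  if (is.null(catalog)) {
    tm <- max(2L, max(genome$truth$a_major + genome$truth$a_minor))
    catalog <- enumerate_profiles(tm)
  }
  if (catalog$j != ncol(output$class_probs))
    stop("catalogue does not match class_probs columns")
  y <- profile_index(genome$truth$a_major, genome$truth$a_minor, catalog)
  l_ss <- sequence_loss(output$class_probs, y)
  rho_hat <- output$purity_estimate
  l_srho <- abs(genome$params$rho - rho_hat)
  l_sr <- 0
  l_sphi <- NULL
  if (mode == "reads") {
    rd_hat <- estimate_rd(genome$observations$reads, output$class_probs,
                          rho_hat, catalog)
    l_sr <- abs(genome$params$r_d - rd_hat)
    total <- l_ss + lambda_r * l_sr + lambda_rho * l_srho
  } else {
    tvec <- catalog$profiles$total
    phi_hat <- rho_hat * mean(output$class_probs %*% tvec) + 2 * (1 - rho_hat)
    st <- sample_copy_track(genome$truth, genome$params$rho)
    l_sphi <- abs(sample_ploidy(st$c_s_total) - phi_hat)
    total <- l_ss + lambda_r * l_sphi + lambda_rho * l_srho
  }
  structure(list(l_ss = l_ss, l_sr = l_sr, l_srho = l_srho, l_sphi = l_sphi,
                 total = total, lambda_r = lambda_r, lambda_rho = lambda_rho),
            class = "loss_values")
}
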