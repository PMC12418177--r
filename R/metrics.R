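#' BAF reconstruction root mean square error
#'
#' For each locus with an observed BAF, the reconstructed BAF under each
#' haplotype configuration `(s1, s2)` in `{0,1}^2` is
#' `[s1 ((1-rho) + rho A_M) + s2 ((1-rho) + rho A_m)] /
#'  [2 (1-rho) + rho (A_M + A_m)]`;
#' the configuration minimising the absolute residual to the observed BAF
#' (the most probable haplotype) is selected and the RMSE of the selected
#' residuals returned. Loci with missing BAF, or zero sample copy number
#' (purity 1 with total copy number 0), are skipped.
#'
#' @param obs_baf Observed per-locus BAF (may contain `NA`).
#' @param called_major,called_minor Called major/minor copy numbers
#'   (numeric; fractional values from subclonal mixtures are allowed).
#' @param purity Purity estimate in \[0, 1\].
#' @return A `reconstruction` list with `value` (the RMSE) and `n_loci_used`.
#' @export
baf_rmse <- function(obs_baf, called_major, called_minor, purity) {
  check_rho(purity)
  L <- length(obs_baf)
  stopifnot(length(called_major) == L, length(called_minor) == L)
  denom <- 2 * (1 - purity) + purity * (called_major + called_minor)
  use <- !is.na(obs_baf) & denom > 0
  if (!any(use)) return(list(value = NA_real_, n_loci_used = 0L))
  fM <- ((1 - purity) + purity * called_major[use]) / denom[use]
  fm <- ((1 - purity) + purity * called_minor[use]) / denom[use]
  b <- obs_baf[use]
  res <- pmin(abs(b - 0), abs(b - fM), abs(b - fm), abs(b - 1))
  list(value = sqrt(mean(res^2)), n_loci_used = sum(use))
}

#' Read-depth reconstruction mean absolute error
#'
#' Computes the called sample total copy number
#' `C^s_T = 2 (1-rho) + rho (A_M + A_m)`, the implied reads per copy
#' `r_d_hat = robust_mean(reads) / mean(C^s_T)`, the reconstructed depth
#' `R_hat = r_d_hat * C^s_T`, and returns the mean absolute error
#' `(1/L) sum |R - R_hat|`. Absolute (not squared) error is used because
#' mapping artefacts inflate read depth at some loci. All loci are retained,
#' including those with missing BAF.
#'
#' @param obs_reads Observed per-locus read counts.
#' @param called_major,called_minor Called copy numbers (numeric).
#' @param purity Purity estimate in \[0, 1\].
#' @param trim Trim fraction for the robust mean.
#' @return A `reconstruction` list with `value` (the MAE), `rd_hat` and
#'   `n_loci_used`.
#' @export
read_depth_mae <- function(obs_reads, called_major, called_minor, purity,
                           trim = 0.05) {
  check_rho(purity)
  L <- length(obs_reads)
  stopifnot(length(called_major) == L, length(called_minor) == L)
  cst <- 2 * (1 - purity) + purity * (called_major + called_minor)
  if (mean(cst) <= 1e-9) stop("degenerate reconstruction: zero mean copy number")
  rd_hat <- robust_mean(obs_reads, trim) / mean(cst)
  list(value = mean(abs(obs_reads - rd_hat * cst)), rd_hat = rd_hat,
       n_loci_used = L)
}

#' Locuswise concordance between two sets of copy number calls
#'
#' Agreement rates of the major, minor, both and total copy numbers. When
#' the second caller reports only total copy number, only `cc_total` is
#' defined. With ground truth as the first input the values read as
#' accuracies.
#'
#' @param calls1,calls2 data.frames with `major_cn` and `minor_cn` columns
#'   (or `total_cn` only for `calls2`).
#' @return A `concordance_metrics` list with `cc_major`, `cc_minor`,
#'   `cc_both`, `cc_total`.
#' @export
concordance <- function(calls1, calls2) {
  if (nrow(calls1) != nrow(calls2))
    stop("call tracks have different lengths")
  tot1 <- if (!is.null(calls1$total_cn)) calls1$total_cn else
    calls1$major_cn + calls1$minor_cn
  if (is.null(calls2$major_cn) || is.null(calls2$minor_cn)) {
    tot2 <- calls2$total_cn
    return(structure(list(cc_major = NA_real_, cc_minor = NA_real_,
                          cc_both = NA_real_, cc_total = mean(tot1 == tot2)),
                     class = "concordance_metrics"))
  }
  tot2 <- if (!is.null(calls2$total_cn)) calls2$total_cn else
    calls2$major_cn + calls2$minor_cn
  eq_major <- calls1$major_cn == calls2$major_cn
  eq_minor <- calls1$minor_cn == calls2$minor_cn
  structure(list(cc_major = mean(eq_major), cc_minor = mean(eq_minor),
                 cc_both = mean(eq_major & eq_minor),
                 cc_total = mean(tot1 == tot2)),
            class = "concordance_metrics")
}

#' @export
print.concordance_metrics <- function(x, ...) {
  cat(sprintf("Concordance: major %.3f, minor %.3f, both %.3f, total %.3f\n",
              x$cc_major, x$cc_minor, x$cc_both, x$cc_total))
  invisible(x)
}

#' Subclonal (Battenberg-style) segment track
#'
#' @param tau Per-locus fraction attributed to clone 1, in \[0, 1\].
#' @param a1_major,a1_minor Clone-1 major/minor copy numbers.
#' @param a2_major,a2_minor Clone-2 major/minor copy numbers.
#' @return A `subclonal_track` data.frame.
#' @export
subclonal_track <- function(tau, a1_major, a1_minor, a2_major, a2_minor) {
  stopifnot(all(tau >= 0 & tau <= 1),
            all(c(a1_major, a1_minor, a2_major, a2_minor) >= 0))
  structure(data.frame(tau = tau, a1_major = a1_major, a1_minor = a1_minor,
                       a2_major = a2_major, a2_minor = a2_minor),
            class = c("subclonal_track", "data.frame"))
}

#' Multiclonal sample copy number reconstruction
#'
#' Mixes the two clones' copy numbers by the clonal fraction `tau`:
#' `C^s_T = 2 (1-rho) + rho [tau (A1_M + A1_m) + (1-tau) (A2_M + A2_m)]` and
#' `C^s_B = s1 ((1-rho) + rho [tau A1_M + (1-tau) A2_M]) +
#'          s2 ((1-rho) + rho [tau A1_m + (1-tau) A2_m])`.
#' With `tau = 1` everywhere this reduces exactly to the single-clone sample
#' copy computation with clone-1 copy numbers.
#'
#' @param track A [subclonal_track()].
#' @param purity Purity in \[0, 1\].
#' @param s1,s2 Per-locus (or scalar) B-allele indicators of the
#'   major/minor haplotype; default heterozygous (1, 0).
#' @return List with `c_s_total`, `c_s_ballele` and the mixed fractional
#'   copy numbers `mix_major`, `mix_minor`.
#' @export
battenberg_reconstruction <- function(track, purity, s1 = 1, s2 = 0) {
  check_rho(purity)
  mixM <- track$tau * track$a1_major + (1 - track$tau) * track$a2_major
  mixm <- track$tau * track$a1_minor + (1 - track$tau) * track$a2_minor
  c_s_total <- 2 * (1 - purity) + purity * (mixM + mixm)
  c_s_ballele <- s1 * ((1 - purity) + purity * mixM) +
    s2 * ((1 - purity) + purity * mixm)
  list(c_s_total = c_s_total, c_s_ballele = c_s_ballele,
       mix_major = mixM, mix_minor = mixm)
}

#' Project a subclonal track onto its main clone
#'
#' Per locus, returns the copy numbers of the clone with the larger
#' fraction: clone 1 when `tau >= 0.5` (ties to clone 1), else clone 2.
#'
#' @param track A [subclonal_track()].
#' @return data.frame with per-locus `major_cn`, `minor_cn`.
#' @export
main_clone_projection <- function(track) {
  use1 <- track$tau >= 0.5
  data.frame(major_cn = ifelse(use1, track$a1_major, track$a2_major),
             minor_cn = ifelse(use1, track$a1_minor, track$a2_minor))
}

#' Reconstruction metrics for a call against an observation track
#'
#' Convenience wrapper combining [baf_rmse()] and [read_depth_mae()] for a
#' `call_result` (or any per-locus major/minor call track).
#'
#' @param obs Observation track with `reads` and `baf`.
#' @param result A `call_result`, or a data.frame with `major_cn`,
#'   `minor_cn` per locus plus a `purity` attribute.
#' @param purity Purity override (defaults to `result$purity`).
#' @return A `reconstruction_metrics` list with `baf_rmse`,
#'   `read_depth_mae`, `n_loci_used`.
#' @export
reconstruction_metrics <- function(obs, result, purity = NULL) {
  if (inherits(result, "call_result")) {
    major <- result$catalog$profiles$a_major[result$states]
    minor <- result$catalog$profiles$a_minor[result$states]
    if (is.null(purity)) purity <- result$purity
  } else {
    major <- result$major_cn
    minor <- result$minor_cn
    if (is.null(purity)) stop("purity required for plain call tracks")
  }
  b <- baf_rmse(obs$baf, major, minor, purity)
  r <- read_depth_mae(obs$reads, major, minor, purity)
  structure(list(baf_rmse = b$value, read_depth_mae = r$value,
                 n_loci_used = b$n_loci_used),
            class = "reconstruction_metrics")
}
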