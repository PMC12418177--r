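#' Sample total copy number under normal-cell contamination
#'
#' The sequenced sample is a mixture of tumour cells (fraction `rho`, the
#' purity) and normal cells assumed diploid everywhere. The per-locus sample
#' total copy number is `rho * c_total + 2 * (1 - rho)`.
#'
#' @param c_total Per-locus tumour total copy number (non-negative).
#' @param rho Tumour purity in \[0, 1\].
#' @return Per-locus sample total copy number (numeric).
#' @export
sample_total_cn <- function(c_total, rho) {
  check_rho(rho)
  if (any(c_total < 0)) stop("c_total must be non-negative")
  rho * c_total + 2 * (1 - rho)
}

#' Sample B-allele copy number
#'
#' Each parental haplotype either carries the SNP B allele (`s = 1`) or not
#' (`s = 0`); the normal compartment contributes one copy of each haplotype.
#' Returns `s_p * ((1 - rho) + rho * c_p) + s_m * ((1 - rho) + rho * c_m)`.
#'
#' @param c_p,c_m Per-locus paternal/maternal copy numbers.
#' @param s_p,s_m Per-locus binary B-allele indicators.
#' @param rho Tumour purity in \[0, 1\].
#' @return Per-locus sample B-allele copy number.
#' @export
sample_ballele_cn <- function(c_p, c_m, s_p, s_m, rho) {
  check_rho(rho)
  if (!all(s_p %in% c(0, 1)) || !all(s_m %in% c(0, 1)))
    stop("haplotype indicators must be 0 or 1")
  s_p * ((1 - rho) + rho * c_p) + s_m * ((1 - rho) + rho * c_m)
}

#' Noise-free expected observations from sample copy numbers
#'
#' Expected read depth is `r_d * C^s_T`; expected B-allele frequency (BAF) is
#' `C^s_B / C^s_T` where the sample total copy number is positive and missing
#' (`NA`) otherwise, since zero expected reads carry no allelic signal.
#'
#' @param sample_track List or data.frame with numeric `c_s_total` and
#'   `c_s_ballele` (the latter bounded by the former).
#' @param r_d Expected reads per copy, positive scalar.
#' @return List with per-locus `reads` and `baf`.
#' @export
expected_observations <- function(sample_track, r_d) {
  if (length(r_d) != 1L || !is.finite(r_d) || r_d <= 0)
    stop("r_d must be a positive scalar")
  ct <- sample_track$c_s_total
  cb <- sample_track$c_s_ballele
  if (any(cb > ct + 1e-9) || any(cb < -1e-9))
    stop("c_s_ballele must lie in [0, c_s_total]")
  baf <- ifelse(ct > 0, cb / ct, NA_real_)
  list(reads = r_d * ct, baf = baf)
}

#' Trimmed (robust) mean
#'
#' Mean after dropping `floor(trim_fraction * n)` values from each tail of
#' the sorted input. `trim_fraction = 0.05` trims the top and bottom 5%.
#'
#' @param values Non-empty numeric vector.
#' @param trim_fraction Fraction in \[0, 0.5) trimmed from each tail.
#' @return Scalar trimmed mean.
#' @export
robust_mean <- function(values, trim_fraction = 0.05) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("robust_mean of an empty vector")
  if (trim_fraction < 0 || trim_fraction >= 0.5)
    stop("trim_fraction must be in [0, 0.5)")
  n <- length(values)
  k <- floor(trim_fraction * n)
  if (k > 0) {
    s <- sort(values)
    values <- s[(k + 1L):(n - k)]
  }
  mean(values)
}

#' Sample ploidy
#'
#' The mean sample total copy number across loci, including the diploid
#' normal-cell contribution.
#'
#' @param c_s_total Per-locus sample total copy number, length >= 1.
#' @return Scalar sample ploidy.
#' @export
sample_ploidy <- function(c_s_total) {
  if (length(c_s_total) == 0L) stop("sample_ploidy of an empty track")
  mean(c_s_total)
}

#' Build the sample copy track for a ground-truth genome
#'
#' Convenience composition of [sample_total_cn()] and [sample_ballele_cn()].
#'
#' @param truth Ground-truth track with `c_p`, `c_m`, `s_p`, `s_m`.
#' @param rho Tumour purity.
#' @return List with `c_s_total` and `c_s_ballele`.
#' @export
sample_copy_track <- function(truth, rho) {
  list(
    c_s_total = sample_total_cn(truth$c_p + truth$c_m, rho),
    c_s_ballele = sample_ballele_cn(truth$c_p, truth$c_m,
                                    truth$s_p, truth$s_m, rho)
  )
}

check_rho <- function(rho) {
  if (length(rho) != 1L || is.na(rho) || rho < 0 || rho > 1)
    stop("rho must be a single value in [0, 1]")
  invisible(rho)
}
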