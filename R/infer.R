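#' Smoothing configuration
#'
#' @param lambda_t Transition penalty on the negative log-likelihood scale;
#'   500 by default, so a state change must be supported by substantial
#'   accumulated evidence. 0 disables smoothing (per-locus argmax).
#' @param per_chromosome Smooth each chromosome independently, with no
#'   transition penalty across chromosome boundaries (segments cannot
#'   biologically span chromosomes)?
#' @return A `smoothing_config` list.
#' @export
smoothing_config <- function(lambda_t = 500, per_chromosome = TRUE) {
  stopifnot(lambda_t >= 0)
  structure(list(lambda_t = lambda_t,
                 per_chromosome = isTRUE(per_chromosome)),
            class = "smoothing_config")
}

#' Length-scaled transition penalty
#'
#' The default penalty of 500 is calibrated for full-scale tracks of about
#' 650,000 SNPs. The penalty balances per-transition cost against the
#' log-likelihood evidence a segment accumulates, which grows with the
#' number of loci per segment; at shorter desk-scale lengths the same
#' genome-level smoothing therefore corresponds to a proportionally smaller
#' penalty, `lambda_t = 500 * length / 650000`.
#'
#' @param length Sequence length the penalty is scaled to.
#' @param lambda_full Penalty at full scale.
#' @param full_length Reference full-scale length.
#' @return Scaled penalty.
#' @export
desk_lambda_t <- function(length, lambda_full = 500, full_length = 650000) {
  lambda_full * length / full_length
}

#' Transition-penalised state smoothing
#'
#' Finds the state sequence minimising
#' `-sum_i log p[i, S_i] + lambda_t * #(i : S_i != S_{i+1})`
#' by forward dynamic programming with backtracking, as in the Viterbi
#' algorithm. With `lambda_t = 0` this is the per-locus argmax; as
#' `lambda_t` grows the solution becomes the single best constant state.
#' Ties break toward the lowest state index, biasing to lower copy numbers.
#'
#' @param class_probs L x J matrix of per-locus state probabilities.
#' @param lambda_t Non-negative transition penalty.
#' @return Integer vector of 1-based state indices.
#' @export
smooth <- function(class_probs, lambda_t) {
  if (lambda_t < 0) stop("lambda_t must be non-negative")
  P <- as.matrix(class_probs)
  if (any(!is.finite(P)) || any(P < 0)) stop("invalid probability matrix")
  smooth_dp(log(pmax(P, LOG_EPS)), lambda_t)
}

#' Whole-genome duplication flag
#'
#' `TRUE` iff the fraction of loci whose called major copy number is at
#' least `major_cn_threshold` exceeds `genome_fraction`.
#'
#' @param states Per-locus catalogue state indices.
#' @param catalog The class catalogue.
#' @param major_cn_threshold Major copy number counting as duplicated.
#' @param genome_fraction Fraction of the genome required.
#' @return Logical flag.
#' @export
compute_wgd <- function(states, catalog, major_cn_threshold = 2,
                        genome_fraction = 0.5) {
  if (!length(states)) stop("empty state sequence")
  mean(catalog$profiles$a_major[states] >= major_cn_threshold) >
    genome_fraction
}

states_to_segments <- function(chrom, pos, states) {
  out <- list()
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    r <- rle(states[sel])
    ends <- cumsum(r$lengths)
    starts <- c(1L, head(ends, -1L) + 1L)
    out[[length(out) + 1L]] <- data.frame(
      chrom = ch,
      start_pos = pos[sel][starts],
      end_pos = pos[sel][ends],
      n_loci = r$lengths,
      state = r$values
    )
  }
  do.call(rbind, out)
}

#' Zero-shot copy number calling on an observation track
#'
#' Runs the model forward, smooths the per-locus class probabilities per
#' chromosome (no penalty across chromosome boundaries), assembles segments
#' from runs of equal states, and derives the global estimates: purity from
#' the global token, tumour ploidy as the mean called total copy number,
#' sample ploidy from the smoothed hard states, reads per copy (reads mode)
#' and the whole-genome duplication flag.
#'
#' @param model A trained `aracna_model`.
#' @param obs Observation track data.frame (`chrom`, `pos`, `reads`, `baf`,
#'   optionally `logr`).
#' @param smoothing A [smoothing_config()].
#' @return A `call_result` list: `class_probs`, `states`, `segments`
#'   (chrom, start_pos, end_pos, n_loci, major_cn, minor_cn, total_cn),
#'   `purity`, `ploidy`, `sample_ploidy`, `rd_estimate`, `wgd`, `lambda_t`.
#' @export
call_genome <- function(model, obs, smoothing = smoothing_config()) {
  stopifnot(inherits(model, "aracna_model"),
            inherits(smoothing, "smoothing_config"))
  if (model$mode == "logr" && is.null(obs$logr))
    stop("model is in logR mode but the track has no logr channel")
  if (model$mode == "reads" && is.null(obs$reads))
    stop("model is in reads mode but the track has no reads channel")
  out <- model_forward(model, obs)
  P <- out$class_probs
  catalog <- model$catalog
  L <- nrow(P)
  if (smoothing$per_chromosome) {
    states <- integer(L)
    for (ch in unique(obs$chrom)) {
      sel <- which(obs$chrom == ch)
      states[sel] <- smooth(P[sel, , drop = FALSE], smoothing$lambda_t)
    }
  } else {
    states <- smooth(P, smoothing$lambda_t)
  }
  segs <- states_to_segments(obs$chrom, obs$pos, states)
  segs$major_cn <- catalog$profiles$a_major[segs$state]
  segs$minor_cn <- catalog$profiles$a_minor[segs$state]
  segs$total_cn <- segs$major_cn + segs$minor_cn
  segs$state <- NULL
  rho_hat <- out$purity_estimate
  tot <- catalog$profiles$total[states]
  ploidy <- mean(tot)
  sample_pl <- rho_hat * ploidy + 2 * (1 - rho_hat)
  rd_est <- if (model$mode == "reads" && sample_pl > 1e-9)
    robust_mean(obs$reads, 0.05) / sample_pl else NA_real_
  structure(list(class_probs = P, states = states, segments = segs,
                 purity = rho_hat, ploidy = ploidy,
                 sample_ploidy = sample_pl, rd_estimate = rd_est,
                 wgd = compute_wgd(states, catalog),
                 lambda_t = smoothing$lambda_t, catalog = catalog),
            class = "call_result")
}

#' @export
print.call_result <- function(x, ...) {
  cat(sprintf(paste0("Copy number call: %d loci, %d segment(s), purity %.3f,",
                     " ploidy %.2f, reads/copy %s, WGD %s\n"),
              length(x$states), nrow(x$segments), x$purity, x$ploidy,
              ifelse(is.na(x$rd_estimate), "NA",
                     sprintf("%.2f", x$rd_estimate)),
              x$wgd))
  invisible(x)
}

#' Expand called segments back to per-locus states
#'
#' Inverse of the segment assembly in [call_genome()]; used for round-trip
#' consistency checks.
#'
#' @param segments Segment data.frame with `chrom`, `start_pos`, `end_pos`,
#'   `major_cn`, `minor_cn`.
#' @param chrom,pos Per-locus coordinates to expand onto.
#' @param catalog The class catalogue.
#' @return Integer vector of per-locus state indices.
#' @export
segments_to_states <- function(segments, chrom, pos, catalog) {
  states <- rep(NA_integer_, length(pos))
  idx <- profile_index(segments$major_cn, segments$minor_cn, catalog)
  for (i in seq_len(nrow(segments))) {
    sel <- chrom == segments$chrom[i] & pos >= segments$start_pos[i] &
      pos <= segments$end_pos[i]
    states[sel] <- idx[i]
  }
  if (anyNA(states)) stop("segments do not cover all loci")
  states
}
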