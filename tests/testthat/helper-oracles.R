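# Independent oracles used to freeze expected values.

# brute-force pair count: all (A_M, A_m) with A_M >= A_m >= 0, sum <= t
brute_profile_count <- function(t) {
  n <- 0L
  for (aM in 0:t) for (am in 0:t) {
    if (aM >= am && aM + am <= t) n <- n + 1L
  }
  n
}

# exhaustive minimisation of the smoothing objective over all J^L sequences
brute_smooth <- function(P, lambda) {
  L <- nrow(P)
  J <- ncol(P)
  logp <- log(pmax(P, 1e-12))
  grid <- as.matrix(expand.grid(rep(list(seq_len(J)), L)))
  best <- NULL
  best_cost <- Inf
  for (r in seq_len(nrow(grid))) {
    s <- grid[r, ]
    cost <- -sum(logp[cbind(seq_len(L), s)]) +
      lambda * sum(s[-1] != s[-L])
    if (cost < best_cost - 1e-12) {
      best_cost <- cost
      best <- s
    }
  }
  list(states = unname(best), cost = best_cost)
}

# noiseless pure-tumour class rule for the diploid-regime catalogue:
# maps (reads / r_d, BAF) to the four classes by the forward model
hand_rule_stage1 <- function(reads, baf, r_d, catalog) {
  ratio <- reads / r_d
  idx <- integer(length(reads))
  for (i in seq_along(reads)) {
    if (ratio[i] < 0.5) {
      aM <- 0; am <- 0
    } else if (ratio[i] < 1.5) {
      aM <- 1; am <- 0
    } else if (!is.na(baf[i]) && baf[i] > 0.25 && baf[i] < 0.75) {
      aM <- 1; am <- 1
    } else {
      # ambiguous between (1,1) homozygous and (2,0); depth alone cannot
      # separate them -- callers need segment context, which this per-locus
      # rule does not have
      aM <- NA; am <- NA
    }
    idx[i] <- if (is.na(aM)) NA_integer_ else
      which(catalog$profiles$a_major == aM & catalog$profiles$a_minor == am)
  }
  idx
}

make_obs <- function(reads, baf, chrom = NULL, pos = NULL) {
  L <- length(reads)
  data.frame(chrom = chrom %||% rep("chr1", L),
             pos = pos %||% seq_len(L) * 1000L,
             reads = reads, baf = baf)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
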