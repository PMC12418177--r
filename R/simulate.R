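#' Noise configuration for the simulator
#'
#' Read counts are Poisson with a per-locus lognormal rate modulation
#' (per-genome sigma drawn uniformly from `read_dispersion_range`), which
#' reproduces the overdispersion of WGS coverage. BAF gets Gaussian jitter
#' (per-genome sigma from `baf_jitter_range`) after the binomial draw, then
#' clipping to \[0, 1\].
#'
#' @param read_dispersion_range,baf_jitter_range Length-2 non-negative
#'   numeric ranges for the per-genome noise scales.
#' @param enabled When `FALSE` both noise channels are switched off and only
#'   Poisson/binomial sampling variation remains.
#' @return A `noise_config` list.
#' @export
noise_config <- function(read_dispersion_range = c(0, 0.15),
                         baf_jitter_range = c(0, 0.02),
                         enabled = TRUE) {
  stopifnot(length(read_dispersion_range) == 2L, all(read_dispersion_range >= 0),
            length(baf_jitter_range) == 2L, all(baf_jitter_range >= 0))
  structure(list(read_dispersion_range = read_dispersion_range,
                 baf_jitter_range = baf_jitter_range,
                 enabled = isTRUE(enabled)),
            class = "noise_config")
}

#' Identity-by-descent (IBD) region configuration
#'
#' Real genomes contain runs of homozygosity inherited from a common
#' ancestor; there the BAF is uninformative for copy number and calls must
#' rely on read depth and flanking context. The simulator injects such
#' regions at random.
#'
#' @param region_prob Per-genome probability of injecting at least one region.
#' @param length_range Length-2 integer range of region lengths in loci; when
#'   `NULL` it defaults to `c(min(500, max(2, floor(0.01 * L))), floor(0.05 * L))`
#'   at simulation time, keeping regions long relative to typical segments.
#' @param max_regions Maximum number of injected regions.
#' @return An `ibd_config` list.
#' @export
ibd_config <- function(region_prob = 0.2, length_range = NULL, max_regions = 3L) {
  stopifnot(region_prob >= 0, region_prob <= 1, max_regions >= 1)
  structure(list(region_prob = region_prob, length_range = length_range,
                 max_regions = as.integer(max_regions)),
            class = "ibd_config")
}

#' Simulation configuration
#'
#' Defaults follow the generative procedure used for training: segment count
#' from a uniform/Poisson mixture, uniform breakpoints with a minimum
#' segment length, profiles biased toward (1,1), purity uniform on
#' `purity_range` and reads-per-copy uniform on `rd_range`.
#'
#' @param length Number of loci L.
#' @param t_max Maximum total copy number of simulated profiles.
#' @param max_segments Upper bound N of the uniform branch of the segment
#'   count mixture.
#' @param swap_prob Probability q_s of using the uniform branch; otherwise a
#'   truncated Poisson skews toward fewer segments.
#' @param poisson_rate Rate of the Poisson branch.
#' @param min_segment_len Minimum segment length in loci.
#' @param purity_range,rd_range Uniform sampling ranges for purity and
#'   reads per copy.
#' @param noise A [noise_config()].
#' @param ibd An [ibd_config()].
#' @param n_chrom Number of synthetic chromosomes the loci are split into.
#' @param seed Integer seed; `simulate_genome` is fully reproducible from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(length = 2000L, t_max = 2L, max_segments = 250L,
                       swap_prob = 0.3, poisson_rate = 15, min_segment_len = 25L,
                       purity_range = c(0.5, 1), rd_range = c(5, 70),
                       noise = noise_config(), ibd = ibd_config(),
                       n_chrom = 22L, seed = 1L) {
  stopifnot(length >= 1, min_segment_len >= 1, min_segment_len <= length,
            t_max >= 0, max_segments >= 1, swap_prob >= 0, swap_prob <= 1,
            poisson_rate > 0, purity_range[1] >= 0, purity_range[2] <= 1,
            purity_range[1] <= purity_range[2], all(rd_range > 0),
            inherits(noise, "noise_config"), inherits(ibd, "ibd_config"))
  structure(list(length = as.integer(length), t_max = as.integer(t_max),
                 max_segments = as.integer(max_segments),
                 swap_prob = swap_prob, poisson_rate = poisson_rate,
                 min_segment_len = as.integer(min_segment_len),
                 purity_range = purity_range, rd_range = rd_range,
                 noise = noise, ibd = ibd,
                 n_chrom = as.integer(min(n_chrom, length)),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Sample the approximate number of copy number segments
#'
#' With probability `swap_prob` draws uniformly on `{1..max_segments}`;
#' otherwise draws from a Poisson truncated to the same support, skewing
#' toward few segments — the harder cases for global parameter inference.
#'
#' @param config A [sim_config()].
#' @return A single integer in `1..max_segments`.
#' @export
sample_segment_count <- function(config) {
  n <- config$max_segments
  if (runif(1) < config$swap_prob) {
    sample.int(n, 1L)
  } else {
    repeat {
      k <- rpois(1L, config$poisson_rate)
      if (k >= 1L && k <= n) return(k)
    }
  }
}

#' Sample segment breakpoints and form a minimum-length partition
#'
#' Draws `n_hat` breakpoints uniformly from `1..length`, deduplicates them,
#' forms segments, and merges any segment shorter than `min_len` into its
#' left neighbour (the leftmost merges right), so the result partitions the
#' genome with every part at least `min_len` loci long.
#'
#' @param n_hat Number of breakpoints to draw (>= 1).
#' @param length Number of loci.
#' @param min_len Minimum segment length in loci.
#' @return data.frame with 1-based inclusive `start`, `end` columns.
#' @export
sample_breakpoints <- function(n_hat, length, min_len) {
  if (length < min_len) stop("length must be at least min_len")
  if (n_hat < 1) stop("n_hat must be >= 1")
  b <- sample.int(length, n_hat, replace = TRUE)
  ends <- sort(unique(c(b[b < length], length)))
  repeat {
    lens <- diff(c(0L, ends))
    short <- which(lens < min_len)
    if (!length(short)) break
    i <- short[1L]
    # merge into the left neighbour; the leftmost segment merges right
    ends <- if (i == 1L) ends[-1L] else ends[-(i - 1L)]
  }
  starts <- c(1L, head(ends, -1L) + 1L)
  data.frame(start = as.integer(starts), end = as.integer(ends))
}

#' Sample an allele-specific profile for each segment
#'
#' Profiles are drawn from the catalogue with weights proportional to
#' `exp(-alpha * (|A_M - 1| + |A_m - 1|))` where
#' `alpha = alpha0 / (1 + n_segments / n_half)`. Genomes with few segments
#' are strongly biased toward the diploid (1,1) profile — the weakly
#' identifiable cases — while many-segment genomes are sampled closer to
#' uniformly yet still favour low copy numbers, biasing the trained caller
#' toward lower-ploidy explanations when the data are ambiguous.
#'
#' @param segments data.frame of segments as from [sample_breakpoints()].
#' @param catalog A [enumerate_profiles()] catalogue.
#' @param alpha0 Bias strength at one segment.
#' @param n_half Segment count at which the bias halves.
#' @return data.frame with per-segment `a_major`, `a_minor`.
#' @export
sample_segment_profiles <- function(segments, catalog, alpha0 = 1.5,
                                    n_half = 20) {
  stopifnot(inherits(catalog, "profile_catalog"))
  ns <- nrow(segments)
  if (is.null(ns) || ns == 0L) stop("segments must be non-empty")
  if (catalog$j == 0L) stop("empty catalogue")
  p <- catalog$profiles
  alpha <- alpha0 / (1 + ns / n_half)
  w <- exp(-alpha * (abs(p$a_major - 1) + abs(p$a_minor - 1)))
  idx <- sample.int(catalog$j, ns, replace = TRUE, prob = w)
  data.frame(a_major = p$a_major[idx], a_minor = p$a_minor[idx])
}

#' Sample per-locus haplotype B-allele indicators
#'
#' Outside IBD regions both parental indicators are independent fair coin
#' flips; inside IBD regions the two haplotypes are identical by descent so
#' `s_p == s_m` at every locus and no heterozygous locus exists.
#'
#' @param length Number of loci.
#' @param ibd_regions data.frame with 1-based inclusive `start`, `end`
#'   columns (possibly zero rows).
#' @return List with binary vectors `s_p`, `s_m`.
#' @export
sample_haplotypes <- function(length, ibd_regions = NULL) {
  s_p <- rbinom(length, 1L, 0.5)
  s_m <- rbinom(length, 1L, 0.5)
  if (!is.null(ibd_regions) && nrow(ibd_regions)) {
    for (i in seq_len(nrow(ibd_regions))) {
      idx <- ibd_regions$start[i]:ibd_regions$end[i]
      if (any(idx < 1 | idx > length)) stop("IBD region outside the genome")
      s_m[idx] <- s_p[idx]
    }
  }
  list(s_p = s_p, s_m = s_m)
}

#' Sample noisy observations from a ground-truth genome
#'
#' Reads are Poisson with mean `r_d * C^s_T * g_i`, `g_i` lognormal(0, sigma)
#' per locus (`g_i = 1` with noise disabled). B-allele reads are binomial
#' out of the sampled total with success probability `C^s_B / C^s_T`; the
#' ratio gets Gaussian jitter and is clipped to \[0, 1\]. Zero-read loci have
#' missing BAF.
#'
#' @param truth List with `c_p`, `c_m`, `s_p`, `s_m` per-locus vectors.
#' @param params List with `rho` and `r_d`.
#' @param noise A [noise_config()].
#' @return List with `reads`, `baf` and the drawn `sigma_read`, `sigma_baf`.
#' @export
sample_observations <- function(truth, params, noise = noise_config()) {
  check_rho(params$rho)
  stopifnot(params$r_d > 0)
  st <- sample_copy_track(truth, params$rho)
  L <- length(st$c_s_total)
  if (noise$enabled) {
    sigma_read <- runif(1, noise$read_dispersion_range[1],
                        noise$read_dispersion_range[2])
    sigma_baf <- runif(1, noise$baf_jitter_range[1], noise$baf_jitter_range[2])
    g <- rlnorm(L, 0, sigma_read)
  } else {
    sigma_read <- 0
    sigma_baf <- 0
    g <- rep(1, L)
  }
  reads <- rpois(L, params$r_d * st$c_s_total * g)
  p_b <- ifelse(st$c_s_total > 0, st$c_s_ballele / st$c_s_total, 0)
  bcount <- rbinom(L, reads, pmin(pmax(p_b, 0), 1))
  baf <- ifelse(reads > 0, bcount / reads, NA_real_)
  if (sigma_baf > 0) {
    jit <- rnorm(L, 0, sigma_baf)
    baf <- ifelse(is.na(baf), NA_real_, pmin(pmax(baf + jit, 0), 1))
  }
  list(reads = as.numeric(reads), baf = baf,
       sigma_read = sigma_read, sigma_baf = sigma_baf)
}

sample_ibd_regions <- function(config) {
  L <- config$length
  ibd <- config$ibd
  if (runif(1) >= ibd$region_prob) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  lr <- ibd$length_range
  if (is.null(lr)) {
    lr <- c(min(500L, max(2L, floor(0.01 * L))), max(2L, floor(0.05 * L)))
  }
  lr <- pmin(pmax(as.integer(lr), 1L), L)
  k <- sample.int(ibd$max_regions, 1L)
  start <- integer(0)
  end <- integer(0)
  for (i in seq_len(k)) {
    len <- if (lr[1] >= lr[2]) lr[1] else sample(lr[1]:lr[2], 1L)
    s <- sample.int(L - len + 1L, 1L)
    start <- c(start, s)
    end <- c(end, s + len - 1L)
  }
  data.frame(start = start, end = end)
}

chrom_blocks <- function(L, n_chrom) {
  # synthetic chromosome labels in n_chrom near-equal contiguous blocks
  sizes <- rep(L %/% n_chrom, n_chrom)
  extra <- L %% n_chrom
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  rep(paste0("chr", seq_len(n_chrom)), times = sizes)
}

#' Simulate one supervised training genome
#'
#' Composes the four sampling steps — segment count, breakpoints, segment
#' profiles, observations — with purity drawn uniformly from
#' `purity_range` and reads per copy from `rd_range`. Fully deterministic
#' given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A `simulated_genome`: list with `observations` (data.frame
#'   `chrom`, `pos`, `reads`, `baf`), `truth` (data.frame `c_p`, `c_m`,
#'   `a_major`, `a_minor`, `s_p`, `s_m`), `params` (`rho`, `r_d`),
#'   `segments`, `ibd_regions` and `config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$length
  catalog <- enumerate_profiles(config$t_max)

  n_hat <- sample_segment_count(config)
  segs <- sample_breakpoints(n_hat, L, config$min_segment_len)
  # a genome cannot be homozygously deleted everywhere; redraw the rare
  # all-(0,0) profile vector (deterministic under the seed)
  repeat {
    prof <- sample_segment_profiles(segs, catalog)
    if (config$t_max == 0L || any(prof$a_major + prof$a_minor > 0)) break
  }
  ibd <- sample_ibd_regions(config)
  hap <- sample_haplotypes(L, ibd)

  rho <- runif(1, config$purity_range[1], config$purity_range[2])
  r_d <- runif(1, config$rd_range[1], config$rd_range[2])

  seg_id <- rep(seq_len(nrow(segs)), times = segs$end - segs$start + 1L)
  a_major <- prof$a_major[seg_id]
  a_minor <- prof$a_minor[seg_id]
  # parental assignment of major/minor is arbitrary; swap per segment
  swap <- rbinom(nrow(segs), 1L, 0.5)[seg_id] == 1L
  c_p <- ifelse(swap, a_minor, a_major)
  c_m <- ifelse(swap, a_major, a_minor)

  truth <- data.frame(c_p = c_p, c_m = c_m, a_major = a_major,
                      a_minor = a_minor, s_p = hap$s_p, s_m = hap$s_m)
  params <- list(rho = rho, r_d = r_d)
  obs_raw <- sample_observations(truth, params, config$noise)

  chrom <- chrom_blocks(L, config$n_chrom)
  pos <- as.integer(stats::ave(seq_len(L), chrom, FUN = seq_along)) * 1000L

  observations <- data.frame(chrom = chrom, pos = pos,
                             reads = obs_raw$reads, baf = obs_raw$baf,
                             stringsAsFactors = FALSE)
  structure(list(observations = observations, truth = truth, params = params,
                 segments = cbind(segs, prof), ibd_regions = ibd,
                 config = config),
            class = "simulated_genome")
}

#' @export
print.simulated_genome <- function(x, ...) {
  cat(sprintf(paste0("Simulated genome: %d loci, %d segments, purity %.3f, ",
                     "reads/copy %.2f, %d IBD region(s)\n"),
              nrow(x$observations), nrow(x$segments), x$params$rho,
              x$params$r_d, nrow(x$ibd_regions)))
  invisible(x)
}

#' Convert a simulated genome to logR inputs
#'
#' Emulates matched-normal normalisation: samples a normal reads-per-copy
#' `r_d_normal`, computes the coverage ratio `t_r = reads / (2 r_d_normal)`
#' and the log ratio `l_r = log(t_r / robust_mean(t_r))` with 5% two-sided
#' trimming, so a flat diploid pure genome has `l_r = 0` everywhere and
#' global rescaling of reads cancels. Zero-read loci get missing `l_r`.
#'
#' @param genome A `simulated_genome`.
#' @param rd_normal_range Uniform sampling range for the matched-normal
#'   reads per copy; defaults to the genome's tumour `rd_range`.
#' @return The genome with an added `logr` observation column and
#'   `params$r_d_normal` set.
#' @export
to_logr_inputs <- function(genome, rd_normal_range = NULL) {
  stopifnot(inherits(genome, "simulated_genome"))
  reads <- genome$observations$reads
  if (all(reads == 0)) stop("all-zero reads: cannot form logR")
  if (is.null(rd_normal_range)) rd_normal_range <- genome$config$rd_range
  r_d_n <- runif(1, rd_normal_range[1], rd_normal_range[2])
  t_r <- reads / (2 * r_d_n)
  mu <- robust_mean(t_r, 0.05)
  l_r <- ifelse(reads > 0, log(t_r / mu), NA_real_)
  genome$observations$logr <- l_r
  genome$params$r_d_normal <- r_d_n
  genome
}

#' Derive a reproducible sub-seed from a base seed and counter
#'
#' Used so that genome k of a streamed batch is individually reproducible.
#' Result is kept within the 32-bit integer range.
#'
#' @param seed Base integer seed.
#' @param counter Non-negative integer counter.
#' @return Integer seed.
#' @export
derive_seed <- function(seed, counter) {
  as.integer((as.double(seed) * 48271 + as.double(counter) * 9973 + 1) %%
               2147483647)
}
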