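#' Deterministic demonstration fixtures
#'
#' Small seeded genomes written in all supported formats, used by the tests
#' and examples:
#'
#' * `diploid` — a pure noiseless all-(1,1) genome.
#' * `two_segment` — two copy number segments; an identifiability twin with
#'   every copy number doubled and reads per copy halved (same expected
#'   observations at purity 1) is emitted alongside as `<prefix>_doubled`.
#' * `ibd_demo` — one injected run of homozygosity on a (1,1) background and
#'   one true minor-copy-0 deletion: the two look alike in BAF but differ in
#'   read depth.
#' * `subclonal_demo` — a subclonal segment table plus observations from its
#'   mixed fractional copy numbers.
#'
#' @param kind Fixture kind.
#' @param seed Integer seed; identical seeds give byte-identical files.
#' @param dir Output directory (created if missing); `NULL` writes nothing.
#' @param length Number of loci (<= 5000).
#' @return The `simulated_genome` (invisible file paths in
#'   `attr(, "files")`); for `two_segment` the doubled twin is in
#'   `attr(, "twin")`, for `subclonal_demo` the track in
#'   `attr(, "subclonal")`.
#' @export
make_fixture <- function(kind = c("diploid", "two_segment", "ibd_demo",
                                  "subclonal_demo"),
                         seed = 1L, dir = NULL, length = 1200L) {
  kind <- match.arg(kind)
  stopifnot(length <= 5000L)
  L <- as.integer(length)
  noiseless <- noise_config(enabled = FALSE)
  no_ibd <- ibd_config(region_prob = 0)

  base_cfg <- sim_config(length = L, t_max = 2L, noise = noiseless,
                         ibd = no_ibd, purity_range = c(1, 1),
                         rd_range = c(30, 30), seed = seed)
  set.seed(seed)

  build_manual <- function(a_major, a_minor, seg_id, rho, r_d, ibd_regions,
                           cfg) {
    hap <- sample_haplotypes(L, ibd_regions)
    swap <- rbinom(max(seg_id), 1L, 0.5)[seg_id] == 1L
    c_p <- ifelse(swap, a_minor, a_major)
    c_m <- ifelse(swap, a_major, a_minor)
    truth <- data.frame(c_p = c_p, c_m = c_m, a_major = a_major,
                        a_minor = a_minor, s_p = hap$s_p, s_m = hap$s_m)
    params <- list(rho = rho, r_d = r_d)
    obs_raw <- sample_observations(truth, params, noiseless)
    chrom <- chrom_blocks(L, min(4L, L))
    pos <- as.integer(stats::ave(seq_len(L), chrom, FUN = seq_along)) * 1000L
    ends <- cumsum(rle(seg_id)$lengths)
    starts <- c(1L, head(ends, -1L) + 1L)
    segs <- data.frame(start = starts, end = ends,
                       a_major = a_major[starts], a_minor = a_minor[starts])
    structure(list(
      observations = data.frame(chrom = chrom, pos = pos,
                                reads = obs_raw$reads, baf = obs_raw$baf),
      truth = truth, params = params, segments = segs,
      ibd_regions = ibd_regions, config = cfg),
      class = "simulated_genome")
  }

  twin <- NULL
  sub <- NULL
  if (kind == "diploid") {
    gen <- build_manual(rep(1L, L), rep(1L, L), rep(1L, L), 1, 30,
                        data.frame(start = integer(0), end = integer(0)),
                        base_cfg)
  } else if (kind == "two_segment") {
    half <- L %/% 2L
    a_major <- c(rep(1L, half), rep(2L, L - half))
    a_minor <- c(rep(1L, half), rep(0L, L - half))
    seg_id <- c(rep(1L, half), rep(2L, L - half))
    gen <- build_manual(a_major, a_minor, seg_id, 1, 30,
                        data.frame(start = integer(0), end = integer(0)),
                        base_cfg)
    # identifiability twin: copy numbers doubled, reads per copy halved
    set.seed(seed)
    twin <- build_manual(2L * a_major, 2L * a_minor, seg_id, 1, 15,
                         data.frame(start = integer(0), end = integer(0)),
                         base_cfg)
  } else if (kind == "ibd_demo") {
    third <- L %/% 3L
    # true deletion (1,0) in the middle third; IBD run in the last third
    a_major <- rep(1L, L)
    a_minor <- rep(1L, L)
    a_minor[(third + 1L):(2L * third)] <- 0L
    seg_id <- c(rep(1L, third), rep(2L, third), rep(3L, L - 2L * third))
    ibd <- data.frame(start = 2L * third + third %/% 2L, end = L)
    gen <- build_manual(a_major, a_minor, seg_id, 1, 30, ibd, base_cfg)
  } else {
    half <- L %/% 2L
    tau <- c(rep(1, half), rep(0.6, L - half))
    sub <- subclonal_track(tau,
                           a1_major = rep(2L, L), a1_minor = rep(1L, L),
                           a2_major = rep(1L, L), a2_minor = rep(1L, L))
    rec <- battenberg_reconstruction(sub, purity = 0.8)
    r_d <- 30
    reads <- rpois(L, r_d * rec$c_s_total)
    hap <- sample_haplotypes(L, NULL)
    p_b <- ifelse(rec$c_s_total > 0,
                  (hap$s_p * ((1 - 0.8) + 0.8 * rec$mix_major) +
                     hap$s_m * ((1 - 0.8) + 0.8 * rec$mix_minor)) /
                    rec$c_s_total, 0)
    bc <- rbinom(L, reads, pmin(pmax(p_b, 0), 1))
    baf <- ifelse(reads > 0, bc / reads, NA_real_)
    chrom <- chrom_blocks(L, 4L)
    pos <- as.integer(stats::ave(seq_len(L), chrom, FUN = seq_along)) * 1000L
    gen <- structure(list(
      observations = data.frame(chrom = chrom, pos = pos, reads = reads,
                                baf = baf),
      truth = data.frame(c_p = sub$a1_major, c_m = sub$a1_minor,
                         a_major = sub$a1_major, a_minor = sub$a1_minor,
                         s_p = hap$s_p, s_m = hap$s_m),
      params = list(rho = 0.8, r_d = r_d),
      segments = data.frame(start = c(1L, half + 1L), end = c(half, L),
                            a_major = c(2L, 2L), a_minor = c(1L, 1L)),
      ibd_regions = data.frame(start = integer(0), end = integer(0)),
      config = base_cfg), class = "simulated_genome")
  }

  files <- character(0)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- write_genome_files(gen, file.path(dir, kind))
    if (!is.null(twin))
      files <- c(files, write_genome_files(
        twin, file.path(dir, paste0(kind, "_doubled"))))
    if (!is.null(sub)) {
      sub_path <- file.path(dir, paste0(kind, ".subclonal.tsv"))
      write.table(format(sub, digits = 6), sub_path, sep = "\t",
                  quote = FALSE, row.names = FALSE)
      files <- c(files, subclonal = sub_path)
    }
  }
  attr(gen, "files") <- files
  if (!is.null(twin)) attr(gen, "twin") <- twin
  if (!is.null(sub)) attr(gen, "subclonal") <- sub
  gen
}
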