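test_that("segment count mixture has the right branches", {
  set.seed(1)
  cfg_u <- sim_config(length = 1000, max_segments = 10, swap_prob = 1)
  draws <- replicate(10000, sample_segment_count(cfg_u))
  expect_true(all(draws >= 1 & draws <= 10))
  # uniform branch: each cell within 4 multinomial SEs of 1/N
  se <- sqrt(0.1 * 0.9 / 10000)
  freq <- tabulate(draws, 10) / 10000
  expect_true(all(abs(freq - 0.1) < 4 * se))

  cfg_p <- sim_config(length = 1000, max_segments = 250, swap_prob = 0,
                      poisson_rate = 1)
  draws_p <- replicate(10000, sample_segment_count(cfg_p))
  # truncated Poisson(1) mass above 5 is ~9e-4
  expect_gte(mean(draws_p <= 5), 0.99)

  cfg_1 <- sim_config(length = 100, max_segments = 1, swap_prob = 0.5)
  expect_true(all(replicate(50, sample_segment_count(cfg_1)) == 1))
})

test_that("breakpoints produce a minimum-length partition", {
  set.seed(2)
  for (i in 1:200) {
    L <- sample(100:2000, 1)
    min_len <- sample(5:50, 1)
    n_hat <- sample(1:60, 1)
    segs <- sample_breakpoints(n_hat, L, min_len)
    lens <- segs$end - segs$start + 1L
    expect_identical(segs$start[1], 1L)
    expect_identical(segs$end[nrow(segs)], as.integer(L))
    if (nrow(segs) > 1)
      expect_identical(segs$start[-1], head(segs$end, -1) + 1L)
    expect_true(all(lens >= min_len))
  }
  # pigeonhole: at most L / min_len segments
  segs <- sample_breakpoints(50, 1000, 100)
  expect_lte(nrow(segs), 10)
  expect_error(sample_breakpoints(1, 10, 20), "at least")
})

test_that("profile sampling biases toward (1,1) for few segments, uniform at zero bias", {
  catalog <- enumerate_profiles(2)
  seg1 <- data.frame(start = 1L, end = 100L)
  set.seed(3)
  draws <- replicate(10000, {
    p <- sample_segment_profiles(seg1, catalog, alpha0 = 20)
    paste(p$a_major, p$a_minor)
  })
  tab <- table(draws)
  expect_identical(names(tab)[which.max(tab)], "1 1")
  # alpha0 = 0 removes the bias entirely
  draws0 <- replicate(10000, {
    p <- sample_segment_profiles(seg1, catalog, alpha0 = 0)
    paste(p$a_major, p$a_minor)
  })
  freq <- table(factor(draws0, levels = paste(catalog$profiles$a_major,
                                              catalog$profiles$a_minor)))
  se <- sqrt(0.25 * 0.75 / 10000)
  expect_true(all(abs(freq / 10000 - 0.25) < 4 * se))
  # support property on a larger catalogue
  segs <- data.frame(start = c(1L, 51L), end = c(50L, 100L))
  p8 <- sample_segment_profiles(segs[rep(1, 200), ], enumerate_profiles(8))
  expect_no_error(profile_index(p8$a_major, p8$a_minor, enumerate_profiles(8)))
})

test_that("haplotype sampling is fair outside IBD regions and homozygous inside", {
  set.seed(4)
  L <- 100000
  ibd <- data.frame(start = 20001L, end = 40000L)
  hap <- sample_haplotypes(L, ibd)
  inside <- 20001:40000
  outside <- setdiff(seq_len(L), inside)
  het_out <- mean(hap$s_p[outside] != hap$s_m[outside])
  expect_lt(abs(het_out - 0.5), 4 * sqrt(0.25 / length(outside)))
  expect_identical(sum(hap$s_p[inside] != hap$s_m[inside]), 0L)
  expect_error(sample_haplotypes(100, data.frame(start = 90L, end = 120L)),
               "outside")
})

test_that("noiseless observations match the forward model up to sampling error", {
  set.seed(5)
  L <- 50000
  truth <- data.frame(c_p = rep(1L, L), c_m = rep(1L, L),
                      s_p = rbinom(L, 1, 0.5), s_m = rbinom(L, 1, 0.5))
  obs <- sample_observations(truth, list(rho = 1, r_d = 30),
                             noise_config(enabled = FALSE))
  expect_lt(abs(mean(obs$reads) - 60), 4 * sqrt(60 / L))
  # homozygous-B loci have BAF exactly 1 wherever reads exist
  homB <- truth$s_p == 1 & truth$s_m == 1 & obs$reads > 0
  expect_true(all(obs$baf[homB] == 1))
  # heterozygous loci centre on 0.5
  het <- xor(truth$s_p == 1, truth$s_m == 1) & obs$reads > 0
  expect_lt(abs(mean(obs$baf[het]) - 0.5), 4 * sqrt(0.25 / sum(het)) + 1e-3)
  # zero-read loci get missing BAF
  truth0 <- data.frame(c_p = 0L, c_m = 0L, s_p = 1L, s_m = 0L)
  obs0 <- sample_observations(truth0, list(rho = 1, r_d = 30),
                              noise_config(enabled = FALSE))
  expect_true(is.na(obs0$baf))
})

test_that("simulated genomes are reproducible and respect the catalogue", {
  cfg <- sim_config(length = 500, t_max = 2, seed = 42)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1, g2)
  expect_no_error(profile_index(g1$truth$a_major, g1$truth$a_minor,
                                enumerate_profiles(2)))
  # segment labels constant within segments and partition the genome
  expect_identical(g1$segments$start[1], 1L)
  expect_identical(g1$segments$end[nrow(g1$segments)], 500L)
  for (i in seq_len(nrow(g1$segments))) {
    idx <- g1$segments$start[i]:g1$segments$end[i]
    expect_true(all(g1$truth$a_major[idx] == g1$segments$a_major[i]))
    expect_true(all(g1$truth$a_minor[idx] == g1$segments$a_minor[i]))
  }
  # observation track invariants
  expect_true(all(diff(g1$observations$pos[g1$observations$chrom == "chr1"]) > 0))
  expect_true(all(is.na(g1$observations$baf) |
                    (g1$observations$baf >= 0 & g1$observations$baf <= 1)))
  expect_true(all(g1$observations$reads[is.na(g1$observations$baf)] == 0))
})

test_that("IBD regions look homozygous in BAF while depth follows copy number", {
  cfg <- sim_config(length = 3000, t_max = 2,
                    ibd = ibd_config(region_prob = 1,
                                     length_range = c(400, 600),
                                     max_regions = 1),
                    noise = noise_config(enabled = FALSE),
                    purity_range = c(1, 1), seed = 17)
  g <- simulate_genome(cfg)
  expect_gte(nrow(g$ibd_regions), 1)
  idx <- g$ibd_regions$start[1]:g$ibd_regions$end[1]
  baf_in <- g$observations$baf[idx]
  baf_in <- baf_in[!is.na(baf_in)]
  expect_true(all(baf_in %in% c(0, 1)))
  # read depth inside the IBD region still tracks the copy number profile
  exp_reads <- g$params$r_d *
    sample_total_cn(g$truth$a_major[idx] + g$truth$a_minor[idx], g$params$rho)
  obs_reads <- g$observations$reads[idx]
  expect_lt(abs(mean(obs_reads) - mean(exp_reads)),
            4 * sqrt(mean(exp_reads) / length(idx)))
})

test_that("logR conversion centres diploid coverage at zero and is scale free", {
  dip <- make_fixture("diploid", seed = 3, length = 1000)
  # constant copy number: every locus's coverage ratio equals the robust
  # mean up to Poisson noise; force exact constancy for the zero check
  dip$observations$reads <- rep(44, 1000)
  set.seed(10)
  lr <- to_logr_inputs(dip)
  expect_equal(lr$observations$logr, rep(0, 1000))
  # scaling all reads leaves logr unchanged (the ratio cancels)
  g <- simulate_genome(sim_config(length = 800, t_max = 2, seed = 6))
  set.seed(11); a <- to_logr_inputs(g)
  g2 <- g
  g2$observations$reads <- 2 * g$observations$reads
  set.seed(11); b <- to_logr_inputs(g2)
  expect_equal(a$observations$logr, b$observations$logr)
  expect_true(all(is.finite(a$observations$logr[g$observations$reads > 0])))
  g0 <- g
  g0$observations$reads[] <- 0
  expect_error(to_logr_inputs(g0), "all-zero")
})

test_that("derived sub-seeds stay in integer range and separate genomes", {
  s <- vapply(0:1000, function(k) derive_seed(123, k), integer(1))
  expect_true(all(s > 0 & s < 2^31))
  expect_false(any(duplicated(s)))
})
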