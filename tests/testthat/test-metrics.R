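test_that("BAF RMSE selects the nearest haplotype reconstruction", {
  # het locus reconstructed exactly by (1,0) or (0,1)
  expect_equal(baf_rmse(0.5, 1, 1, 1)$value, 0)
  # observed 0.4 against {0, 0.5, 1} leaves residual 0.1
  expect_equal(baf_rmse(0.4, 1, 1, 1)$value, 0.1)
  # homozygous observations reconstructed by (0,0) or (1,1)
  expect_equal(baf_rmse(c(0, 1), c(2, 2), c(1, 1), 0.8)$value, 0)
  # missing BAF and zero-copy loci are skipped
  r <- baf_rmse(c(NA, 0.5, 0.3), c(0, 1, 1), c(0, 1, 1), 1)
  expect_identical(r$n_loci_used, 2L)
  expect_equal(r$value, sqrt(mean(c(0, 0.2^2))))
})

test_that("reconstruction errors vanish for truth on noiseless expectations", {
  g <- make_fixture("two_segment", seed = 11, length = 1000)
  # replace sampled reads by their exact expectations
  st <- sample_copy_track(g$truth, g$params$rho)
  eo <- expected_observations(st, g$params$r_d)
  expect_equal(
    read_depth_mae(eo$reads, g$truth$a_major, g$truth$a_minor,
                   g$params$rho)$value, 0, tolerance = 1e-9)
  expect_equal(
    baf_rmse(eo$baf, g$truth$a_major, g$truth$a_minor, g$params$rho)$value,
    0, tolerance = 1e-12)
  # injected mis-calls make both strictly positive
  bad_major <- g$truth$a_major
  bad_major[1:300] <- bad_major[1:300] + 1L
  expect_gt(read_depth_mae(eo$reads, bad_major, g$truth$a_minor,
                           g$params$rho)$value, 0)
  expect_gt(baf_rmse(eo$baf, bad_major, g$truth$a_minor,
                     g$params$rho)$value, 0)
})

test_that("read-depth MAE scales linearly with the data", {
  set.seed(12)
  reads <- rpois(500, 60)
  major <- rep(1L, 500); minor <- rep(1L, 500)
  m1 <- read_depth_mae(reads, major, minor, 1)$value
  m2 <- read_depth_mae(2 * reads, major, minor, 1)$value
  expect_equal(m2, 2 * m1)
  expect_equal(read_depth_mae(rep(80, 100), major[1:100], minor[1:100],
                              1)$value, 0)
})

test_that("concordance formulas count locuswise agreement", {
  a <- data.frame(major_cn = c(2, 1, 1, 3), minor_cn = c(1, 1, 0, 2))
  expect_equal(unclass(concordance(a, a))[c("cc_major", "cc_minor",
                                            "cc_both", "cc_total")],
               list(cc_major = 1, cc_minor = 1, cc_both = 1, cc_total = 1))
  # swapping major/minor preserves totals; cc_both drops to the symmetric loci
  b <- data.frame(major_cn = a$minor_cn, minor_cn = a$major_cn)
  cc <- concordance(a, b)
  expect_equal(cc$cc_total, 1)
  expect_equal(cc$cc_both, mean(a$major_cn == a$minor_cn))
  # one disagreeing total out of 10
  a10 <- data.frame(major_cn = rep(1, 10), minor_cn = rep(1, 10))
  b10 <- a10; b10$major_cn[4] <- 2
  expect_equal(concordance(a10, b10)$cc_total, 0.9)
  # total-only second caller
  cc_tot <- concordance(a, data.frame(total_cn = c(3, 2, 1, 5)))
  expect_true(is.na(cc_tot$cc_major))
  expect_equal(cc_tot$cc_total, 1)
  expect_error(concordance(a, a10), "lengths")
})

test_that("concordance bounds hold on random call pairs", {
  set.seed(13)
  for (i in 1:30) {
    L <- sample(10:100, 1)
    a <- data.frame(major_cn = sample(0:3, L, TRUE),
                    minor_cn = sample(0:2, L, TRUE))
    b <- data.frame(major_cn = sample(0:3, L, TRUE),
                    minor_cn = sample(0:2, L, TRUE))
    cc <- concordance(a, b)
    expect_lte(cc$cc_both, min(cc$cc_major, cc$cc_minor))
    expect_lte(cc$cc_both, cc$cc_total)
  }
})

test_that("multiclonal reconstruction mixes clones and collapses at tau 1", {
  set.seed(14)
  L <- 50
  tr <- subclonal_track(runif(L), sample(0:3, L, TRUE), sample(0:1, L, TRUE),
                        sample(0:3, L, TRUE), sample(0:1, L, TRUE))
  rho <- 0.7
  # tau = 1 reduces bitwise to the single-clone computation
  tr1 <- tr; tr1$tau <- rep(1, L)
  rec1 <- battenberg_reconstruction(tr1, rho, s1 = 1, s2 = 0)
  single <- list(
    c_s_total = sample_total_cn(tr$a1_major + tr$a1_minor, rho),
    c_s_ballele = sample_ballele_cn(tr$a1_major, tr$a1_minor, 1, 0, rho))
  expect_identical(rec1$c_s_total, single$c_s_total)
  expect_identical(rec1$c_s_ballele, single$c_s_ballele)
  # hand value: tau 0.5, clones (2,1) and (1,1), purity 1
  tr2 <- subclonal_track(0.5, 2, 1, 1, 1)
  expect_equal(battenberg_reconstruction(tr2, 1)$c_s_total, 2.5)
  # swapping clones and tau -> 1 - tau is invisible
  sw <- subclonal_track(1 - tr$tau, tr$a2_major, tr$a2_minor,
                        tr$a1_major, tr$a1_minor)
  recA <- battenberg_reconstruction(tr, rho)
  recB <- battenberg_reconstruction(sw, rho)
  expect_equal(recA$c_s_total, recB$c_s_total)
  expect_equal(recA$c_s_ballele, recB$c_s_ballele)
})

test_that("main clone projection picks the larger fraction with ties to clone 1", {
  tr <- subclonal_track(c(1, 0.3, 0.5, 0.8, 0),
                        a1_major = c(2, 2, 2, 2, 2), a1_minor = c(1, 1, 1, 1, 1),
                        a2_major = c(1, 1, 1, 1, 1), a2_minor = c(0, 0, 0, 0, 0))
  pr <- main_clone_projection(tr)
  expect_identical(pr$major_cn, c(2, 1, 2, 2, 1))
  expect_identical(pr$minor_cn, c(1, 0, 1, 1, 0))
})
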