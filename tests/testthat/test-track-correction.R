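test_that("bin_reads apportions interval values by overlap", {
  iv <- data.frame(chrom = "chr1", start = 0, end = 10000, value = 5)
  tr <- bin_reads(iv, 10000, c(chr1 = 30000))
  expect_equal(tr$values$chr1, c(5, 0, 0))

  iv2 <- data.frame(chrom = "chr1", start = 5000, end = 15000, value = 4)
  tr2 <- bin_reads(iv2, 10000, c(chr1 = 30000))
  expect_equal(tr2$values$chr1, c(2, 2, 0))

  set.seed(1)
  iv3 <- data.frame(chrom = "chr1",
                    start = c(0, 2500, 9000, 12000, 28000),
                    end = c(4000, 11000, 9500, 25000, 30000),
                    value = c(3, 7, 2, 1.5, 4))
  tr3 <- bin_reads(iv3, 10000, c(chr1 = 30000))
  # brute force: per-bp accumulation
  bp <- numeric(30000)
  for (r in seq_len(nrow(iv3))) {
    ix <- (iv3$start[r] + 1):iv3$end[r]
    bp[ix] <- bp[ix] + iv3$value[r] / (iv3$end[r] - iv3$start[r])
  }
  expect_equal(tr3$values$chr1,
               as.numeric(tapply(bp, rep(1:3, each = 10000), sum)))
  expect_equal(sum(tr3$values$chr1), sum(iv3$value))

  expect_warning(bin_reads(data.frame(chrom = "chr1", start = 25000,
                                      end = 35000, value = 2),
                           10000, c(chr1 = 30000)), "clipped")
  expect_warning(bin_reads(data.frame(chrom = c("chr1", "chrX"),
                                      start = 0, end = 10000, value = 1),
                           10000, c(chr1 = 30000)), "unknown")
})

test_that("library-size normalization rescales to counts per million", {
  v <- c(200, rep(0, 9), rep(2e6 / 10 - 20, 10))
  tr <- binned_track(list(chr1 = v), 1e4)
  out <- libsize_normalize(tr)
  expect_equal(out$values$chr1[1], 200 * 1e6 / sum(v))
  expect_equal(sum(track_values(out)), 1e6, tolerance = 1e-6)

  tr2 <- binned_track(list(chr1 = 3 * v), 1e4)
  expect_equal(track_values(libsize_normalize(tr2)), track_values(out))

  expect_error(libsize_normalize(binned_track(list(chr1 = rep(0, 5)), 1e4)),
               "zero")
})

test_that("loess residuals remove a covariate trend and honor degenerate fits", {
  set.seed(8)
  n <- 5000
  covariate <- binned_track(list(chr1 = runif(n, 10, 70)), 1e4)
  noise <- rnorm(n)

  const <- binned_track(list(chr1 = rep(5, n)), 1e4)
  y <- binned_track(list(chr1 = noise + 3), 1e4)
  out <- loess_residuals(y, const)
  expect_equal(track_values(out), noise + 3 - mean(noise + 3))

  y2 <- binned_track(list(chr1 = noise), 1e4)
  expect_lt(abs(spearman_rho(track_values(loess_residuals(y2, covariate)),
                             track_values(covariate))), 0.05)

  y3 <- binned_track(list(chr1 = 2 * track_values(covariate) + noise), 1e4)
  r3 <- track_values(loess_residuals(y3, covariate))
  expect_lt(abs(spearman_rho(r3, track_values(covariate))), 0.05)
  expect_equal(var(r3), var(noise), tolerance = 0.1)

  expect_error(loess_residuals(binned_track(list(chr1 = rnorm(50)), 1e4),
                               binned_track(list(chr1 = runif(50)), 1e4)),
               "fewer than 100")
})

test_that("correction masks low-mappability bins and leaves no detectable trend", {
  # independent-covariate construction: the regime where sequential
  # residualization is clean and weakly idempotent
  set.seed(21)
  n <- 8000
  re <- rpois(n, 40)
  gc <- runif(n, 0.35, 0.6)
  lam <- 150 * (2 * re / (re + mean(re))) * (1 + 0.3 * exp(-(gc - 0.45)^2 / 0.005))
  cnt <- binned_track(list(chr1 = as.numeric(rpois(n, lam))), 1e4)
  re_t <- binned_track(list(chr1 = as.numeric(re)), 1e4)
  gc_t <- binned_track(list(chr1 = gc), 1e4)
  mp <- rep(1, n); mp[sample(n, 100)] <- 0.5
  mp_t <- binned_track(list(chr1 = mp), 1e4)

  corr <- correct_visibility(cnt, re_t, gc_t, mp_t)
  expect_identical(track_mask(corr), mp >= 0.8)
  xc <- track_values(corr)
  expect_lt(abs(spearman_rho(xc, as.numeric(re))), 0.05)
  expect_lt(abs(spearman_rho(xc, gc)), 0.05)

  # weak idempotence: once the trends are captured (large n, effects the
  # degree-1 fit estimates without bias), re-application only perturbs
  # values by a small fraction of the corrected signal's spread
  set.seed(22)
  n2 <- 50000
  re2 <- rpois(n2, 40); gc2 <- runif(n2, 0.35, 0.6)
  y2 <- binned_track(list(chr1 = 3 * re2 + 200 * gc2 + rnorm(n2, 0, 10)),
                     1e4)
  re2_t <- binned_track(list(chr1 = as.numeric(re2)), 1e4)
  gc2_t <- binned_track(list(chr1 = gc2), 1e4)
  mp2_t <- binned_track(list(chr1 = rep(1, n2)), 1e4)
  c1 <- correct_visibility(y2, re2_t, gc2_t, mp2_t)
  c2 <- correct_visibility(c1, re2_t, gc2_t, mp2_t)
  ch <- track_values(c2) - track_values(c1)
  expect_lt(sd(ch, na.rm = TRUE),
            0.05 * sd(track_values(c1), na.rm = TRUE))
})

test_that("correction removes most of the covariate trend on generator output", {
  spec <- small_spec(seed = 6)
  tr <- generate_truth(spec)
  cov <- generate_covariates(tr)
  cnt <- simulate_counts(tr, cov$gc, cov$re_density)
  raw_re <- spearman_rho(track_values(cnt), track_values(cov$re_density))
  raw_gc <- spearman_rho(track_values(cnt), track_values(cov$gc))
  corr <- correct_visibility(cnt, cov$re_density, cov$gc, cov$mappability)
  post_re <- spearman_rho(track_values(corr), track_values(cov$re_density))
  post_gc <- spearman_rho(track_values(corr), track_values(cov$gc))
  expect_gte(abs(raw_re), 0.2)
  expect_gte(abs(raw_gc), 0.2)
  expect_lt(abs(post_re), abs(raw_re) / 3)
  expect_lt(abs(post_gc), abs(raw_gc) / 3)

  # nothing to detect when the condensation effect is off
  tr1 <- generate_truth(small_spec(seed = 6, visibility_delta = 1))
  cnt1 <- simulate_counts(tr1, cov$gc, cov$re_density)
  corr1 <- correct_visibility(cnt1, cov$re_density, cov$gc, cov$mappability)
  st <- unlist(domain_bin_states(tr1$domains, spec$bin_size,
                                 spec$chrom_lengths), use.names = FALSE)
  x1 <- track_values(corr1)
  gap <- abs(mean(x1[st == "C"], na.rm = TRUE) -
               mean(x1[st == "D"], na.rm = TRUE))
  expect_lt(gap, 0.05 * sd(x1, na.rm = TRUE))
})

test_that("Z-scoring standardizes unmasked bins with the sample convention", {
  tr <- binned_track(list(chr1 = c(1, 2, 3)), 1e4)
  expect_equal(track_values(zscore_track(tr)), c(-1, 0, 1))

  set.seed(2)
  v <- rnorm(500, 4, 3)
  m <- c(rep(TRUE, 450), rep(FALSE, 50))
  tr2 <- binned_track(list(chr1 = v), 1e4, mask = list(chr1 = m))
  z <- track_values(zscore_track(tr2))
  expect_equal(mean(z, na.rm = TRUE), 0, tolerance = 1e-9)
  expect_equal(sd(z, na.rm = TRUE), 1, tolerance = 1e-9)
  expect_true(all(is.na(z[!m])))

  tr3 <- binned_track(list(chr1 = 7 * v - 2), 1e4, mask = list(chr1 = m))
  expect_equal(track_values(zscore_track(tr3)), z)

  expect_error(zscore_track(binned_track(list(chr1 = rep(2, 9)), 1e4)),
               "zero standard deviation")
})

test_that("matrix coverage sums symmetric columns with the diagonal once", {
  bins <- data.frame(chrom = "chr1", start = c(0, 1, 2) * 1e4,
                     end = c(1, 2, 3) * 1e4, bin_id = 0:2)
  ent <- data.frame(i = c(1, 1, 2), j = c(2, 3, 3), value = c(1, 2, 3))
  cm <- contact_matrix(bins, ent, 1e4)
  expect_equal(track_values(matrix_coverage_1d(cm)), c(3, 4, 5))

  cm0 <- contact_matrix(bins, ent[0, ], 1e4)
  expect_equal(track_values(matrix_coverage_1d(cm0)), c(0, 0, 0))

  spec <- synthetic_spec(chrom_lengths = c(10e6, 10e6), seed = 2,
                         contact_scale = 500)
  tr <- generate_truth(spec)
  cov1d <- track_values(matrix_coverage_1d(simulate_matrix(tr)))
  st <- unlist(domain_bin_states(tr$domains, spec$bin_size,
                                 spec$chrom_lengths), use.names = FALSE)
  expect_lt(mann_whitney_u(cov1d[st == "C"], cov1d[st == "D"], "less")$p,
            0.01)
})
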