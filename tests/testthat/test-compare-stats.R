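test_that("Mann-Whitney U matches enumeration, wilcox.test and its examples", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6), "less")
  expect_equal(r$U, 0)
  expect_equal(r$p, 1 / 20)
  expect_equal(r$method, "exact")

  same <- mann_whitney_u(c(1, 2, 2, 5), c(1, 2, 2, 5), "two.sided")
  expect_equal(same$U, 4 * 4 / 2)
  expect_gt(same$p, 0.99)

  # exact mode equals brute-force enumeration for n, m <= 7
  set.seed(12)
  for (i in 1:6) {
    n <- sample(2:7, 1); m <- sample(2:7, 1)
    x <- rnorm(n); y <- rnorm(m, 0.8)
    expect_equal(mann_whitney_u(x, y, "less")$p, brute_mw_p_less(x, y))
    wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "less",
                                              exact = TRUE))
    expect_equal(mann_whitney_u(x, y, "less")$U, unname(wt$statistic))
    expect_equal(mann_whitney_u(x, y, "less")$p, wt$p.value)
    wt2 <- suppressWarnings(stats::wilcox.test(x, y, exact = TRUE))
    expect_equal(mann_whitney_u(x, y, "two.sided")$p, wt2$p.value)
  }

  # the normal approximation tracks the exact null closely
  set.seed(13)
  x <- rnorm(15); y <- rnorm(15, 0.5)
  expect_equal(mann_whitney_u(x, y, "less")$method, "exact")
  approx <- mann_whitney_u(c(x, x[1]), c(y, y[1]), "less")  # ties -> normal
  expect_equal(approx$method, "normal")
  x2 <- rnorm(21); y2 <- rnorm(20, 0.5)  # n*m > 400, no ties -> normal
  mine <- mann_whitney_u(x2, y2, "less")
  expect_equal(mine$method, "normal")
  exact_ref <- stats::wilcox.test(x2, y2, alternative = "less",
                                  exact = TRUE)$p.value
  expect_lt(abs(mine$p - exact_ref), 0.005)

  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("Spearman correlation is the Pearson correlation of midranks", {
  x <- sort(rnorm(20))
  expect_equal(spearman_rho(x, exp(x)), 1)
  expect_equal(spearman_rho(x, rev(x)), -1)
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  set.seed(3)
  a <- rnorm(50); b <- a + rnorm(50)
  expect_equal(spearman_rho(a, b), cor(a, b, method = "spearman"))
  expect_warning(r <- spearman_rho(rep(1, 5), rnorm(5)), "constant")
  expect_true(is.na(r))
})

test_that("track quantile normalization equalizes sorted values and keeps ranks", {
  set.seed(6)
  mk <- function(v) binned_track(list(chr1 = v), 1e4)
  tracks <- list(mk(rnorm(300, 5)), mk(rexp(300)), mk(runif(300)))
  qn <- quantile_normalize_tracks(tracks)
  s1 <- sort(track_values(qn[[1]]))
  expect_equal(sort(track_values(qn[[2]])), s1)
  expect_equal(sort(track_values(qn[[3]])), s1)
  for (i in 1:3)
    expect_equal(rank(track_values(qn[[i]])),
                 rank(track_values(tracks[[i]])), tolerance = 1e-12)
  # independent reference implementation on untied columns
  lq0 <- limma::normalizeQuantiles(vapply(tracks, track_values,
                                          numeric(300)))
  for (i in 1:3) expect_equal(track_values(qn[[i]]), unname(lq0[, i]))

  # identical tracks unchanged; k = 3 toy against the oracle and limma
  two <- quantile_normalize_tracks(list(mk(c(1, 5, 2)), mk(c(1, 5, 2))))
  expect_equal(track_values(two[[1]]), c(1, 5, 2))
  # ties receive the mean of their rank-averages (group-mean semantics)
  cols <- list(c(2, 2, 6, 1), c(4, 1, 9, 9), c(0.5, 3, 3, 3))
  qn3 <- quantile_normalize_tracks(lapply(cols, mk))
  orc <- qn_oracle(cols)
  for (i in 1:3) expect_equal(track_values(qn3[[i]]), orc[[i]])

  one <- quantile_normalize_tracks(list(mk(c(3, 1))))
  expect_equal(track_values(one[[1]]), c(3, 1))
})

test_that("overlap fractions measure state coverage by an annotation", {
  dom <- domain_set(data.frame(
    chrom = "chr1", start = c(0, 1e5), end = c(1e5, 3e5),
    state = c("condensed", "decondensed"), proportion = 1))
  ann_in <- data.frame(chrom = "chr1", start = 0, end = 2e5)
  expect_equal(overlap_fraction(dom, ann_in, "condensed"), 1)
  ann_half <- data.frame(chrom = "chr1", start = 5e4, end = 2e5)
  expect_equal(overlap_fraction(dom, ann_half, "condensed"), 0.5)
  expect_warning(f <- overlap_fraction(dom, ann_in, "ambiguous"),
                 "undefined")
  expect_true(is.na(f))
})

test_that("switch tables count per-bin state changes", {
  a <- domain_set(data.frame(chrom = "chr1", start = c(0, 1e5),
                             end = c(1e5, 2e5),
                             state = c("condensed", "decondensed"),
                             proportion = 1))
  expect_equal(switch_table(a, a)$pct_condensed_to_decondensed, 0)
  flip <- a; flip$state <- rev(flip$state)
  st <- switch_table(a, flip)
  expect_equal(st$pct_condensed_to_decondensed, 100)
  expect_equal(st$pct_decondensed_to_condensed, 100)

  # 10 condensed bins in a, 3 of them decondensed in b
  b <- domain_set(data.frame(chrom = "chr1",
                             start = c(0, 7e4, 1e5),
                             end = c(7e4, 1e5, 2e5),
                             state = c("condensed", "decondensed",
                                       "decondensed"),
                             proportion = 1))
  expect_equal(switch_table(a, b)$pct_condensed_to_decondensed, 30)

  # invariant to chromosome ordering
  a2 <- domain_set(data.frame(chrom = c("chr2", "chr1"), start = 0,
                              end = 1e5, state = "condensed",
                              proportion = 1))
  b2 <- domain_set(data.frame(chrom = c("chr1", "chr2"), start = 0,
                              end = 1e5,
                              state = c("decondensed", "condensed"),
                              proportion = 1))
  expect_equal(switch_table(a2, b2)$pct_condensed_to_decondensed, 50)
})

test_that("boundary aggregation orients profiles and applies the flank rule", {
  dom <- domain_set(data.frame(
    chrom = "chr1", start = c(0, 1e6, 2.5e6), end = c(1e6, 2.5e6, 4e6),
    state = c("decondensed", "condensed", "decondensed"), proportion = 1))
  n <- 400
  const <- binned_track(list(chr1 = rep(2.5, n)), 1e4)
  pr <- boundary_aggregate(const, dom, flank = 5e5)
  expect_equal(pr$n_boundaries, 2L)
  expect_true(all(abs(pr$mean - 2.5) < 1e-12))

  # indicator track: +1 on decondensed, -1 on condensed bins
  st <- domain_bin_states(dom, 1e4, c(chr1 = 4e6))$chr1
  ind <- binned_track(list(chr1 = ifelse(st == "D", 1, -1)), 1e4)
  pr2 <- boundary_aggregate(ind, dom, flank = 5e5)
  expect_true(all(pr2$mean[pr2$offsets < -1e4] == 1))
  expect_true(all(pr2$mean[pr2$offsets > 1e4] == -1))

  pr01 <- boundary_aggregate(ind, dom, flank = 5e5, scale01 = TRUE)
  expect_equal(range(pr01$mean), c(0, 1))

  # boundaries flanked by a 150 kb domain are excluded at min_side = 200 kb
  dom2 <- domain_set(data.frame(
    chrom = "chr1",
    start = c(0, 1e6, 2.2e6, 2.35e6), end = c(1e6, 2.2e6, 2.35e6, 4e6),
    state = c("decondensed", "condensed", "decondensed", "condensed"),
    proportion = 1))
  st2 <- domain_bin_states(dom2, 1e4, c(chr1 = 4e6))$chr1
  ind2 <- binned_track(list(chr1 = ifelse(st2 == "D", 1, -1)), 1e4)
  pr3 <- boundary_aggregate(ind2, dom2, flank = 5e5, min_side = 2e5)
  expect_equal(pr3$n_boundaries, 1L)
  expect_error(boundary_aggregate(const,
                                  domain_set(data.frame(
                                    chrom = "chr1", start = c(0, 1e5),
                                    end = c(1e5, 2e5),
                                    state = c("condensed", "decondensed"),
                                    proportion = 1)),
                                  flank = 5e5, min_side = 2e5),
               "min_side")
})

test_that("log-ratio tracks expose the KO decondensation direction", {
  mk <- function(v) binned_track(list(chr1 = v), 1e4)
  a <- mk(c(10, 20, 40, 80))
  expect_true(all(abs(track_values(log_ratio_track(a, a))) < 1e-12))

  set.seed(7)
  base <- runif(400, 500, 2000)
  b <- mk(base); a2 <- mk(2 * base)
  # identical CPM after normalization: ratio 0; without normalization ~1
  expect_true(all(abs(track_values(log_ratio_track(a2, b))) < 0.01))
  raw <- log_ratio_track(a2, b, normalize = FALSE)
  expect_equal(mean(track_values(raw)), 1, tolerance = 0.01)

  # synthetic KO: condensed visibility reset to 1 vs WT at 0.5
  spec <- synthetic_spec(chrom_lengths = c(10e6, 10e6), seed = 8)
  wt_tr <- generate_truth(spec)
  cov <- generate_covariates(wt_tr)
  wt <- simulate_counts(wt_tr, cov$gc, cov$re_density)
  ko_tr <- wt_tr
  ko_tr$visibility$values <- lapply(ko_tr$visibility$values,
                                    function(v) rep(1, length(v)))
  ko_tr$spec$seed <- spec$seed + 1000L
  ko <- simulate_counts(ko_tr, cov$gc, cov$re_density)
  lr <- track_values(log_ratio_track(ko, wt))
  st <- unlist(domain_bin_states(wt_tr$domains, spec$bin_size,
                                 spec$chrom_lengths), use.names = FALSE)
  expect_lt(mann_whitney_u(lr[st == "D"], lr[st == "C"], "less")$p, 0.01)
  expect_gt(mean(lr[st == "C"]), mean(lr[st == "D"]))
})
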