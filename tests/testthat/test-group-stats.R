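test_that("Kruskal-Wallis matches the brute-force rank definition", {
  g <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)) # no ties
  res <- kruskal_wallis(g)
  expect_equal(res$H, kw_oracle(g), tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$p, pchisq(res$H, 2, lower.tail = FALSE))

  # property: random instances with ties, n <= 30
  for (i in 1:25) {
    gl <- withr::with_seed(1000 + i, {
      k <- sample(2:4, 1)
      lapply(seq_len(k), function(j) sample(1:6, sample(2:8, 1), replace = TRUE))
    })
    expect_equal(kruskal_wallis(gl)$H, kw_oracle(gl), tolerance = 1e-10,
                 info = paste("instance", i))
  }
})

test_that("Kruskal-Wallis handles total ties as H = 0, p = 1", {
  res <- kruskal_wallis(list(rep(2, 3), rep(2, 3), rep(2, 3)))
  expect_equal(res$H, 0)
  expect_equal(res$p, 1)
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "non-empty")
})

test_that("eta-squared effect size reproduces its defining arithmetic", {
  expect_equal(eta_squared_H(38.48, 5, 74), (38.48 - 4) / 69)
  expect_equal(eta_squared_H(4, 5, 74), 0) # H = k - 1 centres at zero
  expect_error(eta_squared_H(10, 5, 5), "exceed")
  # round-trip: reconstruct H from a reported effect size
  H_back <- 0.500 * (74 - 5) + 5 - 1
  expect_equal(round(eta_squared_H(H_back, 5, 74), 3), 0.500)
})

test_that("Dunn z-values match the hand formula, with tie correction", {
  g <- list(A = c(1, 2), B = c(3, 4), C = c(5, 6))
  d <- dunn_test(g)
  ac <- d[d$group1 == "A" & d$group2 == "C", ]
  expect_equal(ac$z, unname(dunn_oracle(g, 1, 3)), tolerance = 1e-12)
  expect_equal(ac$p, 2 * pnorm(-abs(ac$z)))

  # ties exercised
  gt <- list(A = c(1, 1, 2), B = c(2, 2, 3), C = c(3, 4, 4))
  dt <- dunn_test(gt)
  expect_equal(dt$z[dt$group1 == "A" & dt$group2 == "B"],
               unname(dunn_oracle(gt, 1, 2)), tolerance = 1e-12)

  # antisymmetry under pair swap: reverse the list order
  g_rev <- rev(g)
  d_rev <- dunn_test(g_rev)
  expect_equal(d_rev$z[d_rev$group1 == "C" & d_rev$group2 == "A"], -ac$z,
               tolerance = 1e-12)
})

test_that("Dunn handles identical groups, dominance and degeneracy", {
  g <- list(A = c(1, 5), B = c(1, 5), C = c(9, 10))
  d <- dunn_test(g)
  ab <- d[d$group1 == "A" & d$group2 == "B", ]
  expect_equal(ab$z, 0)
  expect_equal(ab$p, 1)
  # C dominates A: z > 0 under (C, A) orientation = -(A, C)
  expect_lt(d$z[d$group1 == "A" & d$group2 == "C"], 0)

  expect_warning(dz <- dunn_test(list(A = c(1, 1), B = c(1, 1))),
                 class = "undefined_z")
  expect_true(all(is.na(dz$z)))
})

test_that("Spearman correlation equals Pearson on average ranks", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  y <- c(2, 7, 1, 8, 2, 8, 1, 8) # with ties
  s <- spearman_rank(x, y)
  expect_equal(s$rho, cor(rank(x), rank(y)), tolerance = 1e-12)

  expect_equal(spearman_rank(1:8, (1:8)^3)$rho, 1)       # monotone transform
  expect_equal(spearman_rank(1:8, -(1:8))$rho, -1)
  expect_warning(sc <- spearman_rank(rep(1, 5), 1:5), class = "undefined_rho")
  expect_true(is.na(sc$rho))
  expect_error(spearman_rank(1:3, 1:3), "4")
})

test_that("outlier flagging follows the interpolated-quantile rule", {
  v <- c(1:99, 1000)
  fl <- flag_outliers(v, 0.975)
  expect_true(fl[100])
  expect_lte(sum(fl), ceiling(0.025 * 100))
  expect_gt(1000, quantile(v, 0.975, type = 7)) # the oracle inequality

  expect_false(any(flag_outliers(rep(5, 40))))
  n40 <- withr::with_seed(1, rnorm(40))
  expect_lte(sum(flag_outliers(n40)), ceiling(0.025 * 40))
  expect_error(flag_outliers(1), "2 values")
})

test_that("the per-parameter group report has omnibus and pairwise entries", {
  fits <- withr::with_seed(5, data.frame(
    participant_id = sprintf("P%02d", 1:30),
    group = rep(c("Controls", "AD", "svPPA"), each = 10),
    threshold = c(rnorm(10, 3.1, 0.3), rnorm(10, 4.3, 1.2), rnorm(10, 3.6, 0.5)),
    slope = rnorm(30, 0.9, 0.3),
    lam = runif(30, 0, 0.05), gamma = runif(30, 0, 0.05),
    eta = rep(0, 30)))
  rep_ <- group_stats_report(fits)
  expect_named(rep_, c("threshold", "slope", "lam", "gamma", "eta",
                       "threshold_outliers", "underpowered"), ignore.order = TRUE)
  expect_s3_class(rep_$threshold$omnibus, "kw_result")
  expect_equal(nrow(rep_$threshold$pairwise), 3)
  expect_false(rep_$underpowered)
})
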