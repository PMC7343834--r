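test_that("summaries match brute-force moment formulas", {
  s <- summarize_values(c(1, 1, 1))
  expect_equal(s$mean, 1)
  expect_equal(s$std, 0)
  expect_equal(s$skewness, 0)
  expect_true(s$skewness_flag)
  expect_equal(summarize_values(c(1, 2, 3))$skewness, 0)
  expect_error(summarize_values(numeric(0)), "empty")

  v <- c(1, 2, 3, 4, 100)
  s2 <- summarize_values(v)
  # adjusted Fisher-Pearson skewness, computed from scratch
  n <- length(v)
  g1 <- (sum((v - mean(v))^3) / n) / (sum((v - mean(v))^2) / n)^1.5
  G1 <- g1 * sqrt(n * (n - 1)) / (n - 2)
  expect_gt(s2$skewness, 0)
  expect_equal(s2$skewness, G1, tolerance = 1e-12)

  set.seed(31)
  for (rep in 1:5) {
    x <- rnorm(200, 5, 2)
    s3 <- summarize_values(x)
    expect_equal(s3$mean, sum(x) / length(x), tolerance = 1e-12)
    expect_equal(s3$std,
                 sqrt(sum((x - mean(x))^2) / (length(x) - 1)),
                 tolerance = 1e-12)
    expect_equal(unname(s3$quantiles[["50%"]]), median(x),
                 tolerance = 1e-12)
  }
})

test_that("the elongation rule keeps S < mean + std, strictly", {
  rec <- data.frame(sphericity = c(0.85, 0.95, 0.88, 0.89))
  summ <- summarize_values(c(rep(0.82, 50), rep(0.89, 25)))
  # impose the reported population values directly
  summ$mean <- 0.82; summ$std <- 0.07  # cutoff 0.89
  kept <- select_elongated(rec, summ)
  expect_equal(kept$sphericity, c(0.85, 0.88))
  # all-identical sphericities: zero spread, strict rule empties the set
  same <- data.frame(sphericity = rep(0.8, 5))
  expect_identical(nrow(select_elongated(same, summarize_values(
    same$sphericity))), 0L)
  # filter properties: subset, idempotent
  set.seed(41)
  rec2 <- data.frame(sphericity = rnorm(200, 0.82, 0.07))
  summ2 <- summarize_values(rec2$sphericity)
  k1 <- select_elongated(rec2, summ2)
  expect_true(all(k1$sphericity %in% rec2$sphericity))
  expect_identical(select_elongated(k1, summ2), k1)
})

test_that("the retained fraction under a normal sphericity model is near
           Phi(1)", {
  set.seed(42)
  s <- pmin(rnorm(500, 0.82, 0.07), 1)
  summ <- summarize_values(s)
  frac <- nrow(select_elongated(data.frame(sphericity = s), summ)) / 500
  expect_gte(frac, 0.80)
  expect_lte(frac, 0.88)
})

test_that("the KS statistic separates log-normal from uniform volumes", {
  set.seed(7)
  v_ln <- rlnorm(500, log(1000), 0.8)
  chk <- lognormal_check(v_ln)
  expect_lte(chk$ks_stat, 0.06)
  expect_equal(chk$log_mean, mean(log(v_ln)))
  # overlay histogram is area-normalized
  binw <- diff(chk$hist$mid[1:2])
  expect_equal(sum(chk$hist$density) * binw, 1, tolerance = 1e-6)
  v_un <- runif(500, 1e3, 2e3)
  expect_gt(lognormal_check(v_un)$ks_stat, chk$ks_stat)
  expect_error(lognormal_check(rep(10, 50)), "degenerate")
  expect_error(lognormal_check(c(-1, rep(2, 20))), "positive")
  expect_error(lognormal_check(rlnorm(5)), "at least 10")
})

test_that("group comparison is exact for tiny n and approximate for large", {
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
  expect_match(same$method, "exact")
  # 3 vs 3 fully separated: 2 extreme arrangements of choose(6,3) = 20
  sep <- compare_groups(c(1, 2, 3), c(10, 11, 12))
  expect_equal(sep$p_value, 0.1)
  # exact enumeration agrees with wilcox.test's exact p on untied data
  set.seed(5)
  a <- rnorm(6); b <- rnorm(7, 1)
  expect_equal(compare_groups(a, b)$p_value,
               wilcox.test(a, b, exact = TRUE)$p.value, tolerance = 1e-12)
  big <- compare_groups(rnorm(30), rnorm(30, 2))
  expect_match(big$method, "approximation")
  expect_lt(big$p_value, 0.001)
  expect_error(compare_groups(c(1, 2), c(1, 2, 3)), "at least 3")
})

test_that("orientation statistics treat axes as undirected", {
  set.seed(55)
  # axes uniformly distributed in a 30-degree cap about (1, 0, 0)
  n <- 200
  cosd <- runif(n, cos(30 * pi / 180), 1)
  phi <- runif(n, 0, 2 * pi)
  sind <- sqrt(1 - cosd^2)
  A <- cbind(cosd, sind * cos(phi), sind * sin(phi))
  rec <- data.frame(ax = A[, 1], ay = A[, 2], az = A[, 3],
                    tie_flag = FALSE, region = "hemisphere")
  os <- orientation_summary(rec)$hemisphere
  expect_gte(abs(sum(os$mean_axis * c(1, 0, 0))), 0.99)
  # 90th percentile of the uniform-cap deviation: F(d) ~ (1-cos d)/(1-cos 30)
  expect_gte(os$p90_deg, 25)
  expect_lte(os$p90_deg, 30)
  # all-identical axes give zero deviations
  one <- data.frame(ax = 1, ay = 0, az = 0, tie_flag = FALSE,
                    region = "x")[rep(1, 5), ]
  os1 <- orientation_summary(one)$x
  expect_equal(os1$p50_deg, 0)
  expect_equal(os1$p90_deg, 0)
  # sign flips of any subset leave the summary unchanged
  flip <- sample(c(-1, 1), n, replace = TRUE)
  rec2 <- data.frame(ax = flip * A[, 1], ay = flip * A[, 2],
                     az = flip * A[, 3], tie_flag = FALSE,
                     region = "hemisphere")
  os2 <- orientation_summary(rec2)$hemisphere
  expect_gte(abs(sum(os2$mean_axis * os$mean_axis)), 1 - 1e-9)
  expect_equal(os2$p50_deg, os$p50_deg, tolerance = 1e-9)
  expect_equal(os2$p90_deg, os$p90_deg, tolerance = 1e-9)
  # antipodally doubled histogram: total count is 2n and symmetric
  expect_equal(sum(os$hist$counts), 2L * n)
})

test_that("orientation-tensor eigenvalues match the characteristic
           polynomial", {
  set.seed(66)
  A <- matrix(rnorm(60), 20, 3)
  A <- A / sqrt(rowSums(A^2))
  T_ <- crossprod(A) / nrow(A)
  ev <- eigen(T_, symmetric = TRUE)$values
  # coefficients of det(T - x I) = -x^3 + tr x^2 - m2 x + det
  tr <- sum(diag(T_))
  m2 <- (tr^2 - sum(T_ * T_)) / 2
  roots <- sort(Re(polyroot(c(det(T_), -m2, tr, -1))), decreasing = TRUE)
  expect_equal(ev, roots, tolerance = 1e-10)
})

test_that("empty region groups are skipped with a warning", {
  rec <- data.frame(ax = c(1, NA), ay = c(0, NA), az = c(0, NA),
                    tie_flag = c(FALSE, TRUE),
                    region = factor(c("hemisphere", "vermis"),
                                    levels = c("hemisphere", "vermis")))
  expect_warning(os <- orientation_summary(rec), "vermis")
  expect_named(os, "hemisphere")
})
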