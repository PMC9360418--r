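test_that("spearman hits +/-1 on strictly monotone pairs", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5)
  expect_equal(spearman(x, exp(x))$rho, 1)
  expect_equal(spearman(x, -x^3)$rho, -1)
})

test_that("spearman with ties matches the rank-then-Pearson oracle and cor.test", {
  x <- c(1, 2, 2, 3, 5, 5, 5, 8, 9, 10, 11, 4)
  y <- c(2, 1, 4, 4, 6, 3, 7, 9, 8, 12, 10, 5)
  s <- spearman(x, y)
  oracle <- stats::cor(rank(x), rank(y)) # midranks then Pearson
  expect_equal(s$rho, oracle, tolerance = 1e-12)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  expect_equal(s$rho, unname(ct$estimate), tolerance = 1e-12)
  # t-approximation p for n = 12
  tval <- oracle * sqrt(10 / (1 - oracle^2))
  expect_equal(s$p, 2 * pt(-abs(tval), 10), tolerance = 1e-12)
})

test_that("small-sample p comes from exact rank permutation", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(2, 1, 4, 3, 6, 5)
  s <- spearman(x, y)
  # brute-force oracle over all 6! permutations
  perms <- n1sense:::all_permutations(6)
  rho_obs <- cor(rank(x), rank(y))
  rhos <- apply(perms, 1, function(idx) cor(rank(x), rank(y)[idx]))
  expect_equal(s$p, mean(abs(rhos) >= abs(rho_obs) - 1e-12), tolerance = 1e-12)
  # exact test agrees with cor.test for tie-free small n
  ct <- stats::cor.test(x, y, method = "spearman", exact = TRUE)
  expect_equal(s$p, ct$p.value, tolerance = 1e-10)
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(1)
  x <- rnorm(25)
  y <- x + rnorm(25)
  a <- spearman(x, y)
  b <- spearman(exp(x), y)
  cc <- spearman(x, qnorm(pnorm(y)))
  expect_equal(a$rho, b$rho, tolerance = 1e-12)
  expect_equal(a$rho, cc$rho, tolerance = 1e-10)
})

test_that("degenerate inputs are flagged or rejected", {
  expect_false(spearman(rep(1, 10), rnorm(10))$defined)
  expect_error(spearman(1:3, 1:3), "at least 4")
})

test_that("BH step-up matches the hand-computed worked example", {
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.216,
         0.222, 0.251, 0.269, 0.275, 0.34, 0.341, 0.384, 0.569, 0.594, 0.696,
         0.762, 0.94, 0.942, 0.975, 1)
  # step-up oracle applied literally
  n <- length(p)
  o <- order(p)
  adj <- rev(cummin(rev(p[o] * n / seq_len(n))))
  expect_equal(bh_fdr(p)[o], pmin(1, adj))
})

test_that("the default grid enumerates 36 cells over hemisphere x contrast x behavior", {
  g <- default_correlation_grid()
  expect_equal(nrow(g), 36)
  expect_equal(nrow(dplyr::distinct(g)), 36)
  expect_setequal(unique(g$hemisphere), c("LOT", "ROT"))
  expect_setequal(unique(g$contrast), c("coarse", "fine"))
  expect_equal(nrow(dplyr::distinct(
    g, g$measure, g$behavior_timepoint, g$neural_timepoint
  )), 9)
})

test_that("correlation grid joins, corrects, and respects p_fdr >= p", {
  bundle <- run_simulate(run_config(seed = 31))
  res_d <- sensitivity_differences(bundle$amplitude_table)
  cg <- correlation_grid(res_d, bundle$behavior_table)
  expect_s3_class(cg, "correlation_grid")
  expect_equal(nrow(cg), 36)
  ok <- !cg$insufficient
  expect_true(all(cg$p_fdr[ok] >= cg$p[ok] - 1e-12))
  expect_true(all(cg$p_fdr[ok] <= 1))
  # the coupled cell carries the strongest association
  cell <- dplyr::filter(
    cg, neural_timepoint == "T4", hemisphere == "LOT",
    contrast == "coarse", measure == "arithmetic_pr"
  )
  expect_gt(cell$rho, 0.3)
  expect_lt(cell$p, 0.05)
  # outlier-excluded variant reports its own FDR family
  expect_true(all(cg$p_fdr_excl[ok & !is.na(cg$p_excl)] >=
    cg$p_excl[ok & !is.na(cg$p_excl)] - 1e-12))
})

test_that("cells below the minimum n are marked insufficient", {
  d <- tibble::tibble(
    subject = c("S01", "S02", "S03"), timepoint = "T4", hemisphere = "LOT",
    contrast = "coarse", difference_uv = c(-1, 0, 1)
  )
  b <- tibble::tibble(
    subject = c("S01", "S02", "S03"), timepoint = "T4",
    measure = "arithmetic_pr", score = c(10, 50, 90)
  )
  g <- tibble::tibble(
    neural_timepoint = "T4", hemisphere = "LOT", contrast = "coarse",
    measure = "arithmetic_pr", behavior_timepoint = "T4"
  )
  cg <- correlation_grid(d, b, grid = g, min_n = 5)
  expect_true(cg$insufficient)
  expect_true(is.na(cg$rho))
})

test_that("the MAD outlier rule removes a gross neural outlier from a grid cell", {
  set.seed(3)
  n <- 27
  d <- tibble::tibble(
    subject = sprintf("S%02d", 1:n), timepoint = "T4", hemisphere = "LOT",
    contrast = "coarse", difference_uv = c(rnorm(n - 1, -2, 1), 30)
  )
  b <- tibble::tibble(
    subject = sprintf("S%02d", 1:n), timepoint = "T4",
    measure = "arithmetic_pr", score = runif(n, 0, 100)
  )
  g <- tibble::tibble(
    neural_timepoint = "T4", hemisphere = "LOT", contrast = "coarse",
    measure = "arithmetic_pr", behavior_timepoint = "T4"
  )
  cg <- correlation_grid(d, b, grid = g)
  expect_equal(cg$n_excluded, 1L)
})
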