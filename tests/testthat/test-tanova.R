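test_that("map normalization yields unit GFP, is idempotent, flags zero maps", {
  set.seed(1)
  map <- rnorm(30)
  out <- normalize_map(map)
  expect_equal(gfp(out), 1, tolerance = 1e-9)
  expect_equal(normalize_map(out), out, tolerance = 1e-12, ignore_attr = TRUE)

  m2 <- map / gfp(map) * 2 # GFP 2
  expect_equal(gfp(normalize_map(m2)), 1, tolerance = 1e-12)

  z <- rep(1.5, 30) # zero spatial variance
  nz <- normalize_map(z)
  expect_equal(unname(nz), z, ignore_attr = TRUE)
  expect_equal(attr(nz, "zero_gfp"), 1L)

  x <- matrix(rnorm(30 * 8), 30)
  nx <- normalize_map(x)
  expect_true(all(abs(gfp(nx) - 1) < 1e-9))
})

literal_tanova <- function(maps) {
  # literal-formula oracle: s = sqrt((1/K) sum_c GFP(M_c - Mbar)^2)
  K <- dim(maps)[2]
  grand <- lapply(seq_len(K), function(cc) colMeans(maps[, cc, ]))
  mbar <- Reduce(`+`, grand) / K
  sqrt(mean(vapply(grand, function(g) {
    d <- g - mbar
    mean((d - mean(d))^2)
  }, numeric(1))))
}

test_that("TANOVA statistic: zero for identical maps, K=2 reduction, literal oracle", {
  set.seed(2)
  base <- rnorm(20)
  maps <- array(0, c(5, 3, 20))
  for (s in 1:5) for (cc in 1:3) maps[s, cc, ] <- base
  expect_equal(tanova_statistic(maps), 0, tolerance = 1e-12)

  maps2 <- array(rnorm(6 * 2 * 20), c(6, 2, 20))
  m1 <- colMeans(maps2[, 1, ])
  m2 <- colMeans(maps2[, 2, ])
  d <- m1 - m2
  expect_equal(
    tanova_statistic(maps2),
    sqrt(mean((d - mean(d))^2)) / 2, # GFP(difference)/2
    tolerance = 1e-12
  )

  maps3 <- array(rnorm(4 * 3 * 15), c(4, 3, 15))
  expect_lt(abs(tanova_statistic(maps3) - literal_tanova(maps3)), 1e-12)
})

test_that("statistic is invariant to per-subject positive rescaling before normalization", {
  set.seed(3)
  raw <- array(rnorm(6 * 2 * 20 * 3), c(6, 2, 20, 3))
  scaled <- raw
  fac <- runif(6, 0.2, 5)
  for (s in 1:6) scaled[s, , , ] <- fac[s] * raw[s, , , ]
  norm4 <- function(a) {
    for (s in seq_len(dim(a)[1])) {
      for (cc in seq_len(dim(a)[2])) a[s, cc, , ] <- normalize_map(a[s, cc, , ])
    }
    a
  }
  a1 <- norm4(raw)
  a2 <- norm4(scaled)
  for (ti in 1:3) {
    expect_equal(
      tanova_statistic(a1[, , , ti]), tanova_statistic(a2[, , , ti]),
      tolerance = 1e-12
    )
  }
})

test_that("Monte-Carlo p matches exhaustive enumeration on 3 subjects x 2 conditions", {
  set.seed(4)
  maps <- array(rnorm(3 * 2 * 12 * 2), c(3, 2, 12, 2))
  maps[, 1, , ] <- maps[, 1, , ] + 0.8 # mild true difference
  for (s in 1:3) for (cc in 1:2) maps[s, cc, , ] <- normalize_map(maps[s, cc, , ])
  ms <- manual_map_set(maps)

  # exhaustive oracle over all 2^3 within-subject swaps
  exact_p <- vapply(1:2, function(ti) {
    obs <- tanova_statistic(maps[, , , ti])
    svals <- vapply(0:7, function(mask) {
      mm <- maps[, , , ti]
      for (s in 1:3) {
        if (bitwAnd(mask, bitwShiftL(1L, s - 1L)) > 0) mm[s, , ] <- mm[s, 2:1, ]
      }
      tanova_statistic(mm)
    }, numeric(1))
    mean(svals >= obs - 1e-15)
  }, numeric(1))

  B <- 4000
  res <- tanova_permutation_test(ms, n_permutations = B, seed = 11)
  for (ti in 1:2) {
    mc_se <- sqrt(exact_p[ti] * (1 - exact_p[ti]) / B)
    expect_lt(abs(res$p[ti] - exact_p[ti]), 2 * mc_se + 2 / B)
  }
})

test_that("generic and two-condition permutation paths agree with enumeration conventions", {
  # p floor: observed statistic above every permuted one gives 1/(B+1)
  maps <- array(0, c(4, 2, 10, 1))
  sep <- c(rep(1, 5), rep(-1, 5))
  for (s in 1:4) {
    maps[s, 1, , 1] <- normalize_map(sep + 0.01 * s)
    maps[s, 2, , 1] <- normalize_map(-sep + 0.01 * s)
  }
  ms <- manual_map_set(maps)
  B <- 1000
  res <- tanova_permutation_test(ms, n_permutations = B, seed = 2)
  # only the no-swap and all-swap label assignments (prob 2/16) reproduce
  # s_obs; every other permutation partially cancels the difference maps
  p_true <- 2 / 16
  se <- sqrt(p_true * (1 - p_true) / B)
  expect_gte(res$p[1], 1 / (B + 1)) # add-one floor
  expect_lt(abs(res$p[1] - (1 + B * p_true) / (B + 1)), 3 * se + 1e-3)
  expect_error(tanova_permutation_test(ms, n_permutations = 0), "n_permutations")
})

test_that("three-condition path runs and is seed-reproducible", {
  set.seed(6)
  maps <- array(rnorm(4 * 3 * 10 * 2), c(4, 3, 10, 2))
  for (s in 1:4) for (cc in 1:3) maps[s, cc, , ] <- normalize_map(maps[s, cc, , ])
  ms <- manual_map_set(maps)
  r1 <- tanova_permutation_test(ms, n_permutations = 200, seed = 5)
  r2 <- tanova_permutation_test(ms, n_permutations = 200, seed = 5)
  expect_identical(r1$p, r2$p)
  expect_true(all(r1$p > 0 & r1$p <= 1))
  expect_true(all(r1$statistic >= 0))
})

test_that("doubling permutations moves p by less than 3 Monte-Carlo SEs", {
  set.seed(7)
  maps <- array(rnorm(8 * 2 * 15 * 1), c(8, 2, 15, 1))
  maps[, 1, , ] <- maps[, 1, , ] + 0.3
  for (s in 1:8) for (cc in 1:2) maps[s, cc, , ] <- normalize_map(maps[s, cc, , ])
  ms <- manual_map_set(maps)
  p1 <- tanova_permutation_test(ms, n_permutations = 2000, seed = 1)$p[1]
  p2 <- tanova_permutation_test(ms, n_permutations = 4000, seed = 99)$p[1]
  se <- sqrt(p1 * (1 - p1) / 2000)
  expect_lt(abs(p2 - p1), 3 * se + 1e-3)
})

test_that("electrode t-maps match the one-sample closed form and flag zero variance", {
  diffs <- matrix(0, 5, 3)
  colnames(diffs) <- c("E1", "E2", "E3")
  tm <- electrode_t_map(diffs)
  expect_true(all(tm$t == 0))

  set.seed(8)
  d2 <- matrix(rnorm(10 * 4, mean = -1), 10, 4)
  tm2 <- electrode_t_map(d2)
  for (j in 1:4) {
    expect_equal(
      tm2$t[j], mean(d2[, j]) * sqrt(10) / sd(d2[, j]),
      tolerance = 1e-12
    )
    tt <- t.test(d2[, j]) # textbook oracle
    expect_equal(tm2$p[j], tt$p.value, tolerance = 1e-12)
  }

  d3 <- cbind(rep(2, 6), rnorm(6))
  tm3 <- electrode_t_map(d3)
  expect_true(is.infinite(tm3$t[1]) && tm3$t[1] > 0)
  expect_true(tm3$zero_variance[1])
})
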