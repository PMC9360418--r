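mk_erp <- function(wf, times_ms, montage = tiny_montage(), cond = "DIG",
                   subject = "S01", timepoint = "T1", n_epochs = 30) {
  rownames(wf) <- montage$channels[seq_len(nrow(wf))]
  structure(
    list(
      waveform = wf, n_epochs = n_epochs, condition = cond, subject = subject,
      timepoint = timepoint, times_ms = times_ms, rate = 500, montage = montage
    ),
    class = "erp_average"
  )
}

test_that("averaging identical epochs returns the single epoch; zero epochs errors", {
  m <- tiny_montage()
  one <- matrix(rnorm(24 * 20), 24)
  a <- array(0, c(5, 24, 20))
  for (i in 1:5) a[i, , ] <- one
  es <- manual_epochs(list(DIG = a), times_ms = seq(0, 38, by = 2), montage = m)
  av <- average_condition(es)
  expect_equal(unname(av$DIG$waveform), one, tolerance = 1e-12)
  expect_equal(av$DIG$n_epochs, 5)

  es0 <- manual_epochs(list(FF = array(0, c(0, 24, 20))),
    times_ms = seq(0, 38, by = 2), montage = m
  )
  expect_error(average_condition(es0), "zero retained epochs")
})

test_that("averaging N iid-noise epochs shrinks the SD like 1/sqrt(N)", {
  set.seed(5)
  m <- tiny_montage()
  sds <- vapply(c(4, 64), function(n) {
    a <- array(rnorm(n * 24 * 200), c(n, 24, 200))
    es <- manual_epochs(list(DIG = a), times_ms = seq(0, 398, by = 2), montage = m)
    sd(average_condition(es)$DIG$waveform)
  }, numeric(1))
  expect_equal(sds[1], 1 / sqrt(4), tolerance = 0.05)
  expect_equal(sds[2], 1 / sqrt(64), tolerance = 0.05)
})

test_that("GFP closed forms and the spatial-SD oracle agree", {
  expect_equal(gfp(rep(3.7, 10)), 0)
  expect_equal(gfp(c(1, 1, -1, -1)), 1)
  set.seed(3)
  map <- rnorm(61)
  # independent oracle: population SD across channels
  oracle <- sqrt(mean((map - mean(map))^2))
  expect_lt(abs(gfp(map) - oracle), 1e-12)
  x <- matrix(rnorm(61 * 9), 61)
  oracle_m <- apply(x, 2, function(cl) sqrt(mean((cl - mean(cl))^2)))
  expect_equal(gfp(x), oracle_m, tolerance = 1e-12)
})

test_that("GFP is offset-invariant and absolutely homogeneous", {
  set.seed(9)
  x <- matrix(rnorm(30 * 7), 30)
  expect_equal(gfp(x + 5), gfp(x), tolerance = 1e-12)
  expect_equal(gfp(-2.5 * x), 2.5 * gfp(x), tolerance = 1e-12)
  expect_true(all(gfp(x) >= 0))
})

two_bump_trace <- function(t1 = 120, t2 = 228, shift = 0) {
  t_ms <- seq(-100, 612, by = 2)
  tibble::tibble(
    time_ms = t_ms,
    gfp = exp(-(t_ms - t1 - shift)^2 / 600) + 2 * exp(-(t_ms - t2 - shift)^2 / 900)
  )
}

test_that("second GFP local maximum at 228 ms yields the 198-258 ms window", {
  w <- find_n1_window(two_bump_trace())
  expect_equal(w$peak_ms, 228)
  expect_equal(w$start_ms, 198)
  expect_equal(w$end_ms, 258)
  expect_equal(w$end_ms - w$start_ms, 60)
  expect_equal(nrow(w$candidates), 2)
})

test_that("window selection fails informatively on monotone traces", {
  t_ms <- seq(-100, 612, by = 2)
  tr <- tibble::tibble(time_ms = t_ms, gfp = seq_along(t_ms) * 0.01)
  expect_error(find_n1_window(tr), "local maxima")
  expect_error(find_n1_window(tr), "manually")
})

test_that("three-bump trace picks the middle bump as second maximum", {
  t_ms <- seq(-100, 612, by = 2)
  tr <- tibble::tibble(
    time_ms = t_ms,
    gfp = exp(-(t_ms - 100)^2 / 300) + exp(-(t_ms - 200)^2 / 300) +
      exp(-(t_ms - 300)^2 / 300)
  )
  # brute-force local-maximum scan oracle
  g <- tr$gfp
  peaks <- which(diff(sign(diff(g))) == -2) + 1
  peaks <- peaks[t_ms[peaks] >= 80 & t_ms[peaks] <= 350]
  expect_equal(t_ms[peaks[2]], 200)
  expect_equal(find_n1_window(tr)$peak_ms, 200)
})

test_that("window selection is translation-equivariant", {
  w0 <- find_n1_window(two_bump_trace())
  w1 <- find_n1_window(two_bump_trace(shift = 40))
  expect_equal(w1$peak_ms - w0$peak_ms, 40)
  expect_equal(w1$start_ms - w0$start_ms, 40)
})

test_that("topography veto advances to the next candidate", {
  tr <- two_bump_trace()
  w <- find_n1_window(tr, which_max = 1, topo_check = function(peak) peak > 150)
  expect_equal(w$peak_ms, 228) # 120 ms candidate vetoed
})

test_that("cluster mean amplitude: constant field, mirror symmetry, brute-force oracle, linearity", {
  m <- tiny_montage()
  t_ms <- seq(-100, 612, by = 2)
  w <- find_n1_window(two_bump_trace())

  erp_c <- mk_erp(matrix(4.2, 24, length(t_ms)), t_ms, m)
  expect_equal(cluster_mean_amplitude(erp_c, w, m, "LOT"), 4.2)

  # mirror-symmetric field: equal LOT and ROT means
  sym <- matrix(0, 24, length(t_ms))
  rownames(sym) <- m$channels
  for (i in seq_len(9)) {
    v <- sin(t_ms / 50 + i)
    sym[m$clusters$LOT[i], ] <- v
    sym[m$clusters$ROT[i], ] <- v
  }
  erp_s <- mk_erp(sym, t_ms, m)
  expect_equal(
    cluster_mean_amplitude(erp_s, w, m, "LOT"),
    cluster_mean_amplitude(erp_s, w, m, "ROT"),
    tolerance = 1e-12
  )

  set.seed(7)
  wf <- matrix(rnorm(24 * length(t_ms)), 24)
  erp_r <- mk_erp(wf, t_ms, m)
  # flat double-loop oracle
  acc <- 0
  nacc <- 0
  for (ch in m$clusters$ROT) {
    for (j in seq_along(t_ms)) {
      if (t_ms[j] >= w$start_ms && t_ms[j] <= w$end_ms) {
        acc <- acc + wf[match(ch, m$channels), j]
        nacc <- nacc + 1
      }
    }
  }
  expect_equal(cluster_mean_amplitude(erp_r, w, m, "ROT"), acc / nacc,
    tolerance = 1e-12
  )

  erp_2 <- mk_erp(2 * wf + 1, t_ms, m)
  expect_equal(
    cluster_mean_amplitude(erp_2, w, m, "ROT"),
    2 * cluster_mean_amplitude(erp_r, w, m, "ROT") + 1,
    tolerance = 1e-12
  )

  expect_error(cluster_mean_amplitude(erp_r, w, m, "XYZ"), "cluster")
})

test_that("sensitivity differences are signed digits-minus-control", {
  amp <- tidyr::expand_grid(
    subject = c("S01", "S02"), timepoint = "T1",
    condition = c("DIG", "LET", "FF"), hemisphere = c("LOT", "ROT")
  )
  amp$n1_mean_amplitude <- ifelse(amp$condition == "DIG", -8,
    ifelse(amp$condition == "LET", -7, -6)
  )
  d <- sensitivity_differences(amp)
  expect_equal(nrow(d), 2 * 2 * 2)
  expect_true(all(d$difference_uv[d$contrast == "coarse"] == -2))
  expect_true(all(d$difference_uv[d$contrast == "fine"] == -1))

  amp0 <- dplyr::mutate(amp, n1_mean_amplitude = -5)
  d0 <- sensitivity_differences(amp0)
  expect_true(all(d0$difference_uv == 0))

  # missing condition rows are skipped, not fabricated
  amp_m <- dplyr::filter(amp, !(subject == "S02" & condition == "FF"))
  dm <- sensitivity_differences(amp_m)
  expect_equal(sum(dm$contrast == "coarse"), 2) # only S01
  expect_equal(sum(dm$contrast == "fine"), 4)
})
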