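test_that("injected topographies are zero-mean and unit over their clusters", {
  m <- tiny_montage()
  tr <- quiet_truth(m)
  expect_lt(abs(sum(tr$topography)), 1e-9)
  expect_lt(abs(sum(tr$p1$topography)), 1e-9)
  ch <- unlist(m$clusters)
  expect_equal(mean(tr$topography[ch]), 1, tolerance = 1e-12)
})

test_that("noiseless forward model reproduces amplitude x topography at the peak", {
  m <- tiny_montage()
  tr <- quiet_truth(m, p1_amplitude_uv = 0) # isolate the N1 component
  ev <- make_design(tiny_design(items = 6, targets = 0), seed = 2)
  rec <- simulate_subject(m, ev, tr, "T1", seed = 1, rate = 500)
  es <- epoch_recording(rec, ev, baseline = FALSE)
  av <- average_condition(es)
  lat <- tr$n1_latency_ms[["T1"]] # 228 ms, on the 500 Hz grid
  for (cond in names(av)) {
    peak_map <- av[[cond]]$waveform[, which(av[[cond]]$times_ms == lat)]
    expected <- tr$condition_amplitude_uv[cond, "T1"] * tr$topography
    expect_equal(peak_map, expected, tolerance = 1e-9)
  }
})

test_that("condition averages under default noise sit within 3 SEM of ground truth", {
  m <- tiny_montage()
  tr <- ground_truth(m, artifact_epoch_rate = 0, blink_rate = 0)
  ev <- make_design(design_spec(blocks_per_condition = 2, items_per_block = 27,
    targets_per_condition = 0
  ), seed = 3)
  rec <- simulate_subject(m, ev, tr, "T1", seed = 9, rate = 500)
  es <- epoch_recording(rec, ev, baseline = TRUE)
  av <- average_condition(es)
  w <- structure(
    list(start_ms = 198, end_ms = 258, peak_ms = 228),
    class = "n1_window"
  )
  for (cond in c("DIG", "FF")) {
    got <- cluster_mean_amplitude(av[[cond]], w, m, "LOT")
    # expected cluster-window mean of the injected component (kernel < 1 off-peak)
    tsel <- av[[cond]]$times_ms[av[[cond]]$times_ms >= 198 & av[[cond]]$times_ms <= 258]
    kern <- mean(n1sense:::gaussian_kernel(tsel, 228, tr$n1_width_ms))
    expected <- tr$condition_amplitude_uv[cond, "T1"] * kern
    # SEM of the cluster-window mean across 54 epochs, measured from the epochs
    a <- es$epochs[[cond]]
    rows <- match(m$clusters$LOT, m$channels)
    cols <- which(es$times_ms >= 198 & es$times_ms <= 258)
    per_epoch <- apply(a[, rows, cols, drop = FALSE], 1, mean)
    sem <- sd(per_epoch) / sqrt(length(per_epoch))
    expect_lt(abs(got - expected), 3 * sem + 0.05)
  }
})

test_that("artifact rate produces the expected share of threshold exceedances", {
  m <- tiny_montage()
  tr <- quiet_truth(m, artifact_epoch_rate = 0.2)
  ev <- make_design(design_spec(blocks_per_condition = 2, items_per_block = 25,
    targets_per_condition = 0
  ), seed = 5)
  hits <- 0L
  n <- 0L
  for (seed in 1:3) {
    rec <- simulate_subject(m, ev, tr, "T1", seed = seed, rate = 500)
    es <- epoch_recording(rec, ev, baseline = FALSE)
    for (cond in names(es$epochs)) {
      a <- es$epochs[[cond]]
      hits <- hits + sum(apply(abs(a) > 200, 1, any))
      n <- n + dim(a)[1]
    }
  }
  # binomial check: 450 epochs at rate 0.2
  expect_gt(hits / n, 0.2 - 3 * sqrt(0.2 * 0.8 / n))
  expect_lt(hits / n, 0.2 + 3 * sqrt(0.2 * 0.8 / n))
})

test_that("stronger injected digit amplitude strictly increases the recovered coarse difference", {
  m <- tiny_montage()
  ev <- make_design(tiny_design(items = 4, targets = 0), seed = 2)
  w <- structure(list(start_ms = 198, end_ms = 258, peak_ms = 228), class = "n1_window")
  diffs <- vapply(c(-7, -8, -10), function(dig) {
    amp <- default_condition_amplitudes()
    amp["DIG", ] <- dig
    tr <- quiet_truth(m, condition_amplitude_uv = amp, p1_amplitude_uv = 0)
    rec <- simulate_subject(m, ev, tr, "T1", seed = 1, rate = 500)
    av <- average_condition(epoch_recording(rec, ev, baseline = FALSE))
    cluster_mean_amplitude(av$DIG, w, m, "LOT") -
      cluster_mean_amplitude(av$FF, w, m, "LOT")
  }, numeric(1))
  expect_true(all(diff(abs(diffs)) > 0))
  expect_true(all(diffs < 0))
})

test_that("recordings are reproducible per seed", {
  m <- tiny_montage()
  tr <- ground_truth(m)
  ev <- make_design(tiny_design(items = 3, targets = 0), seed = 1)
  r1 <- simulate_subject(m, ev, tr, "T2", seed = 4, rate = 500)
  r2 <- simulate_subject(m, ev, tr, "T2", seed = 4, rate = 500)
  expect_identical(r1$signal, r2$signal)
})

test_that("visit patterns match the configured per-timepoint group sizes", {
  cs <- cohort_spec()
  vp <- draw_visit_pattern(cs, seed = 3)
  expect_equal(unname(colSums(vp)), unname(cs$group_size))
  expect_true(all(rowSums(vp) >= 1))
  expect_identical(vp, draw_visit_pattern(cs, seed = 3))
})

test_that("amplitude-level cohorts carry the injected effect structure", {
  cs <- cohort_spec()
  tr <- ground_truth(tiny_montage())
  tab <- simulate_amplitude_table(cs, tr, seed = 21)
  expect_equal(nrow(tab), sum(cs$group_size) * 3 * 2)
  means <- tab |>
    dplyr::group_by(condition) |>
    dplyr::summarise(m = mean(n1_mean_amplitude))
  expect_lt(means$m[means$condition == "DIG"], means$m[means$condition == "FF"])
})

test_that("zero rank coupling leaves behavior and neural measures unassociated", {
  cs <- cohort_spec(timepoints = "T4", group_size = 40, n_subjects = 40)
  tr <- ground_truth(tiny_montage(), timepoints = "T4",
    n1_latency_ms = c(T4 = 210),
    condition_amplitude_uv = default_condition_amplitudes("T4")
  )
  rhos <- vapply(1:200, function(i) {
    b <- simulate_cohort(cs, tr,
      behavior_truth(brain_behavior_rho = 0),
      seed = 1000 + i
    )
    d <- sensitivity_differences(b$amplitude_table)
    x <- d[d$contrast == "coarse" & d$hemisphere == "LOT", ]
    sc <- b$behavior_table[b$behavior_table$measure == "arithmetic_pr", ]
    j <- merge(x, sc, by = "subject")
    spearman(j$difference_uv, j$score)$rho
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 2 * sd(rhos) / sqrt(length(rhos)) + 0.02)
})

test_that("cohort bundles are byte-identical under a fixed seed", {
  cs <- cohort_spec(
    timepoints = c("T1", "T4"), group_size = c(6, 6), n_subjects = 8
  )
  tr <- ground_truth(tiny_montage(),
    timepoints = c("T1", "T4"),
    condition_amplitude_uv = default_condition_amplitudes(c("T1", "T4"))
  )
  b1 <- simulate_cohort(cs, tr, seed = 12)
  b2 <- simulate_cohort(cs, tr, seed = 12)
  expect_identical(b1$amplitude_table, b2$amplitude_table)
  expect_identical(b1$behavior_table, b2$behavior_table)
  expect_identical(b1$manifest, b2$manifest)
})
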