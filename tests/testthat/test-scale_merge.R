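# Joint scaling, merging and the merging-statistics block.

test_that("R statistics match hand-evaluated closed forms", {
  # one unique measured twice: I = {10, 12}, equal sigmas
  ds <- tiny_dataset(h = c(1, 1), k = c(2, 2), l = c(3, 3),
                     intensity = c(10, 12), batch = c(1, 2))
  st <- compute_stats(list(ds), n_shells = 2)
  expect_equal(st$overall$rmerge, 2 / 22, tolerance = 1e-12)
  expect_equal(st$overall$rmeas, sqrt(2) * 2 / 22, tolerance = 1e-12)
  expect_equal(st$overall$rpim, 2 / 22, tolerance = 1e-12)
  expect_equal(st$overall$multiplicity, 2)
  # 6 observations over 3 uniques -> multiplicity 2
  ds2 <- tiny_dataset(h = c(1, 1, 2, 2, 3, 3), k = c(0, 0, 1, 1, 0, 0),
                      l = c(2, 2, 1, 1, 3, 3),
                      intensity = c(5, 6, 9, 11, 20, 22),
                      batch = c(1, 2, 1, 2, 1, 2))
  st2 <- compute_stats(list(ds2), n_shells = 2)
  expect_equal(st2$overall$multiplicity, 2)
  # every unique measured exactly twice: Rmeas = sqrt(2) Rmerge, Rpim = Rmerge
  expect_equal(st2$overall$rmeas, sqrt(2) * st2$overall$rmerge,
               tolerance = 1e-12)
  expect_equal(st2$overall$rpim, st2$overall$rmerge, tolerance = 1e-12)
})

test_that("degenerate merges give exact zero/undefined statistics", {
  # identical observations per unique: all R stats 0, CC1/2 = 1
  ds <- tiny_dataset(h = rep(c(1, 2, 3, 4), each = 2),
                     k = rep(c(0, 1, 0, 2), each = 2),
                     l = rep(c(2, 1, 3, 1), each = 2),
                     intensity = rep(c(5, 9, 20, 33), each = 2),
                     batch = rep(1:2, 4))
  st <- compute_stats(list(ds), n_shells = 2)
  expect_equal(st$overall$rmerge, 0)
  expect_equal(st$overall$rmeas, 0)
  expect_equal(st$overall$rpim, 0)
  expect_equal(st$overall$cc_half, 1)
  # no unique measured twice: R stats and CC1/2 undefined (NA), not numbers
  single <- tiny_dataset(h = 1:4, k = c(0, 1, 0, 2), l = c(2, 1, 3, 1),
                         intensity = c(5, 9, 20, 33))
  st0 <- compute_stats(list(single), n_shells = 2)
  expect_true(is.na(st0$overall$rmerge))
  expect_true(is.na(st0$overall$rmeas))
  expect_true(is.na(st0$overall$rpim))
  expect_true(is.na(st0$overall$cc_half))
})

test_that("Rpim <= Rmerge <= Rmeas wherever defined", {
  camp <- simulate_campaign(small_config(61, alpha = 1, sigma0 = 2))
  st <- compute_stats(camp$datasets, fit_scales(camp$datasets))
  o <- st$overall
  expect_lte(o$rpim, o$rmerge)
  expect_lte(o$rmerge, o$rmeas)
  sh <- st$shells[!is.na(st$shells$rmeas), ]
  expect_true(all(sh$rpim <= sh$rmerge + 1e-12))
  expect_true(all(sh$rmerge <= sh$rmeas + 1e-12))
})

test_that("duplicating every observation halves Rpim's weight, not the mean", {
  camp <- simulate_campaign(small_config(67, datasets_per_group = 2))
  ds <- camp$datasets
  dup <- lapply(ds, function(d) {
    ob <- d$observations
    new_dataset(rbind(ob, ob), d$cell, d$space_group, label = d$label,
                crystal = d$crystal, id = d$id)
  })
  s1 <- compute_stats(ds, n_shells = 3)
  s2 <- compute_stats(dup, n_shells = 3)
  m1 <- merge_datasets(ds); m2 <- merge_datasets(dup)
  expect_equal(m2$intensity, m1$intensity, tolerance = 1e-12)
  expect_equal(s2$overall$multiplicity, 2 * s1$overall$multiplicity)
  expect_lt(s2$overall$rpim, s1$overall$rpim)
})

test_that("scaling recovers known (k, B) exactly on noise-free data", {
  cfg <- small_config(71, jitter_length = 0, sigma0 = 0, alpha = 0)
  camp <- simulate_campaign(cfg)
  m <- fit_scales(camp$datasets)
  kt <- camp$truth$k / camp$truth$k[1]
  Bt <- camp$truth$B - camp$truth$B[1]
  expect_lt(max(abs(m$k - kt)), 1e-6)
  expect_lt(max(abs(m$B - Bt)), 1e-6)
  # identical copies of one dataset: k = 1, B = 0 for all
  base <- camp$datasets[[1]]
  copies <- lapply(1:3, function(i) {
    new_dataset(base$observations, base$cell, base$space_group,
                label = paste0("copy", i), id = i)
  })
  mi <- fit_scales(copies)
  expect_equal(mi$k, rep(1, 3), tolerance = 1e-12)
  expect_equal(mi$B, rep(0, 3), tolerance = 1e-12)
  # single dataset: identity model
  expect_equal(fit_scales(list(base))$k, 1)
})

test_that("the scaling objective is non-increasing across iterations", {
  camp <- simulate_campaign(small_config(73, alpha = 0.5))
  m <- fit_scales(camp$datasets)
  tr <- m$residual_trace
  expect_gte(length(tr), 2)
  expect_true(all(diff(tr) <= 1e-8 * max(tr)))
})

test_that("(k, B) recovery holds across seeds at 5 percent relative noise", {
  # complete sweeps to 2.5 A; every intensity perturbed with sigma = 0.05 I
  worst_B <- 0
  for (seed in 1:20) {
    cfg <- sim_config(seed = seed, cell = c(30, 35, 40, 90, 90, 90),
                      space_group = "P2221", n_groups = 1,
                      datasets_per_group = 4, n_batches = 20,
                      coverage = 0.5, jitter_length = 0, jitter_angle = 0,
                      d_min = 2.5, sigma0 = 0, alpha = 0)
    camp <- simulate_campaign(cfg)
    set.seed(10000 + seed)
    noisy <- lapply(camp$datasets, function(ds) {
      ob <- ds$observations
      sig <- 0.05 * abs(ob$intensity)
      ob$intensity <- ob$intensity + rnorm(nrow(ob), 0, sig)
      ob$sigma <- pmax(sig, 1e-8)
      new_dataset(ob, ds$cell, ds$space_group, label = ds$label,
                  id = ds$id)
    })
    m <- fit_scales(noisy)
    Bt <- camp$truth$B - camp$truth$B[1]
    worst_B <- max(worst_B, max(abs(m$B - Bt)))
  }
  expect_lt(worst_B, 0.1)
})

test_that("disjoint or barely-overlapping datasets are rejected/flagged", {
  cl <- unit_cell(20, 25, 30)
  a <- tiny_dataset(h = 1:5, k = rep(1, 5), l = rep(2, 5),
                    intensity = rep(10, 5), cell = cl, label = "a", id = 1)
  b <- tiny_dataset(h = 1:5, k = rep(3, 5), l = rep(4, 5),
                    intensity = rep(10, 5), cell = cl, label = "b", id = 2)
  expect_error(fit_scales(list(a, b)), "disjoint")
  shared <- tiny_dataset(h = c(1:5, 1), k = c(rep(3, 5), 1), l = c(rep(4, 5), 2),
                         intensity = rep(10, 6), cell = cl, label = "c",
                         id = 3)
  expect_warning(fit_scales(list(a, shared)), "fewer than 10")
})

test_that("merging equals a brute-force accumulation oracle", {
  camp <- simulate_campaign(small_config(79))
  model <- fit_scales(camp$datasets)
  merged <- merge_datasets(camp$datasets, model)
  # independent accumulation pass over raw observations
  acc <- new.env()
  for (j in seq_along(camp$datasets)) {
    ds <- camp$datasets[[j]]
    ob <- ds$observations
    d <- resolution_of(ds$cell, ob$h, ob$k, ob$l)
    asu <- map_to_asu(ob$h, ob$k, ob$l, ds$space_group)
    g <- model$k[j] * exp(-2 * model$B[j] / (4 * d^2))
    for (i in seq_len(nrow(ob))) {
      key <- paste(asu$h[i], asu$k[i], asu$l[i])
      w <- (g[i] / ob$sigma[i])^2
      prev <- if (!is.null(acc[[key]])) acc[[key]] else c(0, 0, 0)
      acc[[key]] <- prev + c(w * ob$intensity[i] / g[i], w, 1)
    }
  }
  for (i in seq_len(nrow(merged))) {
    key <- paste(merged$h[i], merged$k[i], merged$l[i])
    v <- acc[[key]]
    expect_equal(merged$intensity[i], v[1] / v[2], tolerance = 1e-12)
    expect_equal(merged$sigma[i], sqrt(1 / v[2]), tolerance = 1e-12)
    expect_equal(merged$nobs[i], as.integer(v[3]))
  }
  # every accumulated unique is present
  expect_equal(nrow(merged), length(ls(acc)))
})

test_that("noise-free merging recovers the ground truth intensities", {
  cfg <- small_config(83, jitter_length = 0, sigma0 = 0, alpha = 0,
                      scale_range = c(1, 1), b_range = c(0, 0))
  camp <- simulate_campaign(cfg)
  merged <- merge_datasets(camp$datasets, fit_scales(camp$datasets))
  tr <- camp$truth$reflections
  idx <- match(paste(merged$h, merged$k, merged$l),
               paste(tr$h, tr$k, tr$l))
  expect_true(all(!is.na(idx)))
  expect_lt(max(abs(merged$intensity / tr$intensity[idx] - 1)), 1e-10)
})

test_that("resolution shells partition the data evenly", {
  expect_error(shell_binning(c(10, 5, 3), 1), ">= 2")
  camp <- simulate_campaign(small_config(89, coverage = 0.5))
  merged <- merge_datasets(camp$datasets)
  b <- shell_binning(merged, 6)
  expect_length(b, 7)
  expect_true(all(diff(b) < 0))                 # strictly decreasing in d
  idx <- mxmerge:::.shell_index(merged$d, b)
  expect_equal(sort(unique(idx)), 1:6)
  expect_equal(length(idx), nrow(merged))       # every unique in one shell
  counts <- tabulate(idx, 6)
  expect_lte(max(counts) / min(counts), 2)      # dense set: roughly equal
})

test_that("Rmeas grows monotonically with planted noise", {
  rmeas_at <- function(alpha) {
    mean(vapply(1:5, function(seed) {
      camp <- simulate_campaign(small_config(900 + seed, alpha = alpha,
                                             sigma0 = 1))
      compute_stats(camp$datasets, fit_scales(camp$datasets),
                    n_shells = 3)$overall$rmeas
    }, numeric(1)))
  }
  ladder <- vapply(c(0.1, 1, 5), rmeas_at, numeric(1))
  expect_true(all(diff(ladder) > 0))
})

test_that("statistics resolution estimates respect the applied cutoff", {
  camp <- simulate_campaign(small_config(97, sigma0 = 0.1, alpha = 0.01))
  st <- compute_stats(camp$datasets, fit_scales(camp$datasets, 6.5),
                      resolution_max = 6.5)
  o <- st$overall
  expect_gte(o$resolution_cc, 6.5)
  expect_gte(o$resolution_isd, 6.5)
  expect_equal(o$resolution_max, 6.5)
  # strong, clean data everywhere: both estimates sit at the cutoff
  expect_equal(o$resolution_cc, 6.5)
  expect_equal(o$resolution_isd, 6.5)
  expect_true(o$completeness >= 0 && o$completeness <= 100)
  expect_gte(o$multiplicity, 1)
  expect_true(abs(o$cc_half) <= 1)
})
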