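test_that("classify_movement uses max-velocity semantics per bin", {
  # 1 Hz displacement samples, 10 s bins, threshold 1 px/s
  mk <- function(disp) {
    behav_table(
      tibble::tibble(id = "a", t = seq_along(disp) - 1, displacement = disp),
      tibble::tibble(id = "a")
    )
  }
  still <- classify_movement(mk(rep(0, 30)), sleep_params())
  expect_equal(still$moving, rep(0L, 3))

  spike <- rep(0, 30); spike[15] <- 5   # one fast frame in bin 2
  ms <- classify_movement(mk(spike), sleep_params())
  expect_equal(ms$moving, c(0L, 1L, 0L))

  inf_thr <- classify_movement(mk(runif(30) * 100),
                               sleep_params(velocity_threshold = Inf))
  expect_true(all(inf_thr$moving == 0))

  expect_error(classify_movement(mk(rep(0, 10)), variable = "nope"), "nope")
})

test_that("unobserved grid bins are missing, not still", {
  bt <- behav_table(
    tibble::tibble(id = "a", t = c(1, 2, 41, 42), displacement = 0),
    tibble::tibble(id = "a")
  )
  ms <- classify_movement(bt, sleep_params())
  expect_equal(ms$t, c(0, 10, 20, 30, 40))
  expect_equal(is.na(ms$moving), c(FALSE, TRUE, TRUE, TRUE, FALSE))
})

test_that("the five-minute rule is inclusive at exactly 300 s", {
  p <- sleep_params()   # 10 s bins, 300 s minimum
  run <- function(n_inactive) {
    ms <- make_series(c(1, rep(0, n_inactive), 1))
    sleep_annotation(ms, p)$asleep
  }
  expect_equal(sum(run(30)), 30)   # 300 s: asleep, boundary inclusive
  expect_equal(sum(run(29)), 0)    # 290 s: not sleep
  expect_equal(sum(sleep_annotation(make_series(rep(1, 100)), p)$asleep), 0)
})

test_that("missing bins break inactivity runs", {
  p <- sleep_params()
  m <- c(rep(0, 20), NA, rep(0, 20))   # two 200 s runs separated by a gap
  ann <- sleep_annotation(make_series(m), p)
  expect_equal(sum(ann$asleep, na.rm = TRUE), 0)
  expect_true(is.na(ann$asleep[21]))

  # without the gap the merged run passes threshold
  ann2 <- sleep_annotation(make_series(rep(0, 41)), p)
  expect_equal(sum(ann2$asleep), 41)
})

test_that("sleep annotation invariants hold on random series", {
  p <- sleep_params()
  set.seed(11)
  for (rep in 1:20) {
    m <- rbinom(200, 1, 0.4)
    ann <- sleep_annotation(make_series(m), p)
    # never asleep while moving
    expect_true(all(ann$moving[ann$asleep == 1] == 0))
    # idempotent: re-annotating the asleep series as movement of 0/1
    ann2 <- sleep_annotation(ann[c("id", "t", "moving")], p)
    expect_equal(ann2$asleep, ann$asleep)
    # lowering the threshold never decreases total sleep
    lo <- sleep_annotation(make_series(m), sleep_params(min_sleep_s = 100))
    expect_gte(sum(lo$asleep), sum(ann$asleep))
  }
})

test_that("bout encoding is a lossless run-length encoding", {
  b <- bout_analysis(make_series(c(0, 0, 1, 1, 1, 0)), "moving", bin_s = 10)
  expect_equal(b$state, c("0", "1", "0"))
  expect_equal(b$onset_t, c(0, 20, 50))
  expect_equal(b$duration_s, c(20, 30, 10))

  single <- bout_analysis(make_series(1), "moving", bin_s = 10)
  expect_equal(single$duration_s, 10)

  set.seed(3)
  for (rep in 1:10) {
    m <- rbinom(150, 1, 0.5)
    ms <- make_series(m)
    bouts <- bout_analysis(ms, "moving", bin_s = 10)
    # durations tile the covered span exactly
    expect_equal(sum(bouts$duration_s), 1500)
    back <- bouts_to_series(bouts, bin_s = 10)
    expect_equal(as.integer(back$state), m)
    expect_equal(back$t, ms$t)
  }
})

test_that("sleep_profile means and bootstrap intervals behave", {
  p <- sleep_params(bin_s = 600, min_sleep_s = 600)
  mk_ann <- function(ids, asleep_val) {
    tidyr::expand_grid(id = ids, t = seq(0, 1800 - 1, by = 600)) |>
      dplyr::mutate(moving = 0L, asleep = asleep_val[id])
  }
  # every specimen fully asleep: mean 1, degenerate interval
  ann <- mk_ann(c("a", "b"), c(a = 1L, b = 1L))
  prof <- sleep_profile(ann, profile_bin_s = 1800, n_boot = 200, seed = 1)
  expect_true(all(prof$mean_fraction_asleep == 1))
  expect_true(all(prof$ci_low == 1 & prof$ci_high == 1))

  # single specimen: CI collapses to the point estimate
  one <- sleep_profile(mk_ann("a", c(a = 1L)), profile_bin_s = 1800,
                       n_boot = 200, seed = 1)
  expect_equal(one$ci_low, one$mean_fraction_asleep)

  # two specimens at 0 and 1: mean 0.5, bootstrap endpoints in {0, .5, 1}
  two <- sleep_profile(mk_ann(c("a", "b"), c(a = 0L, b = 1L)),
                       profile_bin_s = 1800, n_boot = 500, seed = 1)
  expect_equal(unique(two$mean_fraction_asleep), 0.5)
  expect_true(all(two$ci_low %in% c(0, 0.5, 1)))
  expect_true(all(two$ci_high %in% c(0, 0.5, 1)))
})

test_that("heatmap matrix matches the population profile column-wise", {
  sim <- small_sim()
  m <- heatmap_matrix(sim$bt, "moving", bin_s = 1800)
  expect_equal(dim(m), c(3, 48))
  expect_equal(rownames(m), sim$bt$meta$id)

  # column means equal the pooled per-bin mean across specimens
  binned <- bin_time(sim$bt, "moving", 1800, "mean")
  pooled <- tapply(binned$value, binned$t_bin, mean)
  expect_equal(unname(colMeans(m)), unname(as.numeric(pooled)))

  const <- sim
  const$bt$data$moving <- 1L
  mc <- heatmap_matrix(const$bt, "moving", bin_s = 1800)
  expect_true(all(mc == 1))
})

test_that("rebound quantification compares matched clock windows", {
  p <- sleep_params(bin_s = 60, min_sleep_s = 300)
  day <- 86400
  # 12 h baseline window then the matched 12 h window next morning; fly r
  # sleeps 60 min extra in the rebound window, fly s is unchanged
  mk_fly <- function(id, extra_min) {
    awake_bins <- 720 - extra_min
    m <- c(rep(c(0, 1), 360),                       # baseline: 0 sleep
           rep(0, extra_min), rep(1, awake_bins))   # rebound half-day
    make_series(m, bin_s = 60, id = id)
  }
  ann <- dplyr::bind_rows(
    sleep_annotation(mk_fly("r", 60), p),
    sleep_annotation(mk_fly("s", 0), p)
  )
  res <- rebound_quantification(ann, c(0, 43200), c(43200, 86400),
                                bin_s = 60, n_boot = 100, seed = 1)
  expect_equal(res$per_specimen$delta_min[res$per_specimen$id == "r"], 60)
  expect_equal(res$per_specimen$delta_min[res$per_specimen$id == "s"], 0)

  # identical windows: delta exactly 0
  same <- rebound_quantification(ann, c(0, 43200), c(0, 43200),
                                 bin_s = 60, n_boot = 50, seed = 1)
  expect_true(all(same$per_specimen$delta_min == 0))

  # missing data in one window: excluded and reported
  short <- sleep_annotation(make_series(rep(0, 100), bin_s = 60, id = "q"), p)
  res2 <- rebound_quantification(dplyr::bind_rows(ann, short),
                                 c(0, 43200), c(43200, 86400),
                                 bin_s = 60, n_boot = 50, seed = 1)
  expect_true("q" %in% res2$excluded)
  expect_false("q" %in% res2$per_specimen$id)

  expect_error(rebound_quantification(ann, c(0, 100), c(0, 200)),
               "same clock length")
})

test_that("deprived cohorts show positive mean rebound", {
  day <- 86400
  cfg <- sim_config(
    genotypes = tibble::tibble(name = "CantonS", period_h = 24,
                               n_flies = 8),
    days = 2, bin_s = 60, seed = 14,
    deprivation_windows = list(c(0.5 * day, 1 * day)),
    rebound_boost = 0.6
  )
  sim <- simulate_population(cfg)
  p <- sleep_params(bin_s = 60)
  ann <- sleep_annotation(sim$bt$data[, c("id", "t", "moving")], p)
  # deprivation 12-24 h; compare the first post-deprivation morning with
  # the matched baseline morning
  res <- rebound_quantification(ann, c(0, 0.5 * day),
                                c(day, 1.5 * day),
                                bin_s = 60, n_boot = 200, seed = 2)
  expect_gt(res$summary$mean_delta_min, 0)
  expect_gt(res$summary$ci_low, 0)
})
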