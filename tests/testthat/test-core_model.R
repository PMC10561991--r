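test_that("link_metadata enforces referential integrity", {
  data <- tibble::tibble(id = c("a", "b"), t = c(0, 0), x = 1:2)
  meta <- tibble::tibble(id = c("a", "b", "c"))

  bt <- link_metadata(data, meta)
  expect_s3_class(bt, "behav_table")
  expect_equal(nrow(bt$meta), 3)   # superset metadata allowed
  expect_equal(nrow(bt$data), 2)

  expect_error(link_metadata(tibble::tibble(id = "a", t = 0, x = 1),
                             tibble::tibble(id = "b")),
               "a")
  expect_error(link_metadata(data, tibble::tibble(id = c("a", "a", "b"))),
               "duplicate")
  expect_error(link_metadata(tibble::tibble(id = "a", x = 1), meta),
               "t")

  empty <- link_metadata(tibble::tibble(id = character(), t = numeric(),
                                        x = numeric()), meta)
  expect_equal(nrow(empty$data), 0)
  expect_equal(nrow(empty$meta), 3)
})

test_that("filter_by_meta restricts meta and data coherently", {
  bt <- make_bt()
  cs <- filter_by_meta(bt, genotype == "CantonS")
  expect_setequal(cs$meta$id, c("a", "b"))
  expect_setequal(unique(cs$data$id), c("a", "b"))

  none <- filter_by_meta(bt, genotype == "nonesuch")
  expect_equal(nrow(none$meta), 0)
  expect_equal(nrow(none$data), 0)

  all_rows <- filter_by_meta(bt, genotype == genotype)
  expect_equal(all_rows$data, bt$data)
  expect_equal(all_rows$meta, bt$meta)

  expect_error(filter_by_meta(bt, no_such_column == 1), "predicate")
})

test_that("time_window keeps the half-open interval [t_min, t_max)", {
  bt <- make_bt()
  w <- time_window(bt, 0, 120)
  expect_setequal(unique(w$data$t), c(0, 60))   # 120 excluded
  expect_equal(nrow(w$meta), nrow(bt$meta))     # meta untouched

  expect_equal(time_window(bt, -1, 1e6)$data, bt$data)
  expect_equal(nrow(time_window(bt, 5000, 6000)$data), 0)
  expect_error(time_window(bt, 10, 10), "t_min")
})

test_that("bin_time labels bins by left edge and aggregates correctly", {
  bt <- behav_table(
    tibble::tibble(id = "a", t = c(5, 15), v = c(1, 3)),
    tibble::tibble(id = "a")
  )
  out <- bin_time(bt, "v", 10, "mean")
  expect_equal(out$t_bin, c(0, 10))
  expect_equal(out$value, c(1, 3))

  bt2 <- behav_table(
    tibble::tibble(id = "a", t = c(2, 8), v = c(1, 3)),
    tibble::tibble(id = "a")
  )
  out2 <- bin_time(bt2, "v", 10, "max")
  expect_equal(out2$t_bin, 0)
  expect_equal(out2$value, 3)

  expect_error(bin_time(make_bt(), "x", 0), "bin_size")
  bt3 <- make_bt()
  bt3$data$label <- "text"
  expect_error(bin_time(bt3, "label", 10), "not numeric")
})

test_that("bin_time with sum conserves the column total", {
  set.seed(7)
  data <- tibble::tibble(
    id = sample(c("a", "b"), 200, replace = TRUE),
    t = runif(200, 0, 5000),
    v = rnorm(200)
  )
  bt <- behav_table(data, tibble::tibble(id = c("a", "b")))
  for (bin in c(10, 37, 600)) {
    out <- bin_time(bt, "v", bin, "sum")
    totals <- tapply(data$v, data$id, sum)
    binned_totals <- tapply(out$value, out$id, sum)
    expect_equal(as.numeric(binned_totals[names(totals)]),
                 as.numeric(totals))
  }
})

test_that("to_zeitgeber wraps to [0, 24) hours", {
  ref <- 3600 * 8
  bt <- behav_table(
    tibble::tibble(id = "a",
                   t = ref + c(0, 15 * 3600, 25 * 3600, -3600),
                   v = 0),
    tibble::tibble(id = "a")
  )
  out <- to_zeitgeber(bt, lights_on_reference = ref)$data
  zt_by_t <- out$zt[match(ref + c(0, 15 * 3600, 25 * 3600, -3600), out$t)]
  expect_equal(zt_by_t, c(0, 15, 1, 23))
  expect_true(all(out$zt >= 0 & out$zt < 24))
})

test_that("filter_by_meta and time_window commute", {
  bt <- make_bt()
  a <- time_window(filter_by_meta(bt, genotype == "CantonS"), 0, 130)
  b <- filter_by_meta(time_window(bt, 0, 130), genotype == "CantonS")
  expect_equal(a$data, b$data)
  expect_equal(a$meta, b$meta)
})

test_that("curate_dead drops trailing immobility runs", {
  hours <- function(h) h * 3600
  mk <- function(moving) {
    behav_table(
      tibble::tibble(id = "a", t = seq_along(moving) * 600 - 600,
                     moving = moving),
      tibble::tibble(id = "a")
    )
  }
  # 10 h active then 30 h immobile at 10-min bins
  bt <- mk(c(rep(1, 60), rep(0, 180)))
  cur <- curate_dead(bt, "moving", immobility_span = hours(24))
  expect_equal(nrow(cur$data), 60)

  # only 2 h trailing immobility: untouched
  bt2 <- mk(c(rep(1, 60), rep(0, 12)))
  expect_equal(nrow(curate_dead(bt2, "moving", hours(24))$data), 72)

  # immobile for the whole recording: all rows dropped, id kept in meta
  bt3 <- mk(rep(0, 180))
  cur3 <- curate_dead(bt3, "moving", hours(24))
  expect_equal(nrow(cur3$data), 0)
  expect_equal(cur3$meta$id, "a")

  bt4 <- mk(rep(1, 10))
  bt4$data$moving <- 0.5
  expect_error(curate_dead(bt4, "moving"), "binary")
})

test_that("behav_table round-trips through the CSV store", {
  bt <- make_bt()
  dir <- withr::local_tempdir()
  write_behav_csv(bt, dir)
  back <- read_behav_csv(dir)
  expect_equal(back$data, bt$data)
  expect_equal(back$meta, bt$meta)
})

test_that("tidy and glance summarise a behav_table", {
  bt <- make_bt()
  td <- tidy(bt)
  expect_true("genotype" %in% names(td))
  expect_equal(nrow(td), nrow(bt$data))
  g <- glance(bt)
  expect_equal(g$n_specimens_meta, 4)
  expect_equal(g$n_specimens_data, 3)
})
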