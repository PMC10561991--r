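# independent fold-and-score oracle: plain loops, no shared code with the
# package implementation
oracle_chi_sq <- function(x, p_bins) {
  sapply(p_bins, function(P) {
    K <- length(x) %/% P
    xs <- x[1:(K * P)]
    M_h <- numeric(P)
    for (h in 1:P) {
      vals <- c()
      for (k in 0:(K - 1)) vals <- c(vals, xs[k * P + h])
      M_h[h] <- mean(vals)
    }
    M_bar <- mean(xs)
    K * sum((M_h - M_bar)^2) / (sum((xs - M_bar)^2) / (K * P))
  })
}

test_that("chi-squared periodogram matches the naive fold oracle", {
  set.seed(21)
  bin_s <- 1800
  for (rep in 1:5) {
    n <- sample(300:500, 1)
    x <- rnorm(n) + sin(2 * pi * seq_len(n) / 48)
    pg <- chi_squared_periodogram(
      tibble::tibble(id = "a", t = (seq_len(n) - 1) * bin_s, value = x),
      period_range_h = c(16, 32), bin_s = bin_s
    )
    p_bins <- pg$period_h * 3600 / bin_s
    expect_equal(pg$Q, oracle_chi_sq(x, p_bins), tolerance = 1e-9)
  }
})

test_that("deterministic square waves peak at their true period", {
  bin_s <- 1800
  mk_square <- function(period_h, days) {
    n <- days * 48
    phase <- ((seq_len(n) - 1) * 0.5) %% period_h
    tibble::tibble(id = "a", t = (seq_len(n) - 1) * bin_s,
                   value = as.numeric(phase < period_h / 2))
  }
  for (period in c(19, 24, 29)) {
    pg <- chi_squared_periodogram(mk_square(period, 8), c(16, 32), bin_s)
    expect_equal(pg$period_h[which.max(pg$Q)], period)
  }
})

test_that("Q is invariant under affine transforms of the series", {
  set.seed(4)
  x <- rnorm(400)
  bin_s <- 1800
  mk <- function(v) tibble::tibble(id = "a", t = (seq_along(v) - 1) * bin_s,
                                   value = v)
  q0 <- chi_squared_periodogram(mk(x), c(16, 32), bin_s)$Q
  q1 <- chi_squared_periodogram(mk(3.7 * x - 11), c(16, 32), bin_s)$Q
  expect_equal(q0, q1, tolerance = 1e-9)
})

test_that("periodogram input contracts are enforced", {
  bin_s <- 1800
  const <- tibble::tibble(id = "a", t = (0:399) * bin_s, value = 1)
  expect_error(chi_squared_periodogram(const, c(16, 32), bin_s),
               "constant series")
  short <- tibble::tibble(id = "a", t = (0:50) * bin_s, value = rnorm(51))
  expect_error(chi_squared_periodogram(short, c(16, 32), bin_s),
               "shorter than twice")
})

test_that("significance thresholds follow the chi-squared null", {
  pg <- structure(
    tibble::tibble(id = "a", period_h = 24, Q = 1, df = 1,
                   threshold = NA_real_),
    class = c("behav_periodogram", class(tibble::tibble()))
  )
  out <- periodogram_significance(pg, alpha = 0.05, correction = "none")
  expect_equal(out$threshold, 3.841, tolerance = 1e-3)

  set.seed(2)
  x <- rnorm(400)
  full <- chi_squared_periodogram(
    tibble::tibble(id = "a", t = (0:399) * 1800, value = x), c(16, 32), 1800
  )
  none <- periodogram_significance(full, 0.01, "none")
  bonf <- periodogram_significance(full, 0.01, "bonferroni")
  m <- dplyr::n_distinct(full$period_h)
  expect_equal(bonf$threshold,
               stats::qchisq(1 - 0.01 / m, none$df), tolerance = 1e-12)
  # thresholds increase with df at fixed alpha
  expect_true(all(diff(none$threshold[order(none$df)]) > 0))
  expect_error(periodogram_significance(full, alpha = 1.5), "alpha")
})

test_that("peak detection respects threshold, ordering and ties", {
  mk_pg <- function(Q, thr = 0) {
    structure(
      tibble::tibble(id = "a", period_h = seq(16, by = 0.5,
                                              length.out = length(Q)),
                     Q = Q, df = 2, threshold = thr),
      class = c("behav_periodogram", class(tibble::tibble()))
    )
  }
  # monotone: at most one endpoint peak
  mono <- peak_periods(mk_pg(1:10))
  expect_equal(nrow(mono), 1)
  expect_equal(mono$period_h, 20.5)

  # everything below threshold: empty
  expect_equal(nrow(peak_periods(mk_pg(1:10, thr = 100))), 0)

  # two equal peaks: sorted output breaks the tie toward the shorter period
  q <- c(1, 5, 1, 5, 1)
  pk <- peak_periods(mk_pg(q))
  expect_equal(pk$period_h[1], 16.5)
})

test_that("population periodogram averages pointwise", {
  set.seed(5)
  mk <- function(id, v) tibble::tibble(id = id, t = (seq_along(v) - 1) * 1800,
                                       value = v)
  x1 <- rnorm(400); x2 <- rnorm(400)
  pg <- chi_squared_periodogram(dplyr::bind_rows(mk("a", x1), mk("b", x2)),
                                c(16, 32), 1800)
  pop <- population_periodogram(pg)
  per_a <- pg$Q[pg$id == "a"]; per_b <- pg$Q[pg$id == "b"]
  expect_equal(pop$Q, (per_a + per_b) / 2)

  solo <- population_periodogram(chi_squared_periodogram(mk("a", x1),
                                                         c(16, 32), 1800))
  expect_equal(solo$Q, per_a)

  twin <- chi_squared_periodogram(dplyr::bind_rows(mk("a", x1), mk("b", x1)),
                                  c(16, 32), 1800)
  expect_equal(population_periodogram(twin)$Q, per_a)
})

test_that("actogram matrices double-plot with the overlap invariant", {
  set.seed(6)
  n <- 2 * 48
  b <- tibble::tibble(id = "a", t = (seq_len(n) - 1) * 1800,
                      value = runif(n))
  m <- actogram_matrix(b)
  expect_equal(dim(m), c(2, 96))
  expect_true(all(is.na(m[2, 49:96])))           # last row right half
  expect_equal(m[1, 49:96], m[2, 1:48])          # overlap invariant

  n3 <- 3 * 48
  b3 <- tibble::tibble(id = "a", t = (seq_len(n3) - 1) * 1800,
                       value = runif(n3))
  m3 <- actogram_matrix(b3)
  for (r in 1:2) expect_equal(m3[r, 49:96], m3[r + 1, 1:48])

  const <- actogram_matrix(dplyr::mutate(b, value = 2), double = FALSE)
  expect_true(all(const == 2))
})
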