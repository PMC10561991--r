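test_that("the default template satisfies its structural contract", {
  spec <- default_hmm_spec()
  expect_equal(length(spec$labels), 4)
  expect_equal(rowSums(spec$transition), rep(1, 4), ignore_attr = TRUE)
  expect_equal(rowSums(spec$emission), rep(1, 4), ignore_attr = TRUE)

  A <- spec$transition
  expect_identical(A["deep_sleep", "quiet_awake"], 0)
  expect_identical(A["deep_sleep", "active_awake"], 0)
  expect_identical(A["active_awake", "deep_sleep"], 0)
  expect_equal(unname(spec$emission["deep_sleep", ]), c(1, 0))
  expect_equal(unname(spec$emission["light_sleep", ]), c(1, 0))

  expect_error(hmm_spec(spec$labels, A * 2, spec$emission, spec$initial),
               "sum to 1")
})

test_that("training preserves structural zeros and EM monotonicity", {
  cfg <- sim_config(
    genotypes = tibble::tibble(name = "g", period_h = 24, n_flies = 3),
    days = 1, bin_s = 60, seed = 8
  )
  sim <- simulate_population(cfg)
  ms <- sim$bt$data[, c("id", "t", "moving")]
  fit <- train_hmm(ms, n_restarts = 2, seed = 3, max_iter = 200)

  spec <- default_hmm_spec()
  expect_true(all(fit$transition[!spec$allowed_transition] == 0))
  expect_true(all(fit$emission[!spec$allowed_emission] == 0))
  for (trace in fit$loglik_trace) {
    expect_true(all(diff(trace) > -1e-8))
  }
  # deterministic for a fixed seed
  fit2 <- train_hmm(ms, n_restarts = 2, seed = 3, max_iter = 200)
  expect_equal(fit2$transition, fit$transition)
  expect_equal(fit2$restart_logliks, fit$restart_logliks)

  expect_error(train_hmm(ms[0, ]), "no observations")
  const <- make_series(rep(0, 500), bin_s = 60)
  expect_warning(train_hmm(const, n_restarts = 1, seed = 1, max_iter = 20),
                 "constant")
})

test_that("decoding respects degenerate dynamics and impossibility", {
  labels <- c("deep_sleep", "light_sleep", "quiet_awake", "active_awake")
  frozen <- hmm_spec(labels, diag(4), matrix(c(1, 1, 1, 0, 0, 0, 0, 1), 4, 2),
                     c(1, 0, 0, 0),
                     allowed_transition = diag(4) > 0,
                     allowed_emission = matrix(c(TRUE, TRUE, TRUE, FALSE,
                                                 FALSE, FALSE, FALSE, TRUE),
                                               4, 2))
  ms <- make_series(rep(0, 50), bin_s = 60)
  dec <- decode_states(frozen, ms, bin_s = 60)
  expect_true(all(dec$state == "deep_sleep"))

  # a state whose emission of movement is structurally zero can never be
  # decoded on a moving bin
  cfg <- sim_config(
    genotypes = tibble::tibble(name = "g", period_h = 24, n_flies = 2),
    days = 1, bin_s = 60, seed = 9
  )
  sim <- simulate_population(cfg)
  ms2 <- sim$bt$data[, c("id", "t", "moving")]
  fit <- train_hmm(ms2, n_restarts = 1, seed = 2, max_iter = 100)
  dec2 <- decode_states(fit, ms2, posterior = TRUE)
  joined <- dplyr::left_join(dec2, dplyr::rename(ms2, t_bin = t),
                             by = c("id", "t_bin"))
  expect_true(all(!joined$state[joined$moving == 1] %in%
                    c("deep_sleep", "light_sleep")))
  post <- as.matrix(joined[paste0("p_", fit$labels)])
  expect_true(all(abs(rowSums(post) - 1) < 1e-9))

  bad <- make_series(c(0, 1, 2), bin_s = 60)
  expect_error(decode_states(fit, bad, bin_s = 60), "binary")
})

test_that("Viterbi equals exhaustive search on short sequences", {
  set.seed(31)
  enumerate_best <- function(obs, A, B, pi0) {
    L <- length(obs)
    paths <- as.matrix(expand.grid(rep(list(1:4), L)))
    logp <- log(pi0[paths[, 1]]) + log(B[cbind(paths[, 1], obs[1] + 1)])
    if (L > 1) {
      for (t in 2:L) {
        logp <- logp + log(A[cbind(paths[, t - 1], paths[, t])]) +
          log(B[cbind(paths[, t], obs[t] + 1)])
      }
    }
    max(logp)
  }
  spec <- default_hmm_spec()
  for (rep in 1:8) {
    # random mask-respecting parameters
    rrow <- function(mask) {
      p <- numeric(length(mask)); g <- rgamma(sum(mask), 1)
      p[mask] <- g / sum(g); p
    }
    A <- t(apply(spec$allowed_transition, 1, rrow))
    B <- t(apply(spec$allowed_emission, 1, rrow))
    pi0 <- rrow(rep(TRUE, 4))
    obs <- rbinom(8, 1, 0.5)
    path <- behavkit:::cpp_viterbi(as.integer(obs), log(A), log(B),
                                   log(pi0)) + 1
    lp_viterbi <- log(pi0[path[1]]) + log(B[path[1], obs[1] + 1]) +
      sum(log(A[cbind(path[-8], path[-1])])) +
      sum(log(B[cbind(path[-1], obs[-1] + 1)]))
    expect_equal(lp_viterbi, enumerate_best(obs, A, B, pi0),
                 tolerance = 1e-10)
  }
})

test_that("state occupancy fractions sum to one per zeitgeber bin", {
  cfg <- sim_config(
    genotypes = tibble::tibble(name = "g", period_h = 24, n_flies = 3),
    days = 1, bin_s = 60, seed = 12
  )
  sim <- simulate_population(cfg)
  ms <- sim$bt$data[, c("id", "t", "moving")]
  fit <- train_hmm(ms, n_restarts = 1, seed = 2, max_iter = 100)
  dec <- decode_states(fit, ms, posterior = FALSE)
  occ <- state_occupancy(dec, bin_s = 1800)
  sums <- occ |>
    dplyr::summarise(s = sum(fraction), .by = c(group, zt_bin))
  expect_true(all(abs(sums$s - 1) < 1e-9))
  expect_equal(nrow(occ), 48 * 4)

  # constant decoded path gives occupancy one everywhere
  const <- dec
  const$state <- factor("quiet_awake", levels = fit$labels)
  occ2 <- state_occupancy(const, bin_s = 1800)
  expect_true(all(occ2$fraction[occ2$state == "quiet_awake"] == 1))
})

test_that("models serialize to JSON and back", {
  spec <- default_hmm_spec()
  path <- withr::local_tempfile(fileext = ".json")
  write_hmm_json(spec, path)
  back <- read_hmm_json(path)
  expect_equal(back$transition, spec$transition)
  expect_equal(back$emission, spec$emission)
  expect_equal(back$labels, spec$labels)
  expect_equal(back$allowed_transition,
               unname(spec$allowed_transition), ignore_attr = TRUE)
})
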