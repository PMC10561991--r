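#' Configure a synthetic fly population
#'
#' The simulator generates populations of virtual flies whose latent
#' behaviour follows the four-stage sleep chain: at each bin the transition
#' matrix is a circadian mixture
#' `A(t) = (1 - w(t)) * A_day + w(t) * A_night`, where the weight
#' `w(t) = ((1 + cos(2 * pi * (h - night_peak_h) / period)) / 2) ^ s`
#' peaks at a configurable zeitgeber hour (default ZT15, mid first half of
#' the night) and cycles with the genotype's free-running period. The
#' sharpness exponent `s` (default 3) concentrates night-like dynamics
#' around the peak hour, so deep sleep shows a single prominent peak
#' rather than a broad plateau. Movement is emitted
#' per state (sleep stages never move), and moving bins receive a
#' log-normal displacement whose median sits well above the movement
#' threshold so classification is meaningful. Mechanical sleep deprivation
#' is modelled as windows during which movement is forced on and the state
#' is pinned to active wake.
#'
#' @param genotypes Data frame with columns `name`, `period_h`, `n_flies`.
#' @param days Recording length in days.
#' @param bin_s Simulation bin, seconds (default 10; coarser bins are fine
#'   for rhythm-level analyses).
#' @param A_day,A_night Day- and night-flavoured 4x4 transition matrices
#'   sharing the structural zeros of [default_hmm_spec()].
#' @param p_move_quiet,p_move_active Per-bin movement probability of the
#'   two wake stages (`p_move_quiet < p_move_active`).
#' @param night_peak_h Zeitgeber hour at which night-like dynamics (deep
#'   sleep propensity) peak.
#' @param modulation_sharpness Exponent applied to the raised-cosine
#'   weight; larger values sharpen the nightly deep-sleep peak.
#' @param displacement_meanlog,displacement_sdlog Log-normal displacement
#'   of moving bins, pixels per bin. The default median is `3 * bin_s`
#'   pixels (3 px/s), three times the default movement threshold, whatever
#'   the bin size.
#' @param deprivation_windows List of `c(start, end)` absolute-second
#'   windows of forced wakefulness.
#' @param rebound_boost Homeostatic sleep pressure after each deprivation
#'   window: the circadian weight is raised by
#'   `rebound_boost * exp(-(t - end) / rebound_tau_s)` (clipped at 1), so
#'   deprived flies sleep more than their own baseline. 0 (default)
#'   disables the homeostat.
#' @param rebound_tau_s Decay time constant of the rebound pressure,
#'   seconds.
#' @param seed Integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(genotypes = tibble::tibble(name = "CantonS",
                                                  period_h = 24,
                                                  n_flies = 10),
                       days = 3, bin_s = 10,
                       A_day = NULL, A_night = NULL,
                       p_move_quiet = 0.1, p_move_active = 0.9,
                       night_peak_h = 15,
                       modulation_sharpness = 3,
                       displacement_meanlog = NULL,
                       displacement_sdlog = 0.5,
                       deprivation_windows = list(),
                       rebound_boost = 0, rebound_tau_s = 6 * 3600,
                       seed = 1) {
  genotypes <- tibble::as_tibble(genotypes)
  stopifnot(all(c("name", "period_h", "n_flies") %in% names(genotypes)))
  if (!(p_move_quiet < p_move_active)) {
    stop("p_move_quiet must be below p_move_active", call. = FALSE)
  }
  if (is.null(displacement_meanlog)) displacement_meanlog <- log(3 * bin_s)
  template <- default_hmm_spec()
  if (is.null(A_day)) {
    A_day <- matrix(c(
      # deep   light  quiet  active
      0.70, 0.30, 0.00, 0.00,   # deep_sleep
      0.05, 0.45, 0.35, 0.15,   # light_sleep
      0.00, 0.10, 0.50, 0.40,   # quiet_awake
      0.00, 0.00, 0.15, 0.85    # active_awake
    ), 4, 4, byrow = TRUE)
  }
  if (is.null(A_night)) {
    # calibrated so peak deep-sleep occupancy stays mid-range (~0.5):
    # occupancy then tracks the circadian weight quasi-statically and its
    # argmax falls on the configured peak hour instead of saturating early
    A_night <- matrix(c(
      0.92, 0.08, 0.00, 0.00,
      0.12, 0.63, 0.18, 0.07,
      0.00, 0.45, 0.43, 0.12,
      0.00, 0.00, 0.50, 0.50
    ), 4, 4, byrow = TRUE)
  }
  check_sim_matrix <- function(A, name) {
    if (any(abs(rowSums(A) - 1) > 1e-9)) {
      stop(name, " rows must sum to 1", call. = FALSE)
    }
    if (any(A[!template$allowed_transition] != 0)) {
      stop(name, " violates the structural zeros of the sleep chain",
           call. = FALSE)
    }
  }
  check_sim_matrix(A_day, "A_day")
  check_sim_matrix(A_night, "A_night")
  structure(list(
    genotypes = genotypes, days = days, bin_s = bin_s,
    A_day = A_day, A_night = A_night,
    p_move = c(0, 0, p_move_quiet, p_move_active),
    night_peak_h = night_peak_h,
    modulation_sharpness = modulation_sharpness,
    displacement_meanlog = displacement_meanlog,
    displacement_sdlog = displacement_sdlog,
    deprivation_windows = deprivation_windows,
    rebound_boost = rebound_boost, rebound_tau_s = rebound_tau_s,
    labels = template$labels,
    seed = seed
  ), class = "sim_config")
}

#' Simulate a fly population with known ground truth
#'
#' Samples each fly's latent stage chain, per-bin movement and displacement
#' according to a [sim_config()]. Output pairs an analysable [behav_table]
#' (variables `displacement`, `moving`) with the ground truth every test
#' needs: the true per-bin stage of every fly, each genotype's true period
#' and the configured deep-sleep peak hour. Deterministic for a fixed
#' seed.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `sim_population`: `$bt` ([behav_table]),
#'   `$truth` (tibble `id`, `t`, `state`), `$config`.
#' @export
simulate_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n_bins <- round(cfg$days * 86400 / cfg$bin_s)
  t_grid <- (seq_len(n_bins) - 1) * cfg$bin_s
  hour <- t_grid / 3600          # absolute hours: periods free-run
  S <- 4L

  deprived <- rep(FALSE, n_bins)
  pressure <- rep(0, n_bins)
  for (w in cfg$deprivation_windows) {
    deprived <- deprived | (t_grid >= w[1] & t_grid < w[2])
    if (cfg$rebound_boost > 0) {
      after <- t_grid >= w[2]
      pressure[after] <- pressure[after] + cfg$rebound_boost *
        exp(-(t_grid[after] - w[2]) / cfg$rebound_tau_s)
    }
  }

  data_pieces <- list(); truth_pieces <- list(); meta_pieces <- list()
  for (g in seq_len(nrow(cfg$genotypes))) {
    geno <- cfg$genotypes$name[g]
    period_h <- cfg$genotypes$period_h[g]
    w_t <- ((1 + cos(2 * pi * (hour - cfg$night_peak_h) / period_h)) /
              2)^cfg$modulation_sharpness
    w_t <- pmin(1, w_t + pressure)
    # per-bin mixture transition matrices, flattened for fast indexing
    for (f in seq_len(cfg$genotypes$n_flies[g])) {
      id <- sprintf("sim|%s|%02d", geno, f)
      states <- integer(n_bins)
      # start from the day/night mixture's more likely flavour at t = 0
      states[1] <- sample.int(S, 1)
      u <- stats::runif(n_bins)
      for (b in 2:n_bins) {
        w <- w_t[b]
        p <- (1 - w) * cfg$A_day[states[b - 1], ] +
          w * cfg$A_night[states[b - 1], ]
        states[b] <- findInterval(u[b], cumsum(p), left.open = TRUE) + 1L
      }
      states[deprived] <- 4L
      moving <- as.integer(stats::runif(n_bins) < cfg$p_move[states])
      moving[deprived] <- 1L
      disp <- numeric(n_bins)
      n_mov <- sum(moving)
      if (n_mov) {
        disp[moving == 1] <- stats::rlnorm(n_mov,
                                           cfg$displacement_meanlog,
                                           cfg$displacement_sdlog)
      }
      # toy positions: bounded random walk driven by displacement
      step <- disp * sample(c(-1, 1), n_bins, replace = TRUE)
      x <- 100 + cumsum(step) %% 200 - 100
      data_pieces[[length(data_pieces) + 1]] <- tibble::tibble(
        id = id, t = t_grid, x = x, y = 20,
        displacement = disp, moving = moving
      )
      truth_pieces[[length(truth_pieces) + 1]] <- tibble::tibble(
        id = id, t = t_grid, state = cfg$labels[states]
      )
      meta_pieces[[length(meta_pieces) + 1]] <- tibble::tibble(
        id = id, genotype = geno, period_h = period_h
      )
    }
  }
  bt <- link_metadata(dplyr::bind_rows(data_pieces),
                      dplyr::bind_rows(meta_pieces))
  truth <- dplyr::bind_rows(truth_pieces)
  truth$state <- factor(truth$state, levels = cfg$labels)
  structure(list(bt = bt, truth = truth, config = cfg),
            class = "sim_population")
}

#' @export
print.sim_population <- function(x, ...) {
  cat("<sim_population>", nrow(x$bt$meta), "flies,",
      x$config$days, "days at", x$config$bin_s, "s bins\n")
  invisible(x)
}

#' Ground-truth stage occupancy of a simulation
#'
#' The occupancy curve computed from the simulator's true states -- the
#' recovery target for [state_occupancy()] of decoded stages.
#'
#' @param sim A `sim_population`.
#' @param bin_s Zeitgeber bin width, seconds.
#' @param lights_on,day_length Zeitgeber reference.
#' @return A tibble (`zt_bin` hours, `state`, `fraction`).
#' @export
ground_truth_occupancy <- function(sim, bin_s = 1800, lights_on = 0,
                                   day_length = 86400) {
  stopifnot(inherits(sim, "sim_population"))
  bin_h <- bin_s / 3600
  lv <- levels(sim$truth$state)
  sim$truth |>
    dplyr::mutate(
      zt = ((.data$t - lights_on) %% day_length) / 3600,
      zt_bin = floor(.data$zt / bin_h) * bin_h
    ) |>
    dplyr::summarise(n = dplyr::n(), .by = c("zt_bin", "state")) |>
    dplyr::group_by(.data$zt_bin) |>
    dplyr::group_modify(function(df, key) {
      total <- sum(df$n)
      full <- tibble::tibble(state = factor(lv, levels = lv))
      full <- dplyr::left_join(full, df, by = "state")
      full$n[is.na(full$n)] <- 0
      tibble::tibble(state = full$state, fraction = full$n / total)
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$zt_bin, .data$state)
}
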