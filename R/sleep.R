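#' Sleep-scoring parameters
#'
#' Bundles the constants of the classical inactivity definition of fly
#' sleep: movement is assessed in short bins (default 10 s), and a bout of
#' complete inactivity counts as sleep once it lasts at least 5 min
#' (`min_sleep_s = 300`, inclusive). The velocity threshold separating
#' "moving" from "still" within a bin is instrument-dependent and
#' configurable; the default 1 px/s suits ethoscope-scale arenas.
#'
#' @param bin_s Movement-classification bin, seconds.
#' @param min_sleep_s Minimum inactivity span scored as sleep, seconds;
#'   must be a multiple of `bin_s`.
#' @param velocity_threshold Instantaneous speed (pixels/s) above which a
#'   frame counts as movement.
#' @return A `sleep_params` list.
#' @export
sleep_params <- function(bin_s = 10, min_sleep_s = 300,
                         velocity_threshold = 1.0) {
  stopifnot(bin_s > 0, min_sleep_s >= bin_s)
  if (abs(min_sleep_s / bin_s - round(min_sleep_s / bin_s)) > 1e-9) {
    stop("min_sleep_s must be an integer multiple of bin_s", call. = FALSE)
  }
  structure(list(bin_s = bin_s, min_sleep_s = min_sleep_s,
                 velocity_threshold = velocity_threshold),
            class = "sleep_params")
}

#' Classify movement into a regular binary grid
#'
#' Reduces a displacement trace to a regular per-bin moving/still series:
#' a bin is "moving" if the maximum instantaneous speed proxy of any frame
#' inside it exceeds the threshold (max semantics: one fast frame suffices).
#' The speed proxy is displacement divided by the inter-frame interval.
#' Grid bins with no observations are `NA` (missing), never silently still.
#'
#' @param bt A [behav_table] with a displacement-like variable sampled at
#'   or below the bin cadence.
#' @param params A [sleep_params].
#' @param variable Name of the displacement column (pixels per frame).
#' @return A tibble (`id`, `t`, `moving`) on a regular grid of step
#'   `params$bin_s` spanning each specimen's recording.
#' @export
classify_movement <- function(bt, params = sleep_params(),
                              variable = "displacement") {
  stopifnot(inherits(bt, "behav_table"))
  if (!variable %in% names(bt$data)) {
    stop("no such data column: ", variable, call. = FALSE)
  }
  bin_s <- params$bin_s
  velo <- bt$data |>
    dplyr::group_by(.data$id) |>
    dplyr::mutate(.dt = {
      dt <- c(NA, diff(.data$t))
      dt[1] <- if (length(dt) > 1) stats::median(dt[-1]) else bin_s
      dt
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(.v = .data[[variable]] / pmax(.data$.dt, 1e-9),
                  t_bin = floor(.data$t / bin_s) * bin_s)
  observed <- velo |>
    dplyr::summarise(vmax = max(.data$.v), .by = c("id", "t_bin"))
  # full grid per specimen so gaps surface as NA
  grid <- observed |>
    dplyr::summarise(t0 = min(.data$t_bin), t1 = max(.data$t_bin),
                     .by = "id") |>
    dplyr::rowwise() |>
    dplyr::reframe(id = .data$id, t = seq(.data$t0, .data$t1, by = bin_s))
  grid |>
    dplyr::left_join(observed, by = c("id", "t" = "t_bin")) |>
    dplyr::mutate(moving = ifelse(is.na(.data$vmax), NA_integer_,
                                  as.integer(.data$vmax > params$velocity_threshold))) |>
    dplyr::select("id", "t", "moving")
}

#' Annotate sleep by the five-minute inactivity rule
#'
#' Sleep is a maximal run of contiguous still bins whose span reaches
#' `min_sleep_s` (inclusive, i.e. "at least 5 min" with defaults). Missing
#' bins terminate runs: no sleep is inferred across gaps in the record.
#'
#' @param ms A movement series as returned by [classify_movement()]:
#'   columns `id`, `t` (regular grid), `moving` in \{0, 1, NA\}.
#' @param params A [sleep_params]; `bin_s` must match the grid step.
#' @return The input with an `asleep` column added (0/1, `NA` where
#'   `moving` is missing).
#' @export
sleep_annotation <- function(ms, params = sleep_params()) {
  check_movement_series(ms, params$bin_s)
  min_bins <- round(params$min_sleep_s / params$bin_s)
  ms |>
    dplyr::group_by(.data$id) |>
    dplyr::mutate(asleep = annotate_runs(.data$moving, min_bins)) |>
    dplyr::ungroup()
}

# runs of zeros >= min_bins become sleep; NA breaks runs and stays NA
annotate_runs <- function(moving, min_bins) {
  key <- ifelse(is.na(moving), -1L, as.integer(moving))
  r <- rle(key)
  sleep_run <- r$values == 0L & r$lengths >= min_bins
  out <- rep(ifelse(sleep_run, 1L, 0L), r$lengths)
  out[key == -1L] <- NA_integer_
  out
}

check_movement_series <- function(ms, bin_s) {
  need <- c("id", "t", "moving")
  miss <- setdiff(need, names(ms))
  if (length(miss)) {
    stop("movement series is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  bad <- ms |>
    dplyr::summarise(ok = all(abs(diff(.data$t) - bin_s) < 1e-6) || dplyr::n() < 2,
                     .by = "id")
  if (!all(bad$ok)) {
    stop("movement series grid is irregular (expected step ", bin_s, " s)",
         call. = FALSE)
  }
  invisible(ms)
}

#' Run-length bout statistics
#'
#' Encodes a per-bin binary label into maximal bouts: one row per run with
#' its state, onset time and duration. The encoding is lossless --
#' [bouts_to_series()] reconstructs the input exactly -- and bout durations
#' per specimen sum to the covered recording span.
#'
#' @param series A tibble (`id`, `t`, <state column>) on a regular grid.
#' @param state_col Name of the binary (or small-integer / factor) label
#'   column, default `"asleep"`.
#' @param bin_s Grid step in seconds.
#' @return A tibble (`id`, `state`, `onset_t`, `duration_s`).
#' @export
bout_analysis <- function(series, state_col = "asleep", bin_s = 10) {
  if (!state_col %in% names(series)) {
    stop("no such column: ", state_col, call. = FALSE)
  }
  series |>
    dplyr::group_by(.data$id) |>
    dplyr::group_modify(function(df, key) {
      x <- df[[state_col]]
      keyed <- ifelse(is.na(x), ".na", as.character(x))
      r <- rle(keyed)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      tibble::tibble(
        state = ifelse(r$values == ".na", NA_character_, r$values),
        onset_t = df$t[starts],
        duration_s = r$lengths * bin_s
      )
    }) |>
    dplyr::ungroup()
}

#' @rdname bout_analysis
#' @param bouts A bout table from [bout_analysis()].
#' @return `bouts_to_series` returns the reconstructed (`id`, `t`, `state`)
#'   series.
#' @export
bouts_to_series <- function(bouts, bin_s = 10) {
  bouts |>
    dplyr::group_by(.data$id) |>
    dplyr::group_modify(function(df, key) {
      n_bins <- round(df$duration_s / bin_s)
      tibble::tibble(
        t = df$onset_t[1] + (seq_len(sum(n_bins)) - 1) * bin_s,
        state = rep(df$state, n_bins)
      )
    }) |>
    dplyr::ungroup()
}

#' Population sleep profile with bootstrap confidence band
#'
#' Averages the fraction of time asleep across specimens in bins of
#' zeitgeber time, per experimental group, with a percentile bootstrap
#' confidence interval obtained by resampling specimens (the independent
#' units), not time bins.
#'
#' @param annotated A sleep-annotated series ([sleep_annotation()]) joined
#'   with `zt` -- or supply `meta` and the function derives `zt` from `t`
#'   assuming lights-on at `lights_on`.
#' @param meta Metadata table used for grouping.
#' @param group_by Name of the metadata column defining groups, or `NULL`
#'   for a single pooled group.
#' @param profile_bin_s Width of the zeitgeber bins, seconds (default
#'   1800 = 30 min).
#' @param ci Confidence level of the percentile bootstrap (default 0.95).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @param lights_on,day_length Zeitgeber reference used when `zt` is not
#'   already present.
#' @return A tibble (`group`, `zt_bin` hours, `mean_fraction_asleep`,
#'   `ci_low`, `ci_high`, `n_specimens`).
#' @export
sleep_profile <- function(annotated, meta = NULL, group_by = NULL,
                          profile_bin_s = 1800, ci = 0.95, n_boot = 1000,
                          seed = 1, lights_on = 0, day_length = 86400) {
  if (!"zt" %in% names(annotated)) {
    annotated <- dplyr::mutate(
      annotated, zt = ((.data$t - lights_on) %% day_length) / 3600
    )
  }
  if (!is.null(group_by)) {
    if (is.null(meta) || !group_by %in% names(meta)) {
      stop("group_by column not found in meta", call. = FALSE)
    }
    annotated <- dplyr::left_join(
      annotated, dplyr::select(meta, "id", dplyr::all_of(group_by)),
      by = "id"
    )
    annotated$group <- as.character(annotated[[group_by]])
  } else {
    annotated$group <- "all"
  }
  bin_h <- profile_bin_s / 3600
  per_spec <- annotated |>
    dplyr::filter(!is.na(.data$asleep)) |>
    dplyr::mutate(zt_bin = floor(.data$zt / bin_h) * bin_h) |>
    dplyr::summarise(frac = mean(.data$asleep),
                     .by = c("group", "id", "zt_bin"))
  boot_mean_ci(per_spec, value_col = "frac", by = c("group", "zt_bin"),
               ci = ci, n_boot = n_boot, seed = seed) |>
    dplyr::rename(mean_fraction_asleep = "mean_value") |>
    dplyr::arrange(.data$group, .data$zt_bin)
}

# percentile bootstrap over specimens of the mean of `value_col`, within
# each combination of `by`; specimens are resampled coherently per group
boot_mean_ci <- function(per_spec, value_col, by, ci, n_boot, seed) {
  alpha <- (1 - ci) / 2
  per_spec |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::group_modify(function(df, key) {
      v <- df[[value_col]]
      n <- length(v)
      est <- mean(v)
      if (n < 2 || n_boot < 1) {
        lo <- hi <- est
      } else {
        # deterministic per-cell stream: offset the seed by a stable hash
        cell <- paste(unlist(key), collapse = "\r")
        set.seed((seed + string_seed_offset(cell)) %% .Machine$integer.max)
        bm <- vapply(seq_len(n_boot), function(i) {
          mean(v[sample.int(n, n, replace = TRUE)])
        }, numeric(1))
        qs <- stats::quantile(bm, c(alpha, 1 - alpha), names = FALSE,
                              type = 7)
        lo <- qs[1]; hi <- qs[2]
      }
      tibble::tibble(mean_value = est, ci_low = lo, ci_high = hi,
                     n_specimens = n)
    }) |>
    dplyr::ungroup()
}

string_seed_offset <- function(s) {
  sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 100000L
}

#' Specimen-by-time heatmap matrix
#'
#' Bins one variable per specimen and lays the result out as a matrix with
#' one row per specimen (ordered as in the metadata) and one column per
#' time bin -- the shape behind population overview heatmaps. Bins with no
#' observations are `NA`.
#'
#' @param bt A [behav_table], or a plain tibble (`id`, `t`, variable).
#' @param variable Variable to aggregate.
#' @param bin_s Bin width, seconds (default 1800).
#' @param aggregator Within-bin aggregate, default `"mean"`.
#' @param meta Metadata used for row ordering when `bt` is a plain tibble.
#' @return A numeric matrix with `dimnames` = (specimen ids, bin start
#'   seconds), class `behav_heatmap`.
#' @export
heatmap_matrix <- function(bt, variable, bin_s = 1800, aggregator = "mean",
                           meta = NULL) {
  if (inherits(bt, "behav_table")) {
    binned <- bin_time(bt, variable, bin_s, aggregator)
    ids <- bt$meta$id
  } else {
    fun <- switch(aggregator, mean = mean, max = max, sum = sum,
                  median = stats::median)
    binned <- bt |>
      dplyr::mutate(t_bin = floor(.data$t / bin_s) * bin_s) |>
      dplyr::summarise(value = fun(.data[[variable]]), .by = c("id", "t_bin"))
    ids <- if (!is.null(meta)) meta$id else unique(binned$id)
  }
  ids <- ids[ids %in% binned$id]   # registry order, data-bearing specimens
  cols <- seq(min(binned$t_bin), max(binned$t_bin), by = bin_s)
  m <- matrix(NA_real_, nrow = length(ids), ncol = length(cols),
              dimnames = list(ids, cols))
  m[cbind(match(binned$id, ids), match(binned$t_bin, cols))] <- binned$value
  structure(m, class = c("behav_heatmap", "matrix"), bin_s = bin_s,
            variable = variable)
}

#' Quantify rebound sleep after deprivation
#'
#' Compares, per specimen, minutes of sleep in a clock window on a
#' post-deprivation day against the identical clock window on a baseline
#' day: `delta = rebound - baseline` minutes. Specimens missing data in
#' either window are excluded and reported. The group summary is the mean
#' delta with a seeded percentile bootstrap interval over specimens.
#'
#' @param annotated Sleep-annotated series (`id`, `t`, `asleep`) on a
#'   regular grid of `bin_s` seconds.
#' @param baseline_window,rebound_window Two-element numeric vectors
#'   `c(start, end)` in absolute seconds; both must span the same length
#'   of clock time.
#' @param meta,group_by Optional grouping as in [sleep_profile()].
#' @param bin_s Grid step of `annotated`, seconds.
#' @param n_boot,seed,ci Bootstrap settings.
#' @return A list of class `rebound_result`: `$per_specimen` (tibble `id`,
#'   `baseline_sleep_min`, `rebound_sleep_min`, `delta_min`), `$summary`
#'   (per group mean delta with CI), `$excluded` (character ids).
#' @export
rebound_quantification <- function(annotated, baseline_window,
                                   rebound_window, meta = NULL,
                                   group_by = NULL, bin_s = 10,
                                   n_boot = 1000, seed = 1, ci = 0.95) {
  span_b <- diff(baseline_window)
  span_r <- diff(rebound_window)
  if (abs(span_b - span_r) > 1e-6) {
    stop("baseline and rebound windows must span the same clock length",
         call. = FALSE)
  }
  sleep_min_in <- function(w) {
    annotated |>
      dplyr::filter(.data$t >= w[1], .data$t < w[2]) |>
      dplyr::summarise(
        minutes = sum(.data$asleep, na.rm = TRUE) * bin_s / 60,
        n_bins = sum(!is.na(.data$asleep)),
        .by = "id"
      )
  }
  b <- sleep_min_in(baseline_window)
  r <- sleep_min_in(rebound_window)
  all_ids <- union(b$id, r$id)
  per <- tibble::tibble(id = all_ids) |>
    dplyr::left_join(b, by = "id") |>
    dplyr::left_join(r, by = "id", suffix = c("_b", "_r"))
  complete <- !is.na(per$n_bins_b) & !is.na(per$n_bins_r) &
    per$n_bins_b > 0 & per$n_bins_r > 0
  excluded <- per$id[!complete]
  per_specimen <- per |>
    dplyr::filter(complete) |>
    dplyr::transmute(
      id = .data$id,
      baseline_sleep_min = .data$minutes_b,
      rebound_sleep_min = .data$minutes_r,
      delta_min = .data$minutes_r - .data$minutes_b
    )
  grp <- if (!is.null(group_by)) {
    if (is.null(meta) || !group_by %in% names(meta)) {
      stop("group_by column not found in meta", call. = FALSE)
    }
    dplyr::left_join(per_specimen,
                     dplyr::select(meta, "id", dplyr::all_of(group_by)),
                     by = "id") |>
      dplyr::mutate(group = as.character(.data[[group_by]]))
  } else {
    dplyr::mutate(per_specimen, group = "all")
  }
  summary <- boot_mean_ci(grp, value_col = "delta_min", by = "group",
                          ci = ci, n_boot = n_boot, seed = seed) |>
    dplyr::rename(mean_delta_min = "mean_value")
  structure(list(per_specimen = per_specimen, summary = summary,
                 excluded = excluded),
            class = "rebound_result")
}

#' @export
print.rebound_result <- function(x, ...) {
  cat("<rebound_result>\n")
  print(x$summary)
  if (length(x$excluded)) {
    cat("excluded (missing data in a window):",
        paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @method tidy rebound_result
#' @export
tidy.rebound_result <- function(x, ...) x$per_specimen

#' @method glance rebound_result
#' @export
glance.rebound_result <- function(x, ...) x$summary
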