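#' Chi-squared periodogram
#'
#' The classical chi-squared periodogram for rhythm detection in equally
#' binned activity: for each candidate period of \eqn{P} bins the series is
#' truncated to \eqn{K = \lfloor N/P \rfloor} complete cycles, folded into
#' \eqn{P} phase columns with means \eqn{M_h}, and scored
#' \deqn{Q_P = \frac{K \sum_h (M_h - \bar M)^2}{\hat\sigma^2}, \qquad
#'       \hat\sigma^2 = \frac{1}{KP}\sum_i (x_i - \bar M)^2,}
#' where \eqn{\bar M} and \eqn{\hat\sigma^2} run over the \eqn{KP} used
#' bins. Under the null of no rhythm \eqn{Q_P \sim \chi^2_{P-1}}
#' (each folded column mean contributes one standardized squared
#' deviation, one constraint for the grand mean). The candidate
#' grid is every integer bin multiple inside `period_range_h` (folding
#' requires whole bins; finer grids would need resampling).
#'
#' @param binned A tibble (`id`, `t`, `value`) of equally binned activity,
#'   e.g. from [bin_time()] (rename `t_bin` to `t`), or a plain numeric
#'   vector for a single anonymous series.
#' @param period_range_h Two-element range of candidate periods, hours.
#' @param bin_s Bin width of the series, seconds.
#' @param value_col Name of the activity column.
#' @return A tibble of class `behav_periodogram` (`id`, `period_h`, `Q`,
#'   `df`, `threshold` = `NA` until [periodogram_significance()]).
#' @export
chi_squared_periodogram <- function(binned, period_range_h = c(16, 32),
                                    bin_s = 1800, value_col = "value") {
  if (is.numeric(binned) && is.null(dim(binned))) {
    binned <- tibble::tibble(id = "series", t = (seq_along(binned) - 1) * bin_s,
                             value = binned)
    value_col <- "value"
  }
  stopifnot(all(c("id", "t", value_col) %in% names(binned)))
  p_bins <- seq(ceiling(period_range_h[1] * 3600 / bin_s),
                floor(period_range_h[2] * 3600 / bin_s))
  if (!length(p_bins)) stop("no representable periods in range", call. = FALSE)
  binned |>
    dplyr::group_by(.data$id) |>
    dplyr::group_modify(function(df, key) {
      x <- df[[value_col]][order(df$t)]
      n <- length(x)
      if (n < 2 * max(p_bins)) {
        stop("series span (", n, " bins) shorter than twice the longest ",
             "tested period (", max(p_bins), " bins)", call. = FALSE)
      }
      if (stats::var(x) == 0) stop("constant series", call. = FALSE)
      Q <- vapply(p_bins, function(P) chi_sq_Q(x, P), numeric(1))
      tibble::tibble(period_h = p_bins * bin_s / 3600, Q = Q,
                     df = p_bins - 1, threshold = NA_real_)
    }) |>
    dplyr::ungroup() |>
    structure(class = c("behav_periodogram", class(tibble::tibble())),
              bin_s = bin_s)
}

# fold-and-score statistic for one period of P bins
chi_sq_Q <- function(x, P) {
  K <- floor(length(x) / P)
  xs <- x[seq_len(K * P)]
  folded <- matrix(xs, nrow = P)           # column per cycle, row per phase
  M_h <- rowMeans(folded)
  M_bar <- mean(xs)
  sigma2 <- sum((xs - M_bar)^2) / (K * P)
  if (sigma2 == 0) return(0)
  K * sum((M_h - M_bar)^2) / sigma2
}

#' Significance threshold for a periodogram
#'
#' Fills the `threshold` column with the chi-squared null quantile at each
#' period's degrees of freedom, Bonferroni-corrected over the number of
#' tested periods by default (the null is tested once per grid point).
#'
#' @param pg A `behav_periodogram`.
#' @param alpha Significance level in (0, 1).
#' @param correction `"bonferroni"` (threshold at `1 - alpha/m`, `m` grid
#'   points) or `"none"`.
#' @return The periodogram with `threshold` filled.
#' @export
periodogram_significance <- function(pg, alpha = 0.01,
                                     correction = c("bonferroni", "none")) {
  correction <- match.arg(correction)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)", call. = FALSE)
  }
  m <- dplyr::n_distinct(pg$period_h)
  a <- if (correction == "bonferroni") alpha / m else alpha
  pg$threshold <- stats::qchisq(1 - a, df = pg$df)
  pg
}

#' Significant periodogram peaks
#'
#' Local maxima of `Q` exceeding the significance threshold, sorted by `Q`
#' descending; ties break toward the shorter period. Endpoints count as
#' local maxima against their single neighbour.
#'
#' @param pg A `behav_periodogram` with thresholds filled.
#' @return A tibble (`id`, `period_h`, `Q`), possibly empty.
#' @export
peak_periods <- function(pg) {
  if (all(is.na(pg$threshold))) {
    stop("fill thresholds with periodogram_significance() first",
         call. = FALSE)
  }
  pg |>
    dplyr::group_by(.data$id) |>
    dplyr::group_modify(function(df, key) {
      df <- df[order(df$period_h), ]
      q <- df$Q
      n <- length(q)
      left <- c(-Inf, q[-n])
      right <- c(q[-1], -Inf)
      is_peak <- q >= left & q >= right & !(q == left & q == right)
      keep <- is_peak & q > df$threshold
      out <- df[keep, c("period_h", "Q")]
      out[order(-out$Q, out$period_h), ]
    }) |>
    dplyr::ungroup()
}

#' Population-average periodogram
#'
#' Averages per-specimen `Q` curves pointwise within experimental groups.
#' The chi-squared null applies to individual curves, not the average; the
#' per-period threshold is carried through for visual reference only.
#'
#' @param pg A multi-specimen `behav_periodogram`.
#' @param meta,group_by Optional grouping (metadata column); default one
#'   pooled group.
#' @return A `behav_periodogram` whose `id` holds group labels.
#' @export
population_periodogram <- function(pg, meta = NULL, group_by = NULL) {
  if (!is.null(group_by)) {
    if (is.null(meta) || !group_by %in% names(meta)) {
      stop("group_by column not found in meta", call. = FALSE)
    }
    pg <- dplyr::left_join(pg, dplyr::select(meta, "id",
                                             dplyr::all_of(group_by)),
                           by = "id")
    pg$.group <- as.character(pg[[group_by]])
  } else {
    pg$.group <- "all"
  }
  out <- pg |>
    dplyr::summarise(Q = mean(.data$Q), df = .data$df[1],
                     threshold = .data$threshold[1],
                     .by = c(".group", "period_h")) |>
    dplyr::rename(id = ".group") |>
    dplyr::select("id", "period_h", "Q", "df", "threshold") |>
    dplyr::arrange(.data$id, .data$period_h)
  structure(out, class = c("behav_periodogram", class(tibble::tibble())),
            bin_s = attr(pg, "bin_s"))
}

#' Double-plotted actogram matrix
#'
#' Lays binned activity out as an actogram raster: one row per day, one
#' column per time-of-day bin. Double plotting (the convention in
#' circadian work) concatenates day \eqn{r} and day \eqn{r+1} in row
#' \eqn{r}, so drifting rhythms read as sloping bands; the final row's
#' right half has no next day and is `NA`.
#'
#' @param binned A tibble (`id`, `t`, `value`) of binned activity; multiple
#'   specimens are averaged per bin (optionally within `group_by` groups --
#'   then one matrix per group is returned in a named list).
#' @param day_length_h Day length in hours (default 24).
#' @param bin_s Bin width in seconds (default 1800).
#' @param double Double-plot (default `TRUE`).
#' @param meta,group_by Optional grouping.
#' @return A matrix of class `behav_actogram` (or a named list of them),
#'   rows = days, columns = `2 * day_length_h * 3600 / bin_s` bins when
#'   double-plotted.
#' @export
actogram_matrix <- function(binned, day_length_h = 24, bin_s = 1800,
                            double = TRUE, meta = NULL, group_by = NULL) {
  if (!is.null(group_by)) {
    if (is.null(meta) || !group_by %in% names(meta)) {
      stop("group_by column not found in meta", call. = FALSE)
    }
    binned <- dplyr::left_join(binned,
                               dplyr::select(meta, "id",
                                             dplyr::all_of(group_by)),
                               by = "id")
    groups <- split(binned, binned[[group_by]])
    return(lapply(groups, actogram_matrix, day_length_h = day_length_h,
                  bin_s = bin_s, double = double))
  }
  day_s <- day_length_h * 3600
  per_bin <- binned |>
    dplyr::mutate(t_bin = floor(.data$t / bin_s) * bin_s) |>
    dplyr::summarise(value = mean(.data$value, na.rm = TRUE), .by = "t_bin")
  bins_per_day <- round(day_s / bin_s)
  day <- floor(per_bin$t_bin / day_s)
  col <- round((per_bin$t_bin %% day_s) / bin_s) + 1
  n_days <- max(day) + 1
  single <- matrix(NA_real_, nrow = n_days, ncol = bins_per_day)
  single[cbind(day + 1, col)] <- per_bin$value
  if (!double) {
    return(structure(single, class = c("behav_actogram", "matrix"),
                     bin_s = bin_s, day_length_h = day_length_h,
                     double = FALSE))
  }
  right <- rbind(single[-1, , drop = FALSE],
                 matrix(NA_real_, 1, bins_per_day))
  m <- cbind(single, right)
  structure(m, class = c("behav_actogram", "matrix"), bin_s = bin_s,
            day_length_h = day_length_h, double = TRUE)
}
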