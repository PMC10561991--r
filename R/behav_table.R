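#' Metadata-linked behavioural tables
#'
#' A `behav_table` pairs a long behavioural time series (one row per
#' observation, keyed by specimen `id` and time `t` in seconds) with a
#' metadata table describing each specimen (genotype, treatment, machine,
#' region, ...). The two tables are hard-linked through the `id` column:
#' every id that appears in the data must be described in the metadata,
#' while the metadata may list specimens that produced no data (e.g. flies
#' dead on arrival). Every verb in the package preserves this referential
#' integrity.
#'
#' @param data A data frame with at least `id` (character) and `t`
#'   (numeric, seconds since the experiment reference) columns, plus one or
#'   more behavioural variables.
#' @param meta A data frame with a unique, non-empty `id` column and
#'   arbitrary descriptor columns.
#'
#' @return An object of class `behav_table`: a list with elements `data`
#'   and `meta`, both tibbles. `data` is sorted by `id`, then `t`.
#'
#' @examples
#' bt <- behav_table(
#'   data = data.frame(id = "a", t = c(0, 10), x = c(1, 2)),
#'   meta = data.frame(id = c("a", "b"), genotype = "CantonS")
#' )
#' bt
#' @export
behav_table <- function(data, meta) {
  link_metadata(data, meta)
}

#' Link behavioural data to its metadata
#'
#' Constructs a [behav_table] from a raw data table and a metadata table,
#' enforcing referential integrity: every id in the data must appear in the
#' metadata (the reverse is allowed -- metadata is the experimental
#' registry and may describe specimens with no recorded data).
#'
#' @param data A data frame with `id` and `t` columns and \eqn{\ge} 1
#'   variable columns.
#' @param meta A data frame with a unique `id` column.
#' @return A `behav_table`.
#' @export
link_metadata <- function(data, meta) {
  data <- tibble::as_tibble(data)
  meta <- tibble::as_tibble(meta)
  if (!"id" %in% names(meta)) {
    stop("metadata must contain an 'id' column", call. = FALSE)
  }
  meta$id <- as.character(meta$id)
  if (anyDuplicated(meta$id)) {
    dup <- unique(meta$id[duplicated(meta$id)])
    stop("duplicate metadata ids: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(meta$id) | meta$id == "")) {
    stop("metadata ids must be non-empty", call. = FALSE)
  }
  missing_cols <- setdiff(c("id", "t"), names(data))
  if (length(missing_cols)) {
    stop("data is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data$id <- as.character(data$id)
  if (nrow(data) && any(!is.finite(data$t))) {
    stop("all t values must be finite", call. = FALSE)
  }
  orphans <- setdiff(unique(data$id), meta$id)
  if (length(orphans)) {
    stop("data ids absent from metadata: ", paste(orphans, collapse = ", "),
         call. = FALSE)
  }
  data <- dplyr::arrange(data, .data$id, .data$t)
  structure(list(data = data, meta = meta), class = "behav_table")
}

#' @export
print.behav_table <- function(x, ...) {
  cat(sprintf(
    "<behav_table> %d observations of %d specimen(s); %d specimen(s) in metadata\n",
    nrow(x$data), dplyr::n_distinct(x$data$id), nrow(x$meta)
  ))
  cat("$data\n")
  print(x$data, n = 5)
  cat("$meta\n")
  print(x$meta, n = 5)
  invisible(x)
}

#' Behavioural data of a behav_table
#' @param bt A [behav_table].
#' @return The data tibble (`bt_data`) or metadata tibble (`bt_meta`).
#' @export
bt_data <- function(bt) {
  stopifnot(inherits(bt, "behav_table"))
  bt$data
}

#' @rdname bt_data
#' @export
bt_meta <- function(bt) {
  stopifnot(inherits(bt, "behav_table"))
  bt$meta
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Flatten a behav_table to a single tibble
#'
#' Joins the metadata columns onto the behavioural rows, the convenient
#' shape for ggplot2 and modelling.
#'
#' @param x A [behav_table].
#' @param ... Unused.
#' @return A tibble with one row per observation, metadata columns joined
#'   by `id`.
#' @method tidy behav_table
#' @export
tidy.behav_table <- function(x, ...) {
  dplyr::left_join(x$data, x$meta, by = "id", suffix = c("", ".meta"))
}

#' @method glance behav_table
#' @export
glance.behav_table <- function(x, ...) {
  span <- if (nrow(x$data)) diff(range(x$data$t)) else NA_real_
  tibble::tibble(
    n_obs = nrow(x$data),
    n_specimens_data = dplyr::n_distinct(x$data$id),
    n_specimens_meta = nrow(x$meta),
    t_span_s = span
  )
}

# internal: rebuild, asserting integrity is preserved
rebuild_behav_table <- function(data, meta) {
  stopifnot(all(unique(data$id) %in% meta$id))
  structure(list(data = tibble::as_tibble(data), meta = tibble::as_tibble(meta)),
            class = "behav_table")
}

#' Filter specimens by a metadata predicate
#'
#' Restricts the metadata to rows matching a predicate over metadata
#' columns, and drops the behavioural rows of every specimen filtered out.
#' A predicate matching nothing yields an empty (but valid) `behav_table`.
#'
#' @param bt A [behav_table].
#' @param ... Logical conditions over metadata columns, as in
#'   [dplyr::filter()].
#' @return A `behav_table`.
#' @examples
#' bt <- behav_table(
#'   data.frame(id = c("a", "b"), t = 0, x = 1),
#'   data.frame(id = c("a", "b"), genotype = c("CantonS", "per-short"))
#' )
#' filter_by_meta(bt, genotype == "CantonS")
#' @export
filter_by_meta <- function(bt, ...) {
  stopifnot(inherits(bt, "behav_table"))
  quos <- rlang::enquos(...)
  meta <- tryCatch(
    dplyr::filter(bt$meta, !!!quos),
    error = function(e) stop("metadata predicate failed: ",
                             conditionMessage(e), call. = FALSE)
  )
  data <- dplyr::filter(bt$data, .data$id %in% meta$id)
  rebuild_behav_table(data, meta)
}

#' Restrict to a time window
#'
#' Keeps behavioural rows with `t` in the half-open interval
#' `[t_min, t_max)`. Metadata is unchanged (specimens whose rows all fall
#' outside the window stay registered).
#'
#' @param bt A [behav_table].
#' @param t_min,t_max Window bounds in seconds; `t_min < t_max`.
#' @return A `behav_table`.
#' @export
time_window <- function(bt, t_min, t_max) {
  stopifnot(inherits(bt, "behav_table"))
  if (!(is.numeric(t_min) && is.numeric(t_max)) || t_min >= t_max) {
    stop("need numeric t_min < t_max", call. = FALSE)
  }
  data <- dplyr::filter(bt$data, .data$t >= t_min, .data$t < t_max)
  rebuild_behav_table(data, bt$meta)
}

#' Bin a behavioural variable in time
#'
#' Aggregates one variable into fixed-width time bins per specimen. Bins
#' are labelled by their left edge: `t_bin = floor(t / bin_size) * bin_size`.
#' Only non-empty bins are returned.
#'
#' @param bt A [behav_table].
#' @param variable Name of a numeric data column.
#' @param bin_size Bin width in seconds (> 0).
#' @param aggregator One of `"mean"`, `"max"`, `"sum"`, `"median"`.
#' @return A tibble with columns `id`, `t_bin`, `value`.
#' @export
bin_time <- function(bt, variable, bin_size,
                     aggregator = c("mean", "max", "sum", "median")) {
  stopifnot(inherits(bt, "behav_table"))
  aggregator <- match.arg(aggregator)
  if (!is.numeric(bin_size) || bin_size <= 0) {
    stop("bin_size must be > 0", call. = FALSE)
  }
  if (!variable %in% names(bt$data)) {
    stop("no such data column: ", variable, call. = FALSE)
  }
  v <- bt$data[[variable]]
  if (!is.numeric(v)) stop("column '", variable, "' is not numeric",
                           call. = FALSE)
  fun <- switch(aggregator, mean = mean, max = max, sum = sum,
                median = stats::median)
  bt$data |>
    dplyr::mutate(t_bin = floor(.data$t / bin_size) * bin_size) |>
    dplyr::summarise(value = fun(.data[[variable]]),
                     .by = c("id", "t_bin")) |>
    dplyr::arrange(.data$id, .data$t_bin)
}

#' Add zeitgeber time
#'
#' Converts absolute experiment time to zeitgeber time (ZT): hours since
#' lights-on, wrapped to the day length. ZT0 is lights-on; in a 12:12
#' light-dark cycle ZT12 is lights-off.
#'
#' @param bt A [behav_table].
#' @param lights_on_reference Absolute time (seconds) of a lights-on event.
#' @param day_length Day length in seconds (default 86400).
#' @return A `behav_table` whose data gains a `zt` column in
#'   `[0, day_length / 3600)` hours.
#' @export
to_zeitgeber <- function(bt, lights_on_reference = 0, day_length = 86400) {
  stopifnot(inherits(bt, "behav_table"))
  if (day_length <= 0) stop("day_length must be > 0", call. = FALSE)
  data <- dplyr::mutate(
    bt$data,
    zt = ((.data$t - lights_on_reference) %% day_length) / 3600
  )
  rebuild_behav_table(data, bt$meta)
}

#' Remove trailing immobility of dead specimens
#'
#' A specimen whose final stretch of complete immobility extends to its
#' last record and spans at least `immobility_span` seconds is assumed
#' dead from that stretch's onset: those rows are dropped. A specimen losing
#' all its rows stays registered in the metadata.
#'
#' @param bt A [behav_table].
#' @param movement_column Name of a binary (0/1) data column.
#' @param immobility_span Minimum trailing immobility to call death,
#'   seconds (default 86400, i.e. 24 h).
#' @return A curated `behav_table`.
#' @export
curate_dead <- function(bt, movement_column = "moving",
                        immobility_span = 86400) {
  stopifnot(inherits(bt, "behav_table"))
  if (!movement_column %in% names(bt$data)) {
    stop("no such data column: ", movement_column, call. = FALSE)
  }
  mv <- bt$data[[movement_column]]
  if (!all(mv %in% c(0, 1, NA))) {
    stop("column '", movement_column, "' is not binary", call. = FALSE)
  }
  keep <- bt$data |>
    dplyr::mutate(.mv = .data[[movement_column]]) |>
    dplyr::group_by(.data$id) |>
    dplyr::mutate(.keep_row = {
      m <- .data$.mv
      n <- length(m)
      # onset of the trailing run of exact zeros
      still <- !is.na(m) & m == 0
      if (n && still[n]) {
        onset <- n
        while (onset > 1 && still[onset - 1]) onset <- onset - 1
        span <- .data$t[n] - .data$t[onset]
        if (span >= immobility_span) seq_len(n) < onset else rep(TRUE, n)
      } else {
        rep(TRUE, n)
      }
    }) |>
    dplyr::ungroup()
  data <- keep |>
    dplyr::filter(.data$.keep_row) |>
    dplyr::select(-".mv", -".keep_row")
  rebuild_behav_table(data, bt$meta)
}

#' Write / read a behav_table as a pair of CSV files
#'
#' The on-disk interchange form is two plain CSV files in one directory:
#' `data.csv` (id, t, variables) and `meta.csv` (id, descriptors).
#'
#' @param bt A [behav_table].
#' @param dir Directory to write into (created if needed).
#' @return `write_behav_csv` returns `dir` invisibly; `read_behav_csv`
#'   returns a `behav_table`.
#' @export
write_behav_csv <- function(bt, dir) {
  stopifnot(inherits(bt, "behav_table"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(bt$data, file.path(dir, "data.csv"), row.names = FALSE)
  utils::write.csv(bt$meta, file.path(dir, "meta.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_behav_csv
#' @export
read_behav_csv <- function(dir) {
  dfile <- file.path(dir, "data.csv")
  mfile <- file.path(dir, "meta.csv")
  if (!file.exists(dfile) || !file.exists(mfile)) {
    stop("expected data.csv and meta.csv under ", dir, call. = FALSE)
  }
  data <- utils::read.csv(dfile, stringsAsFactors = FALSE)
  meta <- utils::read.csv(mfile, stringsAsFactors = FALSE)
  link_metadata(data, meta)
}
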