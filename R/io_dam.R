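#' Read a DAM-style activity monitor file
#'
#' Drosophila Activity Monitors write tab-delimited text with exactly 42
#' fields per row: a reading index, the date (`dd Mon yy`), the time
#' (`HH:MM:SS`), a status code (1 = valid), six reserved columns, then 32
#' integer beam-crossing counts, one per monitor channel. Rows whose status
#' is not 1 are dropped. Times are converted to seconds relative to the
#' first valid reading.
#'
#' @param path Path to the monitor file.
#' @param channel_map Data frame mapping channels to specimens: a `channel`
#'   column (1..32) plus an `id` column and any further metadata columns.
#' @param interval Reading cadence in seconds (kept as metadata; the
#'   timestamps in the file are authoritative).
#' @return A [behav_table] with one variable, `counts`.
#' @export
read_dam_file <- function(path, channel_map, interval = 60) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  channel_map <- tibble::as_tibble(channel_map)
  if (!all(c("channel", "id") %in% names(channel_map))) {
    stop("channel_map needs columns channel and id", call. = FALSE)
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 42)
  if (length(bad)) {
    stop("line ", bad[1], " has ", nf[bad[1]], " fields (expected 42)",
         call. = FALSE)
  }
  m <- do.call(rbind, fields)
  status <- as.integer(m[, 4])
  valid <- which(status == 1)

  meta <- dplyr::select(channel_map, -"channel")
  meta <- meta[!duplicated(meta$id), , drop = FALSE]

  if (!length(valid)) {
    data <- tibble::tibble(id = character(), t = numeric(), counts = numeric())
    return(link_metadata(data, meta))
  }

  stamp <- as.POSIXct(paste(m[valid, 2], m[valid, 3]),
                      format = "%d %b %y %H:%M:%S", tz = "UTC")
  if (anyNA(stamp)) {
    stop("unparseable date/time at line ", valid[which(is.na(stamp))[1]],
         call. = FALSE)
  }
  t <- as.numeric(stamp) - as.numeric(stamp[1])

  counts <- matrix(as.numeric(m[valid, 11:42, drop = FALSE]),
                   nrow = length(valid))
  if (any(counts < 0, na.rm = TRUE)) {
    stop("negative beam counts", call. = FALSE)
  }
  pieces <- lapply(seq_len(nrow(channel_map)), function(k) {
    ch <- channel_map$channel[k]
    if (ch < 1 || ch > 32) stop("channel out of range: ", ch, call. = FALSE)
    tibble::tibble(id = channel_map$id[k], t = t, counts = counts[, ch])
  })
  link_metadata(dplyr::bind_rows(pieces), meta)
}

#' Write a synthetic population as a DAM-style monitor fixture
#'
#' Aggregates the simulated per-bin movement into beam-count readings at
#' the requested cadence and writes a 42-field tab-delimited monitor file
#' (status 1, reserved columns zero, unused channels zero). The first
#' `min(n specimens, 32)` specimens occupy channels 1 upward.
#'
#' @param sim A `sim_population` (or a [behav_table] with a `moving`
#'   column).
#' @param path Output file path.
#' @param interval Reading interval in seconds (default 60).
#' @param start Timestamp of the first reading, POSIXct (fixed default so
#'   fixtures are reproducible).
#' @return A tibble mapping `channel` to `id` (the map to feed back to
#'   [read_dam_file()]), invisibly.
#' @export
write_fixture_dam_file <- function(sim, path, interval = 60,
                                   start = as.POSIXct("2023-09-20 09:00:00",
                                                      tz = "UTC")) {
  bt <- if (inherits(sim, "sim_population")) sim$bt else sim
  stopifnot(inherits(bt, "behav_table"))
  if (!"moving" %in% names(bt$data)) {
    stop("simulation output lacks a moving column", call. = FALSE)
  }
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("unwritable path: ", path, call. = FALSE)

  ids <- utils::head(bt$meta$id[bt$meta$id %in% bt$data$id], 32)
  binned <- bt$data |>
    dplyr::filter(.data$id %in% ids) |>
    dplyr::mutate(t_bin = floor(.data$t / interval) * interval) |>
    dplyr::summarise(counts = sum(.data$moving), .by = c("id", "t_bin"))
  grid <- sort(unique(binned$t_bin))
  wide <- matrix(0L, nrow = length(grid), ncol = 32)
  for (k in seq_along(ids)) {
    rows <- binned[binned$id == ids[k], ]
    wide[match(rows$t_bin, grid), k] <- as.integer(rows$counts)
  }
  stamp <- start + grid
  lines <- vapply(seq_along(grid), function(i) {
    paste(c(
      i,
      format(stamp[i], "%d %b %y"),
      format(stamp[i], "%H:%M:%S"),
      1L,
      rep(0L, 6),
      wide[i, ]
    ), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(tibble::tibble(channel = seq_along(ids), id = ids))
}
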