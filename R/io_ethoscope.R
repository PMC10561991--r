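#' Read an ethoscope-style SQLite tracking database
#'
#' Ethoscopes record one SQLite file per machine run, holding a `METADATA`
#' key/value table (with at least `machine_name` and `date_time`, the run
#' start as POSIX seconds), a `ROI_MAP` table describing the regions of
#' interest, and one `ROI_<n>` table per region with per-frame rows:
#' `id` (row counter), `t` (milliseconds since the run start), `x`, `y`
#' (pixels) and `xy_dist_log10x1000` (1000 times the log10 of the
#' inter-frame displacement in pixels).
#'
#' Times are converted to seconds, and displacement is de-quantized as
#' `10^(xy_dist_log10x1000 / 1000)`. Each region becomes one specimen with
#' id `"<machine_name>|<region>|<date_time>"` (region zero-padded to two
#' digits). Regions present in `ROI_MAP` but with empty tables appear in
#' the metadata with no data rows.
#'
#' @param path Path to the SQLite file.
#' @param metadata_row Optional single-row data frame of descriptors
#'   (genotype, treatment, ...) copied onto every specimen of this machine.
#' @param regions Optional integer vector restricting which ROI indices to
#'   load.
#' @return A [behav_table] with variables `x`, `y`, `displacement`.
#' @export
read_ethoscope_db <- function(path, metadata_row = NULL, regions = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con), add = TRUE)

  tabs <- DBI::dbListTables(con)
  for (required in c("METADATA", "ROI_MAP")) {
    if (!required %in% tabs) {
      stop("ethoscope database is missing table ", required, call. = FALSE)
    }
  }
  kv <- DBI::dbReadTable(con, "METADATA")
  names(kv) <- tolower(names(kv))
  if (!all(c("field", "value") %in% names(kv))) {
    stop("METADATA must have columns field, value", call. = FALSE)
  }
  get_kv <- function(key) {
    i <- match(key, kv$field)
    if (is.na(i)) stop("METADATA is missing key ", key, call. = FALSE)
    kv$value[i]
  }
  machine <- get_kv("machine_name")
  date_time <- get_kv("date_time")

  roi_map <- DBI::dbReadTable(con, "ROI_MAP")
  if (!"roi_idx" %in% names(roi_map)) {
    stop("ROI_MAP is missing column roi_idx", call. = FALSE)
  }
  idx <- sort(roi_map$roi_idx)
  if (!is.null(regions)) idx <- intersect(idx, regions)

  spec_id <- function(r) sprintf("%s|%02d|%s", machine, r, date_time)
  pieces <- lapply(idx, function(r) {
    tab <- sprintf("ROI_%d", r)
    if (!tab %in% tabs) {
      stop("ROI_MAP lists region ", r, " but table ", tab, " is absent",
           call. = FALSE)
    }
    df <- DBI::dbReadTable(con, tab)
    need <- c("t", "x", "y", "xy_dist_log10x1000")
    miss <- setdiff(need, names(df))
    if (length(miss)) {
      stop(tab, " is missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    if (!nrow(df)) return(NULL)
    tibble::tibble(
      id = spec_id(r),
      t = df$t / 1000,
      x = as.numeric(df$x),
      y = as.numeric(df$y),
      displacement = 10^(df$xy_dist_log10x1000 / 1000)
    )
  })
  data <- dplyr::bind_rows(pieces)
  if (!nrow(data)) {
    data <- tibble::tibble(id = character(), t = numeric(), x = numeric(),
                           y = numeric(), displacement = numeric())
  }

  meta <- tibble::tibble(
    id = vapply(idx, spec_id, character(1)),
    machine_name = machine,
    date_time = date_time,
    region_id = as.integer(idx)
  )
  if (!is.null(metadata_row)) {
    extra <- tibble::as_tibble(metadata_row)
    stopifnot(nrow(extra) == 1)
    extra <- extra[setdiff(names(extra), names(meta))]
    if (ncol(extra)) meta <- dplyr::bind_cols(meta, extra[rep(1, nrow(meta)), ])
  }
  link_metadata(data, meta)
}

#' Write a synthetic population as an ethoscope-style SQLite fixture
#'
#' Emits a file in the dialect read by [read_ethoscope_db()] from a
#' simulated population (see [simulate_population()]): one ROI per
#' specimen, times in integer milliseconds and displacement log-quantized
#' to `round(1000 * log10(displacement))`. Zero displacement is clamped to
#' `1e-6` pixels before quantization so immobile frames survive the log
#' encoding as numerically negligible movement.
#'
#' @param sim A `sim_population` (or any [behav_table] with `x`, `y`,
#'   `displacement` columns).
#' @param path Output file path.
#' @param machine_name,date_time Values stored in the METADATA table.
#' @return `path`, invisibly.
#' @export
write_fixture_ethoscope_db <- function(sim, path,
                                       machine_name = "ETHOSCOPE_001",
                                       date_time = 1700000000) {
  bt <- if (inherits(sim, "sim_population")) sim$bt else sim
  stopifnot(inherits(bt, "behav_table"))
  if (!"displacement" %in% names(bt$data)) {
    stop("simulation output lacks a displacement column", call. = FALSE)
  }
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("unwritable path: ", path, call. = FALSE)
  if (file.exists(path)) file.remove(path)

  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con), add = TRUE)

  DBI::dbWriteTable(con, "METADATA", data.frame(
    field = c("machine_name", "date_time"),
    value = c(machine_name, as.character(date_time)),
    stringsAsFactors = FALSE
  ))

  ids <- bt$meta$id
  roi <- seq_along(ids)
  DBI::dbWriteTable(con, "ROI_MAP", data.frame(
    roi_idx = roi, x = 0L, y = (roi - 1L) * 40L, w = 200L, h = 40L
  ))

  for (k in roi) {
    rows <- bt$data[bt$data$id == ids[k], , drop = FALSE]
    d <- pmax(rows$displacement, 1e-6)
    df <- data.frame(
      id = seq_len(nrow(rows)),
      t = as.integer(round(rows$t * 1000)),
      x = if ("x" %in% names(rows)) rows$x else 0,
      y = if ("y" %in% names(rows)) rows$y else 0,
      xy_dist_log10x1000 = as.integer(round(1000 * log10(d)))
    )
    DBI::dbWriteTable(con, sprintf("ROI_%d", k), df)
  }
  invisible(path)
}
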