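#' Read a generic tabular behavioural file
#'
#' Any table that names an animal, a time, and at least one behavioural
#' variable can enter the pipeline: a CSV of id, t, x, y tracking output,
#' a spreadsheet of food consumed per minute, actigraphy exports, and so
#' on. Columns are renamed to the canonical `id` / `t` scheme and time is
#' converted to seconds.
#'
#' @param path CSV file path.
#' @param id_col,t_col Names of the id and time columns in the file.
#' @param variable_cols Character vector of variable columns to carry
#'   through (default: every other column).
#' @param t_unit Unit of the time column: `"s"`, `"ms"`, `"min"` or `"h"`.
#' @param meta Optional metadata table; if omitted a minimal registry of
#'   the observed ids is built.
#' @return A [behav_table].
#' @export
read_generic_table <- function(path, id_col = "id", t_col = "t",
                               variable_cols = NULL,
                               t_unit = c("s", "ms", "min", "h"),
                               meta = NULL) {
  t_unit <- match.arg(t_unit)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c(id_col, t_col)) {
    if (!col %in% names(raw)) {
      stop("file has no column named '", col, "'", call. = FALSE)
    }
  }
  if (is.null(variable_cols)) {
    variable_cols <- setdiff(names(raw), c(id_col, t_col))
  } else {
    miss <- setdiff(variable_cols, names(raw))
    if (length(miss)) {
      stop("file has no column named '", miss[1], "'", call. = FALSE)
    }
  }
  scale <- c(s = 1, ms = 1e-3, min = 60, h = 3600)[[t_unit]]
  data <- tibble::tibble(
    id = as.character(raw[[id_col]]),
    t = as.numeric(raw[[t_col]]) * scale
  )
  data <- dplyr::bind_cols(data, tibble::as_tibble(raw[variable_cols]))
  if (is.null(meta)) meta <- tibble::tibble(id = unique(data$id))
  link_metadata(data, meta)
}

#' Load an experiment metadata file
#'
#' Reads a CSV keyed by a unique `id` column; every other column is an
#' arbitrary experimental descriptor (genotype, treatment, machine, ...).
#'
#' @param path CSV file path.
#' @return A metadata tibble.
#' @export
load_metadata_file <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                  error = function(e) stop("cannot parse metadata file: ",
                                           conditionMessage(e), call. = FALSE))
  if (!nrow(raw)) stop("metadata file has no rows", call. = FALSE)
  if (!"id" %in% names(raw)) {
    stop("metadata file has no id column", call. = FALSE)
  }
  raw$id <- as.character(raw$id)
  if (anyDuplicated(raw$id)) {
    stop("duplicate metadata ids: ",
         paste(unique(raw$id[duplicated(raw$id)]), collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(raw)
}
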