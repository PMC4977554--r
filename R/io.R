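#' Read a 3D image stack from a multi-page TIFF
#'
#' Reads a single-channel volume written by [write_stack()] (or any grayscale
#' multi-page TIFF). Voxel size is taken from the JSON sidecar
#' (`<path>.json`) written by [write_stack()]; if absent, a
#' `voxel_size_override` must be supplied — the reader never silently assumes
#' pixel units.
#'
#' @param path path to a multi-page TIFF file.
#' @param voxel_size_override optional (dz, dy, dx) in micrometres, used when
#'   no sidecar metadata is present (and taking precedence over it otherwise).
#' @param convention intensity convention, used when no sidecar is present.
#' @return A [volume3d()] (or, if the sidecar marks the file as a mask, the
#'   integer-valued volume still comes back as `volume3d`; use
#'   [label_mask()] to re-wrap).
#' @export
read_stack <- function(path, voxel_size_override = NULL,
                       convention = c("absorption", "fluorescence")) {
  convention <- match.arg(convention)
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "nucmorph_io_error")
  }
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  bps <- attr(pages[[1]], "bits.per.sample") %||% 8L
  if (bps < 32L) {
    # 8/16-bit integer TIFF: take the stored values as they are, not rescaled
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
  }
  if (length(pages) < 2L) {
    abort("TIFF has a single page; a 3D stack is required",
          class = "nucmorph_shape_error")
  }
  if (length(dim(pages[[1]])) != 2L) {
    abort("TIFF pages must be single-channel grayscale",
          class = "nucmorph_shape_error")
  }
  nz <- length(pages)
  ny <- nrow(pages[[1]])
  nx <- ncol(pages[[1]])
  dat <- array(0, c(nz, ny, nx))
  for (z in seq_len(nz)) dat[z, , ] <- pages[[z]]

  meta <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    dat <- dat * meta$scale + meta$offset
    if (!is.null(meta$integer) && isTRUE(meta$integer)) dat <- round(dat)
    if (!is.null(meta$convention)) convention <- meta$convention
  }
  voxel_size <- voxel_size_override %||% meta$voxel_size
  if (is.null(voxel_size)) {
    abort("voxel size not found in metadata and no override given",
          class = "nucmorph_unit_error")
  }
  volume3d(dat, voxel_size, convention)
}

#' Write a 3D volume or mask as a multi-page TIFF
#'
#' Data are stored as 32-bit pages rescaled into `[0, 1]` by a power-of-two
#' scale (and, for signed data, an offset) recorded in a JSON sidecar
#' (`<path>.json`) together with the voxel size and intensity convention.
#' Integer-valued data (masks, label images, quantised intensities) round
#' trip exactly; continuous data round trip to within 2^-32 of the intensity
#' range (about 1e-9 relative), the precision of the 32-bit TIFF samples.
#'
#' @param volume a [volume3d()] or [label_mask()].
#' @param path output file path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_stack <- function(volume, path) {
  is_mask <- inherits(volume, "label_mask")
  if (!is_mask && !inherits(volume, "volume3d")) {
    abort("`volume` must be a volume3d or label_mask", class = "nucmorph_value_error")
  }
  dat <- volume$data
  is_int_data <- is_mask || all(dat == round(dat))
  lo <- min(dat)
  hi <- max(dat)
  offset <- if (lo < 0) lo else 0
  span <- hi - offset
  scale <- if (span <= 0) 1 else 2^ceiling(log2(span))
  scaled <- (dat - offset) / scale
  pages <- lapply(seq_len(dim(dat)[1]), function(z) scaled[z, , ])
  ok <- tryCatch(
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                    reduce = FALSE),
    error = function(e) abort(paste0("cannot write TIFF: ", conditionMessage(e)),
                              class = "nucmorph_io_error")
  )
  meta <- list(
    voxel_size = volume$voxel_size,
    scale = scale,
    offset = offset,
    integer = is_int_data,
    convention = if (is_mask) "absorption" else volume$convention,
    role = if (is_mask) volume$role else NULL
  )
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a mask stack back as a `label_mask`
#' @param path TIFF written by [write_stack()] from a `label_mask`.
#' @param role mask role; defaults to the role recorded in the sidecar.
#' @return A [label_mask()].
#' @export
read_mask <- function(path, role = NULL) {
  v <- read_stack(path)
  sidecar <- paste0(path, ".json")
  if (is.null(role) && file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    role <- meta$role
  }
  if (is.null(role)) role <- "cell"
  label_mask(array(as.integer(round(v$data)), dim(v$data)), v$voxel_size, role)
}

feature_table_cols <- c("cell_id", "condition", "feature", "value", "unit")

#' Construct / validate a feature table
#'
#' The long-format per-cell feature table used across the package: one row
#' per (cell, feature) with columns `cell_id`, `condition`, `feature`,
#' `value`, `unit`. Values are always in physical units (um^3 for volumes);
#' dimensionless features carry unit `""`.
#'
#' @param x a data frame with the five columns above.
#' @return A tibble with validated columns.
#' @export
feature_table <- function(x) {
  missing_cols <- setdiff(feature_table_cols, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("feature table lacks columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "nucmorph_format_error")
  }
  x <- tibble::as_tibble(x)[feature_table_cols]
  dup <- dplyr::count(x, .data$condition, .data$cell_id, .data$feature) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0) {
    abort("duplicate (condition, cell_id, feature) rows in feature table",
          class = "nucmorph_format_error")
  }
  x
}

#' Write / read feature tables as CSV
#'
#' RFC-4180 CSV with header `cell_id,condition,feature,value,unit`. Numeric
#' values survive the round trip to better than 1e-9 relative error (full
#' double precision is written).
#'
#' @param table a feature table (see [feature_table()]).
#' @param path CSV path.
#' @return `path` invisibly; `read_feature_table()` returns a tibble.
#' @export
write_feature_table <- function(table, path) {
  table <- feature_table(table)
  readr::write_csv(table, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "nucmorph_io_error")
  }
  header <- strsplit(readLines(path, n = 1L), ",")[[1]]
  if (!identical(trimws(header), feature_table_cols)) {
    abort("malformed feature table header", class = "nucmorph_format_error")
  }
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    cell_id = readr::col_character(),
                    condition = readr::col_character(),
                    feature = readr::col_character(),
                    value = readr::col_double(),
                    unit = readr::col_character()
                  )) |>
    dplyr::mutate(unit = dplyr::coalesce(.data$unit, ""))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
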