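#' Channel roles recognized in a field
#'
#' Names of the acquisition channels the pipeline understands: HRas and the
#' Golgi/plasma-membrane markers for localization, donor/acceptor/transfer
#' channels for sensitized-emission FRET, and DAPI/MHC for myotube fields.
#' @export
FIELD_ROLES <- c("HRAS_EGFP", "GOLGI_RFP", "PM_WGA",
                 "DONOR", "ACCEPTOR", "FRET", "DAPI", "MHC")

#' Construct a multi-channel field
#'
#' A field is the unit of analysis: one micrograph holding named 2D
#' intensity rasters that share dimensions, plus optional physical pixel
#' size and free-form provenance metadata.
#'
#' @param channels Named list of numeric matrices. Names must be channel
#'   roles from [FIELD_ROLES]; all matrices must have identical dimensions,
#'   finite and nonnegative values.
#' @param pixel_size_um Optional physical pixel edge length in micrometres.
#' @param meta Named list of provenance entries (source path, notes).
#' @return An object of class `field`.
#' @examples
#' f <- new_field(list(DAPI = matrix(0, 8, 8), MHC = matrix(1, 8, 8)))
#' dim(field_channel(f, "MHC"))
#' @export
new_field <- function(channels, pixel_size_um = NULL, meta = list()) {
  if (!is.list(channels) || length(channels) == 0L ||
      is.null(names(channels)) || any(names(channels) == "")) {
    stop_myoquant("`channels` must be a non-empty named list of matrices.",
                  "myoquant_config_error")
  }
  roles <- names(channels)
  if (anyDuplicated(roles)) {
    stop_myoquant("channel roles must be unique within a field.",
                  "myoquant_config_error")
  }
  unknown <- setdiff(roles, FIELD_ROLES)
  if (length(unknown)) {
    stop_myoquant(
      sprintf("unknown channel role(s): %s (recognized: %s)",
              paste(unknown, collapse = ", "),
              paste(FIELD_ROLES, collapse = ", ")),
      "myoquant_config_error")
  }
  ref_dim <- dim(channels[[1L]])
  for (role in roles) {
    m <- channels[[role]]
    if (!is.matrix(m) || !is.numeric(m)) {
      stop_myoquant(sprintf("channel '%s' is not a numeric matrix.", role),
                    "myoquant_config_error")
    }
    if (!identical(dim(m), ref_dim)) {
      stop_myoquant(
        sprintf("channel '%s' has dimensions %dx%d, expected %dx%d.",
                role, nrow(m), ncol(m), ref_dim[1L], ref_dim[2L]),
        "myoquant_dimension_error")
    }
    if (!all(is.finite(m)) || any(m < 0)) {
      stop_myoquant(sprintf("channel '%s' contains non-finite or negative values.",
                            role),
                    "myoquant_config_error")
    }
  }
  if (!is.null(pixel_size_um)) {
    stopifnot(is.numeric(pixel_size_um), length(pixel_size_um) == 1L,
              pixel_size_um > 0)
  }
  structure(list(channels = channels,
                 pixel_size_um = pixel_size_um,
                 meta = meta),
            class = "field")
}

#' @export
print.field <- function(x, ...) {
  d <- dim(x$channels[[1L]])
  cat(sprintf("<field> %dx%d px, channels: %s\n", d[1L], d[2L],
              paste(names(x$channels), collapse = ", ")))
  if (!is.null(x$pixel_size_um)) {
    cat(sprintf("  pixel size: %g um\n", x$pixel_size_um))
  }
  invisible(x)
}

#' Extract a channel raster from a field
#'
#' @param field A [new_field()] object.
#' @param role Channel role name.
#' @return The 2D intensity matrix for that role.
#' @export
field_channel <- function(field, role) {
  stopifnot(inherits(field, "field"))
  if (!role %in% names(field$channels)) {
    stop_myoquant(sprintf("field has no '%s' channel (present: %s).",
                          role, paste(names(field$channels), collapse = ", ")),
                  "myoquant_config_error")
  }
  field$channels[[role]]
}

#' Field dimensions
#' @param field A field.
#' @return Integer vector `(height, width)`.
#' @export
field_dim <- function(field) dim(field$channels[[1L]])

# TIFF helpers ------------------------------------------------------------

read_raster_tiff <- function(path, page = 1L) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (page > length(pages)) {
    stop_myoquant(sprintf("'%s' has %d page(s); page %d requested.",
                          path, length(pages), page),
                  "myoquant_config_error")
  }
  m <- pages[[page]]
  if (length(dim(m)) == 3L) m <- m[, , 1L]  # grayscale stored with extra plane
  m
}

write_rasters_tiff <- function(rasters, path, bits = 16L) {
  maxval <- 2^bits - 1
  prep <- lapply(rasters, function(m) {
    m <- round(m)
    if (any(m < 0) || any(m > maxval)) {
      stop_myoquant(sprintf("raster values outside [0, %d] cannot be written at %d bits.",
                            maxval, bits),
                    "myoquant_config_error")
    }
    m / maxval
  })
  tiff::writeTIFF(prep, path, bits.per.sample = as.integer(bits))
  invisible(path)
}

#' Read a multi-channel field from TIFF files
#'
#' Either one multi-page TIFF (`file` + `roles` giving the role of each
#' page) or a named vector of single-channel files (`paths`, names are
#' roles). Integer rasters round-trip bit-exactly through [write_field()].
#'
#' @param paths Named character vector, role -> file path.
#' @param file Single multi-page TIFF path.
#' @param roles Character vector of roles for the pages of `file`, in page
#'   order.
#' @param pixel_size_um,meta Passed to [new_field()].
#' @return A `field`.
#' @export
read_field <- function(paths = NULL, file = NULL, roles = NULL,
                       pixel_size_um = NULL, meta = list()) {
  if (!is.null(paths)) {
    if (is.null(names(paths)) || any(names(paths) == "")) {
      stop_myoquant("`paths` must be named by channel role.",
                    "myoquant_config_error")
    }
    missing <- paths[!file.exists(paths)]
    if (length(missing)) {
      stop_myoquant(sprintf("input file(s) not found: %s",
                            paste(missing, collapse = ", ")),
                    "myoquant_io_error")
    }
    channels <- lapply(paths, read_raster_tiff)
    meta$source <- unname(paths)
  } else if (!is.null(file)) {
    if (!file.exists(file)) {
      stop_myoquant(sprintf("input file not found: %s", file),
                    "myoquant_io_error")
    }
    pages <- tiff::readTIFF(file, all = TRUE, as.is = TRUE)
    if (is.null(roles)) {
      stop_myoquant("`roles` is required when reading a multi-page file.",
                    "myoquant_config_error")
    }
    if (length(roles) != length(pages)) {
      stop_myoquant(sprintf("'%s' has %d page(s) but %d role(s) were given.",
                            file, length(pages), length(roles)),
                    "myoquant_config_error")
    }
    channels <- setNames(lapply(pages, function(m) {
      if (length(dim(m)) == 3L) m[, , 1L] else m
    }), roles)
    meta$source <- file
  } else {
    stop_myoquant("supply either `paths` or `file`.", "myoquant_config_error")
  }
  # name the offending channel on dimension mismatch
  ref <- dim(channels[[1L]])
  for (role in names(channels)) {
    if (!identical(dim(channels[[role]]), ref)) {
      stop_myoquant(
        sprintf("channel '%s' has dimensions %dx%d, expected %dx%d.",
                role, nrow(channels[[role]]), ncol(channels[[role]]),
                ref[1L], ref[2L]),
        "myoquant_dimension_error")
    }
  }
  new_field(channels, pixel_size_um = pixel_size_um, meta = meta)
}

#' Write a field to a multi-page TIFF
#'
#' Pages are written in channel order; intensities are rounded to the
#' nearest integer (detector counts) and stored at the requested bit depth.
#'
#' @param field A field.
#' @param path Output TIFF path.
#' @param bits Bits per sample (8 or 16).
#' @return `path`, invisibly. A read back with [read_field()] reproduces
#'   integer rasters bit-exactly.
#' @export
write_field <- function(field, path, bits = 16L) {
  stopifnot(inherits(field, "field"))
  write_rasters_tiff(field$channels, path, bits = bits)
  invisible(path)
}

#' Read or write a binary mask as an 8-bit TIFF (0/255)
#'
#' @param mask Logical matrix.
#' @param path TIFF path.
#' @return `write_mask()` returns `path` invisibly; `read_mask()` returns a
#'   logical matrix. The round trip is lossless.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.logical(mask), is.matrix(mask))
  write_rasters_tiff(list(mask * 255L), path, bits = 8L)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  read_raster_tiff(path) > 0L
}
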