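## Plate addressing, the filename convention, TIFF readers/writers, and
## z-stack assembly.
##
## Filename grammar (version 1, fixed):
##   <plateID>_<prescan|rescan>_<RowCol>_<BF|GFP470>_Z<three-digit z>.tif
## e.g. "P01_rescan_B05_GFP470_Z012.tif".  plateID is one or more
## alphanumeric characters; RowCol is a row letter A-H plus a zero-padded
## 1-12 column; z is 0-based.  Real-instrument naming schemes can be
## supported by writing an alternative parser that returns the same record.

PLATE_ROWS <- LETTERS[1:8]
PLATE_COLS <- 1:12
CHANNELS <- c("BF", "GFP470")
SCAN_PHASES <- c("prescan", "rescan")

#' Construct a 96-well address
#'
#' @param row row letter, one of A-H.
#' @param column column number, 1-12.
#' @return object of class `well_address` with fields `row`, `column`.
#' @examples
#' well_address("B", 5)
#' parse_well("B05")
#' @export
well_address <- function(row, column) {
  row <- toupper(as.character(row))
  column <- as.integer(column)
  if (length(row) != 1L || !row %in% PLATE_ROWS) {
    stop(sprintf("invalid plate row '%s' (must be A-H)", row), call. = FALSE)
  }
  if (length(column) != 1L || is.na(column) || !column %in% PLATE_COLS) {
    stop(sprintf("invalid plate column '%s' (must be 1-12)", column), call. = FALSE)
  }
  structure(list(row = row, column = column), class = "well_address")
}

#' @rdname well_address
#' @param x canonical well string such as "A01".
#' @export
parse_well <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (!grepl("^[A-Ha-h][0-9]{2}$", x)) {
    stop(sprintf("malformed well '%s' (expect e.g. 'A01')", x), call. = FALSE)
  }
  well_address(substr(x, 1, 1), as.integer(substr(x, 2, 3)))
}

#' @rdname well_address
#' @param well a `well_address`.
#' @export
format_well <- function(well) {
  stopifnot(inherits(well, "well_address"))
  sprintf("%s%02d", well$row, well$column)
}

#' @export
format.well_address <- function(x, ...) format_well(x)

#' @export
print.well_address <- function(x, ...) {
  cat("<well ", format_well(x), ">\n", sep = "")
  invisible(x)
}

#' All 96 wells in row-major order
#' @return character vector "A01".."H12".
#' @export
plate_wells <- function() {
  as.vector(t(outer(PLATE_ROWS, PLATE_COLS, function(r, c) sprintf("%s%02d", r, c))))
}

#' Encode an image file name
#'
#' @param plate plate identifier (alphanumeric).
#' @param phase "prescan" or "rescan".
#' @param well a `well_address` or canonical well string.
#' @param channel "BF" or "GFP470".
#' @param z 0-based z index (0-999).
#' @return file name string.
#' @export
format_filename <- function(plate, phase, well, channel, z) {
  if (is.character(well)) well <- parse_well(well)
  stopifnot(grepl("^[A-Za-z0-9]+$", plate))
  phase <- match.arg(phase, SCAN_PHASES)
  channel <- match.arg(channel, CHANNELS)
  z <- as.integer(z)
  stopifnot(z >= 0L, z <= 999L)
  sprintf("%s_%s_%s_%s_Z%03d.tif", plate, phase, format_well(well), channel, z)
}

#' Decode an image file name
#'
#' Inverse of [format_filename()]; errors name the offending field.
#'
#' @param name file name (directories are stripped).
#' @return list with fields `plate`, `scan_phase`, `well`, `channel`,
#'   `z_index`, `path` (the input).
#' @export
parse_filename <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  base <- basename(name)
  m <- regmatches(base, regexec(
    "^([A-Za-z0-9]+)_([a-z]+)_([A-Za-z][0-9]{2})_([A-Za-z0-9]+)_Z([0-9]{3})\\.tif$",
    base))[[1]]
  if (length(m) == 0L) {
    stop(sprintf("malformed image file name '%s'", base), call. = FALSE)
  }
  phase <- m[3]
  if (!phase %in% SCAN_PHASES) {
    stop(sprintf("invalid scan phase '%s' in '%s'", phase, base), call. = FALSE)
  }
  well <- tryCatch(parse_well(m[4]),
                   error = function(e) stop(sprintf("invalid well '%s' in '%s': %s",
                                                    m[4], base, conditionMessage(e)),
                                            call. = FALSE))
  if (!m[5] %in% CHANNELS) {
    stop(sprintf("invalid channel '%s' in '%s'", m[5], base), call. = FALSE)
  }
  list(plate = m[2], scan_phase = phase, well = well, channel = m[5],
       z_index = as.integer(m[6]), path = name)
}

#' Read a single-plane grayscale TIFF
#'
#' 16-bit grayscale is the native pixel format; 8-bit inputs are promoted to
#' 16-bit (x257) with a warning.  RGB or other multi-sample files are
#' rejected.
#'
#' @param path file path.
#' @return numeric matrix of counts in 0..65535.
#' @export
read_tiff <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  raw <- tryCatch(tiff::readTIFF(path, info = TRUE),
                  error = function(e) stop(sprintf("unreadable TIFF %s: %s",
                                                   path, conditionMessage(e)),
                                           call. = FALSE))
  if (length(dim(raw)) == 3L) {
    stop(sprintf("%s is not single-channel grayscale (%d samples/pixel)",
                 path, dim(raw)[3]), call. = FALSE)
  }
  bits <- attr(raw, "bits.per.sample")
  img <- matrix(round(raw * 65535), nrow(raw), ncol(raw))
  if (!is.null(bits) && bits == 8) {
    warning(sprintf("%s is 8-bit; promoted to 16-bit", path))
  }
  img
}

#' Write a single-plane 16-bit grayscale TIFF
#'
#' @param img numeric matrix, values 0..65535.
#' @param path destination; refuses to overwrite unless `force`.
#' @param force overwrite an existing file.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(img, path, force = FALSE) {
  check_image(img)
  if (file.exists(path) && !force) {
    stop(sprintf("refusing to overwrite %s (use force = TRUE)", path), call. = FALSE)
  }
  img <- clamp16(round(img))
  tiff::writeTIFF(img / 65535, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Construct a z-stack
#'
#' An ordered list of same-shape single-channel planes with physical z
#' spacing and lateral pixel size.
#'
#' @param planes list of numeric matrices (ascending z) or a single matrix.
#' @param dz_um slice spacing in micrometres (> 0).
#' @param pixel_size_um lateral pixel size in micrometres (> 0).
#' @param channel "BF" or "GFP470".
#' @return object of class `zstack`.
#' @export
zstack <- function(planes, dz_um, pixel_size_um, channel = "GFP470") {
  if (is.matrix(planes)) planes <- list(planes)
  stopifnot(is.list(planes), length(planes) >= 1L)
  lapply(planes, check_image, what = "z plane")
  shp <- dim(planes[[1]])
  same <- vapply(planes, function(p) identical(dim(p), shp), logical(1))
  if (!all(same)) stop("z planes differ in shape", call. = FALSE)
  stopifnot(dz_um > 0, pixel_size_um > 0)
  channel <- match.arg(channel, CHANNELS)
  structure(list(planes = planes, dz_um = dz_um,
                 pixel_size_um = pixel_size_um, channel = channel),
            class = "zstack")
}

#' @export
length.zstack <- function(x) length(x$planes)

#' @export
print.zstack <- function(x, ...) {
  cat(sprintf("<zstack %s: %d plane(s) of %dx%d, dz=%g um, px=%g um>\n",
              x$channel, length(x$planes), nrow(x$planes[[1]]),
              ncol(x$planes[[1]]), x$dz_um, x$pixel_size_um))
  invisible(x)
}

#' List and decode the image files of a plate directory
#'
#' @param dir directory of TIFFs named by the package convention.
#' @return data.frame with columns `path`, `plate`, `scan_phase`, `well`
#'   (canonical string), `channel`, `z_index`.
#' @export
list_plate_dir <- function(dir) {
  stopifnot(dir.exists(dir))
  paths <- sort(list.files(dir, pattern = "\\.tif$", full.names = TRUE))
  recs <- lapply(paths, parse_filename)
  data.frame(
    path = paths,
    plate = vapply(recs, `[[`, "", "plate"),
    scan_phase = vapply(recs, `[[`, "", "scan_phase"),
    well = vapply(recs, function(r) format_well(r$well), ""),
    channel = vapply(recs, `[[`, "", "channel"),
    z_index = vapply(recs, `[[`, 0L, "z_index"),
    stringsAsFactors = FALSE)
}

#' Assemble single-plane files into a z-stack
#'
#' Selects the records matching (well, channel, phase), checks the z indices
#' are contiguous from 0, reads the planes and returns them in ascending z.
#'
#' @param records data.frame as returned by [list_plate_dir()].
#' @param well canonical well string or `well_address`.
#' @param channel "BF" or "GFP470".
#' @param phase "prescan" or "rescan".
#' @param dz_um,pixel_size_um physical calibration attached to the stack.
#' @return a [zstack()].
#' @export
assemble_stack <- function(records, well, channel, phase,
                           dz_um = 4, pixel_size_um = 0.65) {
  if (inherits(well, "well_address")) well <- format_well(well)
  channel <- match.arg(channel, CHANNELS)
  phase <- match.arg(phase, SCAN_PHASES)
  sel <- records[records$well == well & records$channel == channel &
                   records$scan_phase == phase, , drop = FALSE]
  if (nrow(sel) == 0L) {
    stop(sprintf("no %s/%s files for well %s", phase, channel, well), call. = FALSE)
  }
  sel <- sel[order(sel$z_index), , drop = FALSE]
  want <- seq(0L, max(sel$z_index))
  missing <- setdiff(want, sel$z_index)
  if (length(missing) > 0L || min(sel$z_index) != 0L) {
    stop(sprintf("z index gap for well %s %s/%s: missing %s", well, phase,
                 channel, paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(sel$z_index)) {
    stop(sprintf("duplicate z indices for well %s %s/%s", well, phase, channel),
         call. = FALSE)
  }
  planes <- lapply(sel$path, read_tiff)
  zstack(planes, dz_um = dz_um, pixel_size_um = pixel_size_um, channel = channel)
}

#' Write a z-stack as one multilayer TIFF
#'
#' @param stack a [zstack()].
#' @param path destination path.
#' @param force overwrite an existing file.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, force = FALSE) {
  stopifnot(inherits(stack, "zstack"))
  if (file.exists(path) && !force) {
    stop(sprintf("refusing to overwrite %s (use force = TRUE)", path), call. = FALSE)
  }
  tiff::writeTIFF(lapply(stack$planes, function(p) clamp16(round(p)) / 65535),
                  path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}
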