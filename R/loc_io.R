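# Localization table I/O, ROI files and 2D histogram rendering.

#' Describe a localization-table dialect
#'
#' Maps the package's canonical event fields onto the column names of a
#' delimited localization file and declares the coordinate unit. The default
#' is the ThunderSTORM-style comma-separated header with bracketed units.
#'
#' @param x,y,z,frame,channel column names in the file; set to NULL for
#'   columns the file does not carry (x and y are mandatory).
#' @param unit coordinate unit of the file: "nm", "um", or "px" (camera
#'   pixels; requires `pixelPitch`).
#' @param pixelPitch nm per camera pixel, required when `unit = "px"`.
#' @param sep field separator.
#' @return a list describing the dialect.
#' @export
locDialect <- function(x = "x [nm]", y = "y [nm]", z = "z [nm]",
                       frame = "frame", channel = "channel",
                       unit = c("nm", "um", "px"), pixelPitch = NULL,
                       sep = ",") {
  unit <- match.arg(unit)
  if (unit == "px" && is.null(pixelPitch))
    stop("unit 'px' requires a pixelPitch (nm per camera pixel)")
  list(x = x, y = y, z = z, frame = frame, channel = channel,
       unit = unit, pixelPitch = pixelPitch, sep = sep)
}

unitFactor <- function(dialect) {
  switch(dialect$unit, nm = 1, um = 1000, px = dialect$pixelPitch)
}

#' Read a localization table
#'
#' Reads a delimited single-molecule localization file and converts all
#' coordinates to nanometers. Row order is preserved; columns not named in
#' the dialect are ignored.
#'
#' @param path path to the delimited text file.
#' @param dialect a [locDialect()] describing column names and units.
#' @return a [LocalizationTable-class].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("x [nm],y [nm]", "0,0", "10,20"), f)
#' readLocalizations(f)
#' @export
readLocalizations <- function(path, dialect = locDialect()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = dialect$sep,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "")
  for (col in c("x", "y")) {
    if (is.null(dialect[[col]]) || !dialect[[col]] %in% names(raw))
      stop(sprintf("format error: missing mandatory column '%s' (mapped to '%s')",
                   col, if (is.null(dialect[[col]])) "<unset>" else dialect[[col]]))
  }
  numCol <- function(field) {
    nm <- dialect[[field]]
    if (is.null(nm) || !nm %in% names(raw)) return(NULL)
    txt <- raw[[nm]]
    val <- suppressWarnings(as.numeric(txt))
    bad <- which(is.na(val) & !is.na(txt) & nzchar(trimws(txt)))
    if (length(bad))
      stop(sprintf("parse error: non-numeric value '%s' in column '%s', row %d",
                   txt[bad[1]], nm, bad[1]))
    val
  }
  k <- unitFactor(dialect)
  x <- numCol("x") * k
  y <- numCol("y") * k
  z <- numCol("z")
  if (!is.null(z)) z <- z * k
  frame <- numCol("frame")
  channel <- if (!is.null(dialect$channel) && dialect$channel %in% names(raw))
    raw[[dialect$channel]] else NULL
  LocalizationTable(x = x, y = y, z = z, frame = frame, channel = channel)
}

#' Write a localization table
#'
#' Writes events as delimited text using the dialect's column names (always
#' in nm, regardless of the dialect's declared read unit), so that
#' `readLocalizations()` reproduces the table.
#'
#' @param table a [LocalizationTable-class].
#' @param path output file path.
#' @param dialect a [locDialect()]; only its column names and separator are
#'   used.
#' @return the output path, invisibly.
#' @export
writeLocalizations <- function(table, path, dialect = locDialect()) {
  stopifnot(is(table, "LocalizationTable"))
  ev <- table@events
  out <- data.frame(row.names = seq_len(nrow(ev)))
  out[[dialect$x]] <- ev$x
  out[[dialect$y]] <- ev$y
  if ("z" %in% names(ev)) out[[dialect$z]] <- ev$z
  if ("frame" %in% names(ev)) out[[dialect$frame]] <- ev$frame
  if ("channel" %in% names(ev)) out[[dialect$channel]] <- ev$channel
  ok <- tryCatch({
    utils::write.table(out, path, sep = dialect$sep, row.names = FALSE,
                       quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("I/O error writing ", path, ": ", conditionMessage(ok))
  invisible(path)
}

#' Render localizations as a 2D histogram image
#'
#' Bins events into square pixels using half-open intervals
#' `[edge, edge + pixelSize)` with the origin at the lower-left corner of the
#' extent; an event exactly on an interior edge belongs to the higher-index
#' pixel. Events outside the extent are dropped and counted, not an error.
#' The default single-color rendering uses 15 nm pixels; multicolor data are
#' conventionally rendered at 5 nm.
#'
#' @param table a [LocalizationTable-class].
#' @param pixelSize pixel edge in nm (default 15).
#' @param extent numeric c(xmin, xmax, ymin, ymax) nm; default snaps the data
#'   bounding box outward to whole pixels.
#' @return an [ImageGrid-class]; `sum(counts)` plus the dropped count equals
#'   the number of events.
#' @export
renderHistogram <- function(table, pixelSize = 15, extent = NULL) {
  stopifnot(is(table, "LocalizationTable"), pixelSize > 0)
  ev <- table@events
  if (is.null(extent)) {
    if (!nrow(ev)) stop("cannot infer an extent from an empty table")
    extent <- c(floor(min(ev$x) / pixelSize) * pixelSize,
                ceiling((max(ev$x) + 1e-9) / pixelSize) * pixelSize,
                floor(min(ev$y) / pixelSize) * pixelSize,
                ceiling((max(ev$y) + 1e-9) / pixelSize) * pixelSize)
  }
  stopifnot(length(extent) == 4, extent[2] > extent[1], extent[4] > extent[3])
  nx <- max(1L, as.integer(ceiling((extent[2] - extent[1]) / pixelSize - 1e-9)))
  ny <- max(1L, as.integer(ceiling((extent[4] - extent[3]) / pixelSize - 1e-9)))
  ix <- floor((ev$x - extent[1]) / pixelSize)
  iy <- floor((ev$y - extent[3]) / pixelSize)
  keep <- ix >= 0 & ix < nx & iy >= 0 & iy < ny
  counts <- matrix(0L, nrow = ny, ncol = nx)
  if (any(keep)) {
    tab <- table(factor(iy[keep] + 1L, levels = seq_len(ny)),
                 factor(ix[keep] + 1L, levels = seq_len(nx)))
    counts <- matrix(as.integer(tab), nrow = ny, ncol = nx)
  }
  new("ImageGrid", pixelSize = pixelSize, origin = c(extent[1], extent[3]),
      counts = counts, nDropped = as.integer(sum(!keep)))
}

#' Write an ImageGrid as a 16-bit grayscale TIFF with a JSON sidecar
#'
#' The sidecar (same path with ".json" appended) records pixel size, origin,
#' image dimensions and the dropped-event count, so renderings remain
#' spatially interpretable.
#'
#' @param grid an [ImageGrid-class].
#' @param path output TIFF path.
#' @return the TIFF path, invisibly.
#' @export
writeImageGrid <- function(grid, path) {
  stopifnot(is(grid, "ImageGrid"))
  img <- pmin(grid@counts, 65535L)
  # top row of a TIFF is the highest y; counts store the bottom row first
  img <- img[rev(seq_len(nrow(img))), , drop = FALSE]
  tiff::writeTIFF(img / 65535, path, bits.per.sample = 16L)
  sidecar <- list(pixel_size_nm = grid@pixelSize,
                  origin_nm = grid@origin,
                  size_px = c(ncol(grid@counts), nrow(grid@counts)),
                  n_events = sum(grid@counts), n_dropped = grid@nDropped)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read / write a polygonal ROI as JSON
#'
#' The on-disk format is a JSON array of `[x, y]` vertex pairs in nm.
#'
#' @param path JSON file path.
#' @return `readRoi`: an [RoiPolygon-class].
#' @export
readRoi <- function(path) {
  v <- jsonlite::read_json(path, simplifyVector = TRUE)
  RoiPolygon(matrix(as.numeric(unlist(v)), ncol = 2, byrow = is.list(v)))
}

#' @rdname readRoi
#' @param roi an [RoiPolygon-class].
#' @export
writeRoi <- function(roi, path) {
  stopifnot(is(roi, "RoiPolygon"))
  jsonlite::write_json(unname(apply(roi@vertices, 1, as.numeric,
                                    simplify = FALSE)),
                       path, digits = NA)
  invisible(path)
}
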