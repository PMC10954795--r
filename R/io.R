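# Text-based readers/writers for the workflow's artifacts: ESRI ASCII grids
# for rasters, GeoJSON for vector layers, CSV for fixes and tables.

#' Write a matrix as an ESRI ASCII grid
#'
#' Row 1 of the matrix is the northern edge, matching the grid convention
#' used throughout the package.
#'
#' @param mat numeric matrix.
#' @param path output file.
#' @param xmin,ymin lower-left corner of the grid (metres).
#' @param cell_size cell size (metres).
#' @param nodata value written for NA cells (default -9999).
#' @export
write_ascii_grid <- function(mat, path, xmin = 0, ymin = 0, cell_size = 10,
                             nodata = -9999) {
  hdr <- c(paste("ncols", ncol(mat)), paste("nrows", nrow(mat)),
           paste("xllcorner", xmin), paste("yllcorner", ymin),
           paste("cellsize", cell_size), paste("NODATA_value", nodata))
  m <- mat
  m[is.na(m)] <- nodata
  body <- apply(m, 1L, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file written by [write_ascii_grid()] (or any ESRI ASCII
#'   grid).
#' @return list with `mat` (NA where nodata), `xmin`, `ymin`, `cell_size`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  keys <- tolower(vapply(hdr, `[`, "", 1L))
  vals <- as.numeric(vapply(hdr, `[`, "", 2L))
  names(vals) <- keys
  body <- lines[-(1:6)]
  mat <- do.call(rbind, lapply(body, function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1L]])))
  mat[mat == vals["nodata_value"]] <- NA
  list(mat = mat, xmin = unname(vals["xllcorner"]),
       ymin = unname(vals["yllcorner"]), cell_size = unname(vals["cellsize"]))
}

#' Write points or a polygon as GeoJSON
#'
#' @param path output file.
#' @param polygon optional closed vertex matrix (one Polygon feature).
#' @param points optional data.frame with `x`, `y` and any attribute
#'   columns (one Point feature per row).
#' @export
write_geojson <- function(path, polygon = NULL, points = NULL) {
  feats <- list()
  if (!is.null(polygon)) {
    p <- close_polygon(polygon)
    coords <- lapply(seq_len(nrow(p)), function(i) c(p[i, 1L], p[i, 2L]))
    feats[[length(feats) + 1L]] <- list(
      type = "Feature", properties = list(name = "fence"),
      geometry = list(type = "Polygon", coordinates = list(coords)))
  }
  if (!is.null(points)) {
    attrs <- setdiff(names(points), c("x", "y"))
    for (i in seq_len(nrow(points))) {
      props <- as.list(points[i, attrs, drop = FALSE])
      feats[[length(feats) + 1L]] <- list(
        type = "Feature", properties = props,
        geometry = list(type = "Point",
                        coordinates = c(points$x[i], points$y[i])))
    }
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write GPS fixes to CSV
#'
#' Schema: `animal_id,timestamp_iso8601,x,y,ehpe_cm`.
#'
#' @param fixes data.frame with `animal_id, timestamp, x, y, ehpe_cm`.
#' @param path output file.
#' @export
write_fixes_csv <- function(fixes, path) {
  out <- data.frame(
    animal_id = fixes$animal_id,
    timestamp_iso8601 = format(fixes$timestamp, "%Y-%m-%dT%H:%M:%SZ",
                               tz = "UTC"),
    x = fixes$x, y = fixes$y, ehpe_cm = fixes$ehpe_cm)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read GPS fixes from CSV
#'
#' @param path file in the [write_fixes_csv()] schema.
#' @return data.frame with POSIXct timestamps (UTC).
#' @export
read_fixes_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  data.frame(animal_id = d$animal_id,
             timestamp = as.POSIXct(d$timestamp_iso8601,
                                    format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
             x = d$x, y = d$y, ehpe_cm = d$ehpe_cm)
}

#' Study-site reference tables bundled with the package
#'
#' Small published summaries of the study system used as workflow inputs:
#' `"cover"` — surface (ha) and frequency (%) of the five cover classes;
#' `"periods"` — the seven sampling periods with fix rates, valid position
#' totals, EHPE summaries and collared animal counts; `"final_model"` — the
#' reported seasonal coefficients of the final RSPF model.
#'
#' @param which one of "cover", "periods", "final_model".
#' @return data.frame.
#' @export
reference_table <- function(which = c("cover", "periods", "final_model")) {
  which <- match.arg(which)
  file <- switch(which, cover = "cover_classes.csv",
                 periods = "sampling_periods.csv",
                 final_model = "final_model_coefficients.csv")
  utils::read.csv(system.file("extdata", file, package = "cattleRSPF"),
                  stringsAsFactors = FALSE)
}
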