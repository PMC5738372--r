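#' OCT B-scan container
#'
#' A 2-D intensity image with physical pixel spacing. Row 1 is the
#' shallowest depth; depth increases with the row index; columns are lateral
#' position. Intensities may be in the `linear` backscatter domain (used for
#' attenuation fitting) or the `log`-compressed 8-bit display domain (used
#' for texture statistics).
#'
#' @param pixels Numeric matrix (>= 8 x 8), non-negative when `linear`.
#' @param axial_spacing_um Depth spacing per row, um.
#' @param lateral_spacing_um Lateral spacing per column, um.
#' @param intensity_domain `"linear"` or `"log"`.
#' @param id Identifier string.
#' @return An object of class `bscan`.
#' @export
bscan <- function(pixels, axial_spacing_um, lateral_spacing_um,
                  intensity_domain = c("linear", "log"), id = "bscan") {
  intensity_domain <- match.arg(intensity_domain)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop_dermoct("pixels must be a numeric matrix", "invalid_parameter")
  if (nrow(pixels) < 8L || ncol(pixels) < 8L)
    stop_dermoct("B-scan must be at least 8 x 8 pixels", "invalid_parameter")
  check_positive(axial_spacing_um, "axial_spacing_um")
  check_positive(lateral_spacing_um, "lateral_spacing_um")
  if (intensity_domain == "linear" && any(pixels < 0))
    stop_dermoct("linear-domain B-scan must be non-negative", "invalid_parameter")
  structure(list(pixels = pixels,
                 axial_spacing_um = as.numeric(axial_spacing_um),
                 lateral_spacing_um = as.numeric(lateral_spacing_um),
                 intensity_domain = intensity_domain,
                 id = as.character(id)),
            class = "bscan")
}

#' @export
print.bscan <- function(x, ...) {
  cat(sprintf("OCT B-scan '%s': %d x %d px (%.3g x %.3g mm), %s domain\n",
              x$id, nrow(x$pixels), ncol(x$pixels),
              nrow(x$pixels) * x$axial_spacing_um / 1000,
              ncol(x$pixels) * x$lateral_spacing_um / 1000,
              x$intensity_domain))
  invisible(x)
}

#' @export
dim.bscan <- function(x) dim(x$pixels)

#' @export
plot.bscan <- function(x, ...) {
  px <- x$pixels
  if (x$intensity_domain == "linear") px <- log10(px + 1e-6)
  graphics::image(t(px)[, nrow(px):1], col = gray.colors(256), axes = FALSE,
                  main = x$id, ...)
  invisible(x)
}

#' Rectangular region of interest within a B-scan
#'
#' Indices are 1-based; the ROI covers rows `top_row .. top_row+height_px-1`
#' and columns `left_col .. left_col+width_px-1`.
#'
#' @param top_row,left_col Top-left corner (1-based).
#' @param height_px,width_px Extent in pixels.
#' @param layer One of `"epidermis"`, `"dermis"`, `"lesion"`, `"surround"`.
#' @param site Body-site tag.
#' @param class_label Class label (e.g. `"healthy"`, `"lesion"`, `"BCC"`).
#' @param subject_id Subject identifier.
#' @return An object of class `oct_roi`.
#' @export
roi <- function(top_row, left_col, height_px, width_px,
                layer = "lesion", site = "unknown",
                class_label = "healthy", subject_id = "s0") {
  structure(list(top_row = check_count(top_row, "top_row"),
                 left_col = check_count(left_col, "left_col"),
                 height_px = check_count(height_px, "height_px", 1L),
                 width_px = check_count(width_px, "width_px", 1L),
                 layer = as.character(layer), site = as.character(site),
                 class_label = as.character(class_label),
                 subject_id = as.character(subject_id)),
            class = "oct_roi")
}

roi_inside <- function(r, b) {
  r$top_row >= 1L && r$left_col >= 1L &&
    r$top_row + r$height_px - 1L <= nrow(b$pixels) &&
    r$left_col + r$width_px - 1L <= ncol(b$pixels)
}

roi_pixels <- function(b, r) {
  if (!roi_inside(r, b))
    stop_dermoct("ROI does not lie inside the B-scan", "invalid_parameter")
  b$pixels[r$top_row:(r$top_row + r$height_px - 1L),
           r$left_col:(r$left_col + r$width_px - 1L), drop = FALSE]
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Read a grayscale OCT image from TIFF or PNG
#'
#' Pixel values are preserved exactly as stored. If a JSON sidecar written by
#' [save_bscan()] sits next to the image, its metadata (spacing, domain, id,
#' intensity scale) overrides the arguments.
#'
#' @param path Image file (.tif/.tiff/.png), single-channel grayscale.
#' @param axial_spacing_um,lateral_spacing_um Pixel spacing in um; required
#'   unless a sidecar provides them.
#' @param intensity_domain Intensity domain flag, default `"linear"`.
#' @return A [bscan()].
#' @export
load_bscan <- function(path, axial_spacing_um = NULL, lateral_spacing_um = NULL,
                       intensity_domain = "linear") {
  if (!file.exists(path))
    stop_dermoct(sprintf("file not found: %s", path), "io_error")
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                tif = , tiff = tiff::readTIFF(path),
                png = png::readPNG(path),
                stop_dermoct("unsupported image format (use TIFF or PNG)",
                             "unsupported_format"))
  if (length(dim(raw)) == 3L) {
    if (dim(raw)[3] == 1L) raw <- raw[, , 1L]
    else stop_dermoct("multi-channel color images are not supported",
                      "unsupported_format")
  }
  scale <- 65535
  if (ext == "png") scale <- 255
  meta <- NULL
  sp <- sidecar_path(path)
  if (file.exists(sp)) meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  if (!is.null(meta)) {
    axial_spacing_um <- meta$axial_spacing_um %||% axial_spacing_um
    lateral_spacing_um <- meta$lateral_spacing_um %||% lateral_spacing_um
    intensity_domain <- meta$intensity_domain %||% intensity_domain
    scale <- (meta$bit_max %||% scale)
    istretch <- meta$intensity_scale %||% 1
  } else istretch <- 1
  if (is.null(axial_spacing_um) || is.null(lateral_spacing_um))
    stop_dermoct("pixel spacing missing: pass spacings or provide a sidecar",
                 "missing_metadata")
  px <- round(raw * scale) * istretch
  b <- bscan(px, axial_spacing_um, lateral_spacing_um, intensity_domain,
             id = meta$id %||% tools::file_path_sans_ext(basename(path)))
  b
}

#' Write a B-scan as a 16-bit grayscale TIFF (or PNG) plus JSON sidecar
#'
#' Intensities are stored as 16-bit integers after division by an intensity
#' scale chosen so the image maximum maps near the top of the range (scale 1
#' when the data already fit); the scale, spacings, domain and id go to a
#' JSON sidecar so [load_bscan()] restores the stored values exactly.
#'
#' @param b A [bscan()].
#' @param path Destination path ending in .tif/.tiff or .png.
#' @param extra Optional named list merged into the sidecar (e.g. ground
#'   truth from the simulator).
#' @return Invisibly, the sidecar path.
#' @export
save_bscan <- function(b, path, extra = NULL) {
  stopifnot(inherits(b, "bscan"))
  ext <- tolower(tools::file_ext(path))
  px <- b$pixels
  mx <- max(px)
  bit_max <- if (ext == "png") 255 else 65535
  istretch <- if (mx <= bit_max && all(px == round(px))) 1 else mx / bit_max
  if (istretch == 0) istretch <- 1
  stored <- round(px / istretch)
  ok <- switch(ext,
    tif = , tiff = tiff::writeTIFF(stored / 65535, path, bits.per.sample = 16L),
    png = png::writePNG(stored / 255, path),
    stop_dermoct("unsupported image format (use TIFF or PNG)", "unsupported_format"))
  if (isFALSE(ok)) stop_dermoct(sprintf("could not write %s", path), "io_error")
  meta <- c(list(id = b$id,
                 axial_spacing_um = b$axial_spacing_um,
                 lateral_spacing_um = b$lateral_spacing_um,
                 intensity_domain = b$intensity_domain,
                 bit_max = bit_max,
                 intensity_scale = istretch), extra)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(sidecar_path(path))
}

metadata_cols <- c("subject_id", "site", "layer", "class_label",
                   "roi_top", "roi_left", "roi_height", "roi_width")

#' Assemble a feature table from ROIs and their feature vectors
#'
#' @param vectors List of named numeric vectors (identical names/order),
#'   as returned by [assemble_feature_vector()].
#' @param rois List of [roi()] objects, same length.
#' @return A data.frame of class `feature_table`: metadata columns
#'   (`subject_id`, `site`, `layer`, `class_label`, ROI coordinates) followed
#'   by one column per feature; the feature schema is kept in
#'   `attr(, "feature_names")`.
#' @export
feature_table <- function(vectors, rois) {
  if (length(vectors) == 0L)
    stop_dermoct("empty feature table", "schema_error")
  schema <- names(vectors[[1]])
  same <- vapply(vectors, function(v) identical(names(v), schema), logical(1))
  if (!all(same))
    stop_dermoct("inconsistent feature schemas across ROIs", "schema_error")
  if (length(rois) != length(vectors))
    stop_dermoct("one ROI per feature vector required", "schema_error")
  meta <- do.call(rbind, lapply(rois, function(r)
    data.frame(subject_id = r$subject_id, site = r$site, layer = r$layer,
               class_label = r$class_label, roi_top = r$top_row,
               roi_left = r$left_col, roi_height = r$height_px,
               roi_width = r$width_px, stringsAsFactors = FALSE)))
  feats <- do.call(rbind, lapply(vectors, function(v) as.data.frame(t(v))))
  out <- cbind(meta, feats)
  as_feature_table(out, schema)
}

as_feature_table <- function(df, feature_names) {
  attr(df, "feature_names") <- feature_names
  class(df) <- c("feature_table", "data.frame")
  df
}

feature_matrix <- function(table) {
  as.matrix(table[, attr(table, "feature_names"), drop = FALSE])
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d ROIs x %d features (%s...)\n",
              nrow(x), length(attr(x, "feature_names")),
              paste(utils::head(attr(x, "feature_names"), 3), collapse = ", ")))
  invisible(x)
}

#' Write a feature table to CSV
#'
#' One header row (metadata columns then feature names in schema order) and
#' one row per ROI; numeric fields at full double precision.
#'
#' @param table A `feature_table`.
#' @param path Destination CSV path.
#' @export
write_feature_table <- function(table, path) {
  if (!inherits(table, "feature_table"))
    stop_dermoct("not a feature_table", "schema_error")
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' The feature schema is taken from the header: every column after the known
#' metadata columns is a feature. Unknown non-numeric columns are kept as
#' passthrough metadata.
#'
#' @param path CSV path.
#' @return A `feature_table`.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path) || file.size(path) == 0L)
    stop_dermoct("empty or missing feature table file", "format_error")
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop_dermoct(
                   sprintf("cannot parse feature table: %s", conditionMessage(e)),
                   "format_error"))
  if (nrow(df) == 0L)
    stop_dermoct("feature table has no rows", "format_error")
  if (!all(c("subject_id", "class_label") %in% names(df)))
    stop_dermoct("missing required metadata columns (subject_id, class_label)",
                 "format_error")
  known <- intersect(metadata_cols, names(df))
  rest <- setdiff(names(df), known)
  is_feat <- vapply(df[rest], is.numeric, logical(1))
  as_feature_table(df, rest[is_feat])
}
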