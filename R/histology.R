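# Pixel-based histology quantification: Masson fibrotic index (%blue/%red),
# myocyte cross-sectional areas, DAB/TUNEL positive-pixel fraction, and
# masked mean intensity for membrane-potential images.
#
# Color rules are expressed in hue/saturation space and are always carried
# along with the results, since the original ImageJ settings they stand in
# for are a matter of convention.

#' RGB image container
#'
#' @param img numeric array H x W x 3 with values in 0..1
#' @param scale_um_per_px physical scale, um per pixel
#' @return object of class `rgb_image`
#' @export
rgb_image <- function(img, scale_um_per_px = 1) {
  stopifnot(is.array(img), length(dim(img)) == 3, dim(img)[3] == 3)
  if (scale_um_per_px <= 0) stop("scale_um_per_px must be positive")
  structure(list(img = img, scale_um_per_px = scale_um_per_px),
            class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x$img)
  cat(sprintf("<rgb_image> %d x %d px, %.3g um/px\n", d[1], d[2],
              x$scale_um_per_px))
  invisible(x)
}

#' Default hue/saturation classification thresholds
#'
#' Hue in degrees (0..360).  Blue (collagen): hue 180-260; red (muscle):
#' hue < 20 or > 340; positive (DAB brown): hue 15-50 with moderate value;
#' pixels with saturation at or below `sat_min` are background.
#'
#' @return a named list of thresholds, serialized with every result
#' @export
default_color_thresholds <- function() {
  list(blue_hue = c(180, 260), red_hue_max = 20, red_hue_min_wrap = 340,
       sat_min = 0.15, positive_hue = c(15, 50), positive_value_max = 0.85)
}

image_hsv <- function(x) {
  d <- dim(x$img)
  m <- rbind(as.vector(x$img[, , 1]), as.vector(x$img[, , 2]),
             as.vector(x$img[, , 3]))
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 1)
  list(h = matrix(hsv[1, ] * 360, d[1], d[2]),
       s = matrix(hsv[2, ], d[1], d[2]),
       v = matrix(hsv[3, ], d[1], d[2]))
}

#' Classify pixels as blue / red / background
#'
#' @param x an [rgb_image()]
#' @param thresholds see [default_color_thresholds()]
#' @return object of class `color_classification`: list with `labels`
#'   (character matrix), `thresholds`, and the pixel counts
#' @export
classify_colors <- function(x, thresholds = default_color_thresholds()) {
  if (thresholds$blue_hue[1] <= thresholds$red_hue_max ||
      thresholds$blue_hue[2] >= thresholds$red_hue_min_wrap) {
    stop("blue and red hue ranges overlap")
  }
  hsv <- image_hsv(x)
  lab <- matrix("background", nrow(hsv$h), ncol(hsv$h))
  sat_ok <- hsv$s > thresholds$sat_min
  blue <- sat_ok & hsv$h >= thresholds$blue_hue[1] & hsv$h <= thresholds$blue_hue[2]
  red <- sat_ok & (hsv$h < thresholds$red_hue_max | hsv$h > thresholds$red_hue_min_wrap)
  lab[blue] <- "blue"
  lab[red] <- "red"
  if (!any(sat_ok)) warning("all-background image: no saturated pixels")
  structure(list(labels = lab, thresholds = thresholds,
                 counts = c(blue = sum(blue), red = sum(red),
                            background = sum(lab == "background"))),
            class = "color_classification")
}

#' Fibrotic index: %blue (collagen) over %red (muscle)
#'
#' Both percentages are relative to all pixels of the image; the index is
#' their ratio and is flagged undefined when no red pixels exist.
#'
#' @param cls a `color_classification` from [classify_colors()]
#' @return one-row data.frame: `pct_blue`, `pct_red`, `index`, `undefined`
#' @export
fibrotic_index <- function(cls) {
  n <- length(cls$labels)
  pct_blue <- 100 * cls$counts[["blue"]] / n
  pct_red <- 100 * cls$counts[["red"]] / n
  undef <- pct_red == 0
  data.frame(pct_blue = pct_blue, pct_red = pct_red,
             index = if (undef) NA_real_ else pct_blue / pct_red,
             undefined = undef)
}

#' Myocyte cross-sectional areas
#'
#' From a binary mask (cells TRUE) or an RGB image segmented by Otsu
#' thresholding of the saturation channel followed by a distance-transform
#' watershed.  Cells touching the image border are excluded; the
#' protocol's inclusion rule of at least `min_cells` cells per image is
#' reported as a flag, not enforced as an error.
#'
#' @param x an [rgb_image()] or a logical matrix mask
#' @param scale_um_per_px required when `x` is a mask
#' @param min_cells inclusion rule (default 20)
#' @param min_area_px discard specks smaller than this (default 9)
#' @return list with `areas_um2` (per cell), `n_cells`, `mean_area`,
#'   `median_area`, `meets_inclusion`
#' @export
cell_areas <- function(x, scale_um_per_px = NULL, min_cells = 20,
                       min_area_px = 9) {
  if (inherits(x, "rgb_image")) {
    scale <- x$scale_um_per_px
    hsv <- image_hsv(x)
    thr <- EBImage::otsu(EBImage::Image(hsv$s), range = c(0, 1))
    mask <- hsv$s > thr
  } else {
    if (is.null(scale_um_per_px)) stop("scale_um_per_px needed with a mask input")
    scale <- scale_um_per_px
    mask <- x
  }
  if (!any(mask)) {
    warning("no cells found")
    return(list(areas_um2 = numeric(0), n_cells = 0L, mean_area = NA_real_,
                median_area = NA_real_, meets_inclusion = FALSE))
  }
  dm <- EBImage::distmap(EBImage::Image(mask * 1))
  lab <- EBImage::watershed(dm, tolerance = 1)
  lab <- as.matrix(EBImage::imageData(lab))
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  ids <- setdiff(sort(unique(as.vector(lab))), c(0, border))
  areas_px <- vapply(ids, function(id) sum(lab == id), numeric(1))
  areas_px <- areas_px[areas_px >= min_area_px]
  areas <- areas_px * scale^2
  list(areas_um2 = areas, n_cells = length(areas),
       mean_area = if (length(areas)) mean(areas) else NA_real_,
       median_area = if (length(areas)) stats::median(areas) else NA_real_,
       meets_inclusion = length(areas) >= min_cells)
}

#' Positive-pixel fraction (DAB/TUNEL)
#'
#' Fraction of tissue pixels classified positive by the brown hue band.
#' White/luminal pixels (saturation at or below `sat_min`) are excluded from
#' the denominator, matching standard practice.
#'
#' @param x an [rgb_image()]
#' @param thresholds see [default_color_thresholds()]
#' @return one-row data.frame: `fraction_positive`, `n_positive`, `n_tissue`
#' @export
positive_pixel_fraction <- function(x, thresholds = default_color_thresholds()) {
  hsv <- image_hsv(x)
  tissue <- hsv$s > thresholds$sat_min
  pos <- tissue & hsv$h >= thresholds$positive_hue[1] &
    hsv$h <= thresholds$positive_hue[2] & hsv$v <= thresholds$positive_value_max
  n_t <- sum(tissue)
  data.frame(fraction_positive = if (n_t > 0) sum(pos) / n_t else NA_real_,
             n_positive = sum(pos), n_tissue = n_t)
}

#' Mean intensity of a grayscale image within an optional mask
#'
#' Group-level normalization to a control percentage lives in
#' [normalize_to_control()].
#'
#' @param img numeric matrix (grayscale intensities)
#' @param mask optional logical matrix
#' @return scalar mean intensity
#' @export
mean_intensity <- function(img, mask = NULL) {
  if (is.null(mask)) return(mean(img))
  if (!any(mask)) stop("empty mask")
  mean(img[mask])
}

#' Write / read an RGB image as PNG with a metadata JSON sidecar
#' @param x an [rgb_image()]
#' @param path PNG path; scale goes to `<path>.json`
#' @export
write_rgb_png <- function(x, path) {
  png::writePNG(x$img, path)
  jsonlite::write_json(list(scale_um_per_px = x$scale_um_per_px),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rgb_png
#' @export
read_rgb_png <- function(path) {
  img <- png::readPNG(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  rgb_image(img, scale_um_per_px = meta$scale_um_per_px)
}
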