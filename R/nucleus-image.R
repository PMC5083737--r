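#' Construct a segmented-nucleus image
#'
#' Pairs a grayscale pixel grid with a binary mask of identical
#' dimensions. Intensity convention: 0 is maximally stained (dark
#' hematoxylin), 255 is light/unstained background.
#'
#' @param pixels Numeric matrix of gray intensities in \[0, 255\]
#'   (row-major grid, top-left origin).
#' @param mask Logical (or 0/1) matrix of the same dimensions marking
#'   in-nucleus pixels; must contain at least one pixel.
#' @param offset Optional integer pair: (row, col) position of this crop
#'   inside the parent image (0-based; default `c(0, 0)`).
#' @return An object of class `nucleus_image` with elements `pixels`,
#'   `mask`, `n_pixels`, `offset`.
#' @export
nucleus_image <- function(pixels, mask, offset = c(0L, 0L)) {
  pixels <- as.matrix(pixels)
  if (is.numeric(mask)) mask <- mask != 0
  mask <- as.matrix(mask)
  if (!identical(dim(pixels), dim(mask)))
    stop("pixels and mask dimensions differ")
  if (any(!is.finite(pixels)) || any(pixels < 0) || any(pixels > 255))
    stop("pixel intensities must be finite and in [0, 255]")
  np <- sum(mask)
  if (np < 1) stop("mask must contain at least one pixel")
  structure(list(pixels = pixels, mask = mask, n_pixels = np,
                 offset = as.integer(offset)),
            class = "nucleus_image")
}

#' @export
print.nucleus_image <- function(x, ...) {
  cat(sprintf("nucleus_image: %d x %d crop, %d in-mask pixels\n",
              nrow(x$pixels), ncol(x$pixels), x$n_pixels))
  invisible(x)
}

#' Specification of a synthetic nucleus to render
#'
#' Describes the elliptical geometry and chromatin texture of one
#' synthetic nucleus, the image-tier stand-in for an H&E-stained
#' nucleus.
#'
#' @param class_label One of `"CP"`, `"IPMN"`, `"PC"`.
#' @param axis_ratio Major/minor axis ratio of the elliptical boundary
#'   (>= 1; 1 is a disk).
#' @param chromatin_blob_density Chromatin blobs per in-mask pixel
#'   (>= 0).
#' @param blob_contrast Intensity offset of blobs relative to the base
#'   staining level (positive values darken).
#' @param light_fraction Target fraction of in-mask pixels rendered
#'   above the light-staining threshold, in \[0, 1\].
#' @param diameter_px Nominal major-axis diameter in pixels (>= 8).
#' @return A validated list of class `nucleus_spec`.
#' @export
nucleus_spec <- function(class_label = "CP", axis_ratio = 1.5,
                         chromatin_blob_density = 0.02,
                         blob_contrast = 60, light_fraction = 0.25,
                         diameter_px = 48) {
  as_karyo_class(class_label)
  if (axis_ratio < 1) stop("axis_ratio must be >= 1")
  if (chromatin_blob_density < 0) stop("chromatin_blob_density must be >= 0")
  if (light_fraction < 0 || light_fraction > 1)
    stop("light_fraction must be in [0, 1]")
  if (diameter_px < 8) stop("nucleus too small to rasterize")
  structure(list(class_label = class_label, axis_ratio = axis_ratio,
                 chromatin_blob_density = chromatin_blob_density,
                 blob_contrast = blob_contrast,
                 light_fraction = light_fraction,
                 diameter_px = diameter_px),
            class = "nucleus_spec")
}

#' Render a synthetic nucleus image
#'
#' Rasterizes an elliptical mask with the requested axis ratio and
#' fills it with chromatin-like texture: a base staining level plus
#' Gaussian-smoothed random blobs at the requested density and
#' contrast. The brightest `light_fraction` of in-mask pixels is lifted
#' above the light-pixel intensity so that the extracted
#' lightly-stained-pixel fraction tracks the requested target.
#'
#' @param spec A [nucleus_spec()].
#' @param seed Integer seed; the rendering is deterministic given
#'   `spec` and `seed`.
#' @param light_value Intensity assigned to lightly stained pixels
#'   (default 230, above the default extraction threshold of 180).
#' @param base_intensity Base staining level of the nuclear interior
#'   (default 120).
#' @return A [nucleus_image()].
#' @export
#' @examples
#' img <- render_nucleus(nucleus_spec(axis_ratio = 2), seed = 1)
#' img$n_pixels
render_nucleus <- function(spec, seed = 1L, light_value = 230,
                           base_intensity = 120) {
  stopifnot(inherits(spec, "nucleus_spec"))
  if (spec$diameter_px < 8) stop("nucleus too small to rasterize")
  withr::with_seed(seed,
                   render_nucleus_impl(spec, light_value, base_intensity))
}

render_nucleus_impl <- function(spec, light_value, base_intensity) {
  a <- spec$diameter_px / 2                 # semi-major
  b <- a / spec$axis_ratio                  # semi-minor
  nr <- ceiling(2 * b) + 5
  nc <- ceiling(2 * a) + 5
  cr <- (nr + 1) / 2
  cc <- (nc + 1) / 2
  rr <- matrix(seq_len(nr), nr, nc)
  cl <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  mask <- ((rr - cr) / b)^2 + ((cl - cc) / a)^2 <= 1

  field <- matrix(base_intensity, nr, nc)
  n_blobs <- rpois(1, spec$chromatin_blob_density * sum(mask))
  if (n_blobs > 0) {
    idx <- sample(which(mask), n_blobs, replace = TRUE)
    bump <- matrix(0, nr, nc)
    bump[idx] <- bump[idx] - spec$blob_contrast
    # smooth blobs into soft chromatin clumps
    sig <- max(1, spec$diameter_px / 24)
    bump <- gaussian_blur(bump, sig)
    field <- field + bump * 6
  }
  field <- field + matrix(rnorm(nr * nc, 0, 8), nr, nc)

  if (spec$light_fraction > 0) {
    vals <- field[mask]
    k <- round(spec$light_fraction * length(vals))
    if (k > 0) {
      thr <- sort(vals, decreasing = TRUE)[k]
      sel <- mask & field >= thr
      # cap at exactly k pixels when ties straddle the cutoff
      extra <- sum(sel) - k
      if (extra > 0) {
        drop <- which(sel & field == thr)[seq_len(extra)]
        sel[drop] <- FALSE
      }
      field[sel] <- light_value + rnorm(sum(sel), 0, 4)
    }
  }

  field[!mask] <- 250                      # light background outside
  field <- pmin(pmax(round(field), 0), 255)
  nucleus_image(field, mask)
}

# separable gaussian blur, reflective edges
gaussian_blur <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  blur1 <- function(x) {
    n <- length(x)
    xp <- c(rev(x[seq_len(min(r, n))]), x, rev(x[seq.int(max(1, n - r + 1), n)]))
    as.numeric(stats::filter(xp, k, sides = 2))[r + seq_len(n)]
  }
  m <- apply(m, 2, blur1)
  t(apply(m, 1, blur1))
}

#' Image-tier rendering presets per diagnostic class
#'
#' One [nucleus_spec()] per class, calibrated so that features
#' extracted from rendered nuclei track the class ordering of the
#' generative feature table: the axis ratio is solved analytically from
#' the class's target form factor (Ramanujan perimeter approximation of
#' the continuous ellipse) and the light fraction from the target
#' lightly-stained-pixel count divided by the expected mask area. The
#' small multiplicative corrections compensate the rasterization bias
#' of the perimeter estimator and were fixed once by the shipped
#' calibration script (`scripts/calibrate_presets.R`).
#'
#' @param diameter_px Nominal nucleus diameter in pixels (default 60).
#' @param calibration Named list of per-class multiplicative
#'   corrections applied to the analytic axis ratio, as produced by the
#'   calibration script.
#' @return Named list of [nucleus_spec()] objects (`CP`, `IPMN`, `PC`).
#' @export
class_presets <- function(diameter_px = 60,
                          calibration = list(
                            axis_ratio = c(CP = 1.0778, IPMN = 1.0398,
                                           PC = 1.0526))) {
  tab <- informative_defaults()
  out <- list()
  for (cl in karyo_classes()) {
    ff <- tab$mean[tab$feature == "nuclear_roundness" & tab$class == cl]
    light <- tab$mean[tab$feature == "n_light_pixels" & tab$class == cl]
    ar <- axis_ratio_for_form_factor(ff) * calibration$axis_ratio[[cl]]
    area <- pi * (diameter_px / 2) * (diameter_px / (2 * ar))
    out[[cl]] <- nucleus_spec(
      class_label = cl, axis_ratio = ar,
      chromatin_blob_density = 0.03, blob_contrast = 60,
      light_fraction = min(1, light / area),
      diameter_px = diameter_px)
  }
  out
}

#' Form factor of a continuous ellipse
#'
#' `P^2 / (4 * pi * A)` with the perimeter from Ramanujan's second
#' approximation; equals 1 for a disk and grows with elongation.
#'
#' @param axis_ratio Major/minor axis ratio (>= 1).
#' @return The dimensionless form factor.
#' @export
ellipse_form_factor <- function(axis_ratio) {
  a <- axis_ratio
  b <- 1
  h <- ((a - b) / (a + b))^2
  P <- pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
  P^2 / (4 * pi * pi * a * b)
}

# invert ellipse_form_factor numerically
axis_ratio_for_form_factor <- function(ff) {
  if (ff <= 1) return(1)
  stats::uniroot(function(r) ellipse_form_factor(r) - ff,
                 c(1 + 1e-9, 50))$root
}
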