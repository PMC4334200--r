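## summed-area table with a zero border row/column so that region sums are
## S[r2+1, c2+1] - S[r1, c2+1] - S[r2+1, c1] + S[r1, c1]
.sat <- function(m) {
  s <- apply(m, 2, cumsum)
  s <- t(apply(s, 1, cumsum))
  rbind(0, cbind(0, s))
}

.sat_sum <- function(S, r1, r2, c1, c2)
  S[r2 + 1, c2 + 1] - S[r1, c2 + 1] - S[r2 + 1, c1] + S[r1, c1]

## gradient magnitude: max of |horizontal| and |vertical| central
## differences, one-sided (halved) at the borders by edge replication
.gradient_max <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  cr <- seq_len(nc)
  dx <- (img[, pmin(cr + 1, nc), drop = FALSE] -
           img[, pmax(cr - 1, 1), drop = FALSE]) / 2
  rr <- seq_len(nr)
  dy <- (img[pmin(rr + 1, nr), , drop = FALSE] -
           img[pmax(rr - 1, 1), , drop = FALSE]) / 2
  pmax(abs(dx), abs(dy))
}

#' RATS: robust automatic threshold selection over a quadtree
#'
#' Local adaptive thresholding for fluorescence images. Each pixel's
#' gradient magnitude \eqn{g} (max of horizontal/vertical central
#' differences) is converted to a weight \eqn{w = g^\lambda} where
#' \eqn{g > } \code{noise_threshold}, else 0. The image is recursively
#' quartered into a quadtree until a further split would produce leaves
#' smaller than \code{min_leaf_size} pixels. A region's threshold is the
#' gradient-weighted mean intensity \eqn{T = \sum w I / \sum w}, accepted
#' only when the region's total weight exceeds
#' \code{noise_threshold^lambda * area / validity_divisor}; leaves failing
#' this inherit the nearest valid ancestor's threshold. Pixels under no
#' valid ancestor are classified background, so a constant-background
#' region with sub-noise gradients yields no foreground.
#'
#' @param image numeric matrix of intensities.
#' @param params a [rats_params()].
#' @return A list with \code{mask} (logical, \code{image > threshold}),
#'   \code{threshold} (per-pixel threshold surface; \code{NA} where no
#'   valid region covered the pixel) and \code{any_valid} (FALSE, with a
#'   warning, when no region anywhere exceeded the gradient noise
#'   threshold).
#' @examples
#' img <- cbind(matrix(10, 20, 10), matrix(30, 20, 10))
#' out <- rats_threshold(img, rats_params(noise_threshold = 5))
#' unique(out$threshold)   # strictly between 10 and 30
#' @export
rats_threshold <- function(image, params = rats_params()) {
  stopifnot(is.matrix(image), is.numeric(image))
  g <- .gradient_max(image)
  w <- ifelse(g > params$noise_threshold, g^params$lambda_factor, 0)
  Sw <- .sat(w)
  Swi <- .sat(w * image)
  wmin_per_px <- params$noise_threshold^params$lambda_factor /
    params$validity_divisor
  surface <- matrix(NA_real_, nrow(image), ncol(image))
  any_valid <- FALSE

  recurse <- function(r1, r2, c1, c2, inherited) {
    area <- (r2 - r1 + 1) * (c2 - c1 + 1)
    sw <- .sat_sum(Sw, r1, r2, c1, c2)
    t_here <- inherited
    if (sw > wmin_per_px * area) {
      t_here <- .sat_sum(Swi, r1, r2, c1, c2) / sw
      any_valid <<- TRUE
    }
    h <- r2 - r1 + 1; wd <- c2 - c1 + 1
    rm <- r1 + h %/% 2 - 1; cm <- c1 + wd %/% 2 - 1
    child_area <- min(rm - r1 + 1, r2 - rm) * min(cm - c1 + 1, c2 - cm)
    if (h >= 2 && wd >= 2 && child_area >= params$min_leaf_size) {
      recurse(r1, rm, c1, cm, t_here)
      recurse(r1, rm, cm + 1, c2, t_here)
      recurse(rm + 1, r2, c1, cm, t_here)
      recurse(rm + 1, r2, cm + 1, c2, t_here)
    } else {
      surface[r1:r2, c1:c2] <<- t_here
    }
  }
  recurse(1, nrow(image), 1, ncol(image), NA_real_)
  if (!any_valid)
    warning("no region exceeded the gradient noise threshold; ",
            "all pixels classified as background", call. = FALSE)
  mask <- !is.na(surface) & image > surface
  list(mask = mask, threshold = surface, any_valid = any_valid)
}

#' Count puncta inside a region of interest by RATS thresholding
#'
#' Thresholds the section with [rats_threshold()], intersects the
#' foreground with the ROI, and counts connected components (4-connected
#' by default, so touching objects merge and are counted once) at or above
#' \code{min_size} pixels.
#'
#' @param section numeric matrix (e.g. one confocal section).
#' @param roi logical matrix, non-empty.
#' @param params a [rats_params()].
#' @param min_size minimum component area in pixels.
#' @param connectivity 4 or 8.
#' @return Integer count.
#' @export
count_puncta <- function(section, roi, params = rats_params(),
                         min_size = 4L, connectivity = 4L) {
  stopifnot(is.matrix(section), is.logical(roi),
            identical(dim(section), dim(roi)))
  if (!any(roi)) stop("roi is empty")
  rt <- suppressWarnings(rats_threshold(section, params))
  m <- rt$mask & roi
  if (!any(m)) return(0L)
  lab <- label_components(m, connectivity)
  sum(tabulate(lab[lab > 0], max(lab)) >= min_size)
}
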