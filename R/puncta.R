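## grayscale morphological reconstruction by geodesic dilation of `marker`
## under `image` (8-connected); raster-scan algorithm in src/
.reconstruct <- function(marker, image) .reconstruct_cpp(marker, image)

## white top-hat: image minus an opening. "reconstruction" opens by
## erosion + geodesic reconstruction, which regrows every structure still
## connected to a surviving marker and therefore leaves no rim artifacts
## at nuclei or cell boundaries; "open" is the plain erosion + dilation.
.white_tophat <- function(image, radius, type = "reconstruction") {
  scale <- max(image)                  # EBImage greyscale morphology
  if (scale <= 0) return(image * 0)    # expects intensities in [0, 1]
  x <- image / scale
  brush <- EBImage::makeBrush(2 * round(radius) + 1, "disc")
  eroded <- as.matrix(EBImage::erode(x, brush))
  bg <- if (type == "reconstruction") .reconstruct(eroded, x)
  else as.matrix(EBImage::dilate(eroded, brush))
  (x - bg) * scale
}

#' Detect GFP puncta inside muscles (granularity-style)
#'
#' Spot detection in the spirit of high-content "granularity" modules:
#' a white top-hat filter with a disk larger than any expected punctum
#' flattens the diffuse cytoplasmic and nuclear reporter signal, and the
#' residue is thresholded at
#' \code{median + max(k_mad * MAD, rel_floor * (q99.9 - median of GFP))}
#' computed over muscle pixels. Connected components are kept when their
#' area lies in \code{size_band}; thresholding is restricted to the muscle
#' mask, so every punctum lies inside a muscle.
#'
#' All cutoffs are relative to robust statistics of the field itself, so
#' the detected puncta (and hence [autophagy_index()]) are invariant under
#' uniform rescaling of the GFP channel.
#'
#' @param field an [image_field()] with a \code{gfp} channel, or a plain
#'   numeric matrix.
#' @param muscle a [muscle_mask()] with non-zero area.
#' @param params a [granularity_params()].
#' @param channel channel role to detect in (default \code{"gfp"}).
#' @return A [puncta_set()].
#' @export
detect_puncta_granularity <- function(field, muscle,
                                      params = granularity_params(),
                                      channel = "gfp") {
  img <- if (inherits(field, "image_field"))
    field_channel(field, channel) else field
  stopifnot(is.matrix(img), inherits(muscle, "muscle_mask"))
  if (muscle$total_area == 0)
    stop("muscle mask is empty: autophagy index undefined")
  if (!identical(dim(img), dim(muscle$mask)))
    stop("image and muscle mask shapes differ")
  sm <- if (params$blur_sigma > 0)
    as.matrix(EBImage::gblur(img, sigma = params$blur_sigma)) else img
  th <- .white_tophat(sm, params$tophat_radius, params$tophat_type)
  vals <- th[muscle$mask]
  gfp_in <- sm[muscle$mask]
  floor_term <- params$rel_floor *
    (quantile(gfp_in, 0.999, names = FALSE) - median(gfp_in))
  ## the 1e-6 relative guard keeps numerically flat fields (top-hat
  ## residue at floating-point level) from producing foreground
  cut <- median(vals) + max(params$k_mad * mad(vals), floor_term,
                            1e-6 * max(gfp_in))
  m <- th > cut & muscle$mask
  ps <- puncta_set(m, intensity = img,
                   connectivity = params$connectivity)
  keep <- ps$objects$area >= params$size_band[1] &
    ps$objects$area <= params$size_band[2]
  if (!all(keep)) {
    drop_lab <- ps$objects$label[!keep]
    m[ps$labels %in% drop_lab] <- FALSE
    ps <- puncta_set(m, intensity = img,
                     connectivity = params$connectivity)
  }
  ps
}

#' Puncta-area per muscle-area autophagy index
#'
#' The screen's readout: total detected puncta area divided by total
#' muscle area in the field. Lies in [0, 1] when the puncta mask is
#' contained in the muscle mask.
#'
#' @param puncta a [puncta_set()].
#' @param muscle a [muscle_mask()] with \code{total_area > 0}.
#' @return Dimensionless ratio.
#' @export
autophagy_index <- function(puncta, muscle) {
  stopifnot(inherits(puncta, "puncta_set"), inherits(muscle, "muscle_mask"))
  if (muscle$total_area <= 0)
    stop("muscle area is zero: autophagy index undefined for this field")
  puncta$total_area / muscle$total_area
}

#' Maximum intensity projection of a z-stack
#'
#' @param stack list of equally shaped numeric matrices, or a 3-D array
#'   with slices along the third dimension.
#' @return Per-pixel maximum as a matrix.
#' @export
max_intensity_projection <- function(stack) {
  if (is.array(stack) && length(dim(stack)) == 3)
    stack <- lapply(seq_len(dim(stack)[3]), function(i) stack[, , i])
  if (!is.list(stack) || length(stack) == 0)
    stop("stack must contain at least one slice")
  d <- dim(stack[[1]])
  for (s in stack)
    if (!identical(dim(s), d)) stop("all slices must have the same shape")
  Reduce(pmax, stack)
}

#' Manders' overlap coefficient between two channels
#'
#' \deqn{\mathrm{MOC} = \frac{\sum_i A_i B_i}
#'   {\sqrt{\sum_i A_i^2 \sum_i B_i^2}}}
#' over the pixels of \code{roi}. Symmetric in its arguments, invariant
#' under positive rescaling of either channel, and in [0, 1] for
#' non-negative images (1 iff the channels are proportional, by
#' Cauchy--Schwarz).
#'
#' @param chan_a,chan_b numeric matrices of equal shape.
#' @param roi optional logical matrix; defaults to the whole image.
#' @return The overlap coefficient.
#' @export
manders_overlap <- function(chan_a, chan_b, roi = NULL) {
  stopifnot(is.matrix(chan_a), is.matrix(chan_b),
            identical(dim(chan_a), dim(chan_b)))
  if (is.null(roi)) roi <- matrix(TRUE, nrow(chan_a), ncol(chan_a))
  stopifnot(identical(dim(roi), dim(chan_a)))
  a <- chan_a[roi]; b <- chan_b[roi]
  if (all(a == 0) || all(b == 0))
    stop("a channel is identically zero in the ROI: MOC undefined")
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

#' Autophagic flux ratio from dual-reporter puncta
#'
#' With a tandem mCherry/GFP reporter, acidified autolysosomes retain the
#' red signal but quench GFP. Red puncta are matched to green puncta by
#' centroid distance; the flux readout is the number of red-only puncta
#' divided by the number of dual (red+green) puncta.
#'
#' @param gfp_puncta,red_puncta [puncta_set()]s from the same field.
#' @param match_radius maximum centroid distance in pixels for a red
#'   punctum to count as dual.
#' @return The ratio. An empty red set returns 0 with a warning; red
#'   puncta with no dual matches return \code{Inf} with a warning.
#' @export
flux_ratio <- function(gfp_puncta, red_puncta, match_radius = 4) {
  stopifnot(inherits(gfp_puncta, "puncta_set"),
            inherits(red_puncta, "puncta_set"))
  red <- red_puncta$objects
  if (nrow(red) == 0) {
    warning("no red puncta detected; flux ratio set to 0", call. = FALSE)
    return(0)
  }
  green <- gfp_puncta$objects
  dual <- if (nrow(green) == 0) rep(FALSE, nrow(red)) else
    vapply(seq_len(nrow(red)), function(i) {
      min(sqrt((green$row - red$row[i])^2 +
                 (green$col - red$col[i])^2)) <= match_radius
    }, logical(1))
  n_dual <- sum(dual)
  if (n_dual == 0) {
    warning("no dual red+green puncta; flux ratio is infinite",
            call. = FALSE)
    return(Inf)
  }
  (nrow(red) - n_dual) / n_dual
}
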