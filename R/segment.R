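#' Segment muscles from the phalloidin/actin channel
#'
#' Muscles are identified from the mixed cell population by bright
#' phalloidin staining: the actin channel is Gaussian-smoothed,
#' thresholded (Otsu by default), morphologically closed, and components
#' below \code{min_area} pixels (phalloidin-dim non-muscle cells, debris)
#' are dropped.
#'
#' @param field an [image_field()] with an \code{actin} channel.
#' @param params a [segmentation_params()].
#' @param connectivity 4 or 8, used when counting muscles.
#' @return A [muscle_mask()].
#' @export
segment_muscle <- function(field, params = segmentation_params(),
                           connectivity = 4L) {
  a <- field_channel(field, "actin")
  rng <- range(a)
  if (diff(rng) == 0)                       # blank field
    return(muscle_mask(matrix(FALSE, nrow(a), ncol(a)), connectivity))
  x <- (a - rng[1]) / diff(rng)
  if (params$blur_sigma > 0)
    x <- as.matrix(EBImage::gblur(x, sigma = params$blur_sigma))
  thr <- if (identical(params$threshold, "otsu"))
    EBImage::otsu(EBImage::Image(x), range = c(0, 1))
  else (params$threshold - rng[1]) / diff(rng)
  m <- x > thr
  if (params$close_radius > 0) {
    brush <- EBImage::makeBrush(2 * params$close_radius + 1, "disc")
    m <- EBImage::closing(m, brush) > 0
  }
  m <- matrix(as.logical(m), nrow(a), ncol(a))
  if (params$min_area > 0 && any(m)) {
    lab <- label_components(m, connectivity)
    keep <- which(tabulate(lab[lab > 0], max(lab)) >= params$min_area)
    m <- matrix(lab %in% keep, nrow(a), ncol(a))
  }
  muscle_mask(m, connectivity)
}
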