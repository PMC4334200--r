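#' Multi-channel field image
#'
#' A single microscope field: a named list of equally sized 2-D intensity
#' rasters (numeric matrices), one per channel role, plus identifiers.
#' Standard roles are \code{gfp} (autophagy reporter), \code{actin}
#' (phalloidin), \code{nuclear} and \code{red} (second reporter).
#'
#' @param channels named list of numeric matrices; all the same dimension,
#'   finite and non-negative.
#' @param pixel_size optional pixel size in micrometres per pixel.
#' @param field_id,well_id,plate_id identifiers.
#' @return An object of class \code{image_field}.
#' @export
image_field <- function(channels, pixel_size = NULL,
                        field_id = "field1", well_id = NA_character_,
                        plate_id = NA_character_) {
  if (!is.list(channels) || length(channels) == 0 ||
      is.null(names(channels)) || any(!nzchar(names(channels))))
    stop("channels must be a non-empty named list of matrices")
  dims <- lapply(channels, dim)
  if (any(vapply(channels, function(m) !is.matrix(m), logical(1))))
    stop("every channel must be a 2-D matrix")
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1)
    stop("all channel rasters must have the same shape")
  for (nm in names(channels)) {
    v <- channels[[nm]]
    if (any(!is.finite(v)) || any(v < 0))
      stop(sprintf("channel '%s' must be finite and non-negative", nm))
  }
  structure(list(channels = channels, pixel_size = pixel_size,
                 field_id = field_id, well_id = well_id,
                 plate_id = plate_id),
            class = "image_field")
}

#' @export
print.image_field <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("image_field '%s' (%d x %d px), channels: %s\n",
              x$field_id, d[1], d[2],
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Extract a channel raster from an image field
#'
#' @param field an [image_field()].
#' @param role channel role, e.g. \code{"gfp"} or \code{"actin"}.
#' @return The channel matrix.
#' @export
field_channel <- function(field, role) {
  stopifnot(inherits(field, "image_field"))
  if (!role %in% names(field$channels))
    stop(sprintf("channel '%s' is missing from field '%s'",
                 role, field$field_id))
  field$channels[[role]]
}

#' Ground truth accompanying a simulated field
#'
#' @param muscle_mask,puncta_mask,nuclei_mask logical matrices; the puncta
#'   mask must be contained in the muscle mask.
#' @param n_puncta,n_acidified optional true object counts.
#' @return An object of class \code{ground_truth} whose \code{true_index}
#'   is exactly \code{sum(puncta_mask) / sum(muscle_mask)}.
#' @export
ground_truth <- function(muscle_mask, puncta_mask,
                         nuclei_mask = NULL, n_puncta = NA_integer_,
                         n_acidified = NA_integer_) {
  stopifnot(is.logical(muscle_mask), is.logical(puncta_mask),
            identical(dim(muscle_mask), dim(puncta_mask)))
  if (any(puncta_mask & !muscle_mask))
    stop("puncta_mask must be contained in muscle_mask")
  ma <- sum(muscle_mask)
  structure(list(muscle_mask = muscle_mask, puncta_mask = puncta_mask,
                 nuclei_mask = nuclei_mask,
                 true_index = if (ma > 0) sum(puncta_mask) / ma else 0,
                 n_puncta = n_puncta, n_acidified = n_acidified),
            class = "ground_truth")
}

#' Binary muscle mask with component bookkeeping
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8; used to count muscles.
#' @return An object of class \code{muscle_mask} with fields \code{mask},
#'   \code{n_muscles} (connected components) and \code{total_area} (pixels).
#' @export
muscle_mask <- function(mask, connectivity = 4L) {
  stopifnot(is.logical(mask), is.matrix(mask))
  lab <- label_components(mask, connectivity)
  structure(list(mask = mask, n_muscles = max(lab),
                 total_area = sum(mask)),
            class = "muscle_mask")
}

#' @export
print.muscle_mask <- function(x, ...) {
  cat(sprintf("muscle_mask: %d muscle(s), %d px\n",
              x$n_muscles, x$total_area))
  invisible(x)
}

#' Labelled puncta objects and their binary mask
#'
#' @param mask logical matrix of detected puncta pixels.
#' @param intensity optional matrix from which per-object mean intensities
#'   are taken.
#' @param connectivity 4 or 8.
#' @return An object of class \code{puncta_set}: the mask, a data frame
#'   \code{objects} (label, centroid row/col, area, mean intensity) and
#'   \code{total_area = sum(mask)}.
#' @export
puncta_set <- function(mask, intensity = NULL, connectivity = 4L) {
  stopifnot(is.logical(mask), is.matrix(mask))
  lab <- label_components(mask, connectivity)
  n <- max(lab)
  if (n == 0) {
    obj <- data.frame(label = integer(0), row = numeric(0),
                      col = numeric(0), area = integer(0),
                      mean_intensity = numeric(0))
  } else {
    idx <- which(lab > 0)
    l <- lab[idx]
    rr <- ((idx - 1L) %% nrow(mask)) + 1L
    cc <- ((idx - 1L) %/% nrow(mask)) + 1L
    area <- tabulate(l, n)
    obj <- data.frame(
      label = seq_len(n),
      row = as.numeric(rowsum(as.numeric(rr), l)) / area,
      col = as.numeric(rowsum(as.numeric(cc), l)) / area,
      area = area,
      mean_intensity = if (is.null(intensity)) NA_real_ else
        as.numeric(rowsum(intensity[idx], l)) / area)
  }
  structure(list(mask = mask, objects = obj, labels = lab,
                 total_area = sum(mask)),
            class = "puncta_set")
}

#' @export
print.puncta_set <- function(x, ...) {
  cat(sprintf("puncta_set: %d object(s), %d px total\n",
              nrow(x$objects), x$total_area))
  invisible(x)
}

#' Label connected components of a binary mask
#'
#' 4-connectivity is the package-wide default; 8-connectivity is available
#' as an option. The 4-connected path delegates to \code{EBImage::bwlabel};
#' the 8-connected path uses iterative label propagation.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return An integer matrix of labels, 0 for background, components
#'   numbered from 1.
#' @export
label_components <- function(mask, connectivity = 4L) {
  stopifnot(is.logical(mask), is.matrix(mask))
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  if (connectivity == 4L) {
    lab <- EBImage::bwlabel(mask)
    return(matrix(as.integer(lab), nrow(mask), ncol(mask)))
  }
  ## 8-connectivity: propagate the minimum provisional label to all
  ## neighbours until stable, then renumber densely
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(Inf, nr, nc)
  lab[mask] <- which(mask)
  shift <- function(m, dr, dc) {
    out <- matrix(Inf, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  repeat {
    new <- lab
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                   c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
      new <- pmin(new, shift(lab, d[1], d[2]))
    new[!mask] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  out <- matrix(0L, nr, nc)
  vals <- lab[mask]
  out[mask] <- as.integer(match(vals, sort(unique(vals))))
  out
}
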