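#' Quantify one field: segment, detect, index
#'
#' @param field an [image_field()].
#' @param gran a [granularity_params()].
#' @param seg a [segmentation_params()].
#' @return One-row data frame: \code{field_id}, \code{well_id},
#'   \code{plate_id}, \code{muscle_area}, \code{n_muscles},
#'   \code{puncta_area}, \code{n_puncta}, \code{index} (NA when the field
#'   has no detectable muscle and is to be excluded upstream).
#' @export
quantify_field <- function(field, gran = granularity_params(),
                           seg = segmentation_params()) {
  mm <- segment_muscle(field, seg, connectivity = gran$connectivity)
  if (mm$total_area == 0) {
    return(data.frame(field_id = field$field_id, well_id = field$well_id,
                      plate_id = field$plate_id, muscle_area = 0L,
                      n_muscles = 0L, puncta_area = 0L, n_puncta = 0L,
                      index = NA_real_, stringsAsFactors = FALSE))
  }
  ps <- detect_puncta_granularity(field, mm, gran)
  data.frame(field_id = field$field_id, well_id = field$well_id,
             plate_id = field$plate_id, muscle_area = mm$total_area,
             n_muscles = mm$n_muscles, puncta_area = ps$total_area,
             n_puncta = nrow(ps$objects),
             index = autophagy_index(ps, mm), stringsAsFactors = FALSE)
}

#' Aggregate per-field measurements into per-well indices
#'
#' Fields with zero detected muscle are excluded (reported via a message).
#' \code{method = "pooled"} (default) computes
#' \eqn{\sum \mathrm{puncta\ area} / \sum \mathrm{muscle\ area}} over a
#' well's usable fields, which is robust to fields with little muscle;
#' \code{method = "mean"} averages the per-field indices.
#'
#' @param field_table data frame of [quantify_field()] rows.
#' @param method \code{"pooled"} or \code{"mean"}.
#' @return Data frame with one row per (plate, well): \code{plate_id},
#'   \code{well}, \code{index}, \code{n_fields}, \code{n_fields_used}.
#' @export
quantify_wells <- function(field_table, method = c("pooled", "mean")) {
  method <- match.arg(method)
  key <- interaction(field_table$plate_id, field_table$well_id,
                     drop = TRUE)
  out <- do.call(rbind, lapply(split(field_table, key), function(g) {
    ok <- g$muscle_area > 0 & !is.na(g$index)
    if (any(!ok))
      message(sprintf(
        "well %s/%s: %d field(s) without muscle excluded",
        g$plate_id[1], g$well_id[1], sum(!ok)))
    idx <- if (!any(ok)) NA_real_
    else if (method == "pooled")
      sum(g$puncta_area[ok]) / sum(g$muscle_area[ok])
    else mean(g$index[ok])
    data.frame(plate_id = g$plate_id[1], well = g$well_id[1],
               index = idx, n_fields = nrow(g),
               n_fields_used = sum(ok), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

## deterministic derived seed, kept inside 32-bit integer range
.derive_seed <- function(base, i) {
  as.integer((as.numeric(base) * 7919 + i * 104729) %% 2147483647)
}

#' Render and quantify fields for every well of a simulated screen
#'
#' Ties the two simulators together: each non-empty well of a
#' [simulate_screen()] result is rendered as \code{fields_per_well}
#' synthetic fields whose \code{autophagy_level} is the well's relative
#' index (\code{index / baseline_index}) times the field configuration's
#' base level, then quantified with the imaging pipeline and aggregated
#' per well. The returned well table carries the \emph{measured} index and
#' can be fed to [normalize_plate()].
#'
#' @param screen result of [simulate_screen()].
#' @param field_config a [field_sim_config()]; its \code{autophagy_level}
#'   is the level at relative index 1 and its \code{seed} seeds the
#'   per-field seed stream.
#' @param fields_per_well number of fields rendered per well.
#' @param gran,seg imaging parameters.
#' @param method per-well aggregation, see [quantify_wells()].
#' @return Well table like \code{screen$wells} but with measured
#'   \code{index} (plus \code{n_fields_used}).
#' @export
quantify_simulated_screen <- function(screen,
                                      field_config = field_sim_config(),
                                      fields_per_well = 1L,
                                      gran = granularity_params(),
                                      seg = segmentation_params(),
                                      method = "pooled") {
  wells <- screen$wells[screen$wells$role != "empty", , drop = FALSE]
  rows <- vector("list", nrow(wells) * fields_per_well)
  k <- 0L
  for (i in seq_len(nrow(wells))) {
    lvl <- field_config$autophagy_level * wells$index[i] /
      screen$config$baseline_index
    for (f in seq_len(fields_per_well)) {
      k <- k + 1L
      cfg <- field_config
      cfg$autophagy_level <- lvl
      cfg$seed <- .derive_seed(field_config$seed, k)
      sim <- simulate_field(cfg,
                            field_id = sprintf("%s_%s_f%d",
                                               wells$plate_id[i],
                                               wells$well[i], f),
                            well_id = wells$well[i],
                            plate_id = wells$plate_id[i])
      rows[[k]] <- quantify_field(sim$field, gran, seg)
    }
  }
  fields <- do.call(rbind, rows)
  per_well <- quantify_wells(fields, method)
  out <- merge(wells[, c("plate_id", "well", "amplicon_id", "gene",
                         "role")],
               per_well, by = c("plate_id", "well"), sort = FALSE)
  out[order(out$plate_id, out$well), ]
}
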