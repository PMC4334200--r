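#' Default pipeline configuration
#'
#' A single declarative configuration for the whole pipeline, suitable for
#' serialization as YAML. Sections: \code{simulation} (screen and field
#' generator settings), \code{imaging} (granularity, RATS, segmentation
#' and per-well aggregation), \code{stats} (hit thresholds, zero-index
#' rule, amplicon aggregation) and \code{seed}.
#'
#' @return Nested named list.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    simulation = list(
      screen = list(n_genes = 20, theta = 1, n_plates = 3,
                    wells_per_plate = 384, amplicons_per_gene = 2,
                    baseline_index = 0.02, sigma_plate = 0.1,
                    sigma_well = 0.2, n_neg_wells = 16, n_pos_wells = 8,
                    pos_control_theta = 0.1),
      field = list(canvas_size = c(256, 256), n_muscles = 3,
                   autophagy_level = 1, noise_sd = 20)),
    imaging = list(granularity = list(tophat_radius = 8, k_mad = 4,
                                      size_band = c(4, 2000)),
                   rats = list(noise_threshold = 20, lambda_factor = 3,
                               min_leaf_size = 100),
                   segmentation = list(blur_sigma = 1, min_area = 500),
                   well_aggregation = "pooled"),
    stats = list(multi_amplicon = 0.5, single_amplicon = 1.0,
                 zero_rule = "epsilon", amplicon_aggregation = "wells"))
}

#' Load a pipeline configuration from YAML, merged over the defaults
#'
#' @param path YAML file, or \code{NULL} for the defaults.
#' @return Nested named list as in [default_pipeline_config()].
#' @export
load_pipeline_config <- function(path = NULL) {
  cfg <- default_pipeline_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  merge_into <- function(base, upd) {
    for (nm in names(upd)) {
      base[[nm]] <- if (is.list(upd[[nm]]) && is.list(base[[nm]]))
        merge_into(base[[nm]], upd[[nm]]) else upd[[nm]]
    }
    base
  }
  merge_into(cfg, user)
}

## translate the declarative screen section into a screen_sim_config;
## genes default to a null panel named gene001.. with theta from config
.screen_cfg_from_pipeline <- function(cfg, gene_effect_map = NULL) {
  sc <- cfg$simulation$screen
  if (is.null(gene_effect_map))
    gene_effect_map <- setNames(rep(sc$theta, sc$n_genes),
                                sprintf("gene%03d", seq_len(sc$n_genes)))
  screen_sim_config(
    gene_effect_map = gene_effect_map,
    n_plates = sc$n_plates, wells_per_plate = sc$wells_per_plate,
    amplicons_per_gene = sc$amplicons_per_gene,
    baseline_index = sc$baseline_index, sigma_plate = sc$sigma_plate,
    sigma_well = sc$sigma_well, pos_control_theta = sc$pos_control_theta,
    n_neg_wells = sc$n_neg_wells, n_pos_wells = sc$n_pos_wells,
    seed = cfg$seed)
}

.imaging_params_from_pipeline <- function(cfg) {
  g <- cfg$imaging$granularity
  s <- cfg$imaging$segmentation
  list(gran = granularity_params(tophat_radius = g$tophat_radius,
                                 k_mad = g$k_mad,
                                 size_band = unlist(g$size_band)),
       seg = segmentation_params(blur_sigma = s$blur_sigma,
                                 min_area = s$min_area))
}

#' Score a measured well table: normalize, score amplicons, call genes
#'
#' Convenience wrapper running [normalize_plate()], [score_amplicons()],
#' [call_genes()], [summarize_calls()] and [control_qc()] in sequence.
#'
#' @param wells well table with an \code{index} column.
#' @param thresholds a [hit_thresholds()].
#' @param zero_rule,aggregate passed to [normalize_plate()] and
#'   [score_amplicons()].
#' @return List with \code{wells_d}, \code{scores}, \code{calls},
#'   \code{summary}, \code{qc}.
#' @export
score_screen <- function(wells, thresholds = hit_thresholds(),
                         zero_rule = "epsilon", aggregate = "wells") {
  wells_d <- normalize_plate(wells, zero_rule = zero_rule)
  scores <- score_amplicons(wells_d, aggregate = aggregate)
  calls <- call_genes(scores, thresholds)
  list(wells_d = wells_d, scores = scores, calls = calls,
       summary = summarize_calls(calls), qc = control_qc(wells_d))
}
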