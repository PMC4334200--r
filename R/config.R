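#' Configuration for synthetic field image simulation
#'
#' Describes a single microscope field of primary muscle culture: elongated
#' muscle cells (rendered as rotated capsules) among smaller non-muscle
#' cells, with a diffuse cytoplasmic plus nuclear GFP reporter signal and
#' bright autophagosome puncta whose expected number scales with
#' \code{autophagy_level}.
#'
#' @param canvas_size integer length-2, image height and width in pixels.
#' @param n_muscles number of muscle cells to place.
#' @param muscle_length,muscle_width length-2 numeric ranges (pixels) from
#'   which each muscle's length and width are drawn uniformly.
#' @param n_nonmuscle_cells number of small phalloidin-dim background cells.
#' @param autophagy_level dimensionless, >= 0. Expected puncta count is
#'   \code{autophagy_level * puncta_density * muscle area}.
#' @param puncta_density expected puncta per muscle pixel per unit
#'   \code{autophagy_level}.
#' @param puncta_radius_mean,puncta_radius_sd punctum disk radius (pixels),
#'   drawn from a normal truncated at 1.
#' @param puncta_min_sep minimum distance between puncta centres (pixels);
#'   0 disables the separation constraint.
#' @param diffuse_gfp_level,nuclear_gfp_level,puncta_gfp_level intensity of
#'   the GFP reporter in muscle cytoplasm, in muscle nuclei, and added on
#'   puncta, on a 16-bit-style scale.
#' @param actin_level phalloidin/actin intensity inside muscles.
#' @param nonmuscle_actin_frac actin intensity of non-muscle cells as a
#'   fraction of \code{actin_level}.
#' @param striation_amp relative amplitude of the sinusoidal sarcomere
#'   texture along the muscle axis in the actin channel (0 disables).
#' @param nuclear_radius muscle nucleus radius in pixels.
#' @param noise_sd additive Gaussian noise standard deviation per channel.
#' @param acidified_fraction \code{NULL}, or a fraction in [0, 1) of puncta
#'   that are acidified (autolysosomes): these appear in the red (mCherry)
#'   channel but not in GFP, emulating a tandem-fluorescent flux reporter.
#'   When non-\code{NULL} a \code{red} channel is rendered.
#' @param seed integer seed; identical configurations give bit-identical
#'   fields.
#'
#' @return An object of class \code{field_sim_config}.
#' @seealso [simulate_field()]
#' @export
field_sim_config <- function(canvas_size = c(256L, 256L),
                             n_muscles = 3,
                             muscle_length = c(120, 200),
                             muscle_width = c(28, 40),
                             n_nonmuscle_cells = 20,
                             autophagy_level = 1,
                             puncta_density = 6e-4,
                             puncta_radius_mean = 3,
                             puncta_radius_sd = 0.8,
                             puncta_min_sep = 0,
                             diffuse_gfp_level = 300,
                             nuclear_gfp_level = 600,
                             puncta_gfp_level = 1500,
                             actin_level = 800,
                             nonmuscle_actin_frac = 0.15,
                             striation_amp = 0.1,
                             nuclear_radius = 12,
                             noise_sd = 20,
                             acidified_fraction = NULL,
                             seed = 1L) {
  cfg <- list(canvas_size = as.integer(canvas_size), n_muscles = n_muscles,
              muscle_length = muscle_length, muscle_width = muscle_width,
              n_nonmuscle_cells = n_nonmuscle_cells,
              autophagy_level = autophagy_level,
              puncta_density = puncta_density,
              puncta_radius_mean = puncta_radius_mean,
              puncta_radius_sd = puncta_radius_sd,
              puncta_min_sep = puncta_min_sep,
              diffuse_gfp_level = diffuse_gfp_level,
              nuclear_gfp_level = nuclear_gfp_level,
              puncta_gfp_level = puncta_gfp_level,
              actin_level = actin_level,
              nonmuscle_actin_frac = nonmuscle_actin_frac,
              striation_amp = striation_amp,
              nuclear_radius = nuclear_radius,
              noise_sd = noise_sd,
              acidified_fraction = acidified_fraction,
              seed = as.integer(seed))
  class(cfg) <- "field_sim_config"
  validate_field_sim_config(cfg)
}

validate_field_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (length(cfg$canvas_size) != 2L || any(cfg$canvas_size < 8))
    stop("canvas_size must be two positive pixel dimensions")
  for (f in c("n_muscles", "puncta_density", "puncta_radius_mean",
              "puncta_radius_sd", "diffuse_gfp_level", "nuclear_gfp_level",
              "puncta_gfp_level", "actin_level", "nuclear_radius"))
    if (any(cfg[[f]] <= 0)) stop(sprintf("'%s' must be positive", f))
  if (cfg$autophagy_level < 0) stop("autophagy_level must be >= 0")
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (any(cfg$muscle_length <= 0) || any(cfg$muscle_width <= 0))
    stop("muscle dimensions must be positive")
  if (!is.null(cfg$acidified_fraction) &&
      (cfg$acidified_fraction < 0 || cfg$acidified_fraction >= 1))
    stop("acidified_fraction must be in [0, 1)")
  ## the largest muscle must fit on the canvas in any orientation
  need <- max(cfg$muscle_length) / 2 + max(cfg$muscle_width) / 2 + 2
  if (2 * need > min(cfg$canvas_size))
    stop("canvas too small to hold one muscle of the requested size")
  cfg
}

#' Configuration for a simulated replicate-plate RNAi screen
#'
#' Wells carry a per-well autophagy index
#' \deqn{y = A_0 \,\theta_g\, \pi_r\, \varepsilon,}
#' where \eqn{A_0} is the baseline index, \eqn{\theta_g} the gene's
#' multiplicative knockdown effect (1 = null, < 1 suppressor of puncta,
#' > 1 enhancer), \eqn{\pi_r} a per-plate lognormal effect shared by all
#' wells of replicate plate \eqn{r}, and \eqn{\varepsilon} i.i.d. lognormal
#' well noise.
#'
#' @param gene_effect_map named numeric vector of \eqn{\theta_g} per gene
#'   (all > 0). Must be non-empty.
#' @param n_plates number of replicate plates (>= 3; the SSMD estimator
#'   needs at least three replicates).
#' @param wells_per_plate plate size, at most 384 (16 x 24 layout).
#' @param amplicons_per_gene independent dsRNA amplicons per gene, each
#'   occupying one well per plate.
#' @param baseline_index \eqn{A_0}, dimensionless.
#' @param sigma_plate,sigma_well lognormal scale parameters (sd of the log)
#'   of the plate and well effects; >= 0.
#' @param neg_control_label,pos_control_label labels for the null negative
#'   control (lacZ-like, \eqn{\theta = 1}) and the strong-suppressor
#'   positive control (Atg18-like).
#' @param pos_control_theta \eqn{\theta} of the positive control; default
#'   0.1 (strong suppression).
#' @param n_neg_wells,n_pos_wells control wells per plate.
#' @param off_target_map optional named numeric vector of per-amplicon
#'   \eqn{\theta} overrides (names are amplicon ids), emulating off-target
#'   reagents.
#' @param seed integer seed.
#'
#' @return An object of class \code{screen_sim_config}.
#' @seealso [simulate_screen()]
#' @export
screen_sim_config <- function(gene_effect_map,
                              n_plates = 3L,
                              wells_per_plate = 384L,
                              amplicons_per_gene = 2L,
                              baseline_index = 0.02,
                              sigma_plate = 0.1,
                              sigma_well = 0.2,
                              neg_control_label = "lacZ",
                              pos_control_label = "Atg18",
                              pos_control_theta = 0.1,
                              n_neg_wells = 16L,
                              n_pos_wells = 8L,
                              off_target_map = NULL,
                              seed = 1L) {
  cfg <- list(gene_effect_map = gene_effect_map,
              n_plates = as.integer(n_plates),
              wells_per_plate = as.integer(wells_per_plate),
              amplicons_per_gene = as.integer(amplicons_per_gene),
              baseline_index = baseline_index,
              sigma_plate = sigma_plate, sigma_well = sigma_well,
              neg_control_label = neg_control_label,
              pos_control_label = pos_control_label,
              pos_control_theta = pos_control_theta,
              n_neg_wells = as.integer(n_neg_wells),
              n_pos_wells = as.integer(n_pos_wells),
              off_target_map = off_target_map,
              seed = as.integer(seed))
  class(cfg) <- "screen_sim_config"
  validate_screen_sim_config(cfg)
}

validate_screen_sim_config <- function(cfg) {
  if (length(cfg$gene_effect_map) == 0)
    stop("gene_effect_map is empty: at least one gene effect is required")
  if (is.null(names(cfg$gene_effect_map)) ||
      any(!nzchar(names(cfg$gene_effect_map))))
    stop("gene_effect_map must be a named numeric vector (gene -> theta)")
  if (any(cfg$gene_effect_map <= 0) || cfg$pos_control_theta <= 0)
    stop("all gene effects theta must be > 0")
  if (cfg$n_plates < 3)
    stop("n_plates must be >= 3 (SSMD needs at least three replicates)")
  if (cfg$sigma_plate < 0 || cfg$sigma_well < 0)
    stop("sigma_plate and sigma_well must be >= 0")
  if (cfg$wells_per_plate < 1 || cfg$wells_per_plate > 384)
    stop("wells_per_plate must be between 1 and 384")
  if (cfg$baseline_index <= 0) stop("baseline_index must be > 0")
  n_sample <- length(cfg$gene_effect_map) * cfg$amplicons_per_gene
  need <- n_sample + cfg$n_neg_wells + cfg$n_pos_wells
  if (need > cfg$wells_per_plate)
    stop(sprintf(
      "layout needs %d wells (%d sample + %d controls) but plate has %d",
      need, n_sample, cfg$n_neg_wells + cfg$n_pos_wells,
      cfg$wells_per_plate))
  cfg
}

#' Parameters of the granularity-style puncta detector
#'
#' Stand-in for the proprietary high-content "granularity" spot detector:
#' a white top-hat filter followed by a robust threshold and a size filter.
#'
#' @param tophat_radius structuring-disk radius in pixels; must be at least
#'   the largest expected punctum radius.
#' @param k_mad robust threshold multiplier: the threshold is the median of
#'   top-hat values inside the muscle plus \code{k_mad} MADs.
#' @param size_band length-2 numeric, the (min, max) component area in
#'   pixels kept as a punctum.
#' @param blur_sigma Gaussian pre-smoothing sigma (pixels) applied to the
#'   channel before the top-hat; suppresses the noise bias of the erosion
#'   step. 0 disables.
#' @param rel_floor lower bound on the threshold expressed as a fraction of
#'   the GFP dynamic range inside the muscle (99.9th percentile minus
#'   median). Keeps the detector silent on puncta-free fields where the MAD
#'   degenerates to 0, without breaking intensity-scale invariance. The
#'   default (together with \code{blur_sigma}) is calibrated so that
#'   noise-free synthetic recovery of the true puncta area is unbiased to
#'   within a few percent.
#' @param tophat_type \code{"reconstruction"} (default) computes the
#'   top-hat against a morphological opening-by-reconstruction, which does
#'   not produce rim artifacts at nuclei or cell boundaries; \code{"open"}
#'   uses the plain opening.
#' @param connectivity pixel connectivity for connected components (4 or 8).
#'
#' @return An object of class \code{granularity_params}.
#' @export
granularity_params <- function(tophat_radius = 8,
                               k_mad = 4,
                               size_band = c(4, 2000),
                               blur_sigma = 0.6,
                               rel_floor = 0.35,
                               tophat_type = c("reconstruction", "open"),
                               connectivity = 4L) {
  tophat_type <- match.arg(tophat_type)
  if (tophat_radius < 1) stop("tophat_radius must be >= 1")
  if (k_mad < 0) stop("k_mad must be >= 0")
  if (blur_sigma < 0) stop("blur_sigma must be >= 0")
  if (length(size_band) != 2L || size_band[1] >= size_band[2])
    stop("size_band must be (min, max) with min < max")
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  structure(list(tophat_radius = tophat_radius, k_mad = k_mad,
                 size_band = size_band, blur_sigma = blur_sigma,
                 rel_floor = rel_floor, tophat_type = tophat_type,
                 connectivity = as.integer(connectivity)),
            class = "granularity_params")
}

#' Parameters of RATS (Robust Automatic Threshold Selection)
#'
#' @param noise_threshold gradient magnitude below which pixels contribute
#'   no weight (gradient units).
#' @param lambda_factor exponent applied to the gradient when weighting
#'   pixel intensities; larger values concentrate the threshold estimate on
#'   the strongest edges.
#' @param min_leaf_size minimum quadtree leaf area in pixels; regions are
#'   recursively quartered until a further split would produce leaves below
#'   this size.
#' @param validity_divisor leaves are deemed valid when the sum of their
#'   gradient weights exceeds \code{noise_threshold^lambda_factor * area /
#'   validity_divisor}; invalid leaves inherit the nearest valid ancestor's
#'   threshold.
#'
#' @return An object of class \code{rats_params}.
#' @seealso [rats_threshold()]
#' @export
rats_params <- function(noise_threshold = 20,
                        lambda_factor = 3,
                        min_leaf_size = 100,
                        validity_divisor = 100) {
  if (noise_threshold < 0) stop("noise_threshold must be >= 0")
  if (lambda_factor <= 0) stop("lambda_factor must be > 0")
  if (min_leaf_size < 4) stop("min_leaf_size must be >= 4 pixels")
  structure(list(noise_threshold = noise_threshold,
                 lambda_factor = lambda_factor,
                 min_leaf_size = min_leaf_size,
                 validity_divisor = validity_divisor),
            class = "rats_params")
}

#' Parameters of phalloidin-based muscle segmentation
#'
#' @param blur_sigma Gaussian smoothing sigma (pixels) applied to the actin
#'   channel before thresholding.
#' @param threshold \code{"otsu"} or a numeric absolute intensity cutoff.
#' @param close_radius radius of the disk used for morphological closing.
#' @param min_area connected components smaller than this (pixels) are
#'   dropped; rejects phalloidin-dim non-muscle cells and debris.
#'
#' @return An object of class \code{segmentation_params}.
#' @export
segmentation_params <- function(blur_sigma = 1,
                                threshold = "otsu",
                                close_radius = 3,
                                min_area = 500) {
  if (blur_sigma < 0) stop("blur_sigma must be >= 0")
  if (min_area < 0) stop("min_area must be >= 0")
  structure(list(blur_sigma = blur_sigma, threshold = threshold,
                 close_radius = close_radius, min_area = min_area),
            class = "segmentation_params")
}

#' SSMD cutoffs for two-tier gene hit calling
#'
#' A gene is called a regulator ("multi" tier) when two or more of its
#' amplicons reach \code{|SSMD| >= multi_amplicon} in the same direction;
#' it is a "single"-tier candidate when exactly one amplicon reaches
#' \code{|SSMD| >= single_amplicon} and no other amplicon reaches
#' \code{multi_amplicon} in the opposite direction. Ties at exactly the
#' cutoff count as meeting it.
#'
#' @param multi_amplicon cutoff for the two-or-more-amplicon tier.
#' @param single_amplicon cutoff for the single-amplicon tier.
#' @return An object of class \code{hit_thresholds}.
#' @export
hit_thresholds <- function(multi_amplicon = 0.5, single_amplicon = 1.0) {
  if (!(single_amplicon >= multi_amplicon && multi_amplicon > 0))
    stop("thresholds must satisfy single_amplicon >= multi_amplicon > 0")
  structure(list(multi_amplicon = multi_amplicon,
                 single_amplicon = single_amplicon),
            class = "hit_thresholds")
}
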