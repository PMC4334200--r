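## 384-well coordinates A01..P24, row-major by row letter
.well_names <- function(n) {
  all <- as.vector(t(outer(LETTERS[1:16], sprintf("%02d", 1:24), paste0)))
  all[seq_len(n)]
}

#' Simulate a replicate-plate RNAi screen at the well level
#'
#' Builds one plate layout (shared by every replicate plate, as in a real
#' screen) with negative-control, positive-control and sample wells, then
#' draws per-well autophagy indices
#' \eqn{y = A_0\,\theta\,\pi_r\,\varepsilon} with a shared lognormal plate
#' effect \eqn{\pi_r} and i.i.d. lognormal well noise \eqn{\varepsilon}.
#' Control wells share one amplicon id each (one dsRNA reagent plated in
#' many wells); every sample amplicon occupies one well per plate.
#'
#' @param config a [screen_sim_config()].
#' @return A list with elements:
#'   \describe{
#'     \item{wells}{data frame with one row per well and plate:
#'       \code{plate_id}, \code{well}, \code{amplicon_id}, \code{gene},
#'       \code{role} (sample/neg_ctrl/pos_ctrl/empty), \code{index}.}
#'     \item{truth}{data frame \code{amplicon_id}, \code{gene},
#'       \code{role}, \code{theta}.}
#'     \item{plate_effects}{named numeric, the realized \eqn{\pi_r}.}
#'     \item{config}{the configuration used.}
#'   }
#' @examples
#' scr <- simulate_screen(screen_sim_config(c(geneA = 0.3, geneB = 1)))
#' head(scr$wells)
#' @export
simulate_screen <- function(config) {
  config <- validate_screen_sim_config(config)
  genes <- names(config$gene_effect_map)
  amp <- data.frame(
    amplicon_id = paste0(rep(genes, each = config$amplicons_per_gene),
                         "_amp", seq_len(config$amplicons_per_gene)),
    gene = rep(genes, each = config$amplicons_per_gene),
    role = "sample",
    theta = rep(unname(config$gene_effect_map),
                each = config$amplicons_per_gene),
    stringsAsFactors = FALSE)
  if (!is.null(config$off_target_map)) {
    hit <- match(amp$amplicon_id, names(config$off_target_map))
    amp$theta[!is.na(hit)] <- config$off_target_map[hit[!is.na(hit)]]
  }
  ctrl <- data.frame(
    amplicon_id = c(rep(config$neg_control_label, config$n_neg_wells),
                    rep(config$pos_control_label, config$n_pos_wells)),
    gene = c(rep(config$neg_control_label, config$n_neg_wells),
             rep(config$pos_control_label, config$n_pos_wells)),
    role = c(rep("neg_ctrl", config$n_neg_wells),
             rep("pos_ctrl", config$n_pos_wells)),
    theta = c(rep(1, config$n_neg_wells),
              rep(config$pos_control_theta, config$n_pos_wells)),
    stringsAsFactors = FALSE)

  ## spread controls evenly through the used wells, samples fill the rest
  wells <- .well_names(config$wells_per_plate)
  n_used <- nrow(amp) + nrow(ctrl)
  ctrl_pos <- unique(round(seq(1, n_used, length.out = nrow(ctrl))))
  while (length(ctrl_pos) < nrow(ctrl))   # collisions on tiny layouts
    ctrl_pos <- sort(unique(c(ctrl_pos, setdiff(seq_len(n_used),
                                                ctrl_pos)[1])))
  combined <- rbind(amp, ctrl)
  ord <- integer(n_used)
  ord[ctrl_pos] <- nrow(amp) + seq_len(nrow(ctrl))
  ord[setdiff(seq_len(n_used), ctrl_pos)] <- seq_len(nrow(amp))
  layout <- combined[ord, ]
  layout$well <- wells[seq_len(n_used)]
  if (config$wells_per_plate > n_used) {
    empty <- data.frame(amplicon_id = NA_character_, gene = NA_character_,
                        role = "empty", theta = NA_real_,
                        well = wells[(n_used + 1):config$wells_per_plate])
    layout <- rbind(layout, empty)
  }

  withr::with_seed(config$seed, {
    pi_r <- rlnorm(config$n_plates, 0, config$sigma_plate)
    names(pi_r) <- paste0("plate", seq_len(config$n_plates))
    out <- do.call(rbind, lapply(seq_len(config$n_plates), function(r) {
      eps <- rlnorm(nrow(layout), 0, config$sigma_well)
      data.frame(plate_id = names(pi_r)[r], well = layout$well,
                 amplicon_id = layout$amplicon_id, gene = layout$gene,
                 role = layout$role,
                 index = config$baseline_index * layout$theta * pi_r[r] *
                   eps,
                 stringsAsFactors = FALSE)
    }))
  })
  rownames(out) <- NULL
  truth <- unique(layout[layout$role != "empty",
                         c("amplicon_id", "gene", "role", "theta")])
  rownames(truth) <- NULL
  list(wells = out, truth = truth, plate_effects = pi_r, config = config)
}
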