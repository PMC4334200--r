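## Rendering primitives ------------------------------------------------------

## distance from every pixel of an (nr x nc) grid to the segment
## (cx, cy) +- (L/2) * (ux, uy); returns a matrix. Coordinates are
## (row = y, col = x), origin top-left, 1-based in R.
.pixel_grid <- function(nr, nc)
  list(px = matrix(rep(seq_len(nc), each = nr), nr, nc),
       py = matrix(rep(seq_len(nr), nc), nr, nc))

.disk_mask <- function(nr, nc, cx, cy, radius) {
  r1 <- max(1L, floor(cy - radius)); r2 <- min(nr, ceiling(cy + radius))
  c1 <- max(1L, floor(cx - radius)); c2 <- min(nc, ceiling(cx + radius))
  out <- matrix(FALSE, nr, nc)
  if (r1 > r2 || c1 > c2) return(out)
  sub_r <- r1:r2; sub_c <- c1:c2
  dd <- outer((sub_r - cy)^2, (sub_c - cx)^2, "+")
  out[sub_r, sub_c] <- dd <= radius^2
  out
}

## Place one capsule muscle; returns NULL if it cannot be placed without
## overlapping `occupied` within `tries` attempts (caller then allows
## overlap).
.place_capsule <- function(grid, nr, nc, len_range, wid_range, occupied,
                           tries = 40L) {
  for (i in seq_len(tries)) {
    L <- runif(1, len_range[1], len_range[2])
    R <- runif(1, wid_range[1], wid_range[2]) / 2
    phi <- runif(1, 0, pi)
    ux <- cos(phi); uy <- sin(phi)
    hx <- abs(ux) * L / 2 + R + 2
    hy <- abs(uy) * L / 2 + R + 2
    if (2 * hx >= nc || 2 * hy >= nr) next
    cx <- runif(1, hx, nc - hx)
    cy <- runif(1, hy, nr - hy)
    ## work on the capsule's bounding box only
    rs <- max(1, floor(cy - hy)):min(nr, ceiling(cy + hy))
    cs <- max(1, floor(cx - hx)):min(nc, ceiling(cx + hx))
    dx <- matrix(rep(cs, each = length(rs)), length(rs)) - cx
    dy <- matrix(rep(rs, length(cs)), length(rs)) - cy
    t <- pmin(pmax(dx * ux + dy * uy, -L / 2), L / 2)
    dloc <- sqrt((dx - t * ux)^2 + (dy - t * uy)^2)
    if (!any(dloc <= R + 3 & occupied[rs, cs])) {
      mask <- matrix(FALSE, nr, nc)
      mask[rs, cs] <- dloc <= R
      return(list(mask = mask, cx = cx, cy = cy,
                  ux = ux, uy = uy, L = L, R = R,
                  rs = rs, cs = cs, tloc = t))
    }
  }
  NULL
}

## Main generator ------------------------------------------------------------

#' Simulate a multi-channel muscle-culture field with ground truth
#'
#' Renders elongated muscle cells (capsules) among small non-muscle cells.
#' The actin (phalloidin) channel is bright inside muscles only (with an
#' optional sarcomere striation texture) and faint in non-muscle cells.
#' The GFP reporter channel carries the diffuse cytoplasmic level inside
#' muscles, an elevated level in muscle nuclei, and autophagosome puncta
#' rendered as hard disks whose count is Poisson with mean
#' \code{autophagy_level * puncta_density * muscle area}. Puncta centres
#' are cytoplasmic (outside nuclei) and puncta are clipped to the muscle,
#' so the ground-truth puncta mask is contained in the muscle mask and
#' \code{true_index} is exact by construction.
#'
#' With \code{acidified_fraction} set, a \code{red} channel is rendered in
#' which \emph{all} puncta appear, while the acidified subset is omitted
#' from GFP -- a tandem mCherry/GFP flux reporter.
#'
#' @param config a [field_sim_config()].
#' @param field_id,well_id,plate_id identifiers stored on the result.
#' @return A list with elements \code{field} ([image_field()]) and
#'   \code{truth} ([ground_truth()]).
#' @examples
#' sim <- simulate_field(field_sim_config(seed = 7))
#' sim$truth$true_index
#' @export
simulate_field <- function(config = field_sim_config(),
                           field_id = "field1", well_id = NA_character_,
                           plate_id = NA_character_) {
  config <- validate_field_sim_config(config)
  withr::with_seed(config$seed, {
    nr <- config$canvas_size[1]; nc <- config$canvas_size[2]
    grid <- .pixel_grid(nr, nc)
    muscle <- matrix(FALSE, nr, nc)
    muscles <- list()
    for (i in seq_len(config$n_muscles)) {
      cap <- .place_capsule(grid, nr, nc, config$muscle_length,
                            config$muscle_width, muscle)
      if (is.null(cap)) {              # crowded canvas: allow overlap
        cap <- .place_capsule(grid, nr, nc, config$muscle_length,
                              config$muscle_width,
                              matrix(FALSE, nr, nc), tries = 1L)
        if (is.null(cap)) next
      }
      muscles[[length(muscles) + 1L]] <- cap
      muscle <- muscle | cap$mask
    }
    if (length(muscles) == 0)
      stop("no muscle could be placed on the canvas")

    ## muscle nuclei: spaced along each capsule axis, kept fully interior
    ## (myonuclei sit inside the fibre; a nucleus never pokes out of the
    ## muscle boundary)
    nuclei <- matrix(FALSE, nr, nc)
    for (cap in muscles) {
      k <- max(1L, round(cap$L / 50))
      t_max <- max(cap$L / 2 - 4, 0)
      tpos <- pmin(pmax(
        seq(-t_max + cap$L / (2 * k), t_max, length.out = k) +
          runif(k, -cap$L / 10, cap$L / 10), -t_max), t_max)
      off_max <- max(cap$R - config$nuclear_radius - 1, 0)
      for (t in tpos) {
        off <- runif(1, -off_max, off_max)
        cx <- cap$cx + t * cap$ux - off * cap$uy
        cy <- cap$cy + t * cap$uy + off * cap$ux
        nuclei <- nuclei | .disk_mask(nr, nc, cx, cy, config$nuclear_radius)
      }
    }
    nuclei <- nuclei & muscle

    ## non-muscle cells: small, phalloidin-dim, GFP-negative
    nonmuscle <- matrix(FALSE, nr, nc)
    nm_nuclei <- matrix(FALSE, nr, nc)
    for (i in seq_len(config$n_nonmuscle_cells)) {
      r <- runif(1, 5, 8)
      cx <- runif(1, 1, nc); cy <- runif(1, 1, nr)
      nonmuscle <- nonmuscle | .disk_mask(nr, nc, cx, cy, r)
      nm_nuclei <- nm_nuclei | .disk_mask(nr, nc, cx, cy, r / 2)
    }
    nonmuscle <- nonmuscle & !muscle
    nm_nuclei <- nm_nuclei & !muscle

    ## puncta: Poisson count, cytoplasmic centres, disks clipped to muscle
    area <- sum(muscle)
    lambda <- config$autophagy_level * config$puncta_density * area
    n_puncta <- if (lambda > 0) rpois(1, lambda) else 0L
    cyto_idx <- which(muscle & !nuclei)
    puncta_all <- matrix(FALSE, nr, nc)
    centres <- matrix(numeric(0), ncol = 2)
    per_masks <- list()
    placed <- 0L
    guard <- 0L
    while (placed < n_puncta && length(cyto_idx) > 0 &&
           guard < 20L * n_puncta + 20L) {
      guard <- guard + 1L
      idx <- cyto_idx[sample.int(length(cyto_idx), 1)]
      cy <- ((idx - 1L) %% nr) + 1L
      cx <- ((idx - 1L) %/% nr) + 1L
      if (config$puncta_min_sep > 0 && nrow(centres) > 0 &&
          min(sqrt((centres[, 1] - cx)^2 + (centres[, 2] - cy)^2)) <
            config$puncta_min_sep) next
      rad <- max(1, rnorm(1, config$puncta_radius_mean,
                          config$puncta_radius_sd))
      m <- .disk_mask(nr, nc, cx, cy, rad) & muscle
      placed <- placed + 1L
      centres <- rbind(centres, c(cx, cy))
      per_masks[[placed]] <- m
      puncta_all <- puncta_all | m
    }
    n_puncta <- placed

    ## flux reporter: acidified puncta lose GFP but keep red
    acid <- rep(FALSE, n_puncta)
    if (!is.null(config$acidified_fraction) && n_puncta > 0)
      acid <- runif(n_puncta) < config$acidified_fraction
    puncta_gfp <- puncta_all
    if (any(acid)) {
      puncta_gfp <- matrix(FALSE, nr, nc)
      for (j in which(!acid)) puncta_gfp <- puncta_gfp | per_masks[[j]]
    }

    ## channels
    gfp <- config$diffuse_gfp_level * muscle
    gfp[nuclei] <- config$nuclear_gfp_level
    gfp <- gfp + config$puncta_gfp_level * puncta_gfp

    actin <- config$actin_level * muscle
    if (config$striation_amp > 0) {
      for (cap in muscles) {
        ## sarcomere banding along the axis, within the capsule's bbox
        t <- (grid$px[cap$rs, cap$cs] - cap$cx) * cap$ux +
          (grid$py[cap$rs, cap$cs] - cap$cy) * cap$uy
        mod <- 1 + config$striation_amp * sin(2 * pi * t / 8)
        sub <- cap$mask[cap$rs, cap$cs]
        loc <- actin[cap$rs, cap$cs]
        loc[sub] <- config$actin_level * mod[sub]
        actin[cap$rs, cap$cs] <- loc
      }
    }
    actin <- actin + config$nonmuscle_actin_frac * config$actin_level *
      nonmuscle
    nuclear <- 1000 * (nuclei | nm_nuclei)

    channels <- list(gfp = gfp, actin = actin, nuclear = nuclear)
    if (!is.null(config$acidified_fraction)) {
      red <- 0.1 * config$diffuse_gfp_level * muscle +
        config$puncta_gfp_level * puncta_all
      channels$red <- red
    }
    if (config$noise_sd > 0)
      channels <- lapply(channels, function(ch)
        ch + matrix(rnorm(nr * nc, 0, config$noise_sd), nr, nc))
    channels <- lapply(channels, function(ch)
      round(pmin(pmax(ch, 0), 65535)))

    list(field = image_field(channels, field_id = field_id,
                             well_id = well_id, plate_id = plate_id),
         truth = ground_truth(muscle, puncta_all, nuclei,
                              n_puncta = n_puncta,
                              n_acidified = sum(acid)))
  })
}
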