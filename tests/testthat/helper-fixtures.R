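# Shared small-scale configurations and hand-built objects for tests.

# modest field: two muscles on a 160 px canvas, fast to render and quantify
small_field_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(canvas_size = c(160, 160), n_muscles = 2,
         muscle_length = c(70, 100), muscle_width = c(28, 36),
         n_nonmuscle_cells = 8, seed = seed),
    list(...))
  do.call(field_sim_config, args)
}

# screen of null genes plus the two controls
null_screen_config <- function(seed = 1, n_genes = 20, ...) {
  screen_sim_config(setNames(rep(1, n_genes),
                             sprintf("g%03d", seq_len(n_genes))),
                    seed = seed, ...)
}

# a rectangular muscle with puncta disks at given centres/radii, as an
# image_field plus matching masks (no noise, no nuclei)
manual_field <- function(canvas = c(120, 120),
                         muscle_rows = 11:110, muscle_cols = 11:110,
                         puncta = list(), diffuse = 300, bright = 1800,
                         actin = 800) {
  m <- matrix(FALSE, canvas[1], canvas[2])
  m[muscle_rows, muscle_cols] <- TRUE
  p <- matrix(FALSE, canvas[1], canvas[2])
  for (pt in puncta) {
    rr <- outer((seq_len(canvas[1]) - pt[1])^2,
                (seq_len(canvas[2]) - pt[2])^2, "+")
    p <- p | (rr <= pt[3]^2)
  }
  p <- p & m
  gfp <- diffuse * m + (bright - diffuse) * p
  field <- image_field(list(gfp = gfp, actin = actin * m),
                       field_id = "manual")
  list(field = field, muscle = m, puncta = p)
}
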