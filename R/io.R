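#' Write and read multi-channel fields as per-channel 16-bit TIFFs
#'
#' Channels are written as \code{<field_id>_<role>.tif} (16-bit, values
#' stored as intensity / 65535). Masks use 8-bit TIFF via
#' [write_mask_tiff()].
#'
#' @param field an [image_field()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_field_tiff <- function(field, dir) {
  stopifnot(inherits(field, "image_field"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (role in names(field$channels)) {
    p <- file.path(dir, sprintf("%s_%s.tif", field$field_id, role))
    tiff::writeTIFF(pmin(field$channels[[role]], 65535) / 65535, p,
                    bits.per.sample = 16)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname write_field_tiff
#' @param field_id identifier used in the file name pattern.
#' @param channels channel roles to look for.
#' @param well_id,plate_id identifiers stored on the result.
#' @return \code{read_field_tiff} returns an [image_field()].
#' @export
read_field_tiff <- function(dir, field_id,
                            channels = c("gfp", "actin", "nuclear", "red"),
                            well_id = NA_character_,
                            plate_id = NA_character_) {
  chans <- list()
  for (role in channels) {
    p <- file.path(dir, sprintf("%s_%s.tif", field_id, role))
    if (file.exists(p))
      chans[[role]] <- round(tiff::readTIFF(p) * 65535)
  }
  if (length(chans) == 0)
    stop(sprintf("no channel TIFFs found for field '%s' in %s",
                 field_id, dir))
  image_field(chans, field_id = field_id, well_id = well_id,
              plate_id = plate_id)
}

#' Write a binary mask as an 8-bit TIFF
#'
#' @param mask logical matrix.
#' @param path output file.
#' @export
write_mask_tiff <- function(mask, path) {
  tiff::writeTIFF(mask * 1, path, bits.per.sample = 8)
  invisible(path)
}

#' Plate map and tabular I/O
#'
#' Plate maps are CSV with columns \code{plate_id}, \code{well},
#' \code{amplicon_id}, \code{gene}, \code{role}; well tables, amplicon
#' score tables and gene-call tables are TSV.
#'
#' @param x data frame to write.
#' @param path file path.
#' @name screen_io
#' @export
write_plate_map <- function(x, path) {
  req <- c("plate_id", "well", "amplicon_id", "gene", "role")
  stopifnot(all(req %in% names(x)))
  write.csv(x[, req], path, row.names = FALSE)
  invisible(path)
}

#' @rdname screen_io
#' @export
read_plate_map <- function(path) {
  pm <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("plate_id", "well", "amplicon_id", "gene", "role")
  if (!all(req %in% names(pm)))
    stop("plate map must have columns: ", paste(req, collapse = ", "))
  bad <- setdiff(unique(pm$role), c("sample", "neg_ctrl", "pos_ctrl",
                                    "empty"))
  if (length(bad))
    stop("unknown role(s) in plate map: ", paste(bad, collapse = ", "))
  pm
}

#' @rdname screen_io
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname screen_io
#' @export
read_tsv <- function(path) read.delim(path, stringsAsFactors = FALSE)

#' Write a reproducibility manifest
#'
#' Records the command, configuration echo, seed, package version and md5
#' checksums of the listed input and output files. Timestamps are omitted
#' so that reruns on identical inputs are byte-identical.
#'
#' @param path output JSON path.
#' @param command character command name.
#' @param config list echoed into the manifest.
#' @param seed integer seed used.
#' @param inputs,outputs character vectors of file paths to checksum.
#' @export
write_manifest <- function(path, command, config = list(), seed = NA,
                           inputs = character(0), outputs = character(0)) {
  sum_of <- function(files) {
    files <- files[file.exists(files)]
    as.list(setNames(unname(tools::md5sum(files)), basename(files)))
  }
  manifest <- list(
    command = command,
    package = "atgscreen",
    version = as.character(utils::packageVersion("atgscreen")),
    seed = seed,
    config = config,
    inputs = sum_of(inputs),
    outputs = sum_of(outputs))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
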