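#' Plate-median log normalization of well indices
#'
#' For each well, computes the normalized log difference
#' \deqn{d = \log(\mathrm{index}) - \mathrm{median}_{\mathrm{neg}}
#'   \log(\mathrm{index}),}
#' where the median is over the plate's negative-control wells.
#' Negative-control wells receive their own \eqn{d}. Wells with index 0
#' are offset by \eqn{\epsilon} = (smallest positive index on the plate)
#' \eqn{\times 10^{-3}} before the log (reported via a message); setting
#' \code{zero_rule = "drop"} removes them instead. Plates without positive
#' negative-control wells are rejected (their rows are dropped with a
#' warning). Rows with role \code{"empty"} or missing index are dropped
#' silently from the output.
#'
#' @param wells data frame with columns \code{plate_id}, \code{well},
#'   \code{amplicon_id}, \code{gene}, \code{role}, \code{index}.
#' @param zero_rule \code{"epsilon"} (default) or \code{"drop"}.
#' @param min_neg minimum negative-control wells per plate before a
#'   warning is issued.
#' @return The input rows (minus rejected plates/empty wells) with an
#'   added numeric column \code{d}.
#' @export
normalize_plate <- function(wells, zero_rule = c("epsilon", "drop"),
                            min_neg = 4L) {
  zero_rule <- match.arg(zero_rule)
  req <- c("plate_id", "well", "amplicon_id", "gene", "role", "index")
  if (!all(req %in% names(wells)))
    stop("wells table must have columns: ", paste(req, collapse = ", "))
  wells <- wells[wells$role != "empty" & !is.na(wells$index), , drop = FALSE]
  if (any(wells$index < 0)) stop("well indices must be >= 0")
  out <- lapply(split(wells, wells$plate_id), function(pl) {
    neg <- pl$index[pl$role == "neg_ctrl" & pl$index > 0]
    if (length(neg) == 0) {
      warning(sprintf(
        "plate '%s' rejected: no usable negative-control wells",
        pl$plate_id[1]), call. = FALSE)
      return(NULL)
    }
    if (length(neg) < min_neg)
      warning(sprintf("plate '%s' has only %d negative-control wells",
                      pl$plate_id[1], length(neg)), call. = FALSE)
    idx <- pl$index
    if (any(idx == 0)) {
      if (zero_rule == "drop") {
        pl <- pl[idx > 0, , drop = FALSE]
        idx <- pl$index
      } else {
        eps <- min(idx[idx > 0]) * 1e-3
        message(sprintf(
          "plate '%s': %d zero-index well(s) offset by epsilon = %g",
          pl$plate_id[1], sum(idx == 0), eps))
        idx <- idx + (idx == 0) * eps
      }
    }
    pl$d <- log(idx) - median(log(neg))
    pl
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0)
    stop("no plate had usable negative-control wells")
  rownames(out) <- NULL
  out
}

#' UMVUE correction factor for the sample SSMD
#'
#' @param n number of replicates.
#' @return \eqn{c(n) = \Gamma((n-1)/2)/\Gamma((n-2)/2)\,\sqrt{2/(n-1)}}.
#' @export
umvue_constant <- function(n) {
  gamma((n - 1) / 2) / gamma((n - 2) / 2) * sqrt(2 / (n - 1))
}

#' UMVUE estimate of the strictly standardized mean difference (SSMD)
#'
#' Scores a vector of per-replicate normalized log differences as
#' \deqn{\hat\beta = c(n)\,\bar d / s_d,}
#' with \eqn{c(n)} from [umvue_constant()] and \eqn{s_d} the sample
#' standard deviation (denominator \eqn{n-1}). This is the uniformly
#' minimum-variance unbiased estimator of the population SSMD
#' \eqn{\mu_d/\sigma_d} under normality.
#'
#' @param d numeric vector of replicate differences, length >= 3.
#' @return The SSMD score (scalar).
#' @examples
#' ssmd_umvue(c(1, 2, 3))   # = (1/sqrt(pi)) * 2
#' @export
ssmd_umvue <- function(d) {
  d <- as.numeric(d)
  if (any(!is.finite(d))) stop("differences must be finite")
  n <- length(d)
  if (n < 3) stop("insufficient replicates: SSMD needs n >= 3")
  s <- sd(d)
  if (s == 0)
    stop(sprintf(
      "sd of differences is zero (mean has sign %+d); SSMD undefined",
      sign(mean(d))))
  umvue_constant(n) * mean(d) / s
}

#' Score every amplicon of a normalized well table
#'
#' Gathers each amplicon's normalized log differences \code{d} across
#' replicate plates and applies [ssmd_umvue()]. Amplicons present on fewer
#' than \code{min_plates} plates are excluded with a message.
#'
#' With \code{aggregate = "wells"} (default) every well of an amplicon is
#' one replicate; a control dsRNA plated in many wells is thus scored with
#' all of its wells, which is what keeps null negative-control scores
#' tightly inside \eqn{\pm 0.5} (see the package vignette). With
#' \code{aggregate = "plate_mean"}, wells of the same amplicon within one
#' plate are first averaged on the log scale so that the replicate unit is
#' the plate. The two modes coincide for amplicons with one well per plate.
#'
#' @param wells_d output of [normalize_plate()] (must contain \code{d}).
#' @param min_plates minimum number of distinct replicate plates.
#' @param aggregate \code{"wells"} or \code{"plate_mean"}.
#' @return Data frame with one row per scored amplicon: \code{amplicon_id},
#'   \code{gene}, \code{role}, \code{n_plates}, \code{n} (replicates used),
#'   \code{mean_d}, \code{ssmd}.
#' @export
score_amplicons <- function(wells_d, min_plates = 3L,
                            aggregate = c("wells", "plate_mean")) {
  aggregate <- match.arg(aggregate)
  if (!"d" %in% names(wells_d))
    stop("wells table has no 'd' column; run normalize_plate() first")
  w <- wells_d[!is.na(wells_d$amplicon_id), , drop = FALSE]
  res <- lapply(split(w, w$amplicon_id), function(a) {
    plates <- unique(a$plate_id)
    if (length(plates) < min_plates) {
      message(sprintf(
        "amplicon '%s' excluded: on %d plate(s), need >= %d",
        a$amplicon_id[1], length(plates), min_plates))
      return(NULL)
    }
    d <- if (aggregate == "plate_mean")
      as.numeric(tapply(a$d, a$plate_id, mean)) else a$d
    data.frame(amplicon_id = a$amplicon_id[1], gene = a$gene[1],
               role = a$role[1], n_plates = length(plates),
               n = length(d), mean_d = mean(d), ssmd = ssmd_umvue(d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out))
    return(data.frame(amplicon_id = character(0), gene = character(0),
                      role = character(0), n_plates = integer(0),
                      n = integer(0), mean_d = numeric(0),
                      ssmd = numeric(0)))
  rownames(out) <- NULL
  out
}

#' Per-plate control quality report
#'
#' Summarizes the behaviour of negative and positive control wells after
#' plate normalization: counts, median normalized difference, and spread.
#'
#' @param wells_d output of [normalize_plate()].
#' @return Data frame with one row per plate and control role.
#' @export
control_qc <- function(wells_d) {
  ctrl <- wells_d[wells_d$role %in% c("neg_ctrl", "pos_ctrl"), ,
                  drop = FALSE]
  if (nrow(ctrl) == 0)
    return(data.frame(plate_id = character(0), role = character(0),
                      n_wells = integer(0), median_d = numeric(0),
                      iqr_d = numeric(0)))
  out <- do.call(rbind, lapply(
    split(ctrl, list(ctrl$plate_id, ctrl$role), drop = TRUE),
    function(g) data.frame(
      plate_id = g$plate_id[1], role = g$role[1], n_wells = nrow(g),
      median_d = median(g$d),
      iqr_d = unname(diff(quantile(g$d, c(0.25, 0.75)))),
      stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out[order(out$plate_id, out$role), ]
}

#' Two-sample Student's t-test p-value
#'
#' Classical equal-variance two-sided two-sample t-test, as used for group
#' comparisons of image-derived measurements.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return The two-sided p-value.
#' @export
compare_groups <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 observations")
  pooled <- (length(a) - 1) * var(a) + (length(b) - 1) * var(b)
  if (pooled == 0) stop("zero pooled variance: p-value undefined")
  t.test(a, b, var.equal = TRUE)$p.value
}
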