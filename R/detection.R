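# Neutral-background threshold calibration, the per-sample detection rule
# and power tables.

#' Calibrate detection thresholds from neutral background scores
#'
#' For each statistic, each neutral region contributes its extreme value
#' (in the sweep direction) per non-overlapping 200-kb block -- the
#' extreme of the windows or grid points lying entirely inside the block
#' -- giving 3 values per region; the pooled block extremes are cut at
#' the requested false-positive rates by the order-statistic convention
#' (the k-th most extreme value with k = round(fpr * M), no
#' interpolation), so applying a cutoff back to its calibration set
#' detects exactly the nominal fraction of blocks. The whole-region
#' variant (`span = "region"`) uses the extreme over all windows instead.
#' Blocks in which every window is missing are skipped and counted.
#'
#' @param nb_scores Score-track list from [score_set()] on neutral
#'   background samples.
#' @param fprs Nominal false positive rates.
#' @param region_length,block Region and block lengths in bp.
#' @param span `"block"` (the detection unit is a 200-kb block) or
#'   `"region"`.
#' @return A `threshold_table` data.frame: `stat`, `fpr`, `span`,
#'   `direction`, `cutoff`, `n_values`, `n_skipped`.
#' @export
calibrate_thresholds <- function(nb_scores, fprs = c(0.05, 0.01, 0.001),
                                 region_length = 600000, block = 200000,
                                 span = c("block", "region")) {
  span <- match.arg(span)
  out <- list()
  for (s in names(nb_scores)) {
    mat <- nb_scores[[s]]
    pos <- attr(mat, "pos")
    dir <- attr(mat, "direction")
    ext <- function(x) {
      if (all(is.na(x))) NA_real_
      else if (dir == "high") max(x, na.rm = TRUE) else min(x, na.rm = TRUE)
    }
    if (span == "block") {
      starts <- seq(0, region_length - block, by = block)
      vals <- unlist(lapply(starts, function(b) {
        # windows fully inside the block; bp-grid stats use their points
        w <- grid_cols_in_block(s, pos, b, b + block)
        apply(mat[, w, drop = FALSE], 1, ext)
      }))
    } else {
      vals <- apply(mat, 1, ext)
    }
    n_skipped <- sum(is.na(vals))
    vals <- vals[!is.na(vals)]
    M <- length(vals)
    sorted <- if (dir == "high") sort(vals, decreasing = TRUE) else sort(vals)
    for (f in fprs) {
      k <- max(1L, round(f * M))
      out[[length(out) + 1L]] <- data.frame(
        stat = s, fpr = f, span = span, direction = dir,
        cutoff = sorted[k], n_values = M, n_skipped = n_skipped)
    }
  }
  structure(do.call(rbind, out), class = c("threshold_table", "data.frame"))
}

# Columns of a score track lying entirely inside [from, to): window
# statistics occupy 100-kb windows starting at `pos`; bp-grid statistics
# (clr, xpclr) are points.
grid_cols_in_block <- function(stat, pos, from, to) {
  if (stat %in% c("clr", "xpclr")) {
    which(pos >= from & pos < to)
  } else {
    width <- 100000
    which(pos >= from & pos + width <= to)
  }
}

#' Detection rule for one score track
#'
#' A sample is detected when at least one in-span window (or grid point)
#' scores beyond the cutoff in the sweep direction ("beyond" includes
#' equality, matching the order-statistic calibration). The span is the
#' first 200 kb (centred on the adaptive locus) or the whole region.
#' Tracks whose in-span values are all missing are undetermined (`NA`).
#'
#' @param track Numeric vector of one sample's per-window values.
#' @param pos Window start / grid positions for `track`.
#' @param cutoff,direction Threshold row values.
#' @param stat Statistic name (window span handling).
#' @param span `"first200kb"` or `"region"`.
#' @return `TRUE`, `FALSE` or `NA`.
#' @export
detect <- function(track, pos, cutoff, direction, stat, span = "first200kb") {
  cols <- if (span == "first200kb") grid_cols_in_block(stat, pos, 0, 200000)
          else seq_along(track)
  x <- track[cols]
  if (all(is.na(x))) return(NA)
  if (direction == "high") any(x >= cutoff, na.rm = TRUE)
  else any(x <= cutoff, na.rm = TRUE)
}

#' Detection power of each statistic on a scored sample set
#'
#' Fraction of samples detected per statistic and false positive rate,
#' applying [detect()] with the given threshold table. Undetermined
#' samples are excluded from numerator and denominator (count reported).
#'
#' @param scores Score-track list from [score_set()].
#' @param thresholds A `threshold_table` (same demography as the scores,
#'   unless a mismatched calibration is being studied deliberately).
#' @param span `"first200kb"` or `"region"`.
#' @return data.frame `stat`, `fpr`, `power`, `n`, `n_undetermined`.
#' @export
power_table <- function(scores, thresholds, span = "first200kb") {
  out <- list()
  for (s in intersect(names(scores), unique(thresholds$stat))) {
    mat <- scores[[s]]
    pos <- attr(mat, "pos")
    th <- thresholds[thresholds$stat == s, ]
    for (i in seq_len(nrow(th))) {
      det <- apply(mat, 1, detect, pos = pos, cutoff = th$cutoff[i],
                   direction = th$direction[i], stat = s, span = span)
      out[[length(out) + 1L]] <- data.frame(
        stat = s, fpr = th$fpr[i],
        power = mean(det, na.rm = TRUE),
        n = sum(!is.na(det)), n_undetermined = sum(is.na(det)))
    }
  }
  do.call(rbind, out)
}
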