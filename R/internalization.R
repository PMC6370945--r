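# Extracellular-label internalization time courses and area-fraction-
# calibrated puncta detection.

#' Total region signal on a plane
#' @param plane 2D intensity matrix.
#' @param region_mask logical matrix selecting the region's pixels.
#' @return list with `total` (summed intensity) and `n_pixels`.
#' @export
region_total <- function(plane, region_mask) {
  stopifnot(all(dim(plane) == dim(region_mask)))
  list(total = sum(plane[region_mask]), n_pixels = sum(region_mask))
}

#' Normalize an internalization time course
#'
#' Per genotype: laser-off background (per pixel) is subtracted from each
#' raw total, and readings are divided by the genotype's mean background-
#' corrected 0-min value, so the 0-min group mean is exactly 1. Negative
#' corrected readings are clipped to 0 with a warning.
#'
#' @param records data frame with `wing_id`, `genotype_region`, `time_min`,
#'   `total_signal`, `n_pixels` (e.g. from [simulate_internalization()] or
#'   assembled from [region_total()] measurements).
#' @param background laser-off background per pixel.
#' @param reference_time the chase time serving as the normalization
#'   reference (default 0 min).
#' @return the input with a `normalized_intensity` column appended.
#' @export
normalize_timecourse <- function(records, background = 0, reference_time = 0) {
  need <- c("wing_id", "genotype_region", "time_min", "total_signal", "n_pixels")
  stopifnot(all(need %in% names(records)))
  corrected <- records$total_signal - background * records$n_pixels
  if (any(corrected < 0)) {
    warning("negative background-corrected signal clipped to 0")
    corrected[corrected < 0] <- 0
  }
  out <- records
  out$normalized_intensity <- NA_real_
  for (g in unique(records$genotype_region)) {
    gi <- records$genotype_region == g
    ref <- corrected[gi & records$time_min == reference_time]
    if (length(ref) == 0) {
      stop("protocol error: genotype ", g, " has no ", reference_time,
           "-min reference measurement")
    }
    ref_mean <- mean(ref)
    if (ref_mean <= 0) stop("non-positive reference mean for genotype ", g)
    out$normalized_intensity[gi] <- corrected[gi] / ref_mean
  }
  out
}

#' Measure and normalize an extracellular time course from planes
#'
#' Convenience wrapper: sums each wing/time plane over its region pixels
#' (the 3-brightest-slice average should be supplied as the plane), then
#' applies [normalize_timecourse()].
#'
#' @param measurements list of lists with `wing_id`, `genotype_region`,
#'   `time_min`, `plane`, `region_mask`.
#' @param background laser-off background per pixel.
#' @return normalized records data frame.
#' @export
extracellular_timecourse <- function(measurements, background = 0) {
  rows <- lapply(measurements, function(m) {
    tot <- region_total(m$plane, m$region_mask)
    data.frame(wing_id = m$wing_id, genotype_region = m$genotype_region,
               time_min = m$time_min, total_signal = tot$total,
               n_pixels = tot$n_pixels, stringsAsFactors = FALSE)
  })
  normalize_timecourse(do.call(rbind, rows), background = background)
}

#' ANOVA with Dunnett comparisons against the 0-min control
#'
#' Within each genotype, one-way ANOVA of normalized intensity across chase
#' times followed by Dunnett many-to-one comparisons to the reference time.
#'
#' @param records normalized records from [normalize_timecourse()].
#' @param control_time reference chase time (default 0).
#' @return named list (per genotype) of [anova_dunnett()] results.
#' @export
timecourse_anova <- function(records, control_time = 0) {
  stopifnot("normalized_intensity" %in% names(records))
  out <- list()
  for (g in unique(records$genotype_region)) {
    sub <- records[records$genotype_region == g, ]
    if (length(unique(sub$time_min)) < 2) {
      stop("timecourse_anova needs >= 2 timepoints for genotype ", g)
    }
    out[[g]] <- anova_dunnett(sub$normalized_intensity,
                              factor(sub$time_min),
                              control = as.character(control_time))
  }
  out
}

#' Calibrate the puncta threshold on the wild-type region
#'
#' Finds the smallest observed intensity `t*` in the wild-type region such
#' that the fraction of wild-type pixels strictly above `t*` is at most
#' `target_fraction` (the area-fraction rule: 1% of wild-type area called
#' puncta). Equivalently the `(1 - target)` empirical quantile with "higher"
#' interpolation. The achieved fraction is reported; it can fall below the
#' target when ties cross the cutoff.
#'
#' @param plane 2D intensity matrix.
#' @param wt_mask logical matrix marking wild-type pixels.
#' @param target_fraction target above-threshold area fraction in `(0, 1]`
#'   (default 0.01).
#' @return list with `threshold`, `achieved_fraction`, `n_pixels`.
#' @export
find_puncta_threshold <- function(plane, wt_mask, target_fraction = 0.01) {
  stopifnot(all(dim(plane) == dim(wt_mask)))
  if (target_fraction <= 0 || target_fraction > 1) {
    stop("target_fraction must be in (0, 1]")
  }
  v <- plane[wt_mask]
  n <- length(v)
  if (n == 0) stop("wild-type region is empty")
  if (min(v) == max(v)) {
    warning("constant wild-type region: threshold equals its value, zero puncta")
    return(list(threshold = v[1], achieved_fraction = 0, n_pixels = n))
  }
  k <- floor(target_fraction * n)        # pixels allowed above threshold
  vs <- sort(v)
  if (k >= n) {
    thr <- vs[1] - 1                     # everything is a punctum
  } else {
    thr <- vs[n - k]                     # smallest value with <= k above it
  }
  ach <- sum(v > thr) / n
  list(threshold = thr, achieved_fraction = ach, n_pixels = n)
}

#' 8-connected component labeling of a binary image
#'
#' Iterative minimum-label propagation over the 8-neighbourhood until a
#' fixed point; labels are renumbered 1..n in first-pixel order.
#'
#' @param fg logical matrix of foreground pixels.
#' @return integer matrix of component labels (0 = background).
#' @export
label_components8 <- function(fg) {
  stopifnot(is.matrix(fg))
  H <- nrow(fg); W <- ncol(fg)
  lab <- matrix(0L, H, W)
  lab[fg] <- which(fg)
  repeat {
    prev <- lab
    for (i in seq_len(nrow(NEIGH8))) {
      nb <- shift_mat(lab, NEIGH8[i, 1], NEIGH8[i, 2], fill = 0L)
      upd <- fg & nb > 0L & nb < lab
      lab[upd] <- nb[upd]
    }
    if (identical(lab, prev)) break
  }
  u <- unique(lab[fg])
  lab[fg] <- match(lab[fg], sort(u))
  lab
}

#' Extract puncta above a fixed threshold
#'
#' Puncta are 8-connected components of strictly-above-threshold pixels
#' within the region; components smaller than `min_area` are dropped. The
#' threshold is taken as given — for mutant tissue it must be the one
#' calibrated on the wild-type region of the same wing, never recalibrated.
#'
#' @param plane 2D intensity matrix.
#' @param region_mask logical matrix selecting the region.
#' @param threshold intensity threshold `t*`.
#' @param min_area minimum punctum area in px (default 1).
#' @param region region name carried into the result.
#' @return list of class `PunctaSet`: `threshold`, `region`, `n_region_px`,
#'   and `puncta` (data frame: `area_px`, `integrated_intensity`,
#'   `mean_intensity`, `centroid_row`, `centroid_col`).
#' @export
extract_puncta <- function(plane, region_mask, threshold, min_area = 1,
                           region = "wildtype") {
  stopifnot(is.finite(threshold), all(dim(plane) == dim(region_mask)))
  fg <- region_mask & plane > threshold
  lab <- label_components8(fg)
  ids <- setdiff(unique(as.integer(lab)), 0L)
  if (length(ids)) {
    pix <- which(lab > 0L)
    l <- lab[pix]
    inten <- plane[pix]
    rr <- ((pix - 1L) %% nrow(plane)) + 1L
    cc <- ((pix - 1L) %/% nrow(plane)) + 1L
    area <- as.integer(tapply(rep(1L, length(l)), l, sum))
    puncta <- data.frame(
      area_px = area,
      integrated_intensity = as.numeric(tapply(inten, l, sum)),
      mean_intensity = as.numeric(tapply(inten, l, mean)),
      centroid_row = as.numeric(tapply(rr, l, mean)),
      centroid_col = as.numeric(tapply(cc, l, mean)))
    puncta <- puncta[puncta$area_px >= min_area, , drop = FALSE]
    rownames(puncta) <- NULL
  } else {
    puncta <- data.frame(area_px = integer(), integrated_intensity = numeric(),
                         mean_intensity = numeric(), centroid_row = numeric(),
                         centroid_col = numeric())
  }
  structure(list(threshold = threshold, region = region,
                 n_region_px = sum(region_mask), puncta = puncta),
            class = "PunctaSet")
}

#' @export
print.PunctaSet <- function(x, ...) {
  cat(sprintf("PunctaSet (%s): %d puncta over %d px, threshold %.4g\n",
              x$region, nrow(x$puncta), x$n_region_px, x$threshold))
  invisible(x)
}

#' Per-wing mutant/wild-type puncta ratios
#'
#' Count ratio is normalized per unit region area (regions differ in size);
#' size and intensity ratios compare per-punctum means. Wings whose
#' wild-type region has no puncta yield undefined ratios (`NA` with a
#' warning) and should be excluded from the t test.
#'
#' @param wt,mut `PunctaSet`s for the two regions of one wing, sharing the
#'   wild-type-calibrated threshold.
#' @return one-row data frame: `count_ratio`, `area_ratio`,
#'   `intensity_ratio`.
#' @export
puncta_wing_ratios <- function(wt, mut) {
  stopifnot(inherits(wt, "PunctaSet"), inherits(mut, "PunctaSet"))
  if (!isTRUE(all.equal(wt$threshold, mut$threshold))) {
    stop("mutant puncta must be extracted with the wild-type threshold")
  }
  if (nrow(wt$puncta) == 0) {
    warning("no wild-type puncta: wing excluded (undefined ratio)")
    return(data.frame(count_ratio = NA_real_, area_ratio = NA_real_,
                      intensity_ratio = NA_real_))
  }
  dens_wt <- nrow(wt$puncta) / wt$n_region_px
  dens_mut <- nrow(mut$puncta) / mut$n_region_px
  data.frame(
    count_ratio = dens_mut / dens_wt,
    area_ratio = if (nrow(mut$puncta)) mean(mut$puncta$area_px) /
      mean(wt$puncta$area_px) else NA_real_,
    intensity_ratio = if (nrow(mut$puncta)) mean(mut$puncta$mean_intensity) /
      mean(wt$puncta$mean_intensity) else NA_real_)
}

#' One-sample t tests of puncta ratios across wings
#'
#' @param ratios data frame of per-wing ratios (rows from
#'   [puncta_wing_ratios()]); `NA` rows are dropped per measure.
#' @return named list of `wingpol_test`s (`count_ratio`, `area_ratio`,
#'   `intensity_ratio`), each tested against 1.0.
#' @export
puncta_ratio_tests <- function(ratios) {
  out <- list()
  for (m in c("count_ratio", "area_ratio", "intensity_ratio")) {
    v <- ratios[[m]]
    v <- v[is.finite(v)]
    out[[m]] <- if (length(v) >= 2 && stats::sd(v) > 0) one_sample_t(v, 1)
                else NULL
  }
  out
}
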