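# Per-cell polarity (maximum asymmetry ratio), axial circular statistics,
# per-wing summaries and clone intensity-ratio statistics.

axial_distance <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

#' Per-cell polarity magnitude and angle (maximum asymmetry ratio)
#'
#' For each candidate axis `theta` on a regular grid, boundary samples are
#' split into an axial window (`axial distance(psi, theta) <= half_width`)
#' and its complement, and the asymmetry ratio `R(theta)` is the ratio of
#' the window's mean intensity to the complement's. The polarity magnitude
#' is `max over theta of max(R, 1/R)` (so always >= 1) and the polarity
#' angle is the axis achieving it (`theta` when the window is brighter,
#' `theta + 90` otherwise); ties resolve to the smallest axis.
#'
#' @param samples data frame of boundary samples from
#'   [sample_cell_boundary()] (`intensity`, `psi`, `cell_id`).
#' @param axis_step grid step in degrees (default 1).
#' @param half_width axial window half-width in degrees (default 45, i.e. a
#'   90 degree window versus its complement).
#' @return list of class `CellPolarity`: `cell_id`, `magnitude`, `angle`,
#'   `mean_boundary_intensity`, `n_samples`.
#' @export
cell_polarity <- function(samples, axis_step = 1, half_width = 45) {
  if (nrow(samples) < 8) {
    stop("cell_polarity requires >= 8 boundary samples (cell skipped)")
  }
  axes <- seq(0, 180 - axis_step, by = axis_step)
  inwin <- outer(samples$psi, axes, axial_distance) <= half_width
  n_in <- colSums(inwin)
  n_out <- nrow(samples) - n_in
  # axes whose window or complement is empty carry no ratio; skip them and
  # error only when the boundary leaves no testable axis at all
  valid <- n_in > 0L & n_out > 0L
  if (!any(valid)) {
    stop("degenerate boundary geometry: empty angular class for every axis")
  }
  s_in <- colSums(samples$intensity * inwin)
  s_all <- sum(samples$intensity)
  mean_in <- s_in / n_in
  mean_out <- (s_all - s_in) / n_out
  if (any(mean_out[valid] <= 0) || any(mean_in[valid] <= 0)) {
    stop("degenerate intensities: zero mean in an angular class")
  }
  r <- mean_in / mean_out
  rmax <- pmax(r, 1 / r)
  rmax[!valid] <- -Inf
  i <- which.max(rmax)  # first maximum = smallest axis on ties
  angle <- if (r[i] >= 1) axes[i] else (axes[i] + 90) %% 180
  structure(list(cell_id = samples$cell_id[1], magnitude = rmax[i],
                 angle = angle,
                 mean_boundary_intensity = mean(samples$intensity),
                 n_samples = nrow(samples)),
            class = "CellPolarity")
}

#' Intensity-weighted nematic order parameter of a cell boundary
#'
#' `m = |sum I * exp(2i psi)| / sum I`, the standard nematic magnitude; used
#' as an independent cross-check of the asymmetry-ratio statistic (the two
#' should rank cells near-identically). With `bin_deg > 0` (default 15) the
#' boundary samples are first averaged within regular `psi` bins and the
#' resultant computed over per-bin mean intensities, which removes the
#' contribution of the boundary's own sampling-density anisotropy (a
#' pixelated polygon samples some orientations more densely than others
#' even when the signal is flat); `bin_deg = 0` gives the raw weighted sum.
#'
#' @param samples boundary samples as in [cell_polarity()].
#' @param bin_deg width of the axial bins in degrees (0 = no binning).
#' @return list with `magnitude` (in `[0, 1]`) and `angle` (degrees,
#'   `[0, 180)`).
#' @export
cell_nematic <- function(samples, bin_deg = 15) {
  if (bin_deg > 0) {
    b <- floor((samples$psi %% 180) / bin_deg)
    w <- as.numeric(tapply(samples$intensity, b, mean))
    centers <- (sort(unique(b)) + 0.5) * bin_deg
    ang <- 2 * centers * pi / 180
  } else {
    w <- samples$intensity
    ang <- 2 * samples$psi * pi / 180
  }
  zx <- sum(w * cos(ang))
  zy <- sum(w * sin(ang))
  list(magnitude = sqrt(zx^2 + zy^2) / sum(w),
       angle = (atan2(zy, zx) / 2 * 180 / pi) %% 180)
}

#' Axial circular spread of orientation angles
#'
#' Standard axial-statistics dispersion: angles are doubled, the mean
#' resultant length `Rbar` of the unit vectors computed, and the circular
#' standard deviation `sqrt(-2 log Rbar)` halved and converted back to
#' degrees. `Rbar = 0` (e.g. an antipodal axial pair) means maximal
#' dispersion and returns `Inf` with attribute `undefined = TRUE`.
#'
#' @param angles_deg orientations in degrees, axial (mod 180); `n >= 2`
#'   unless `allow_single`.
#' @param allow_single permit a single angle (spread undefined).
#' @return spread in degrees (>= 0), possibly `Inf` flagged `undefined`.
#' @export
axial_spread <- function(angles_deg, allow_single = FALSE) {
  if (length(angles_deg) == 0) stop("axial_spread: empty input")
  if (length(angles_deg) < 2) {
    if (allow_single) return(structure(Inf, undefined = TRUE))
    stop("axial_spread requires >= 2 angles")
  }
  a <- 2 * angles_deg * pi / 180
  rbar <- sqrt(mean(cos(a))^2 + mean(sin(a))^2)
  if (rbar < 1e-12) return(structure(Inf, undefined = TRUE))
  0.5 * sqrt(-2 * log(rbar)) * 180 / pi
}

#' Axial mean of orientation angles
#' @param angles_deg orientations in degrees (mod 180).
#' @return mean orientation in degrees, `[0, 180)`.
#' @export
axial_mean <- function(angles_deg) {
  a <- 2 * angles_deg * pi / 180
  (atan2(mean(sin(a)), mean(cos(a))) / 2 * 180 / pi) %% 180
}

#' Polarity of every analyzable cell in a wing
#'
#' Runs [cell_polarity()] over all cells, dropping cells that touch the
#' image border, cells not in a pure genotype region (genotype `excluded`),
#' and cells with fewer than 8 boundary samples (with a warning).
#'
#' @param plane analysis plane (e.g. from [select_bright_slices()]).
#' @param label a [label_mask()].
#' @param clone a [clone_map()].
#' @param axis_step,half_width passed to [cell_polarity()].
#' @return data frame: `cell_id`, `region`, `magnitude`, `angle`,
#'   `mean_boundary_intensity`, `n_samples`.
#' @export
wing_cell_polarity <- function(plane, label, clone, axis_step = 1,
                               half_width = 45) {
  skel <- build_skeleton(label, clone)
  drop <- border_cells(label)
  ids <- setdiff(cell_ids(label), drop)
  geno <- skel$cell_genotype
  out <- list()
  for (id in ids) {
    g <- geno[as.character(id)]
    if (is.na(g) || g == CLONE_CODES[["excluded"]]) next
    cp <- tryCatch({
      smp <- sample_cell_boundary(plane, label, id, skeleton = skel)
      cell_polarity(smp, axis_step = axis_step, half_width = half_width)
    }, error = function(e) {
      warning("cell ", id, " skipped: ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(cp)) next
    out[[length(out) + 1L]] <- data.frame(
      cell_id = id,
      region = names(CLONE_CODES)[match(g, CLONE_CODES)],
      magnitude = cp$magnitude, angle = cp$angle,
      mean_boundary_intensity = cp$mean_boundary_intensity,
      n_samples = cp$n_samples, stringsAsFactors = FALSE)
  }
  if (length(out) == 0) stop("no analyzable cells in wing")
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Per-wing polarity summary for one genotype region
#'
#' @param cells per-cell polarity table from [wing_cell_polarity()].
#' @param region region to summarize (`"wildtype"` or `"mutant"`).
#' @return list: `region`, `n_cells`, `mean_magnitude`, `angle_spread`
#'   (degrees; `Inf` when dispersion is maximal or only one cell),
#'   `mean_angle`.
#' @export
wing_summary <- function(cells, region = "wildtype") {
  sub <- cells[cells$region == region, , drop = FALSE]
  if (nrow(sub) < 1) stop("no cells in region ", region)
  spread <- axial_spread(sub$angle, allow_single = TRUE)
  list(region = region, n_cells = nrow(sub),
       mean_magnitude = mean(sub$magnitude),
       angle_spread = spread,
       mean_angle = axial_mean(sub$angle))
}

#' Mean membrane intensity of a genotype region
#'
#' Arithmetic mean of the analysis plane over skeleton pixels tagged with
#' the region; the numerator of the per-wing mutant/wild-type ratio.
#'
#' @param plane 2D intensity matrix.
#' @param skeleton a [build_skeleton()] result of matching shape.
#' @param region `"wildtype"`, `"mutant"` or `"excluded"`.
#' @return scalar mean intensity.
#' @export
region_membrane_mean <- function(plane, skeleton, region) {
  px <- skeleton$pixels[skeleton$pixels$region == region, , drop = FALSE]
  if (nrow(px) == 0) stop("no membrane pixels tagged ", region)
  mean(plane[cbind(px$row, px$col)])
}

#' Per-wing mutant/wild-type membrane intensity ratio
#' @param plane analysis plane.
#' @param skeleton a [build_skeleton()] result.
#' @return scalar ratio (mutant mean / wild-type mean).
#' @export
clone_intensity_ratio <- function(plane, skeleton) {
  wt <- region_membrane_mean(plane, skeleton, "wildtype")
  mu <- region_membrane_mean(plane, skeleton, "mutant")
  if (wt <= 0) stop("non-positive wild-type mean")
  mu / wt
}

#' One-sample t test of per-wing ratios against 1.0
#'
#' @param ratios numeric vector of per-wing mutant/wild-type ratios (one per
#'   wing, `n >= 2`).
#' @return a `wingpol_test`.
#' @export
clone_ratio_test <- function(ratios) {
  if (any(ratios <= 0)) stop("ratios must be positive")
  one_sample_t(ratios, mu0 = 1)
}

#' Paired t test of per-wing region values
#'
#' Compares a measure between wild-type and mutant regions of the same
#' wings.
#'
#' @param wt,mutant per-wing values for each region, matched by position.
#' @return a `wingpol_test` on the within-wing differences.
#' @export
paired_region_test <- function(wt, mutant) paired_t(wt, mutant)
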