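# Synthetic wings, puncta fields, internalization series and FRAP traces.
#
# The generators emulate the statistical structure the analysis assumes --
# polarized junctional signal on an epithelial lattice, clonal regions with
# scaled intensity, Poisson puncta fields, extracellular-label decay, and
# two-phase FRAP recovery with acquisition bleaching -- so every pipeline
# stage can be exercised with known ground truth. Each generator is
# deterministic given its seed.

#' Specification of a synthetic mosaic wing
#'
#' Parameters of the epithelial-lattice generator. Cells are the
#' nearest-centre regions of a jittered hexagonal point set; membrane signal
#' on cell boundaries follows an axial (nematic) modulation around a common
#' polarity axis, and a contiguous clone of cells carries a scaled intensity.
#'
#' @param n_cell_rows,n_cell_cols lattice dimensions in cells.
#' @param cell_diameter_px centre-to-centre spacing in pixels (>= 3).
#' @param jitter centre jitter as a fraction of the diameter (>= 0).
#' @param base_intensity wild-type membrane intensity `B` (> 0, a.u.).
#' @param polarity_amplitude modulation amplitude `a` in `[0, 1)`: membrane
#'   pixel expectation is `B * s * (1 + a * cos 2(psi - axis))`.
#' @param polarity_axis_deg common polarity axis in degrees, axial `[0, 180)`.
#' @param mutant_scale mutant membrane intensity multiplier `s` (> 0).
#' @param mutant_fraction fraction of cells assigned to the mutant clone.
#' @param background_intensity non-membrane (cell interior) level.
#' @param noise_sd additive Gaussian noise SD (a.u.).
#' @param wing_scale_sd_log SD (log scale) of the lognormal whole-wing
#'   brightness effect; cancels in within-wing ratios.
#' @param region_scale_sd_log SD (log scale) of the lognormal per-wing
#'   relative mutant-region effect (staining/imaging heterogeneity between
#'   regions); this is what disperses per-wing mutant/wild-type ratios, at
#'   a level matching the dispersion such clone experiments report.
#' @param z_profile per-slice intensity multipliers (apical first). The
#'   default 9-slice profile peaks mid-stack with a unique brightest triple.
#' @param seed integer RNG seed.
#' @return a `WingSpec` list.
#' @export
wing_spec <- function(n_cell_rows = 8, n_cell_cols = 8, cell_diameter_px = 45,
                      jitter = 0.08, base_intensity = 100,
                      polarity_amplitude = 0.5, polarity_axis_deg = 20,
                      mutant_scale = 1, mutant_fraction = 0.25,
                      background_intensity = 5, noise_sd = 0,
                      wing_scale_sd_log = 0.15, region_scale_sd_log = 0.15,
                      z_profile = c(0.30, 0.50, 0.80, 1.00, 0.90,
                                    0.70, 0.50, 0.30, 0.20),
                      seed = 1L) {
  stopifnot(n_cell_rows >= 1, n_cell_cols >= 1, jitter >= 0,
            base_intensity > 0, polarity_amplitude >= 0, polarity_amplitude < 1,
            polarity_axis_deg >= 0, polarity_axis_deg < 180,
            mutant_scale > 0, mutant_fraction >= 0, mutant_fraction <= 1,
            background_intensity >= 0, noise_sd >= 0,
            wing_scale_sd_log >= 0, region_scale_sd_log >= 0,
            length(z_profile) >= 1, all(z_profile > 0))
  if (cell_diameter_px < 3) stop("degenerate geometry: cell_diameter_px must be >= 3")
  structure(list(n_cell_rows = n_cell_rows, n_cell_cols = n_cell_cols,
                 cell_diameter_px = cell_diameter_px, jitter = jitter,
                 base_intensity = base_intensity,
                 polarity_amplitude = polarity_amplitude,
                 polarity_axis_deg = polarity_axis_deg,
                 mutant_scale = mutant_scale, mutant_fraction = mutant_fraction,
                 background_intensity = background_intensity,
                 noise_sd = noise_sd,
                 wing_scale_sd_log = wing_scale_sd_log,
                 region_scale_sd_log = region_scale_sd_log,
                 z_profile = z_profile,
                 seed = as.integer(seed)),
            class = "WingSpec")
}

hex_centers <- function(spec) {
  d <- spec$cell_diameter_px
  # integer row pitch keeps the jitter-free lattice exactly periodic on the
  # pixel grid (interior cells congruent); ~2% compressed vs ideal hex
  vstep <- round(d * sqrt(3) / 2)
  rows <- seq_len(spec$n_cell_rows) - 1L
  cols <- seq_len(spec$n_cell_cols) - 1L
  g <- expand.grid(r = rows, c = cols)
  # 0.37 px offset avoids exact equidistance ties on the integer pixel grid
  x <- (g$c + 0.5 + (g$r %% 2) * 0.5) * d + d / 2 + 0.37
  y <- (g$r + 0.5) * vstep + d / 2 + 0.37
  data.frame(cell = seq_len(nrow(g)), gr = g$r, gc = g$c, x = x, y = y)
}

#' Generate a synthetic epithelial lattice and clone map
#'
#' Cells are nearest-centre regions of a jittered hexagonal point set, with a
#' 1-px-wide 0-label membrane along boundaries between adjacent cells. A
#' contiguous blob of cells covering about `mutant_fraction` of the lattice is
#' assigned to the mutant clone, growing outward from a central cell.
#'
#' @param spec a [wing_spec()].
#' @return list with `label` ([label_mask()]), `clone` ([clone_map()]),
#'   `centers` (per-cell centre coordinates and genotype), and `assignment`
#'   (the pre-membrane nearest-centre label matrix).
#' @export
make_lattice <- function(spec) {
  stopifnot(inherits(spec, "WingSpec"))
  set.seed(spec$seed)
  ctr <- hex_centers(spec)
  d <- spec$cell_diameter_px
  if (spec$jitter > 0) {
    ctr$x <- ctr$x + stats::runif(nrow(ctr), -1, 1) * spec$jitter * d
    ctr$y <- ctr$y + stats::runif(nrow(ctr), -1, 1) * spec$jitter * d
  }
  W <- ceiling(max(ctr$x) + d / 2)
  H <- ceiling(max(ctr$y) + d / 2)
  px <- matrix(rep(seq_len(W), each = H), H, W)   # x = col
  py <- matrix(rep(seq_len(H), times = W), H, W)  # y = row
  # nearest-centre assignment; ncell is small so the distance matrix is cheap
  d2 <- outer(as.vector(py), ctr$y, function(a, b) (a - b)^2) +
        outer(as.vector(px), ctr$x, function(a, b) (a - b)^2)
  assign <- matrix(max.col(-d2, ties.method = "first"), H, W)

  lab <- assign
  diff_left <- cbind(TRUE, lab[, -1, drop = FALSE] != lab[, -W, drop = FALSE])
  diff_up <- rbind(TRUE, lab[-1, , drop = FALSE] != lab[-H, , drop = FALSE])
  diff_left[, 1] <- FALSE
  diff_up[1, ] <- FALSE
  lab[diff_left | diff_up] <- 0L

  # contiguous mutant blob grown over the cell grid from the central cell
  n_cells <- nrow(ctr)
  n_mut <- round(spec$mutant_fraction * n_cells)
  genotype <- rep(CLONE_CODES[["wildtype"]], n_cells)
  if (n_mut > 0) {
    mid <- ctr$cell[which.min((ctr$x - mean(range(ctr$x)))^2 +
                              (ctr$y - mean(range(ctr$y)))^2)]
    picked <- mid
    frontier <- mid
    while (length(picked) < n_mut && length(frontier) > 0) {
      f <- frontier[1]; frontier <- frontier[-1]
      nb <- ctr$cell[abs(ctr$gr - ctr$gr[f]) <= 1 & abs(ctr$gc - ctr$gc[f]) <= 1]
      nb <- setdiff(nb, picked)
      take <- utils::head(nb, n_mut - length(picked))
      picked <- c(picked, take)
      frontier <- c(frontier, take)
    }
    genotype[picked] <- CLONE_CODES[["mutant"]]
  }
  clone <- matrix(genotype[assign], H, W)
  ctr$genotype <- genotype
  list(label = label_mask(lab), clone = clone_map(clone),
       centers = ctr, assignment = assign)
}

#' Render a polarized membrane stack over a lattice
#'
#' Each membrane (0-label) pixel adjacent to at least two cells receives
#' expectation `B * s(region) * (1 + a * cos 2(psi - axis)) * z_profile[z]`
#' plus Gaussian noise, where `psi` is the axial centroid-to-pixel direction
#' of the pixel's owning (nearest-centre) cell and `s` is the mutant scale
#' inside the clone. Whole-wing and mutant-region lognormal effects
#' (`wing_scale_sd_log`, `region_scale_sd_log`) model wing-to-wing and
#' staining heterogeneity. Non-membrane pixels receive the background level.
#'
#' @param lattice output of [make_lattice()].
#' @param spec the [wing_spec()] used to build it.
#' @return an [image_stack()] with `length(z_profile)` slices.
#' @export
render_membrane_stack <- function(lattice, spec) {
  stopifnot(inherits(spec, "WingSpec"))
  set.seed(spec$seed + 1L)
  lab <- lattice$label
  H <- nrow(lab); W <- ncol(lab)
  skel <- build_skeleton(lab, lattice$clone)
  cents <- cell_centroids(lab)

  wing_eff <- exp(stats::rnorm(1, 0, spec$wing_scale_sd_log))
  region_eff <- exp(stats::rnorm(1, 0, spec$region_scale_sd_log))
  base <- matrix(spec$background_intensity, H, W)
  n_m <- nrow(skel$pixels)
  if (n_m > 0) {
    theta <- spec$polarity_axis_deg * pi / 180
    rows <- skel$pixels$row; cols <- skel$pixels$col
    # each membrane pixel belongs to its nearest-centre (owning) cell; psi is
    # the axial centroid-to-pixel direction of that cell, matching the
    # definition the polarity module measures
    own <- as.character(lattice$assignment[cbind(rows, cols)])
    psi <- atan2(rows - cents[own, "row"], cols - cents[own, "col"])
    fac <- 1 + spec$polarity_amplitude * cos(2 * (psi - theta))
    s <- ifelse(lattice$clone[cbind(rows, cols)] == CLONE_CODES[["mutant"]],
                spec$mutant_scale * region_eff, 1)
    base[cbind(rows, cols)] <- spec$base_intensity * wing_eff * s * fac
  }
  nz <- length(spec$z_profile)
  v <- array(0, dim = c(nz, H, W))
  for (z in seq_len(nz)) {
    plane <- base * spec$z_profile[z]
    if (spec$noise_sd > 0) {
      plane <- plane + matrix(stats::rnorm(H * W, 0, spec$noise_sd), H, W)
      plane[plane < 0] <- 0
    }
    v[z, , ] <- plane
  }
  image_stack(v, channel_name = "membrane")
}

#' Specification of a synthetic puncta field
#'
#' @param density_wt,density_mut expected puncta per 1000 px^2 in each region.
#' @param radius_mean,radius_sd punctum radius distribution in px (radius is
#'   twice the Gaussian sigma of the rendered blob).
#' @param peak_mean,peak_sd punctum peak-intensity distribution (a.u.).
#' @param background,noise_sd additive background level and Gaussian noise SD.
#' @param seed integer RNG seed.
#' @return a `PunctaSpec` list.
#' @export
puncta_spec <- function(density_wt = 2, density_mut = 2,
                        radius_mean = 2.5, radius_sd = 0.5,
                        peak_mean = 120, peak_sd = 20,
                        background = 10, noise_sd = 0, seed = 1L) {
  stopifnot(density_wt >= 0, density_mut >= 0, radius_mean > 0, radius_sd >= 0,
            peak_mean > 0, background >= 0, noise_sd >= 0)
  structure(list(density_wt = density_wt, density_mut = density_mut,
                 radius_mean = radius_mean, radius_sd = radius_sd,
                 peak_mean = peak_mean, peak_sd = peak_sd,
                 background = background, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "PunctaSpec")
}

#' Render a sub-junctional puncta plane
#'
#' Puncta counts per genotype region are Poisson with mean
#' `density * area / 1000`; each punctum is an isotropic Gaussian blob placed
#' uniformly over the region's pixels. Returns the rendered plane together
#' with the ground-truth punctum list for testing.
#'
#' @param lattice output of [make_lattice()] (only the clone map is used).
#' @param spec a [puncta_spec()].
#' @return list with `plane` (matrix), `truth` (data frame of region, row,
#'   col, sigma, peak), and `spec`.
#' @export
render_puncta_plane <- function(lattice, spec) {
  stopifnot(inherits(spec, "PunctaSpec"))
  set.seed(spec$seed)
  clone <- lattice$clone
  H <- nrow(clone); W <- ncol(clone)
  plane <- matrix(spec$background, H, W)
  truth <- list()
  for (reg in c("wildtype", "mutant")) {
    dens <- if (reg == "wildtype") spec$density_wt else spec$density_mut
    idx <- which(clone == CLONE_CODES[[reg]])
    if (length(idx) == 0 || dens == 0) next
    n <- stats::rpois(1, dens * length(idx) / 1000)
    if (n == 0) next
    pos <- sample(idx, n, replace = TRUE)
    rr <- ((pos - 1) %% H) + 1
    cc <- ((pos - 1) %/% H) + 1
    sig <- pmax(0.5, stats::rnorm(n, spec$radius_mean, spec$radius_sd)) / 2
    pk <- pmax(1, stats::rnorm(n, spec$peak_mean, spec$peak_sd))
    truth[[reg]] <- data.frame(region = reg, row = rr, col = cc,
                               sigma = sig, peak = pk)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(region = character(), row = integer(), col = integer(),
               sigma = numeric(), peak = numeric())
  rownames(truth) <- NULL
  for (i in seq_len(nrow(truth))) {
    s <- truth$sigma[i]; r0 <- truth$row[i]; c0 <- truth$col[i]
    w <- ceiling(4 * s)
    rs <- max(1, r0 - w):min(H, r0 + w)
    cs <- max(1, c0 - w):min(W, c0 + w)
    g <- outer((rs - r0)^2, (cs - c0)^2, "+")
    plane[rs, cs] <- plane[rs, cs] + truth$peak[i] * exp(-g / (2 * s^2))
  }
  if (spec$noise_sd > 0) {
    plane <- plane + matrix(stats::rnorm(H * W, 0, spec$noise_sd), H, W)
    plane[plane < 0] <- 0
  }
  list(plane = plane, truth = truth, spec = spec)
}

#' Simulate an antibody-internalization time series
#'
#' Per wing and genotype, raw extracellular totals at chase times 0, 10 and
#' 30 min follow `base * wing_effect * retention(t) + background + noise`,
#' with lognormal multiplicative wing effects. The retention fraction at time
#' 0 is 1 by definition.
#'
#' @param n_wings wings per genotype.
#' @param genotypes character vector of genotype-region names.
#' @param retention named list (per genotype) of retention fractions at
#'   `times_min`; each must start at 1.
#' @param noise_sd additive measurement noise SD on the raw scale.
#' @param seed integer RNG seed.
#' @param base_intensity mean raw total at time 0 (a.u.).
#' @param wing_sd_log SD of the lognormal wing effect (log scale).
#' @param background additive laser-off background carried by every reading.
#' @param times_min chase times in minutes.
#' @return data frame with columns `wing_id`, `genotype_region`, `time_min`,
#'   `total_signal`, `n_pixels` (1 for table-level simulation); the retention
#'   ground truth is attached as attribute `truth`.
#' @export
simulate_internalization <- function(n_wings = 8,
                                     genotypes = c("wildtype", "mutant"),
                                     retention = list(wildtype = c(1, 0.6, 0.3),
                                                      mutant = c(1, 0.6, 0.3)),
                                     noise_sd = 0, seed = 1L,
                                     base_intensity = 1000, wing_sd_log = 0.15,
                                     background = 0, times_min = c(0, 10, 30)) {
  stopifnot(n_wings >= 1, all(genotypes %in% names(retention)))
  for (g in genotypes) {
    stopifnot(length(retention[[g]]) == length(times_min))
    if (retention[[g]][1] != 1) stop("retention at the 0-min reference must be 1")
  }
  set.seed(seed)
  out <- list()
  for (g in genotypes) {
    wing_eff <- exp(stats::rnorm(n_wings, 0, wing_sd_log))
    if (wing_sd_log == 0) wing_eff <- rep(1, n_wings)
    for (w in seq_len(n_wings)) {
      mu <- base_intensity * wing_eff[w] * retention[[g]]
      raw <- mu + background +
        if (noise_sd > 0) stats::rnorm(length(mu), 0, noise_sd) else 0
      out[[length(out) + 1L]] <- data.frame(
        wing_id = sprintf("wing%02d", w), genotype_region = g,
        time_min = times_min, total_signal = raw, n_pixels = 1L)
    }
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  attr(df, "truth") <- retention
  df
}

#' FRAP simulation parameters
#'
#' Ground truth for a simulated recovery trace: post-bleach floor `Y0` (one
#' minus the bleach depth), fast and slow recovery components `(A1, k1)` and
#' `(A2, k2)` with `k1 > k2`, per-frame acquisition-bleaching rate, additive
#' background offset and Gaussian noise. Prebleach level is 1 by convention,
#' so `Y0 + A1 + A2 <= 1`.
#'
#' @param Y0 immediate post-bleach level (default 0.30, i.e. 70% bleaching;
#'   the protocol's stated bleach depth range is 60--75%).
#' @param A1,A2 recovery amplitudes (>= 0).
#' @param k1,k2 recovery rates per second, `k1 > k2 > 0`.
#' @param acq_bleach_rate acquisition-bleaching rate per frame (>= 0).
#' @param background additive offset on every recorded value.
#' @param noise_sd Gaussian noise SD applied to raw and reference traces.
#' @param seed integer RNG seed.
#' @return a `FrapSimSpec` list.
#' @export
frap_sim_spec <- function(Y0 = 0.30, A1 = 0.25, k1 = 0.15, A2 = 0.25,
                          k2 = 0.008, acq_bleach_rate = 0.002,
                          background = 0, noise_sd = 0, seed = 1L) {
  stopifnot(Y0 >= 0, A1 >= 0, A2 >= 0, k1 > 0, k2 > 0,
            acq_bleach_rate >= 0, background >= 0, noise_sd >= 0)
  if (k1 <= k2) stop("rates must satisfy k1 > k2")
  if (Y0 + A1 + A2 > 1 + 1e-12) stop("Y0 + A1 + A2 must be <= 1 (prebleach level)")
  bleach_depth <- 1 - Y0
  structure(list(Y0 = Y0, A1 = A1, k1 = k1, A2 = A2, k2 = k2,
                 bleach_depth = bleach_depth,
                 acq_bleach_rate = acq_bleach_rate, background = background,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "FrapSimSpec")
}

#' Simulate a FRAP trace under the acquisition protocol
#'
#' Prebleach frames at level 1, bleach to `Y0`, recovery following the
#' two-phase exponential association model, all multiplied by
#' `exp(-lambda * frame_index)` acquisition bleaching, plus background offset
#' and Gaussian noise. The reference trace (an unbleached region) carries
#' bleaching, background and noise only.
#'
#' @param spec a [frap_sim_spec()].
#' @param protocol a [frap_protocol()].
#' @return list with `raw`, `reference` (full-length frame vectors, prebleach
#'   first), `background`, `times_s` (post-bleach times), `spec`, `protocol`.
#' @export
simulate_frap_trace <- function(spec, protocol = frap_protocol()) {
  stopifnot(inherits(spec, "FrapSimSpec"))
  set.seed(spec$seed)
  t_post <- frap_post_times(protocol)
  n_pre <- protocol$n_prebleach
  model <- c(rep(1, n_pre), frap_model(t_post, spec$Y0, spec$A1, spec$k1,
                                       spec$A2, spec$k2))
  n_all <- length(model)
  fade <- exp(-spec$acq_bleach_rate * (seq_len(n_all) - 1))
  raw <- model * fade + spec$background
  reference <- fade + spec$background
  if (spec$noise_sd > 0) {
    raw <- raw + stats::rnorm(n_all, 0, spec$noise_sd)
    reference <- reference + stats::rnorm(n_all, 0, spec$noise_sd)
  }
  list(raw = raw, reference = reference, background = spec$background,
       times_s = t_post, spec = spec, protocol = protocol)
}
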