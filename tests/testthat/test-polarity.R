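test_that("asymmetry ratio handles canonical boundary configurations", {
  # flat boundary: no axis beats any other, tie resolves to 0
  u <- data.frame(psi = seq(0, 179, by = 9), intensity = 5, cell_id = 1L)
  cu <- cell_polarity(u)
  expect_equal(cu$magnitude, 1)
  expect_equal(cu$angle, 0)
  # two orthogonal clusters with a 2:1 intensity contrast
  smp <- data.frame(psi = rep(c(0, 90), each = 10),
                    intensity = rep(c(2, 1), each = 10), cell_id = 1L)
  cp <- cell_polarity(smp)
  expect_equal(cp$magnitude, 2)
  expect_equal(cp$angle, 0)
  # dim cluster on the tested axis flips the reported angle by 90
  flip <- cell_polarity(transform(smp, intensity = rev(intensity)))
  expect_equal(flip$magnitude, 2)
  expect_equal(flip$angle, 90)
  expect_error(cell_polarity(u[1:5, ]), ">= 8")
  one_dir <- data.frame(psi = rep(10, 12), intensity = 1:12, cell_id = 1L)
  expect_error(cell_polarity(one_dir), "degenerate")
})

test_that("asymmetry maximization matches a brute-force grid oracle", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(12:60, 1)
    smp <- data.frame(psi = stats::runif(n, 0, 180),
                      intensity = stats::runif(n, 0.2, 3), cell_id = 1L)
    got <- cell_polarity(smp)
    want <- brute_asymmetry(smp$psi, smp$intensity)
    expect_equal(got$magnitude, want$magnitude, tolerance = 1e-12)
    # the reported axis must achieve the oracle's maximum (exact ties on a
    # ratio plateau may resolve to different axes of equal value)
    at <- vapply(c(got$angle, (got$angle + 90) %% 180), function(th) {
      d <- abs(smp$psi - th) %% 180
      inw <- pmin(d, 180 - d) <= 45
      r <- mean(smp$intensity[inw]) / mean(smp$intensity[!inw])
      max(r, 1 / r)
    }, numeric(1))
    expect_equal(max(at), want$magnitude, tolerance = 1e-9)
  }
})

test_that("polarity is invariant to scale and equivariant to rotation", {
  set.seed(12)
  smp <- data.frame(psi = stats::runif(40, 0, 180),
                    intensity = stats::runif(40, 0.5, 2), cell_id = 1L)
  base <- cell_polarity(smp)
  scaled <- cell_polarity(transform(smp, intensity = intensity * 37.5))
  expect_equal(scaled$magnitude, base$magnitude)
  expect_equal(scaled$angle, base$angle)
  rot <- cell_polarity(transform(smp, psi = (psi + 90) %% 180))
  expect_equal(rot$magnitude, base$magnitude)
  expect_equal(rot$angle, (base$angle + 90) %% 180)
})

test_that("axial spread follows the doubled-angle circular formula", {
  expect_equal(axial_spread(c(37, 37, 37)), 0)
  # antipodal axial pair: zero resultant, flagged maximal
  s <- axial_spread(c(0, 90))
  expect_true(is.infinite(s))
  expect_true(attr(s, "undefined"))
  # closed form: 0.5 * sqrt(-2 ln cos(10 deg)) in degrees
  expect_equal(axial_spread(c(0, 10)), 5.01278012423457, tolerance = 1e-10)
  # wrap-around pairs behave like their unwrapped counterparts
  expect_equal(axial_spread(c(175, 5)), axial_spread(c(85, 95)))
  expect_error(axial_spread(numeric(0)), "empty")
  expect_error(axial_spread(42), ">= 2")
})

test_that("wing summaries aggregate per-cell polarity", {
  cells <- data.frame(cell_id = 1:3, region = "wildtype",
                      magnitude = c(1.4, 1.4, 1.4), angle = c(30, 30, 30),
                      mean_boundary_intensity = 1, n_samples = 20)
  ws <- wing_summary(cells, "wildtype")
  expect_equal(ws$mean_magnitude, 1.4)
  expect_equal(ws$angle_spread, 0)
  expect_equal(ws$mean_angle, 30)
  single <- wing_summary(cells[1, ], "wildtype")
  expect_true(is.infinite(single$angle_spread))
  expect_error(wing_summary(cells, "mutant"), "no cells")
})

test_that("region membrane means match direct enumeration", {
  lab <- two_cell_mask()
  sk <- build_skeleton(lab, uniform_clone(lab))
  v <- matrix(3.25, nrow(lab), ncol(lab))
  expect_equal(region_membrane_mean(v, sk, "wildtype"), 3.25)
  chk <- matrix((row(v) + col(v)) %% 2, nrow(v), ncol(v)) * 1.7
  want <- mean(chk[cbind(sk$pixels$row, sk$pixels$col)[
    sk$pixels$region == "wildtype", , drop = FALSE]])
  expect_equal(region_membrane_mean(chk, sk, "wildtype"), want)
  expect_error(region_membrane_mean(v, sk, "mutant"), "no membrane")
})

test_that("clone-ratio and paired region tests reproduce closed forms", {
  r <- clone_ratio_test(c(0.5, 0.6, 0.7))
  expect_equal(r$statistic, -6.92820323027551, tolerance = 1e-10)
  expect_equal(r$df, 2)
  expect_equal(r$p, 2 * stats::pt(-4 * sqrt(3), 2), tolerance = 1e-12)
  sym <- clone_ratio_test(c(0.9, 1.0, 1.1))
  expect_equal(sym$statistic, 0)
  expect_equal(sym$p, 1)
  expect_error(clone_ratio_test(c(0.8, 0.8, 0.8)), "zero variance")
  expect_error(clone_ratio_test(c(-0.1, 0.5)), "positive")

  pr <- paired_region_test(c(1.0, 1.2, 0.9), c(0.8, 0.9, 0.8))
  expect_equal(pr$statistic, 3.46410161513775, tolerance = 1e-10)
  expect_equal(pr$df, 2)
  expect_error(paired_region_test(c(1, 2, 3), c(1, 2, 3)), "zero variance")
  expect_error(paired_region_test(c(1, 2, 3), c(2, 3, 4)), "zero variance")
})

test_that("recovered wing polarity tracks the injected signal", {
  # noiseless wings: the wing-level axis estimate stays inside the
  # hexagonal-geometry envelope (half the 30-degree inter-normal spacing)
  # and mean magnitude increases strictly with the injected amplitude
  means <- c()
  for (a in c(0.1, 0.3, 0.5, 0.7)) {
    sp <- wing_spec(n_cell_rows = 5, n_cell_cols = 5, polarity_amplitude = a,
                    polarity_axis_deg = 20, mutant_fraction = 0, noise_sd = 0,
                    wing_scale_sd_log = 0, region_scale_sd_log = 0,
                    z_profile = 1, seed = 13)
    lat <- make_lattice(sp)
    st <- render_membrane_stack(lat, sp)
    cells <- wing_cell_polarity(stack_plane(st, 1), lat$label, lat$clone)
    axis_err <- abs(axial_mean(cells$angle) - 20)
    expect_lte(min(axis_err, 180 - axis_err), 15)
    means <- c(means, mean(cells$magnitude))
  }
  expect_true(all(diff(means) > 0))
})

test_that("asymmetry ratio and binned nematic rank cells consistently", {
  Ms <- c(); ms <- c()
  for (a in c(0.05, 0.2, 0.4, 0.6)) for (sd in 11:12) {
    sp <- wing_spec(n_cell_rows = 5, n_cell_cols = 5, polarity_amplitude = a,
                    mutant_fraction = 0, noise_sd = 0, z_profile = 1,
                    wing_scale_sd_log = 0, region_scale_sd_log = 0, seed = sd)
    lat <- make_lattice(sp)
    pl <- stack_plane(render_membrane_stack(lat, sp), 1)
    sk <- build_skeleton(lat$label, lat$clone)
    for (id in setdiff(cell_ids(lat$label), border_cells(lat$label))) {
      smp <- sample_cell_boundary(pl, lat$label, id, skeleton = sk)
      Ms <- c(Ms, cell_polarity(smp)$magnitude)
      ms <- c(ms, cell_nematic(smp)$magnitude)
    }
  }
  expect_gt(stats::cor(Ms, ms, method = "spearman"), 0.95)
})
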