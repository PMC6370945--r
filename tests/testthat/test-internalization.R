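test_that("time-course normalization anchors the 0-min reference at 1", {
  rec <- simulate_internalization(n_wings = 5,
                                  retention = list(wildtype = c(1, 0.6, 0.3),
                                                   mutant = c(1, 0.8, 0.5)),
                                  noise_sd = 6, wing_sd_log = 0.1,
                                  background = 40, seed = 14)
  norm <- normalize_timecourse(rec, background = 40)
  for (g in c("wildtype", "mutant")) {
    expect_equal(mean(norm$normalized_intensity[norm$genotype_region == g &
                                                  norm$time_min == 0]), 1)
  }
  # readings identical to the reference normalize to 1 everywhere
  flat <- rec
  flat$total_signal <- 500
  nf <- normalize_timecourse(flat, background = 0)
  expect_true(all(nf$normalized_intensity == 1))
  # readings at or below background clip to zero with a warning
  flat$total_signal[2] <- 400
  expect_warning(z <- normalize_timecourse(flat, background = 450), "clipped")
  expect_equal(z$normalized_intensity[2], 0)
  expect_error(normalize_timecourse(rec[rec$time_min != 0, ], background = 0),
               "protocol error")
})

test_that("plane-level time courses sum regions correctly", {
  pl1 <- matrix(2, 4, 4); pl2 <- matrix(1, 4, 4)
  mask <- matrix(c(TRUE, FALSE), 4, 4)
  ms <- list(
    list(wing_id = "w1", genotype_region = "wildtype", time_min = 0,
         plane = pl1, region_mask = mask),
    list(wing_id = "w1", genotype_region = "wildtype", time_min = 10,
         plane = pl2, region_mask = mask))
  out <- extracellular_timecourse(ms, background = 0.5)
  expect_equal(out$total_signal, c(16, 8))
  expect_equal(out$n_pixels, c(8L, 8L))
  expect_equal(out$normalized_intensity, c(1, 4 / 12))
})

test_that("Dunnett comparisons nest consistently with pairwise tests", {
  set.seed(15)
  rec <- simulate_internalization(n_wings = 8, noise_sd = 40, wing_sd_log = 0,
                                  seed = 16)
  norm <- normalize_timecourse(rec)
  res <- timecourse_anova(norm)
  for (g in names(res)) {
    cmp <- res[[g]]$comparisons
    expect_true(all(cmp$p_adjusted >= cmp$p_unadjusted - 1e-10))
  }
  # a single comparison reduces Dunnett to the two-sample pooled t test
  two <- norm[norm$genotype_region == "wildtype" & norm$time_min != 30, ]
  ad <- anova_dunnett(two$normalized_intensity, factor(two$time_min), "0")
  tt <- stats::t.test(normalized_intensity ~ time_min, data = two,
                      var.equal = TRUE)
  expect_equal(ad$comparisons$p_adjusted, tt$p.value, tolerance = 1e-6)
})

test_that("threshold calibration hits the target area fraction", {
  # discrete worked example: 100 bright pixels among 10,000
  set.seed(20)
  pl <- matrix(0, 100, 100)
  pl[sample.int(10000, 100)] <- 100
  wt <- matrix(TRUE, 100, 100)
  cal <- find_puncta_threshold(pl, wt, 0.01)
  expect_equal(cal$threshold, 0)
  expect_equal(cal$achieved_fraction, 0.01)
  # target 1: everything is a punctum
  all_in <- find_puncta_threshold(pl, wt, 1)
  expect_lt(all_in$threshold, min(pl))
  expect_equal(all_in$achieved_fraction, 1)
  # constant region: threshold collapses with a warning
  expect_warning(flat <- find_puncta_threshold(matrix(5, 10, 10),
                                               matrix(TRUE, 10, 10)),
                 "constant")
  expect_equal(flat$threshold, 5)
  expect_equal(flat$achieved_fraction, 0)
  expect_error(find_puncta_threshold(pl, wt, 0), "target_fraction")
})

test_that("threshold is monotone in the target and tight for continuous data", {
  set.seed(17)
  pl <- matrix(stats::rnorm(120 * 120, 50, 8), 120, 120)
  wt <- matrix(TRUE, 120, 120)
  targets <- c(0.002, 0.005, 0.01, 0.05, 0.2, 0.5)
  thr <- vapply(targets, function(tf)
    find_puncta_threshold(pl, wt, tf)$threshold, numeric(1))
  expect_true(all(diff(thr) <= 0))
  n <- length(pl)
  for (tf in targets) {
    cal <- find_puncta_threshold(pl, wt, tf)
    expect_lte(cal$achieved_fraction, tf)
    expect_gt(cal$achieved_fraction, tf - 1 / n)
  }
})

test_that("puncta extraction uses 8-connectivity and the given threshold", {
  pl <- matrix(0, 12, 12)
  pl[4:6, 4:6] <- 10                     # one 3x3 block
  pl[9, 9] <- 10; pl[10, 10] <- 10       # diagonal pair
  mask <- matrix(TRUE, 12, 12)
  ps <- extract_puncta(pl, mask, threshold = 5)
  expect_identical(nrow(ps$puncta), 2L)
  expect_setequal(ps$puncta$area_px, c(9L, 2L))
  blk <- ps$puncta[ps$puncta$area_px == 9, ]
  expect_equal(blk$integrated_intensity, 90)
  expect_equal(blk$mean_intensity, 10)
  expect_equal(c(blk$centroid_row, blk$centroid_col), c(5, 5))
  # min_area filters the diagonal pair
  expect_identical(nrow(extract_puncta(pl, mask, 5, min_area = 3)$puncta), 1L)
  # region mask confines components
  half <- col(pl) <= 6
  expect_identical(nrow(extract_puncta(pl, half, 5)$puncta), 1L)
})

test_that("component labelling agrees with an independent flood fill", {
  set.seed(18)
  for (i in 1:10) {
    fg <- matrix(stats::runif(40 * 40) < 0.35, 40, 40)
    lab <- label_components8(fg)
    oracle <- flood_fill_components(fg)
    expect_identical(max(lab), max(oracle))
    # same partition: component of each pixel maps one-to-one
    expect_identical(length(unique(paste(lab[fg], oracle[fg]))),
                     max(oracle))
  }
})

test_that("per-wing puncta ratios honour the shared-threshold contract", {
  pl <- matrix(0, 10, 20)
  pl[3:4, 3:4] <- 10; pl[7, 5] <- 8       # wild-type side
  pl[3:4, 13:14] <- 9; pl[8, 16] <- 7     # mutant side
  wt <- col(pl) <= 10; mu <- col(pl) > 10
  a <- extract_puncta(pl, wt, 5, region = "wildtype")
  b <- extract_puncta(pl, mu, 5, region = "mutant")
  r <- puncta_wing_ratios(a, b)
  expect_equal(r$count_ratio, 1)          # same density, equal areas
  b2 <- extract_puncta(pl, mu, 6, region = "mutant")
  expect_error(puncta_wing_ratios(a, b2), "wild-type threshold")
  empty <- extract_puncta(matrix(0, 10, 20), wt, 5, region = "wildtype")
  expect_warning(r0 <- puncta_wing_ratios(empty, b), "excluded")
  expect_true(is.na(r0$count_ratio))
  # identical regions give unit ratios across the board
  same <- puncta_wing_ratios(a, extract_puncta(pl, wt, 5, region = "mutant"))
  expect_equal(unlist(same), c(count_ratio = 1, area_ratio = 1,
                               intensity_ratio = 1))
})

test_that("a doubled mutant density is recovered by the extraction pipeline", {
  lat <- list(clone = clone_map(cbind(
    matrix(CLONE_CODES[["wildtype"]], 140, 140),
    matrix(CLONE_CODES[["mutant"]], 140, 140))))
  wt_mask <- unclass(lat$clone) == CLONE_CODES[["wildtype"]]
  mu_mask <- unclass(lat$clone) == CLONE_CODES[["mutant"]]
  ratios <- vapply(1:30, function(s) {
    pf <- render_puncta_plane(lat, puncta_spec(density_wt = 1, density_mut = 2,
                                               background = 10, noise_sd = 2,
                                               peak_mean = 120, seed = 100 + s))
    cal <- find_puncta_threshold(pf$plane, wt_mask, 0.01)
    a <- extract_puncta(pf$plane, wt_mask, cal$threshold, min_area = 4,
                        region = "wildtype")
    b <- extract_puncta(pf$plane, mu_mask, cal$threshold, min_area = 4,
                        region = "mutant")
    puncta_wing_ratios(a, b)$count_ratio
  }, numeric(1))
  se <- stats::sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - 2), 3 * se)
  tst <- puncta_ratio_tests(data.frame(count_ratio = ratios,
                                       area_ratio = NA, intensity_ratio = NA))
  expect_lt(tst$count_ratio$p, 0.001)
  expect_null(tst$area_ratio)
})
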