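test_that("the acquisition protocol derives the documented timebase", {
  t_post <- frap_post_times(frap_protocol())
  expect_identical(length(t_post), 41L)
  expect_equal(t_post[1], 0)
  expect_equal(t_post[41], 510)
  expect_true(all(diff(t_post) > 0))
  expect_equal(t_post[1:6], c(0, 5, 10, 15, 20, 30))
})

test_that("preprocessing normalizes prebleach to 1 and undoes bleaching", {
  # flat reference, no background: prebleach values are exactly 1
  raw <- c(rep(2, 3), rep(0.8, 41))
  ref <- rep(5, 44)
  ft <- preprocess_trace(raw, ref, background = 0)
  expect_equal(ft$prebleach_values, rep(1, 3))
  expect_equal(ft$intensity, rep(0.4, 41))
  # generator trace with bleaching + background, no noise: the corrected
  # trace equals the pure recovery model
  sp <- frap_sim_spec(Y0 = 0.35, A1 = 0.3, k1 = 0.12, A2 = 0.2, k2 = 0.006,
                      acq_bleach_rate = 0.004, background = 0.1, noise_sd = 0)
  tr <- simulate_frap_trace(sp)
  ft2 <- preprocess_trace(tr$raw, tr$reference, tr$background)
  model <- 0.35 + 0.3 * (1 - exp(-0.12 * ft2$times_s)) +
    0.2 * (1 - exp(-0.006 * ft2$times_s))
  expect_lt(max(abs(ft2$intensity - model)), 1e-9)
  expect_error(preprocess_trace(raw[-1], ref, 0), "does not match")
  expect_error(preprocess_trace(raw, rep(0, 44), 0), "correction error")
})

test_that("frame exclusion masks corrupted points out of the fit", {
  sp <- frap_sim_spec(noise_sd = 0, seed = 21)
  tr <- simulate_frap_trace(sp)
  clean <- fit_recovery(preprocess_trace(tr$raw, tr$reference, tr$background),
                        order = 2)
  bad_raw <- tr$raw
  bad_raw[c(40, 44)] <- bad_raw[c(40, 44)] * 0.3   # drifted frames
  ft <- preprocess_trace(bad_raw, tr$reference, tr$background,
                         excluded_frames = c(37, 41))
  masked <- fit_recovery(ft, order = 2)
  expect_equal(masked$par, clean$par, tolerance = 1e-4)
  expect_identical(masked$n_points, 39L)
})

test_that("recovery fitting is exact on noiseless data and properly nested", {
  t_post <- frap_post_times()
  one <- structure(list(times_s = t_post,
                        intensity = 0.4 + 0.5 * (1 - exp(-0.03 * t_post)),
                        excluded = rep(FALSE, 41)), class = "FrapTrace")
  f1 <- fit_recovery(one, order = 1)
  expect_lt(f1$ss, 1e-12)
  expect_equal(unname(f1$par), c(0.4, 0.5, 0.03), tolerance = 1e-4)
  # two-phase truth recovered to < 1% relative
  sp <- frap_sim_spec(Y0 = 0.3, A1 = 0.3, k1 = 0.2, A2 = 0.2, k2 = 0.01,
                      acq_bleach_rate = 0, background = 0, noise_sd = 0)
  tr <- simulate_frap_trace(sp)
  ft <- preprocess_trace(tr$raw, tr$reference, 0)
  f2 <- fit_recovery(ft, order = 2)
  truth <- c(Y0 = 0.3, A1 = 0.3, k1 = 0.2, A2 = 0.2, k2 = 0.01)
  expect_lt(max(abs(f2$par[names(truth)] - truth) / truth), 0.01)
  expect_true(f2$par["k1"] > f2$par["k2"])
  # nesting: the two-phase fit never has larger SS than the one-phase fit
  for (s in 1:5) {
    spn <- frap_sim_spec(noise_sd = 0.03, seed = s)
    trn <- simulate_frap_trace(spn)
    ftn <- preprocess_trace(trn$raw, trn$reference, trn$background)
    expect_lte(fit_recovery(ftn, 2)$ss, fit_recovery(ftn, 1)$ss + 1e-12)
  }
  expect_error(fit_recovery(structure(list(times_s = t_post[1:6],
                                           intensity = rep(1, 6),
                                           excluded = rep(FALSE, 6)),
                                      class = "FrapTrace"), order = 2),
               "too few")
})

test_that("fits are scale-equivariant", {
  sp <- frap_sim_spec(noise_sd = 0, seed = 22)
  tr <- simulate_frap_trace(sp)
  ft <- preprocess_trace(tr$raw, tr$reference, tr$background)
  base <- fit_recovery(ft, order = 2)
  ft3 <- ft
  ft3$intensity <- ft$intensity * 3
  scaled <- fit_recovery(ft3, order = 2)
  expect_equal(unname(scaled$par[c("Y0", "A1", "A2")]),
               unname(base$par[c("Y0", "A1", "A2")]) * 3, tolerance = 1e-5)
  expect_equal(unname(scaled$par[c("k1", "k2")]),
               unname(base$par[c("k1", "k2")]), tolerance = 1e-5)
})

test_that("the extra-sum-of-squares F test follows its closed form", {
  f1 <- structure(list(ss = 10, n_params = 3L, n_points = 41L), class = "FrapFit")
  f2 <- structure(list(ss = 8, n_params = 5L, n_points = 41L), class = "FrapFit")
  res <- compare_nested_fits(f1, f2)
  expect_equal(res$statistic, 4.5)
  expect_equal(res$df, c(2, 36))
  expect_equal(res$p, stats::pf(4.5, 2, 36, lower.tail = FALSE))
  # equal SS: no evidence for the larger model
  same <- compare_nested_fits(f1, structure(list(ss = 10, n_params = 5L,
                                                 n_points = 41L),
                                            class = "FrapFit"))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  perfect <- compare_nested_fits(f1, structure(list(ss = 0, n_params = 5L,
                                                    n_points = 41L),
                                               class = "FrapFit"))
  expect_identical(perfect$statistic, Inf)
  expect_equal(perfect$p, 0)
  expect_false(is.na(perfect$flag))
  expect_error(compare_nested_fits(f2, f1), "more parameters")
})

test_that("a single-phase truth rarely earns a two-phase preference", {
  suppressWarnings({
    pref <- vapply(1:200, function(i) {
      sp <- frap_sim_spec(Y0 = 0.3, A1 = 0.45, k1 = 0.05, A2 = 0, k2 = 0.005,
                          acq_bleach_rate = 0.002, background = 0.05,
                          noise_sd = 0.02, seed = 3000 + i)
      tr <- simulate_frap_trace(sp)
      ft <- preprocess_trace(tr$raw, tr$reference, tr$background)
      compare_nested_fits(fit_recovery(ft, 1), fit_recovery(ft, 2))$p <= 0.05
    }, logical(1))
  })
  expect_gte(mean(!pref), 0.9)
})

test_that("genotype comparison detects a halved slow phase and not a null", {
  mk <- function(seedbase, A2) lapply(1:10, function(w) {
    sp <- frap_sim_spec(Y0 = 0.3, A1 = 0.25, k1 = 0.15, A2 = A2, k2 = 0.008,
                        acq_bleach_rate = 0.002, background = 0.05,
                        noise_sd = 0.02, seed = seedbase + w)
    tr <- simulate_frap_trace(sp)
    preprocess_trace(tr$raw, tr$reference, tr$background)
  })
  suppressWarnings({
    # identical data in both arms: F collapses to zero
    dup <- mk(1, 0.25)
    expect_lt(compare_genotypes(dup, dup, "all")$test$statistic, 1e-8)
    # power: slow amplitude halved in arm B, alpha 0.01
    hits <- vapply(1:200, function(i) {
      a <- mk(i * 1000, 0.25)
      b <- mk(i * 1000 + 500, 0.125)
      compare_genotypes(a, b, "slow")$test$p <= 0.01
    }, logical(1))
    expect_gte(mean(hits), 0.8)
    # type-I: identical generating parameters, alpha 0.05
    fp <- vapply(1:500, function(i) {
      a <- mk(i * 2000, 0.25)
      b <- mk(i * 2000 + 900, 0.25)
      compare_genotypes(a, b, "slow")$test$p <= 0.05
    }, logical(1))
    expect_lt(abs(mean(fp) - 0.05), 2 * sqrt(0.05 * 0.95 / 500))
  })
})
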