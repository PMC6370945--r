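# FRAP trace preprocessing, one-/two-phase exponential-association fitting,
# and nested-model comparison via the extra-sum-of-squares F test.

#' FRAP acquisition protocol
#'
#' Default protocol: 3 pre-bleach frames at 2 frames/s, a 1 s bleach, then
#' 5 frames at 5 s intervals, 10 at 10 s and 26 at 15 s — 41 post-bleach
#' frames, the last 510 s after the first.
#'
#' @param n_prebleach number of pre-bleach frames.
#' @param prebleach_interval_s pre-bleach frame interval (s).
#' @param bleach_duration_s bleach duration (s); carries no samples.
#' @param post_schedule list of `c(n_frames, interval_s)` blocks.
#' @return a `FrapProtocol` list.
#' @export
frap_protocol <- function(n_prebleach = 3, prebleach_interval_s = 0.5,
                          bleach_duration_s = 1,
                          post_schedule = list(c(5, 5), c(10, 10), c(26, 15))) {
  stopifnot(n_prebleach >= 1,
            all(vapply(post_schedule, function(b) b[1] > 0 && b[2] > 0,
                       logical(1))))
  structure(list(n_prebleach = n_prebleach,
                 prebleach_interval_s = prebleach_interval_s,
                 bleach_duration_s = bleach_duration_s,
                 post_schedule = post_schedule),
            class = "FrapProtocol")
}

#' Post-bleach frame times
#'
#' `t = 0` at the first post-bleach frame; subsequent times follow the
#' protocol's interval blocks.
#' @param protocol a [frap_protocol()].
#' @return numeric vector of times in seconds, strictly increasing.
#' @export
frap_post_times <- function(protocol = frap_protocol()) {
  times <- numeric(0)
  last <- NA_real_
  for (b in protocol$post_schedule) {
    n <- b[1]; dt <- b[2]
    blk <- if (is.na(last)) dt * (seq_len(n) - 1) else last + dt * seq_len(n)
    times <- c(times, blk)
    last <- blk[n]
  }
  times
}

frap_model <- function(t, Y0, A1, k1, A2 = 0, k2 = 1) {
  Y0 + A1 * (1 - exp(-k1 * t)) + A2 * (1 - exp(-k2 * t))
}

#' Preprocess a raw FRAP trace
#'
#' Laser-off background is subtracted from both the bleached-region trace
#' and the unbleached reference trace; the raw trace is divided framewise by
#' the reference's relative decay (double normalization, correcting
#' acquisition bleaching), then normalized against the mean of its own
#' corrected pre-bleach values — which is therefore exactly 1.
#'
#' @param raw full-length raw trace (pre-bleach frames first).
#' @param reference unbleached reference trace over the same frames.
#' @param background laser-off background level.
#' @param protocol a [frap_protocol()].
#' @param excluded_frames optional integer indices (into the post-bleach
#'   frames) to mask from fitting, e.g. frames that drifted out of focus.
#' @return a `FrapTrace`: list with `times_s`, `intensity` (post-bleach,
#'   normalized), `prebleach_values`, `excluded` (logical mask), `protocol`.
#' @export
preprocess_trace <- function(raw, reference, background = 0,
                             protocol = frap_protocol(),
                             excluded_frames = integer()) {
  n_pre <- protocol$n_prebleach
  t_post <- frap_post_times(protocol)
  n_all <- n_pre + length(t_post)
  if (length(raw) != n_all || length(reference) != n_all) {
    stop("trace length ", length(raw), " does not match protocol (", n_all,
         " frames)")
  }
  ref_c <- reference - background
  if (any(ref_c <= 0)) stop("correction error: reference reaches background")
  raw_c <- raw - background
  fade <- ref_c / mean(ref_c[seq_len(n_pre)])
  corrected <- raw_c / fade
  pre_mean <- mean(corrected[seq_len(n_pre)])
  if (pre_mean <= 0) stop("non-positive pre-bleach mean after correction")
  norm <- corrected / pre_mean
  excluded <- rep(FALSE, length(t_post))
  excluded[excluded_frames] <- TRUE
  structure(list(times_s = t_post,
                 intensity = norm[(n_pre + 1):n_all],
                 prebleach_values = norm[seq_len(n_pre)],
                 excluded = excluded, protocol = protocol),
            class = "FrapTrace")
}

#' @export
print.FrapTrace <- function(x, ...) {
  cat(sprintf("FrapTrace: %d post-bleach frames over %.0f s (%d excluded), first value %.3f\n",
              length(x$times_s), max(x$times_s), sum(x$excluded),
              x$intensity[1]))
  invisible(x)
}

fit_one_start <- function(t, y, start, lower, formula) {
  tryCatch({
    fit <- minpack.lm::nlsLM(formula, data = data.frame(t = t, y = y),
                             start = start, lower = lower,
                             control = minpack.lm::nls.lm.control(maxiter = 200))
    list(par = stats::coef(fit), ss = sum(stats::resid(fit)^2))
  }, error = function(e) NULL)
}

#' Fit an exponential-association recovery model
#'
#' Least-squares fit of `I(t) = Y0 + sum_i A_i (1 - exp(-k_i t))` of order 1
#' or 2, using multi-start Levenberg-Marquardt over a grid of rate pairs
#' spanning 1/500 to 1 per second. Rates are constrained positive; plateau
#' and amplitudes are unconstrained, as in standard curve-fitting software,
#' which keeps the extra-sum-of-squares F test calibrated (a non-negativity
#' constraint active at the boundary would censor the null improvement). For
#' order 2 the order-1 solution seeds one start (so the nested fit can never
#' be worse) and rates are reported with `k1 > k2`; a fit with `k1` and `k2`
#' equal to within 1e-6 relative is flagged degenerate.
#'
#' @param trace a `FrapTrace` (or list with `times_s`, `intensity`, optional
#'   `excluded`).
#' @param order 1 or 2 recovery phases.
#' @return a `FrapFit`: list with `order`, `par` (named vector), `ss`,
#'   `n_points`, `n_params`, `fitted`, `degenerate`.
#' @export
fit_recovery <- function(trace, order = 2) {
  stopifnot(order %in% c(1, 2))
  keep <- if (!is.null(trace$excluded)) !trace$excluded else
    rep(TRUE, length(trace$times_s))
  t <- trace$times_s[keep]
  y <- trace$intensity[keep]
  n_par <- if (order == 1) 3L else 5L
  if (length(t) < n_par + 3) stop("too few unmasked points to fit")
  y0g <- max(min(y), 0)
  ag <- max(max(y) - y0g, 0.05)
  rates <- c(1 / 500, 0.01, 0.05, 0.2, 1)
  cands <- list()
  if (order == 1) {
    f <- y ~ Y0 + A1 * (1 - exp(-k1 * t))
    for (k in rates) {
      cands[[length(cands) + 1L]] <-
        fit_one_start(t, y, list(Y0 = y0g, A1 = ag, k1 = k),
                      lower = c(-Inf, -Inf, 1e-8), f)
    }
  } else {
    f <- y ~ Y0 + A1 * (1 - exp(-k1 * t)) + A2 * (1 - exp(-k2 * t))
    grid <- expand.grid(k1 = rates, k2 = rates)
    grid <- grid[grid$k1 > grid$k2, ]
    for (i in seq_len(nrow(grid))) {
      cands[[length(cands) + 1L]] <-
        fit_one_start(t, y, list(Y0 = y0g, A1 = ag / 2, k1 = grid$k1[i],
                                 A2 = ag / 2, k2 = grid$k2[i]),
                      lower = c(-Inf, -Inf, 1e-8, -Inf, 1e-8), f)
    }
    # seed with the order-1 solution so SS(order 2) <= SS(order 1)
    f1 <- fit_recovery(trace, order = 1)
    cands[[length(cands) + 1L]] <-
      fit_one_start(t, y, list(Y0 = unname(f1$par["Y0"]),
                               A1 = unname(f1$par["A1"]),
                               k1 = unname(f1$par["k1"]),
                               A2 = 1e-4, k2 = unname(f1$par["k1"]) / 10),
                    lower = c(-Inf, -Inf, 1e-8, -Inf, 1e-8), f)
    cands[[length(cands) + 1L]] <-
      list(par = c(Y0 = unname(f1$par["Y0"]), A1 = unname(f1$par["A1"]),
                   k1 = unname(f1$par["k1"]), A2 = 0,
                   k2 = unname(f1$par["k1"]) / 10),
           ss = f1$ss)
  }
  cands <- Filter(Negate(is.null), cands)
  if (length(cands) == 0) stop("fit error: no start converged")
  best <- cands[[which.min(vapply(cands, `[[`, numeric(1), "ss"))]]
  par <- best$par
  degenerate <- FALSE
  if (order == 2) {
    if (par["k1"] < par["k2"]) {  # enforce k1 > k2 by swapping components
      par[c("A1", "k1", "A2", "k2")] <- par[c("A2", "k2", "A1", "k1")]
      names(par) <- c("Y0", "A1", "k1", "A2", "k2")
    }
    if (abs(par["k1"] - par["k2"]) <= 1e-6 * abs(par["k1"])) degenerate <- TRUE
  }
  fitted <- if (order == 1) frap_model(t, par["Y0"], par["A1"], par["k1"])
            else frap_model(t, par["Y0"], par["A1"], par["k1"], par["A2"],
                            par["k2"])
  structure(list(order = order, par = par, ss = best$ss,
                 n_points = length(t), n_params = n_par,
                 times = t, fitted = unname(fitted),
                 degenerate = degenerate),
            class = "FrapFit")
}

#' @export
print.FrapFit <- function(x, ...) {
  cat(sprintf("FrapFit order %d: %s; SS = %.4g on %d points%s\n", x$order,
              paste(sprintf("%s = %.4g", names(x$par), x$par), collapse = ", "),
              x$ss, x$n_points, if (x$degenerate) " [degenerate rates]" else ""))
  invisible(x)
}

extra_ss_f <- function(ss1, p1, ss2, p2, n) {
  if (p2 <= p1) stop("complex model must have more parameters")
  if (ss2 > ss1 + 1e-12 * max(1, ss1)) {
    stop("nested-fit contract violated: SS_complex > SS_simple")
  }
  df1 <- p2 - p1
  df2 <- n - p2
  if (ss2 <= 0) {
    return(new_test_result("extra-sum-of-squares F", Inf, c(df1, df2), 0,
                           flag = "SS_complex = 0"))
  }
  f <- ((ss1 - ss2) / df1) / (ss2 / df2)
  f <- max(f, 0)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  new_test_result("extra-sum-of-squares F", f, c(df1, df2), p)
}

#' Extra-sum-of-squares F test between nested curve fits
#'
#' `F = ((SS1 - SS2)/(p2 - p1)) / (SS2/(n - p2))` with `(p2 - p1, n - p2)`
#' degrees of freedom; the standard nested-model comparison for recovery
#' curves (e.g. one-phase vs two-phase).
#'
#' @param fit_simple,fit_complex `FrapFit`s of the same data with
#'   `fit_complex` having strictly more parameters.
#' @return a `wingpol_test`.
#' @export
compare_nested_fits <- function(fit_simple, fit_complex) {
  if (fit_simple$n_points != fit_complex$n_points) {
    stop("fits must be of the same data")
  }
  extra_ss_f(fit_simple$ss, fit_simple$n_params,
             fit_complex$ss, fit_complex$n_params, fit_complex$n_points)
}

average_traces <- function(traces) {
  mat <- vapply(traces, function(tr) tr$intensity, traces[[1]]$intensity)
  excl <- Reduce(`|`, lapply(traces, function(tr) tr$excluded))
  structure(list(times_s = traces[[1]]$times_s,
                 intensity = rowMeans(mat),
                 prebleach_values = rowMeans(vapply(traces,
                   function(tr) tr$prebleach_values,
                   traces[[1]]$prebleach_values)),
                 excluded = excl, protocol = traces[[1]]$protocol),
            class = "FrapTrace")
}

#' Compare FRAP recovery between genotypes
#'
#' Traces are averaged per genotype, then the two averaged curves are fitted
#' jointly: a null model in which the selected component's parameters are
#' shared across genotypes versus the full model in which all parameters are
#' genotype-specific, compared by the extra-sum-of-squares F test.
#' `component = "fast"` shares `(A1, k1)`, `"slow"` shares `(A2, k2)`,
#' `"all"` shares every parameter (a single common curve).
#'
#' @param traces_a,traces_b lists of `FrapTrace`s, one per wing.
#' @param component which recovery component to test.
#' @return list with `test` (a `wingpol_test`), `fit_a`, `fit_b` (per-
#'   genotype order-2 fits) and `ss_shared`.
#' @export
compare_genotypes <- function(traces_a, traces_b,
                              component = c("slow", "fast", "all")) {
  component <- match.arg(component)
  avg_a <- average_traces(traces_a)
  avg_b <- average_traces(traces_b)
  fit_a <- fit_recovery(avg_a, order = 2)
  fit_b <- fit_recovery(avg_b, order = 2)
  ss_free <- fit_a$ss + fit_b$ss
  p_free <- 10L
  n <- fit_a$n_points + fit_b$n_points

  keep_a <- !avg_a$excluded; keep_b <- !avg_b$excluded
  dat <- data.frame(
    t = c(avg_a$times_s[keep_a], avg_b$times_s[keep_b]),
    y = c(avg_a$intensity[keep_a], avg_b$intensity[keep_b]),
    g = rep(c(0, 1), c(sum(keep_a), sum(keep_b))))
  pa <- fit_a$par; pb <- fit_b$par
  avg2 <- function(nm) unname((pa[nm] + pb[nm]) / 2)
  lower0 <- function(k) rep(c(0, 1e-8), c(k[1], k[2]))

  if (component == "all") {
    form <- y ~ Y0 + A1 * (1 - exp(-k1 * t)) + A2 * (1 - exp(-k2 * t))
    start <- list(Y0 = avg2("Y0"), A1 = avg2("A1"), k1 = avg2("k1"),
                  A2 = avg2("A2"), k2 = avg2("k2"))
    lower <- c(-Inf, -Inf, 1e-8, -Inf, 1e-8)
    p_null <- 5L
  } else if (component == "fast") {
    form <- y ~ ifelse(g == 0, Y0a, Y0b) + A1 * (1 - exp(-k1 * t)) +
      ifelse(g == 0, A2a, A2b) * (1 - exp(-ifelse(g == 0, k2a, k2b) * t))
    start <- list(Y0a = unname(pa["Y0"]), Y0b = unname(pb["Y0"]),
                  A1 = avg2("A1"), k1 = avg2("k1"),
                  A2a = unname(pa["A2"]), A2b = unname(pb["A2"]),
                  k2a = unname(pa["k2"]), k2b = unname(pb["k2"]))
    lower <- c(-Inf, -Inf, -Inf, 1e-8, -Inf, -Inf, 1e-8, 1e-8)
    p_null <- 8L
  } else {
    form <- y ~ ifelse(g == 0, Y0a, Y0b) +
      ifelse(g == 0, A1a, A1b) * (1 - exp(-ifelse(g == 0, k1a, k1b) * t)) +
      A2 * (1 - exp(-k2 * t))
    start <- list(Y0a = unname(pa["Y0"]), Y0b = unname(pb["Y0"]),
                  A1a = unname(pa["A1"]), A1b = unname(pb["A1"]),
                  k1a = unname(pa["k1"]), k1b = unname(pb["k1"]),
                  A2 = avg2("A2"), k2 = avg2("k2"))
    lower <- c(-Inf, -Inf, -Inf, -Inf, 1e-8, 1e-8, -Inf, 1e-8)
    p_null <- 8L
  }
  nf <- tryCatch(
    minpack.lm::nlsLM(form, data = dat, start = start, lower = lower,
                      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) stop("shared-parameter fit failed: ",
                             conditionMessage(e)))
  ss_shared <- sum(stats::resid(nf)^2)
  ss_shared <- max(ss_shared, ss_free)  # guard: null can never beat the free fit
  test <- extra_ss_f(ss_shared, p_null, ss_free, p_free, n)
  test$test <- paste0("genotype comparison (", component, " component)")
  list(test = test, fit_a = fit_a, fit_b = fit_b, ss_shared = ss_shared)
}
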