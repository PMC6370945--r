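# Shared fixtures and independent oracles, all built in code.

# two cells separated by a 1-px membrane column
two_cell_mask <- function(nr = 10, half = 10) {
  m <- matrix(0L, nr, 2 * half + 1)
  m[, 1:half] <- 1L
  m[, (half + 2):(2 * half + 1)] <- 2L
  label_mask(m)
}

uniform_clone <- function(label, code = "wildtype") {
  clone_map(matrix(CLONE_CODES[[code]], nrow(label), ncol(label)))
}

# square cell 1 with a 0-ring, embedded in surrounding cell 2
square_cell_mask <- function(n = 25, r = 7) {
  m <- matrix(2L, n, n)
  c0 <- (n + 1) / 2
  inner <- abs(row(m) - c0) <= r & abs(col(m) - c0) <= r
  ring <- abs(row(m) - c0) <= r + 1 & abs(col(m) - c0) <= r + 1 & !inner
  m[inner] <- 1L
  m[ring] <- 0L
  label_mask(m)
}

# disc cell 1 with a thin 0-ring, embedded in cell 2
disc_cell_mask <- function(n = 81, r = 30) {
  m <- matrix(2L, n, n)
  c0 <- (n + 1) / 2
  d2 <- (row(m) - c0)^2 + (col(m) - c0)^2
  m[d2 <= r^2] <- 1L
  m[d2 > r^2 & d2 <= (r + 1.6)^2] <- 0L
  label_mask(m)
}

# stack whose z-th slice is constant at value v[z] (so the membrane mean per
# slice is exactly v[z])
slice_constant_stack <- function(v, nr = 10, nc = 21) {
  a <- array(0, dim = c(length(v), nr, nc))
  for (z in seq_along(v)) a[z, , ] <- v[z]
  image_stack(a)
}

# independent connected-component oracle: explicit stack-based flood fill
flood_fill_components <- function(fg) {
  H <- nrow(fg); W <- ncol(fg)
  lab <- matrix(0L, H, W)
  nxt <- 0L
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (!fg[i, j] || lab[i, j] > 0L) next
    nxt <- nxt + 1L
    stack <- list(c(i, j))
    lab[i, j] <- nxt
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; c <- p[2] + dc
        if (r >= 1 && r <= H && c >= 1 && c <= W && fg[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- nxt
          stack[[length(stack) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# independent asymmetry-ratio oracle: plain loops over the axis grid
brute_asymmetry <- function(psi, intensity, axis_step = 1, half_width = 45) {
  best_m <- -Inf; best_angle <- NA_real_
  for (theta in seq(0, 180 - axis_step, by = axis_step)) {
    d <- abs(psi - theta) %% 180
    d <- pmin(d, 180 - d)
    inw <- d <= half_width
    if (!any(inw) || all(inw)) next
    r <- mean(intensity[inw]) / mean(intensity[!inw])
    m <- max(r, 1 / r)
    if (m > best_m + 1e-12) {
      best_m <- m
      best_angle <- if (r >= 1) theta else (theta + 90) %% 180
    }
  }
  list(magnitude = best_m, angle = best_angle)
}

# small rendered wing for pipeline tests
demo_wing <- function(seed = 1, ...) {
  sp <- wing_spec(n_cell_rows = 5, n_cell_cols = 5, seed = seed, ...)
  lat <- make_lattice(sp)
  list(spec = sp, lattice = lat, stack = render_membrane_stack(lat, sp),
       skeleton = build_skeleton(lat$label, lat$clone))
}
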