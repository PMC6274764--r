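# Fixtures are generated in code; oracles here are deliberately independent
# of the implementation paths they check.

# small fully-valid grid (emission far above excitation + 40)
full_grid <- function(n_exc = 9, n_em = 9, step = 10) {
  wavelength_grid(seq(400, by = step, length.out = n_exc),
                  seq(600, by = step, length.out = n_em))
}

# EEM from an intensity function f(exc, em) on a grid
eem_from_fun <- function(f, grid = default_grid(), meta = NULL) {
  m <- outer(grid$excitation_nm, grid$emission_nm, f)
  m[!osteem:::.scatter_mask(grid)] <- NA
  eem(pmax(m, 0), grid, meta = meta)
}

gauss2 <- function(exc0, em0, s_exc, s_em, amp = 1) {
  function(exc, em) amp * exp(-(exc - exc0)^2 / (2 * s_exc^2)) *
    exp(-(em - em0)^2 / (2 * s_em^2))
}

# noiseless two-component mixture on the default grid
two_component_eem <- function(a_complex, a_cell = 1, grid = default_grid()) {
  comps <- default_components()
  cell <- component_eem(comps$cellular, grid)
  cplx <- component_eem(comps$complex, grid)
  eem(a_cell * cell$intensity + a_complex * cplx$intensity, grid,
      mask = cell$mask)
}

# ---- oracles ---------------------------------------------------------------

# strict 8-neighbour extrema scan on the smoothed surface
oracle_extrema <- function(x, sigma = 1) {
  s <- smooth_eem(x, sigma)
  v <- s$intensity
  mask <- x$mask
  nr <- nrow(v); nc <- ncol(v)
  maxima <- NULL; minima <- NULL; saddles <- NULL
  for (i in 2:(nr - 1)) for (j in 2:(nc - 1)) {
    nb <- mask[(i - 1):(i + 1), (j - 1):(j + 1)]
    if (!all(nb)) next
    patch <- v[(i - 1):(i + 1), (j - 1):(j + 1)]
    others <- patch[-5]
    here <- patch[5]
    cell <- c(x$grid$excitation_nm[i], x$grid$emission_nm[j])
    if (all(here > others)) maxima <- rbind(maxima, cell)
    if (all(here < others)) minima <- rbind(minima, cell)
    row_max <- here > v[i - 1, j] && here > v[i + 1, j]
    row_min <- here < v[i - 1, j] && here < v[i + 1, j]
    col_max <- here > v[i, j - 1] && here > v[i, j + 1]
    col_min <- here < v[i, j - 1] && here < v[i, j + 1]
    if ((row_max && col_min) || (row_min && col_max))
      saddles <- rbind(saddles, cell)
  }
  list(maxima = maxima, minima = minima, saddles = saddles)
}

# closed-form ordinary least squares from the normal equations
lsq_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  slope <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  intercept <- (sy - slope * sx) / n
  res <- y - intercept - slope * x
  list(slope = slope, intercept = intercept,
       r_squared = 1 - sum(res^2) / sum((y - mean(y))^2))
}

# mask-aware Gaussian smoothing by direct per-cell summation
smooth_oracle <- function(x, sigma) {
  v <- x$intensity
  out <- v
  nr <- nrow(v); nc <- ncol(v)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!x$mask[i, j]) next
    num <- 0; den <- 0
    for (a in seq_len(nr)) for (b in seq_len(nc)) {
      if (!x$mask[a, b]) next
      if (abs(a - i) > ceiling(3 * sigma) ||
          abs(b - j) > ceiling(3 * sigma)) next
      w <- exp(-((a - i)^2 + (b - j)^2) / (2 * sigma^2))
      num <- num + w * v[a, b]
      den <- den + w
    }
    out[i, j] <- num / den
  }
  eem(out, x$grid, mask = x$mask)
}

expect_cells_equal <- function(a, b, tol = 1e-12) {
  expect_true(max(abs(a$intensity[a$mask] - b$intensity[b$mask])) <= tol)
}
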