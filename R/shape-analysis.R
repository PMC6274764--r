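# Shape fingerprinting of EEM surfaces: mask-aware smoothing, discrete
# critical-point detection and classification, saddle detection near 560 nm,
# and the rigid-scaling (shape invariance) statistic for free-dye series.
#
# The scientific signature: undifferentiated cells show a single broad
# emission peak near 500 nm; as the ARS-calcium complex forms, a 670 nm peak
# grows and a saddle appears near 560 nm emission. Free dye in solution only
# rescales rigidly with concentration and never forms a saddle.

#' Mask-aware Gaussian smoothing of an EEM
#'
#' Gaussian kernel with standard deviation `sigma_grid_units` (in grid steps),
#' renormalized over the valid cells under its footprint so that constants
#' are preserved next to the scatter-mask boundary. `sigma_grid_units = 0`
#' returns the input unchanged.
#'
#' @param x an [eem()].
#' @param sigma_grid_units kernel standard deviation in grid units (>= 0).
#' @return A smoothed [eem()] with the identical mask.
#' @export
smooth_eem <- function(x, sigma_grid_units = 1) {
  stopifnot(inherits(x, "eem"))
  if (sigma_grid_units < 0)
    .user_error("sigma_grid_units must be >= 0", "osteem_parameter_error")
  if (sigma_grid_units == 0) return(x)
  r <- ceiling(3 * sigma_grid_units)
  k <- outer(-r:r, -r:r, function(a, b)
    exp(-(a^2 + b^2) / (2 * sigma_grid_units^2)))
  v <- x$intensity
  v[!x$mask] <- 0
  w <- matrix(0, nrow(v), ncol(v))
  w[x$mask] <- 1
  num <- .conv2(v, k)
  den <- .conv2(w, k)
  out <- x$intensity
  out[x$mask] <- num[x$mask] / den[x$mask]
  eem(pmax(out, 0), x$grid, meta = x$meta, mask = x$mask)
}

# direct zero-padded 2D convolution; grids here are tiny (<= ~30x30)
.conv2 <- function(m, k) {
  r <- (nrow(k) - 1) / 2
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (di in -r:r) {
    si <- max(1, 1 - di):min(nr, nr - di)
    if (!length(si)) next
    for (dj in -r:r) {
      sj <- max(1, 1 - dj):min(nc, nc - dj)
      if (!length(sj)) next
      out[si, sj] <- out[si, sj] + k[di + r + 1, dj + r + 1] *
        m[si + di, sj + dj]
    }
  }
  out
}

# interior = valid cell whose 8 neighbours are valid and on-grid
.interior_mask <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  if (nr < 3 || nc < 3) return(out)
  for (i in 2:(nr - 1)) for (j in 2:(nc - 1))
    out[i, j] <- all(mask[(i - 1):(i + 1), (j - 1):(j + 1)])
  out
}

#' Stationary points of a smoothed EEM surface
#'
#' After mask-aware smoothing, an interior valid cell is stationary when both
#' central-difference gradient components fall below
#' `grad_tol_frac * (max - min)` per grid step. Stationary cells are
#' classified by the eigenvalue signs of the discrete Hessian (both negative
#' = maximum, both positive = minimum, mixed = saddle); near-zero eigenvalues
#' (below 1e-9 of the dynamic range) mark the point indeterminate and it is
#' dropped. Adjacent stationary cells of one kind are merged to the cell with
#' extremal intensity. Cells on the scatter-mask or grid boundary are never
#' classified.
#'
#' @param x an [eem()].
#' @param sigma_grid_units smoothing bandwidth, see [smooth_eem()].
#' @param grad_tol_frac stationarity tolerance as a fraction of the dynamic
#'   range, in (0, 0.1].
#' @return A data.frame of class `critical_points` with columns `exc_nm`,
#'   `em_nm`, `intensity`, `kind` (maximum / minimum / saddle). Empty for a
#'   constant surface.
#' @export
find_critical_points <- function(x, sigma_grid_units = 1,
                                 grad_tol_frac = 0.02) {
  stopifnot(inherits(x, "eem"))
  if (grad_tol_frac <= 0 || grad_tol_frac > 0.1)
    .user_error("grad_tol_frac must lie in (0, 0.1]", "osteem_parameter_error")
  interior <- .interior_mask(x$mask)
  if (sum(interior) < 25)
    .user_error("EEM grid too small: fewer than 5x5 valid interior cells",
                "osteem_domain_error")
  s <- smooth_eem(x, sigma_grid_units)
  v <- s$intensity
  rng <- diff(range(v[x$mask]))
  empty <- data.frame(exc_nm = numeric(0), em_nm = numeric(0),
                      intensity = numeric(0), kind = character(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("critical_points", "data.frame")
  if (rng == 0) return(empty)
  tol <- grad_tol_frac * rng
  eps <- 1e-9 * rng
  nr <- nrow(v); nc <- ncol(v)
  kind <- matrix(NA_character_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!interior[i, j]) next
    gx <- (v[i + 1, j] - v[i - 1, j]) / 2
    gy <- (v[i, j + 1] - v[i, j - 1]) / 2
    if (abs(gx) >= tol || abs(gy) >= tol) next
    hxx <- v[i + 1, j] - 2 * v[i, j] + v[i - 1, j]
    hyy <- v[i, j + 1] - 2 * v[i, j] + v[i, j - 1]
    hxy <- (v[i + 1, j + 1] - v[i + 1, j - 1] -
              v[i - 1, j + 1] + v[i - 1, j - 1]) / 4
    ev <- eigen(matrix(c(hxx, hxy, hxy, hyy), 2, 2),
                symmetric = TRUE, only.values = TRUE)$values
    if (any(abs(ev) < eps)) next          # degenerate: excluded
    kind[i, j] <- if (all(ev < 0)) "maximum"
    else if (all(ev > 0)) "minimum" else "saddle"
  }
  .merge_stationary(kind, v, x$grid, empty)
}

# does the cell's discrete neighbourhood actually exhibit its Hessian kind?
# (guards against the flat far tails of peaked surfaces, where the relative
# gradient tolerance marks whole regions stationary)
.neighbourhood_supports <- function(v, i, j, kk) {
  here <- v[i, j]
  if (kk == "maximum")
    return(all(here >= v[(i - 1):(i + 1), (j - 1):(j + 1)]))
  if (kk == "minimum")
    return(all(here <= v[(i - 1):(i + 1), (j - 1):(j + 1)]))
  row_max <- here >= v[i - 1, j] && here >= v[i + 1, j]
  row_min <- here <= v[i - 1, j] && here <= v[i + 1, j]
  col_max <- here >= v[i, j - 1] && here >= v[i, j + 1]
  col_min <- here <= v[i, j - 1] && here <= v[i, j + 1]
  (row_max && col_min) || (row_min && col_max)
}

# merge 8-connected components of equal kind; keep the extremal-intensity
# cell whose neighbourhood supports the kind (minimum kind keeps the lowest,
# others the highest; ties broken by lowest emission, then lowest
# excitation); components with no supported cell are spurious and dropped
.merge_stationary <- function(kind, v, grid, empty) {
  idx <- which(!is.na(kind), arr.ind = TRUE)
  if (!nrow(idx)) return(empty)
  n <- nrow(idx)
  comp <- seq_len(n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a >= b) next
    if (kind[idx[a, , drop = FALSE]] != kind[idx[b, , drop = FALSE]]) next
    if (max(abs(idx[a, ] - idx[b, ])) == 1) {
      ca <- comp[a]; cb <- comp[b]
      comp[comp == max(ca, cb)] <- min(ca, cb)
    }
  }
  rows <- lapply(unique(comp), function(cc) {
    members <- idx[comp == cc, , drop = FALSE]
    kk <- kind[members[1, , drop = FALSE]]
    ok <- vapply(seq_len(nrow(members)), function(r)
      .neighbourhood_supports(v, members[r, 1], members[r, 2], kk),
      logical(1))
    if (!any(ok)) return(NULL)
    cand <- members[ok, , drop = FALSE]
    val <- v[cand]
    best <- if (kk == "minimum") val == min(val) else val == max(val)
    cand <- cand[best, , drop = FALSE]
    ord <- order(grid$emission_nm[cand[, 2]], grid$excitation_nm[cand[, 1]])
    pick <- cand[ord[1], , drop = FALSE]
    data.frame(exc_nm = grid$excitation_nm[pick[1, 1]],
               em_nm = grid$emission_nm[pick[1, 2]],
               intensity = v[pick], kind = kk, stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$exc_nm, out$em_nm), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("critical_points", "data.frame")
  out
}

# smoothed 1-D emission profile at a probe excitation (on-grid)
.emission_profile <- function(x, exc_probe_nm, sigma_grid_units = 1) {
  s <- smooth_eem(x, sigma_grid_units)
  i <- match(exc_probe_nm, x$grid$excitation_nm)
  if (is.na(i))
    .user_error(sprintf("probe excitation %g nm is not on the grid",
                        exc_probe_nm), "osteem_domain_error")
  keep <- x$mask[i, ]
  list(em = x$grid$emission_nm[keep], value = s$intensity[i, keep])
}

# lowest profile value inside the window, flanked by strictly higher values
# somewhere on both sides
.window_min_flanked <- function(em, p, window) {
  iw <- which(em >= window[1] & em <= window[2])
  if (!length(iw)) return(FALSE)
  m <- iw[which.min(p[iw])]
  m > 1 && m < length(p) && any(p[1:(m - 1)] > p[m]) &&
    any(p[(m + 1):length(p)] > p[m])
}

.local_maxima <- function(p) {
  n <- length(p)
  if (n < 3) return(integer(0))
  which(p[2:(n - 1)] > p[1:(n - 2)] & p[2:(n - 1)] > p[3:n]) + 1L
}

#' Detect the mineralization saddle near 560 nm
#'
#' Looks for a 2D saddle (from [find_critical_points()]) whose emission
#' wavelength lies in `em_window_nm`, and additionally requires the 1-D
#' signature: the smoothed emission profile at `exc_probe_nm` must have a
#' local minimum in the window flanked by higher values on both sides. Both
#' checks must agree; absence is a valid result (`NULL`), marking an
#' unmineralized or free-dye spectrum.
#'
#' @param x an [eem()].
#' @param em_window_nm emission search window (nm), default `c(520, 600)`,
#'   bracketing the 560 nm saddle with margin.
#' @param exc_probe_nm probe excitation (nm), default 420.
#' @inheritParams find_critical_points
#' @return A one-row `critical_points` data.frame, or `NULL` when no saddle
#'   exists. Among several qualifying saddles the most intense wins (ties:
#'   lowest emission).
#' @export
detect_saddle <- function(x, em_window_nm = c(520, 600), exc_probe_nm = 420,
                          sigma_grid_units = 1, grad_tol_frac = 0.02) {
  cp <- find_critical_points(x, sigma_grid_units, grad_tol_frac)
  sad <- cp[cp$kind == "saddle" & cp$em_nm >= em_window_nm[1] &
              cp$em_nm <= em_window_nm[2], , drop = FALSE]
  if (!nrow(sad)) return(NULL)
  sad <- sad[order(-sad$intensity, sad$em_nm), , drop = FALSE]
  prof <- .emission_profile(x, exc_probe_nm, sigma_grid_units)
  # 2D and 1-D signatures must agree
  if (!.window_min_flanked(prof$em, prof$value, em_window_nm)) return(NULL)
  out <- sad[1, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify an EEM by its mineralization shape signature
#'
#' @param x an [eem()], background-subtracted.
#' @inheritParams detect_saddle
#' @return An object of class `shape_report`: list with `critical_points`,
#'   `has_saddle`, `saddle`, `primary_peak` (global maximum over valid
#'   cells), `classification` (one of `mineralized_double_peak`,
#'   `undifferentiated_single_peak`, `free_dye_single_peak`,
#'   `indeterminate`) and the emission-profile peak positions at the probe
#'   excitation.
#' @export
classify_spectrum <- function(x, em_window_nm = c(520, 600),
                              exc_probe_nm = 420, sigma_grid_units = 1,
                              grad_tol_frac = 0.02) {
  cp <- find_critical_points(x, sigma_grid_units, grad_tol_frac)
  saddle <- detect_saddle(x, em_window_nm, exc_probe_nm,
                          sigma_grid_units, grad_tol_frac)
  s <- smooth_eem(x, sigma_grid_units)
  peak_idx <- which(s$intensity == max(s$intensity[x$mask]), arr.ind = TRUE)
  peak_idx <- peak_idx[1, , drop = FALSE]
  primary <- data.frame(
    exc_nm = x$grid$excitation_nm[peak_idx[1, 1]],
    em_nm = x$grid$emission_nm[peak_idx[1, 2]],
    intensity = s$intensity[peak_idx], kind = "maximum",
    stringsAsFactors = FALSE)
  prof <- .emission_profile(x, exc_probe_nm, sigma_grid_units)
  peak_ems <- prof$em[.local_maxima(prof$value)]
  # the saddle's flanked-minimum signature already implies emission peaks on
  # both sides of the window; without a saddle the class is decided by where
  # the profile culminates (robust to sub-noise micro-maxima on flat bands)
  main_em <- prof$em[which.max(prof$value)]
  classification <- if (!is.null(saddle)) {
    "mineralized_double_peak"
  } else if (main_em < 560) {
    "undifferentiated_single_peak"
  } else if (main_em > 600) {
    "free_dye_single_peak"
  } else "indeterminate"
  structure(list(critical_points = cp,
                 has_saddle = classification == "mineralized_double_peak" &&
                   !is.null(saddle),
                 saddle = if (classification == "mineralized_double_peak")
                   saddle else NULL,
                 primary_peak = primary,
                 profile_peak_em_nm = peak_ems,
                 classification = classification,
                 sample_id = if (!is.null(x$meta)) x$meta$sample_id
                 else NA_character_),
            class = "shape_report")
}

#' @export
print.shape_report <- function(x, ...) {
  cat(sprintf("Shape report%s: %s\n",
              if (!is.na(x$sample_id)) paste0(" [", x$sample_id, "]") else "",
              x$classification))
  cat(sprintf("  primary peak at exc %g nm / em %g nm (%.4g a.u.)\n",
              x$primary_peak$exc_nm, x$primary_peak$em_nm,
              x$primary_peak$intensity))
  if (x$has_saddle)
    cat(sprintf("  saddle at exc %g nm / em %g nm (%.4g a.u.)\n",
                x$saddle$exc_nm, x$saddle$em_nm, x$saddle$intensity))
  invisible(x)
}

#' Flatten a shape report to one record
#' @param x a `shape_report`.
#' @param ... unused.
#' @export
as.data.frame.shape_report <- function(x, ...) {
  data.frame(sample_id = x$sample_id, classification = x$classification,
             has_saddle = x$has_saddle,
             saddle_exc_nm = if (x$has_saddle) x$saddle$exc_nm else NA_real_,
             saddle_em_nm = if (x$has_saddle) x$saddle$em_nm else NA_real_,
             peak_exc_nm = x$primary_peak$exc_nm,
             peak_em_nm = x$primary_peak$em_nm,
             stringsAsFactors = FALSE)
}

#' Rigid-scaling score across EEMs
#'
#' Each EEM is normalized to unit maximum over valid cells; the score is the
#' largest absolute cellwise deviation of any normalized spectrum from the
#' normalized reference. Exactly 0 when all spectra are scalar multiples of
#' the reference ("rigid linear shift" with concentration), bounded by 1.
#'
#' @param reference an [eem()] with positive maximum.
#' @param others a list of [eem()]s on the same grid.
#' @return A number in \[0, 1\].
#' @export
shape_invariance_score <- function(reference, others) {
  stopifnot(inherits(reference, "eem"))
  if (inherits(others, "eem")) others <- list(others)
  norm1 <- function(e) {
    m <- max(e$intensity[e$mask])
    if (m <= 0)
      .user_error("cannot normalize an all-zero EEM", "osteem_domain_error")
    e$intensity / m
  }
  ref <- norm1(reference)
  max(vapply(others, function(e) {
    if (!.same_grid(reference, e))
      .user_error("EEMs must share one grid", "osteem_shape_error")
    max(abs(norm1(e) - ref), na.rm = TRUE)
  }, numeric(1)))
}
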