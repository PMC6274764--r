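# Core containers for excitation-emission matrix (EEM) fluorescence data and
# optical-density (OD) spectra, with long/wide CSV interchange.

.conditions <- c("control", "om_7d", "om_14d", "go_7d", "go_om_7d",
                 "free_ars", "blank")
.substrates <- c("glass", "go", "solution")
.modes <- c("surface", "liquid")

.user_error <- function(msg, class = "osteem_validation_error") {
  stop(structure(class = c(class, "osteem_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Wavelength grid for an EEM
#'
#' An EEM is measured on a rectangular grid of excitation and emission
#' wavelengths with uniform spacing. The default instrument grid excites from
#' 400 to 580 nm in 10 nm steps and records emission from 440 to 700 nm in
#' 10 nm steps; only cells with emission >= excitation + 40 nm are physically
#' valid (the fixed scatter cutoff).
#'
#' @param excitation_nm strictly increasing, uniformly spaced excitation
#'   wavelengths (nm).
#' @param emission_nm strictly increasing, uniformly spaced emission
#'   wavelengths (nm), same step as excitation.
#' @return An object of class `wavelength_grid` with elements
#'   `excitation_nm`, `emission_nm`, `step_nm`.
#' @export
wavelength_grid <- function(excitation_nm, emission_nm) {
  for (w in list(excitation_nm, emission_nm)) {
    if (length(w) < 2 || any(diff(w) <= 0))
      .user_error("grid wavelengths must be strictly increasing")
    if (max(abs(diff(w) - diff(w)[1])) > 1e-8)
      .user_error("grid spacing must be uniform")
  }
  if (abs(diff(excitation_nm)[1] - diff(emission_nm)[1]) > 1e-8)
    .user_error("excitation and emission must share one grid step")
  structure(list(excitation_nm = as.numeric(excitation_nm),
                 emission_nm = as.numeric(emission_nm),
                 step_nm = as.numeric(diff(excitation_nm)[1])),
            class = "wavelength_grid")
}

#' @rdname wavelength_grid
#' @export
default_grid <- function() {
  wavelength_grid(seq(400, 580, by = 10), seq(440, 700, by = 10))
}

.scatter_mask <- function(grid, offset_nm = 40) {
  outer(grid$excitation_nm, grid$emission_nm,
        function(x, m) m >= x + offset_nm)
}

#' Sample metadata
#'
#' @param sample_id character identifier.
#' @param condition one of control, om_7d, om_14d, go_7d, go_om_7d, free_ars,
#'   blank.
#' @param substrate one of glass, go, solution.
#' @param mode "surface" (in situ) or "liquid" (after solvent extraction).
#' @param replicate integer >= 1.
#' @param concentration_mM dye concentration, required for free_ars samples
#'   and forbidden for blanks.
#' @return A `sample_meta` list.
#' @export
sample_meta <- function(sample_id, condition = "control",
                        substrate = "glass", mode = "surface",
                        replicate = 1L, concentration_mM = NULL) {
  condition <- match.arg(condition, .conditions)
  substrate <- match.arg(substrate, .substrates)
  mode <- match.arg(mode, .modes)
  if (replicate < 1) .user_error("replicate must be >= 1")
  if (condition == "free_ars" && is.null(concentration_mM))
    .user_error("free_ars samples require concentration_mM")
  if (condition == "blank" && !is.null(concentration_mM))
    .user_error("blank samples must not carry a concentration")
  if (!is.null(concentration_mM) && concentration_mM < 0)
    .user_error("concentration_mM must be non-negative")
  structure(list(sample_id = as.character(sample_id), condition = condition,
                 substrate = substrate, mode = mode,
                 replicate = as.integer(replicate),
                 concentration_mM = concentration_mM),
            class = "sample_meta")
}

#' Construct an EEM
#'
#' @param intensity numeric matrix, rows indexed by excitation and columns by
#'   emission wavelength; non-negative on the valid (scatter-masked) region.
#'   Cells outside the mask are stored as `NA` and never read.
#' @param grid a [wavelength_grid()].
#' @param meta optional [sample_meta()].
#' @param mask optional logical matrix; defaults to the emission >=
#'   excitation + 40 nm half plane. Supplying a mask can only further
#'   restrict that half plane (e.g. cells absent from a file).
#' @return An object of class `eem`.
#' @export
eem <- function(intensity, grid, meta = NULL, mask = NULL) {
  stopifnot(inherits(grid, "wavelength_grid"))
  intensity <- as.matrix(intensity)
  rule <- .scatter_mask(grid)
  if (!all(dim(intensity) == dim(rule)))
    .user_error("intensity matrix does not match the grid dimensions")
  if (is.null(mask)) mask <- rule
  if (any(mask & !rule))
    .user_error("mask may not include cells with emission < excitation + 40 nm")
  vals <- intensity[mask]
  if (anyNA(vals)) .user_error("missing intensity inside the valid mask")
  if (any(vals < 0)) .user_error("negative intensity inside the valid mask")
  intensity[!mask] <- NA_real_
  structure(list(grid = grid, intensity = intensity, mask = mask,
                 meta = meta),
            class = "eem")
}

#' @export
print.eem <- function(x, ...) {
  g <- x$grid
  cat(sprintf(
    "EEM: %d x %d grid (exc %g-%g nm, em %g-%g nm, step %g nm), %d valid cells\n",
    length(g$excitation_nm), length(g$emission_nm),
    min(g$excitation_nm), max(g$excitation_nm),
    min(g$emission_nm), max(g$emission_nm), g$step_nm, sum(x$mask)))
  if (!is.null(x$meta))
    cat(sprintf("  sample %s (%s, %s, %s, rep %d)\n", x$meta$sample_id,
                x$meta$condition, x$meta$substrate, x$meta$mode,
                x$meta$replicate))
  rng <- range(x$intensity[x$mask])
  cat(sprintf("  intensity range: %.4g to %.4g (a.u.)\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
as.matrix.eem <- function(x, ...) x$intensity

#' Heatmap of an EEM surface
#'
#' @param x an [eem()].
#' @param ... passed to [graphics::image()].
#' @export
plot.eem <- function(x, ...) {
  g <- x$grid
  graphics::image(g$excitation_nm, g$emission_nm, x$intensity,
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "excitation (nm)", ylab = "emission (nm)", ...)
  graphics::contour(g$excitation_nm, g$emission_nm, x$intensity,
                    add = TRUE, col = "grey30", drawlabels = FALSE)
  invisible(x)
}

.same_grid <- function(a, b) {
  isTRUE(all.equal(a$grid$excitation_nm, b$grid$excitation_nm)) &&
    isTRUE(all.equal(a$grid$emission_nm, b$grid$emission_nm))
}

#' Subtract a blank (negative control) EEM
#'
#' Cellwise difference of a sample and a blank measured on the same grid,
#' clipped at zero: fluorescence counts are non-negative and downstream ratio
#' statistics must not see negative denominators.
#'
#' @param sample,blank [eem()] objects on identical grids and masks.
#' @return The background-subtracted `eem` (metadata copied from `sample`).
#' @export
subtract_background <- function(sample, blank) {
  stopifnot(inherits(sample, "eem"), inherits(blank, "eem"))
  if (!.same_grid(sample, blank) || !identical(sample$mask, blank$mask))
    .user_error("sample and blank EEMs must share grid and mask",
                "osteem_shape_error")
  out <- pmax(sample$intensity - blank$intensity, 0)
  eem(out, sample$grid, meta = sample$meta, mask = sample$mask)
}

#' Intensity lookup on an EEM
#'
#' Exact cell value when both wavelengths fall on grid nodes; bilinear
#' interpolation between the four surrounding valid cells otherwise.
#'
#' @param x an [eem()].
#' @param exc_nm,em_nm query wavelengths (nm), scalars or equal-length
#'   vectors.
#' @return Numeric intensity (a.u.).
#' @export
get_intensity <- function(x, exc_nm, em_nm) {
  stopifnot(inherits(x, "eem"), length(exc_nm) == length(em_nm))
  vapply(seq_along(exc_nm), function(k)
    .interp_one(x, exc_nm[k], em_nm[k]), numeric(1))
}

.bracket <- function(axis, q) {
  if (q < axis[1] || q > axis[length(axis)]) return(NULL)
  i <- findInterval(q, axis, rightmost.closed = TRUE)
  t <- (q - axis[i]) / (axis[min(i + 1, length(axis))] - axis[i])
  if (i == length(axis)) t <- 0
  list(i = i, t = t)
}

.interp_one <- function(x, exc, em) {
  bi <- .bracket(x$grid$excitation_nm, exc)
  bj <- .bracket(x$grid$emission_nm, em)
  if (is.null(bi) || is.null(bj))
    .user_error(sprintf("query (%g, %g) lies outside the grid", exc, em),
                "osteem_domain_error")
  ii <- unique(c(bi$i, if (bi$t > 0) bi$i + 1))
  jj <- unique(c(bj$i, if (bj$t > 0) bj$i + 1))
  wi <- if (length(ii) == 2) c(1 - bi$t, bi$t) else 1
  wj <- if (length(jj) == 2) c(1 - bj$t, bj$t) else 1
  cells <- x$intensity[ii, jj, drop = FALSE]
  if (anyNA(cells))
    .user_error(sprintf(
      "query (%g, %g) touches the scatter-masked region", exc, em),
      "osteem_domain_error")
  sum(outer(wi, wj) * cells)
}

# ---- long CSV interchange ---------------------------------------------------

#' Read / write EEMs as long-format CSV
#'
#' The interchange format is a long CSV with header
#' `excitation_nm,emission_nm,intensity`, one row per valid (unmasked) cell.
#' The grid is inferred from the distinct wavelengths in the file; valid-mask
#' cells absent from the file are marked invalid.
#'
#' @param path file path.
#' @param meta optional [sample_meta()] attached to the result.
#' @return `read_eem_csv()` returns an [eem()]; `write_eem_csv()` returns
#'   `path` invisibly.
#' @export
read_eem_csv <- function(path, meta = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("excitation_nm", "emission_nm", "intensity")
  if (!all(need %in% names(df)))
    .user_error(sprintf("%s: missing header columns %s", path,
                        paste(setdiff(need, names(df)), collapse = ", ")),
                "osteem_format_error")
  dup <- duplicated(df[c("excitation_nm", "emission_nm")])
  if (any(dup))
    .user_error(sprintf("%s: duplicate (excitation, emission) pair at row %d",
                        path, which(dup)[1]), "osteem_format_error")
  if (any(df$intensity < 0))
    .user_error(sprintf("%s: negative intensity", path))
  exc <- sort(unique(df$excitation_nm))
  em <- sort(unique(df$emission_nm))
  grid <- tryCatch(wavelength_grid(exc, em), osteem_error = function(e)
    .user_error(sprintf("%s: ragged wavelength grid (%s)", path,
                        conditionMessage(e))))
  if (any(df$emission_nm < df$excitation_nm + 40))
    .user_error(sprintf(
      "%s: rows with emission < excitation + 40 nm violate the scatter mask",
      path))
  m <- matrix(NA_real_, length(exc), length(em))
  m[cbind(match(df$excitation_nm, exc), match(df$emission_nm, em))] <-
    df$intensity
  mask <- .scatter_mask(grid) & !is.na(m)
  eem(m, grid, meta = meta, mask = mask)
}

#' @rdname read_eem_csv
#' @param x an [eem()] to serialize.
#' @export
write_eem_csv <- function(x, path) {
  stopifnot(inherits(x, "eem"))
  idx <- which(x$mask, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  lines <- c("excitation_nm,emission_nm,intensity",
             sprintf("%.10g,%.10g,%.17g",
                     x$grid$excitation_nm[idx[, 1]],
                     x$grid$emission_nm[idx[, 2]],
                     x$intensity[idx]))
  ok <- tryCatch({writeLines(lines, path); TRUE},
                 error = function(e) FALSE, warning = function(e) FALSE)
  if (!ok) .user_error(sprintf("cannot write %s", path), "osteem_io_error")
  invisible(path)
}

#' Wide CSV export of an EEM (for plotting)
#'
#' Emission wavelengths run along columns; the first column is
#' `excitation_nm`; scatter-masked cells are left empty.
#'
#' @inheritParams write_eem_csv
#' @export
write_eem_wide <- function(x, path) {
  stopifnot(inherits(x, "eem"))
  vals <- ifelse(is.na(x$intensity), "", sprintf("%.17g", x$intensity))
  lines <- c(paste(c("excitation_nm", x$grid$emission_nm), collapse = ","),
             vapply(seq_along(x$grid$excitation_nm), function(i)
               paste(c(x$grid$excitation_nm[i], vals[i, ]), collapse = ","),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

# ---- OD spectra -------------------------------------------------------------

#' Optical density spectrum
#'
#' @param wavelength_nm strictly increasing wavelengths (nm).
#' @param od non-negative absorbance values (OD units).
#' @param meta optional [sample_meta()].
#' @return An object of class `od_spectrum`.
#' @export
od_spectrum <- function(wavelength_nm, od, meta = NULL) {
  if (length(wavelength_nm) != length(od))
    .user_error("wavelength and od vectors must have equal length")
  if (any(diff(wavelength_nm) <= 0))
    .user_error("OD wavelengths must be strictly increasing")
  if (any(od < 0)) .user_error("negative OD value")
  structure(list(wavelength_nm = as.numeric(wavelength_nm),
                 od = as.numeric(od), meta = meta),
            class = "od_spectrum")
}

#' @export
print.od_spectrum <- function(x, ...) {
  cat(sprintf("OD spectrum: %d points, %g-%g nm, max OD %.4g\n",
              length(x$od), min(x$wavelength_nm), max(x$wavelength_nm),
              max(x$od)))
  invisible(x)
}

#' @rdname read_eem_csv
#' @export
read_od_csv <- function(path, meta = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("wavelength_nm", "od")
  if (!all(need %in% names(df)))
    .user_error(sprintf("%s: missing header columns %s", path,
                        paste(setdiff(need, names(df)), collapse = ", ")),
                "osteem_format_error")
  od_spectrum(df$wavelength_nm, df$od, meta = meta)
}

#' @rdname read_eem_csv
#' @param od an [od_spectrum()] to serialize.
#' @export
write_od_csv <- function(od, path) {
  stopifnot(inherits(od, "od_spectrum"))
  writeLines(c("wavelength_nm,od",
               sprintf("%.10g,%.17g", od$wavelength_nm, od$od)), path)
  invisible(path)
}

#' OD readout at a wavelength (linear interpolation off-grid)
#' @noRd
.od_at <- function(od, wl) {
  if (wl < min(od$wavelength_nm) || wl > max(od$wavelength_nm))
    .user_error(sprintf("OD spectrum does not cover %g nm", wl),
                "osteem_domain_error")
  stats::approx(od$wavelength_nm, od$od, xout = wl)$y
}

# ---- manifest ---------------------------------------------------------------

.manifest_cols <- c("sample_id", "condition", "substrate", "mode",
                    "replicate", "concentration_mM", "eem_path", "od_path")

#' Read / write a sample manifest CSV
#'
#' Columns: sample_id, condition, substrate, mode, replicate,
#' concentration_mM, eem_path, od_path (empty fields allowed).
#'
#' @param path file path.
#' @return A data.frame with the manifest columns.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(concentration_mM = "numeric"))
  if (!all(.manifest_cols %in% names(df)))
    .user_error(sprintf("%s: missing manifest columns %s", path,
                        paste(setdiff(.manifest_cols, names(df)),
                              collapse = ", ")), "osteem_format_error")
  df[.manifest_cols]
}

#' @rdname read_manifest
#' @param manifest a data.frame with the manifest columns.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(all(.manifest_cols %in% names(manifest)))
  utils::write.csv(manifest[.manifest_cols], path, row.names = FALSE,
                   na = "")
  invisible(path)
}
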