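# The normalized mineralization index and the four-method fold-induction
# comparison (absorbance / fluorescence x in-situ "surface" / solvent-extract
# "liquid"). The index is the ratio of emission intensity at the 670 nm
# ARS-calcium peak to the intensity at the 560 nm saddle, both read at 420 nm
# excitation. Being a ratio of two cells of the same spectrum, it is
# invariant under scalar attenuation -- the property that makes in-situ
# quantification possible on opaque substrates (graphene oxide) where
# absorbance readings are swamped by the substrate itself.

#' Definition of the ratiometric mineralization index
#'
#' @param exc_nm excitation wavelength (nm), default 420.
#' @param peak_em_nm emission wavelength of the ARS-calcium peak (nm),
#'   default 670.
#' @param saddle_em_nm emission wavelength of the saddle (nm), default 560.
#' @return An `index_definition` list.
#' @export
index_definition <- function(exc_nm = 420, peak_em_nm = 670,
                             saddle_em_nm = 560) {
  if (!(peak_em_nm > saddle_em_nm && saddle_em_nm > exc_nm + 40))
    .user_error("index wavelengths must satisfy peak > saddle > exc + 40 nm",
                "osteem_parameter_error")
  structure(list(exc_nm = exc_nm, peak_em_nm = peak_em_nm,
                 saddle_em_nm = saddle_em_nm), class = "index_definition")
}

#' Normalized 670/560 ratio index of an EEM
#'
#' Intensities are read at the fixed definition wavelengths (interpolated if
#' off-grid), not at detected critical points; the detected saddle location
#' is a diagnostic reported by [classify_spectrum()]. The denominator is
#' floored at `epsilon_frac` times the global maximum so near-dark spectra
#' cannot blow the ratio up.
#'
#' @param x an [eem()].
#' @param definition an [index_definition()].
#' @param epsilon_frac denominator floor as a fraction of the global
#'   maximum, default 1e-6.
#' @return An object of class `index_result` with fields `value`,
#'   `numerator`, `denominator`, `definition`.
#' @export
ratio_index <- function(x, definition = index_definition(),
                        epsilon_frac = 1e-6) {
  stopifnot(inherits(x, "eem"), inherits(definition, "index_definition"))
  gmax <- max(x$intensity[x$mask])
  if (gmax <= 0)
    .user_error("ratio index undefined for an all-zero EEM",
                "osteem_domain_error")
  num <- get_intensity(x, definition$exc_nm, definition$peak_em_nm)
  den <- max(get_intensity(x, definition$exc_nm, definition$saddle_em_nm),
             epsilon_frac * gmax)
  structure(list(value = num / den, numerator = num, denominator = den,
                 definition = definition), class = "index_result")
}

#' @export
print.index_result <- function(x, ...) {
  d <- x$definition
  cat(sprintf("I(%g, %g) / I(%g, %g) = %.4g / %.4g = %.4g\n",
              d$exc_nm, d$peak_em_nm, d$exc_nm, d$saddle_em_nm,
              x$numerator, x$denominator, x$value))
  invisible(x)
}

#' Blank-subtracted absorbance readout at the ARS peak
#'
#' @param od,blank [od_spectrum()] objects covering `peak_nm`.
#' @param peak_nm readout wavelength (nm), default 515 (the ARS absorbance
#'   peak).
#' @return Blank-subtracted OD at `peak_nm`, clipped at 0.
#' @export
od_value <- function(od, blank, peak_nm = 515) {
  stopifnot(inherits(od, "od_spectrum"), inherits(blank, "od_spectrum"))
  max(.od_at(od, peak_nm) - .od_at(blank, peak_nm), 0)
}

#' Fold induction relative to the undifferentiated control
#'
#' @param sample_value,control_value raw quantification values under the
#'   same method; `control_value` must be positive.
#' @return `sample_value / control_value`.
#' @export
fold_induction <- function(sample_value, control_value) {
  if (any(control_value <= 0))
    .user_error("control value must be positive", "osteem_domain_error")
  sample_value / control_value
}

.methods4 <- c("od_surface", "od_liquid", "fluor_surface", "fluor_liquid")

#' Pairwise agreement of per-method fold inductions
#'
#' The relative difference of a method pair is symmetric:
#' `|f_i - f_j| / mean(f_i, f_j)`.
#'
#' @param per_method named numeric vector of fold inductions (>= 2 entries).
#' @return An object of class `method_comparison` with `per_method`, a
#'   data.frame `pairs`, and `max_pairwise_rel_diff`.
#' @export
compare_methods <- function(per_method) {
  if (length(per_method) < 2)
    .user_error("method comparison requires at least 2 methods",
                "osteem_specification_error")
  nm <- names(per_method)
  cmb <- utils::combn(length(per_method), 2)
  rel <- apply(cmb, 2, function(ij) {
    f <- per_method[ij]
    abs(f[1] - f[2]) / mean(f)
  })
  pairs <- data.frame(method_a = nm[cmb[1, ]], method_b = nm[cmb[2, ]],
                      rel_diff = as.numeric(rel), stringsAsFactors = FALSE)
  structure(list(per_method = per_method, pairs = pairs,
                 max_pairwise_rel_diff = max(pairs$rel_diff)),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("Fold induction by method:\n")
  for (m in names(x$per_method))
    cat(sprintf("  %-14s %.4g\n", m, x$per_method[[m]]))
  cat(sprintf("max pairwise relative difference: %.4g\n",
              x$max_pairwise_rel_diff))
  if (length(x$excluded))
    cat("excluded (unusable):", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

# raw quantification value of one replicate row of an experiment
.raw_value <- function(exp, row, method) {
  id <- row$sample_id
  blank_of <- function(substrate, what) {
    b <- exp$manifest[exp$manifest$condition == "blank" &
                        exp$manifest$substrate == substrate, , drop = FALSE]
    if (!nrow(b))
      .user_error(sprintf("no blank for substrate %s", substrate),
                  "osteem_specification_error")
    if (what == "eem") exp$eems[[b$sample_id[1]]] else exp$ods[[b$sample_id[1]]]
  }
  switch(method,
    od_surface = od_value(exp$ods[[id]], blank_of(row$substrate, "od")),
    od_liquid = od_value(exp$ods[[id]], blank_of("solution", "od")),
    fluor_surface = ratio_index(subtract_background(
      exp$eems[[id]], blank_of(row$substrate, "eem")))$value,
    fluor_liquid = ratio_index(subtract_background(
      exp$eems[[id]], blank_of("solution", "eem")))$value)
}

# mean raw value over the replicates of (condition, mode) under one method
.method_mean <- function(exp, condition, method) {
  mode <- if (grepl("surface", method)) "surface" else "liquid"
  rows <- exp$manifest[exp$manifest$condition == condition &
                         exp$manifest$mode == mode, , drop = FALSE]
  if (!nrow(rows))
    .user_error(sprintf("no %s measurements for condition %s (method %s)",
                        mode, condition, method),
                "osteem_specification_error")
  mean(vapply(seq_len(nrow(rows)), function(i)
    .raw_value(exp, rows[i, , drop = FALSE], method), numeric(1)))
}

#' Quantify one condition by all four methods
#'
#' Replicate raw values are averaged per method before fold computation
#' (mirroring the averaging of repeated spectral readings at acquisition);
#' folds are taken against the control condition under the same method.
#' In-situ absorbance on graphene-oxide substrates is excluded as unusable
#' (the broadband GO absorbance dominates the dye signal) and recorded in
#' `excluded`, never imputed.
#'
#' @param exp an experiment object from [generate_experiment()] or
#'   [load_experiment()].
#' @param condition the condition to quantify.
#' @param control the control condition name, default `"control"`.
#' @return A `method_comparison` whose `per_method` covers the usable
#'   methods, plus `raw` (per-method mean raw values for condition and
#'   control) and `excluded`.
#' @export
quantify_four_methods <- function(exp, condition, control = "control") {
  stopifnot(inherits(exp, "ars_experiment"))
  subs <- unique(exp$manifest$substrate[
    exp$manifest$condition == condition & exp$manifest$mode == "surface"])
  if (!length(subs))
    .user_error(sprintf("condition %s not present in the experiment",
                        condition), "osteem_specification_error")
  excluded <- if ("go" %in% subs) "od_surface" else character(0)
  usable <- setdiff(.methods4, excluded)
  raw <- lapply(usable, function(m) {
    s <- .method_mean(exp, condition, m)
    ctl <- tryCatch(.method_mean(exp, control, m),
                    osteem_specification_error = function(e) .user_error(
                      sprintf("missing control for method %s", m),
                      "osteem_specification_error"))
    c(sample = s, control = ctl)
  })
  names(raw) <- usable
  folds <- vapply(raw, function(r) fold_induction(r[["sample"]],
                                                  r[["control"]]),
                  numeric(1))
  out <- compare_methods(folds)
  out$raw <- raw
  out$excluded <- excluded
  out$condition <- condition
  out
}
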