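# Seeded synthetic-data generator: EEMs, OD spectra, dilution series and
# full multi-condition experiments with known ground truth. The generator is
# the package's stand-in for raw assay data, emulating (a) a broad cellular
# autofluorescence band peaking at 500 nm emission, (b) the ARS-calcium
# complex band at 670 nm whose growth carves a saddle near 560 nm, (c) free
# dye in solution that rescales rigidly with concentration, (d) OD spectra
# peaking at 515 nm and affine in dye load, and (e) substrate optics: glass
# (transparent), graphene oxide (broadband OD baseline ~2 that swamps in-situ
# absorbance, scalar fluorescence attenuation 0.6), or plain solution.

#' Product-Gaussian spectral component
#'
#' Component intensity at (exc, em) is the product of an excitation and an
#' emission Gaussian, unit amplitude at the joint center.
#'
#' @param name one of "cellular", "complex", "free_ars".
#' @param em_center_nm,em_sigma_nm emission Gaussian center / width (nm).
#' @param exc_center_nm,exc_sigma_nm excitation Gaussian center / width (nm).
#' @return A `component_spectrum` list.
#' @export
component_spectrum <- function(name, em_center_nm, em_sigma_nm,
                               exc_center_nm, exc_sigma_nm) {
  name <- match.arg(name, c("cellular", "complex", "free_ars"))
  if (em_sigma_nm <= 0 || exc_sigma_nm <= 0)
    .user_error("component sigmas must be positive", "osteem_parameter_error")
  structure(list(name = name, em_center_nm = em_center_nm,
                 em_sigma_nm = em_sigma_nm, exc_center_nm = exc_center_nm,
                 exc_sigma_nm = exc_sigma_nm), class = "component_spectrum")
}

#' Default spectral components
#'
#' Peak positions follow the assay's anatomy (cellular emission 500 nm,
#' ARS-calcium complex and free dye 670 nm); line widths are model choices
#' calibrated once so that the two-component mixture places its emission-axis
#' saddle near 560 nm at moderate (2-3.5x) index folds: the cellular band is
#' broad (sigma 180 nm, autofluorescence plus nonspecifically retained dye)
#' and the complex band narrow (sigma 40 nm).
#'
#' @return Named list of [component_spectrum()]s.
#' @export
default_components <- function() {
  list(cellular = component_spectrum("cellular", 500, 180, 440, 50),
       complex = component_spectrum("complex", 670, 40, 430, 60),
       free_ars = component_spectrum("free_ars", 670, 50, 430, 60))
}

#' Evaluate a component on a grid
#'
#' @param component a [component_spectrum()].
#' @param grid a [wavelength_grid()].
#' @return Unit-amplitude [eem()] of the component.
#' @export
component_eem <- function(component, grid = default_grid()) {
  stopifnot(inherits(component, "component_spectrum"))
  m <- outer(
    exp(-(grid$excitation_nm - component$exc_center_nm)^2 /
          (2 * component$exc_sigma_nm^2)),
    exp(-(grid$emission_nm - component$em_center_nm)^2 /
          (2 * component$em_sigma_nm^2)))
  eem(m, grid)
}

#' Measurement noise model
#'
#' Noisy intensity = noiseless * (1 + N(0, cv)) + floor * |N(0, 1)|, clipped
#' at 0, where floor is `additive_floor_frac` of the noiseless maximum.
#' Every sample draws from its own RNG stream keyed by
#' (seed, sample_id, replicate), so outputs are reproducible per seed and
#' independent of generation order.
#'
#' @param multiplicative_cv coefficient of variation, default 0.02.
#' @param additive_floor_frac additive floor as a fraction of the noiseless
#'   maximum, default 0.005.
#' @param seed integer master seed.
#' @return A `noise_model` list.
#' @export
noise_model <- function(multiplicative_cv = 0.02,
                        additive_floor_frac = 0.005, seed = 1L) {
  if (multiplicative_cv < 0 || additive_floor_frac < 0)
    .user_error("noise parameters must be non-negative",
                "osteem_parameter_error")
  structure(list(multiplicative_cv = multiplicative_cv,
                 additive_floor_frac = additive_floor_frac,
                 seed = as.integer(seed)), class = "noise_model")
}

#' @rdname noise_model
#' @export
noise_off <- function(seed = 1L) noise_model(0, 0, seed)

# deterministic 31-bit stream key from (seed, id, replicate)
.derive_seed <- function(seed, id, replicate = 1L) {
  v <- utf8ToInt(id)
  h <- 0
  for (k in seq_along(v)) h <- (h * 131 + v[k]) %% 1000003
  as.integer((abs(seed) * 48271 + h * 2147 + replicate * 7919) %% 2147483629)
}

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

.apply_eem_noise <- function(x, noise, key_id, replicate) {
  if (noise$multiplicative_cv == 0 && noise$additive_floor_frac == 0)
    return(x)
  v <- x$intensity
  n <- sum(x$mask)
  mx <- max(v[x$mask], 0)
  .with_seed(.derive_seed(noise$seed, key_id, replicate), {
    v[x$mask] <- v[x$mask] * (1 + stats::rnorm(n, 0, noise$multiplicative_cv)) +
      noise$additive_floor_frac * mx * abs(stats::rnorm(n))
  })
  eem(pmax(v, 0), x$grid, meta = x$meta, mask = x$mask)
}

#' Substrate optical model
#'
#' @param kind "glass", "go" (graphene oxide) or "solution".
#' @param od_baseline broadband substrate absorbance at 515 nm (OD units);
#'   defaults: glass 0.02, go 2.0, solution 0.01.
#' @param fluor_attenuation wavelength-independent scalar in (0, 1\] applied
#'   to all fluorescence; defaults: glass 1.0, go 0.6, solution 1.0. Scalar
#'   attenuation cancels in the ratio index by construction.
#' @return A `substrate_model` list.
#' @export
substrate_model <- function(kind = c("glass", "go", "solution"),
                            od_baseline = NULL, fluor_attenuation = NULL) {
  kind <- match.arg(kind)
  defs <- list(glass = c(0.02, 1.0), go = c(2.0, 0.6),
               solution = c(0.01, 1.0))[[kind]]
  od_baseline <- if (is.null(od_baseline)) defs[1] else od_baseline
  fluor_attenuation <- if (is.null(fluor_attenuation)) defs[2]
  else fluor_attenuation
  if (fluor_attenuation <= 0 || fluor_attenuation > 1)
    .user_error("fluor_attenuation must lie in (0, 1]",
                "osteem_parameter_error")
  structure(list(kind = kind, od_baseline = od_baseline,
                 fluor_attenuation = fluor_attenuation),
            class = "substrate_model")
}

#' Scenario configuration: generative truth for one condition
#'
#' @param condition condition label (see [sample_meta()]).
#' @param substrate a [substrate_model()] or kind string.
#' @param a_cell cellular amplitude (a.u.), default 1.
#' @param a_complex complex amplitude (a.u.), or `"solve_for_fold"` to
#'   derive it from `target_fold` via [solve_complex_amplitude()].
#' @param target_fold index fold induction this scenario realizes relative
#'   to an a_complex = 0 control (required when `a_complex` is solved).
#' @param extraction_efficiency fraction of the stained layer recovered by
#'   solvent extraction, default 0.9.
#' @param replicates biological replicates, default 3.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(condition, substrate = "glass", a_cell = 1,
                            a_complex = "solve_for_fold",
                            target_fold = NULL,
                            extraction_efficiency = 0.9, replicates = 3L) {
  condition <- match.arg(condition, .conditions)
  if (is.character(substrate)) substrate <- substrate_model(substrate)
  if (identical(a_complex, "solve_for_fold") && is.null(target_fold))
    .user_error("a_complex = 'solve_for_fold' requires target_fold",
                "osteem_specification_error")
  structure(list(condition = condition, substrate = substrate,
                 a_cell = a_cell, a_complex = a_complex,
                 target_fold = target_fold,
                 extraction_efficiency = extraction_efficiency,
                 replicates = as.integer(replicates)),
            class = "scenario_config")
}

#' Default five-scenario experiment design
#'
#' The graphene-oxide folds (2.7 on GO alone, 3.5 on GO + osteogenic medium)
#' are the study conditions the generator realizes; the glass folds (om_7d
#' 2.0, om_14d 3.0) are free model defaults. The control has no complex
#' component and fold 1 by definition.
#'
#' @return Named list of [scenario_config()]s.
#' @export
default_scenarios <- function() {
  list(
    control = scenario_config("control", "glass", a_complex = 0,
                              target_fold = 1),
    om_7d = scenario_config("om_7d", "glass", target_fold = 2.0),
    om_14d = scenario_config("om_14d", "glass", target_fold = 3.0),
    go_7d = scenario_config("go_7d", "go", target_fold = 2.7),
    go_om_7d = scenario_config("go_om_7d", "go", target_fold = 3.5))
}

# noiseless two-component mixture
.mix_eem <- function(a_cell, a_complex, grid, components = default_components(),
                     scale = 1) {
  cell <- component_eem(components$cellular, grid)$intensity
  cplx <- component_eem(components$complex, grid)$intensity
  m <- scale * (a_cell * cell + a_complex * cplx)
  m[is.na(cell)] <- NA
  eem(pmax(m, 0), grid, mask = !is.na(cell))
}

#' Solve the complex amplitude that realizes a target index fold
#'
#' The noiseless ratio index is strictly increasing in the complex
#' amplitude, so bisection (via [stats::uniroot()]) finds the unique
#' `a_complex >= 0` with
#' `index(a_cell, a_complex) = target_fold * index(a_cell, 0)`.
#'
#' @param target_fold target index fold, >= 1.
#' @param a_cell cellular amplitude.
#' @param grid evaluation grid.
#' @param components component set, see [default_components()].
#' @return The solved amplitude (relative tolerance ~1e-9).
#' @export
solve_complex_amplitude <- function(target_fold, a_cell = 1,
                                    grid = default_grid(),
                                    components = default_components()) {
  if (target_fold < 1)
    .user_error("target_fold must be >= 1", "osteem_parameter_error")
  idx <- function(a)
    ratio_index(.mix_eem(a_cell, a, grid, components))$value
  base <- idx(0)
  if (target_fold == 1) return(0)
  f <- function(a) idx(a) - target_fold * base
  hi <- max(a_cell, 1)
  while (f(hi) < 0) {
    hi <- hi * 2
    if (hi > 1e9)
      .user_error("target_fold unreachable with these components",
                  "osteem_parameter_error")
  }
  stats::uniroot(f, c(0, hi), tol = 1e-11)$root
}

# numeric a_complex and the fold actually realized (== target for solved
# scenarios, by construction)
.resolve_scenario <- function(sc, grid, components = default_components()) {
  if (identical(sc$a_complex, "solve_for_fold"))
    sc$a_complex <- solve_complex_amplitude(sc$target_fold, sc$a_cell,
                                            grid, components)
  if (!is.numeric(sc$a_complex))
    .user_error("a_complex is unresolved", "osteem_specification_error")
  idx <- function(a)
    ratio_index(.mix_eem(sc$a_cell, a, grid, components))$value
  sc$realized_fold <- idx(sc$a_complex) / idx(0)
  sc
}

#' Generate one sample EEM under a scenario
#'
#' Surface mode: attenuation * (a_cell * cellular + a_complex * complex),
#' plus noise. Liquid mode: the solvent extract dissolves the stained layer,
#' so the same mixture scaled by `extraction_efficiency` (and a per-extract
#' lognormal jitter), without substrate attenuation.
#'
#' @param scenario a [scenario_config()] with numeric `a_complex` (see
#'   [solve_complex_amplitude()]).
#' @param noise a [noise_model()].
#' @param grid a [wavelength_grid()].
#' @param replicate replicate number (keys the noise stream).
#' @param mode "surface" or "liquid".
#' @param components component set.
#' @param extract_scale extraction scale for liquid mode (efficiency times
#'   jitter); defaults to the scenario's `extraction_efficiency`.
#' @return A noisy [eem()] with [sample_meta()] attached.
#' @export
generate_sample_eem <- function(scenario, noise = noise_model(),
                                grid = default_grid(), replicate = 1L,
                                mode = c("surface", "liquid"),
                                components = default_components(),
                                extract_scale = NULL) {
  stopifnot(inherits(scenario, "scenario_config"))
  mode <- match.arg(mode)
  if (!is.numeric(scenario$a_complex))
    .user_error("a_complex is unresolved; call solve_complex_amplitude first",
                "osteem_specification_error")
  scale <- if (mode == "surface") scenario$substrate$fluor_attenuation
  else if (is.null(extract_scale)) scenario$extraction_efficiency
  else extract_scale
  id <- sprintf("%s_r%d_%s", scenario$condition, replicate, mode)
  meta <- sample_meta(id, scenario$condition,
                      if (mode == "surface") scenario$substrate$kind
                      else "solution", mode, replicate)
  nl <- .mix_eem(scenario$a_cell, scenario$a_complex, grid, components,
                 scale = scale)
  nl$meta <- meta
  .apply_eem_noise(nl, noise, id, replicate)
}

#' Generate an OD spectrum
#'
#' OD(lambda) = substrate baseline + k_od * load * Gaussian(515 nm, sigma
#' 40 nm), with multiplicative noise. `load` is the dye load in
#' mM-equivalents (the concentration itself for dilution-series members).
#'
#' @param load dye load (mM-equivalents), >= 0.
#' @param substrate a [substrate_model()] or kind string.
#' @param noise a [noise_model()].
#' @param wavelength_nm output wavelengths, default 400-700 nm step 5.
#' @param k_od extinction scale (OD per mM at 515 nm), default 0.3.
#' @param sample_id,replicate key of the noise stream.
#' @return An [od_spectrum()].
#' @export
generate_od <- function(load, substrate = "solution",
                        noise = noise_model(),
                        wavelength_nm = seq(400, 700, by = 5), k_od = 0.3,
                        sample_id = "od", replicate = 1L) {
  if (load < 0) .user_error("load must be non-negative",
                            "osteem_parameter_error")
  if (is.character(substrate)) substrate <- substrate_model(substrate)
  od <- substrate$od_baseline +
    k_od * load * exp(-(wavelength_nm - 515)^2 / (2 * 40^2))
  if (noise$multiplicative_cv > 0)
    od <- .with_seed(.derive_seed(noise$seed, paste0(sample_id, "|od"),
                                  replicate),
                     od * (1 + stats::rnorm(length(od), 0,
                                            noise$multiplicative_cv)))
  od_spectrum(wavelength_nm, pmax(od, 0))
}

#' Dilution series container
#'
#' @param concentrations_mM strictly increasing positive concentrations.
#' @param samples list of `list(eem =, od =)` pairs, one per concentration.
#' @param blank_od optional solvent-only [od_spectrum()] for the series.
#' @return A `dilution_series` list.
#' @export
dilution_series <- function(concentrations_mM, samples, blank_od = NULL) {
  if (any(concentrations_mM <= 0) || any(diff(concentrations_mM) <= 0))
    .user_error("concentrations must be positive and strictly increasing",
                "osteem_parameter_error")
  if (length(samples) != length(concentrations_mM))
    .user_error("one sample per concentration required")
  structure(list(concentrations_mM = concentrations_mM, samples = samples,
                 blank_od = blank_od),
            class = "dilution_series")
}

#' Default 12-point dilution ladder, 0.00125 to 4 mM
#'
#' Geometric spacing (ratio ~2.08) between the assay's stated endpoints.
#'
#' @return Numeric vector of 12 concentrations (mM).
#' @export
default_dilution_ladder <- function() {
  signif(0.00125 * (4 / 0.00125)^((0:11) / 11), 6)
}

#' Generate a free-dye dilution series
#'
#' Each member's EEM is concentration times the single free-dye component
#' (so noiseless members are exact scalar multiples of one another and never
#' form a saddle), with a matched OD spectrum linear in concentration.
#'
#' @param concentrations_mM positive increasing concentrations, default
#'   [default_dilution_ladder()].
#' @param noise a [noise_model()].
#' @param grid a [wavelength_grid()].
#' @param components component set (uses `free_ars`).
#' @param f_per_mM fluorescence amplitude per mM, default 1.
#' @param k_od extinction scale, default 0.3 OD/mM.
#' @return A [dilution_series()].
#' @export
generate_dilution_series <- function(concentrations_mM =
                                       default_dilution_ladder(),
                                     noise = noise_model(),
                                     grid = default_grid(),
                                     components = default_components(),
                                     f_per_mM = 1, k_od = 0.3) {
  if (any(concentrations_mM <= 0))
    .user_error("concentrations must be positive", "osteem_parameter_error")
  base <- component_eem(components$free_ars, grid)
  samples <- lapply(seq_along(concentrations_mM), function(i) {
    conc <- concentrations_mM[i]
    id <- sprintf("ars_%g", conc)
    meta <- sample_meta(id, "free_ars", "solution", "liquid",
                        concentration_mM = conc)
    nl <- eem(f_per_mM * conc * base$intensity, grid, meta = meta,
              mask = base$mask)
    list(eem = .apply_eem_noise(nl, noise, id, 1L),
         od = generate_od(conc, "solution", noise, k_od = k_od,
                          sample_id = id))
  })
  dilution_series(concentrations_mM, samples,
                  blank_od = generate_od(0, "solution", noise,
                                         sample_id = "ars_blank"))
}

# od load (mM-equivalents) of a stained sample: control retains a
# nonspecific baseline load; mineralized conditions scale it by the realized
# index fold, so all four channels share one ground truth per condition
.od_load0 <- 0.1

#' Generate a full multi-condition experiment
#'
#' For each scenario and replicate: a surface EEM and OD, and a liquid
#' (extract) EEM and OD sharing one lognormal extraction jitter; plus one
#' blank EEM/OD per substrate (and for the extract solvent). All randomness
#' is keyed by (seed, sample id, replicate), so identical seeds reproduce
#' identical experiments. A ground-truth table records amplitudes and folds.
#'
#' @param scenarios named list of [scenario_config()]s; must include a
#'   control.
#' @param noise a [noise_model()].
#' @param grid a [wavelength_grid()].
#' @param components component set.
#' @param dir optional directory: when given, all spectra, the manifest and
#'   the ground-truth sidecar are written as CSV files.
#' @param jitter_sd lognormal sd of the per-extract efficiency jitter,
#'   default 0.02.
#' @return An object of class `ars_experiment`: list with `manifest`
#'   (data.frame), `eems`, `ods` (named lists), `truth` (data.frame),
#'   `grid`.
#' @export
generate_experiment <- function(scenarios = default_scenarios(),
                                noise = noise_model(),
                                grid = default_grid(),
                                components = default_components(),
                                dir = NULL, jitter_sd = 0.02) {
  if (!any(vapply(scenarios, function(s) s$condition == "control",
                  logical(1))))
    .user_error("scenarios must include a control",
                "osteem_specification_error")
  scenarios <- lapply(scenarios, .resolve_scenario, grid = grid,
                      components = components)
  eems <- list(); ods <- list(); rows <- list()
  add <- function(id, condition, substrate, mode, replicate, e, o) {
    eems[[id]] <<- e
    ods[[id]] <<- o
    rows[[length(rows) + 1]] <<- data.frame(
      sample_id = id, condition = condition, substrate = substrate,
      mode = mode, replicate = replicate, concentration_mM = NA_real_,
      eem_path = NA_character_, od_path = NA_character_,
      stringsAsFactors = FALSE)
  }
  zero <- eem(ifelse(.scatter_mask(grid), 0, NA), grid)
  for (sub in unique(c(vapply(scenarios, function(s) s$substrate$kind,
                              character(1)), "solution"))) {
    id <- paste0("blank_", sub)
    bl <- zero
    bl$meta <- sample_meta(id, "blank", sub,
                           if (sub == "solution") "liquid" else "surface")
    add(id, "blank", sub, bl$meta$mode, 1L,
        .apply_eem_noise(bl, noise, id, 1L),
        generate_od(0, substrate_model(sub), noise, sample_id = id))
  }
  for (sc in scenarios) {
    for (r in seq_len(sc$replicates)) {
      sid <- sprintf("%s_r%d_surface", sc$condition, r)
      add(sid, sc$condition, sc$substrate$kind, "surface", r,
          generate_sample_eem(sc, noise, grid, r, "surface", components),
          generate_od(.od_load0 * sc$realized_fold, sc$substrate, noise,
                      sample_id = sid, replicate = r))
      jitter <- .with_seed(
        .derive_seed(noise$seed, sprintf("%s_r%d|extract", sc$condition, r),
                     r),
        exp(stats::rnorm(1, 0, jitter_sd)))
      lid <- sprintf("%s_r%d_liquid", sc$condition, r)
      add(lid, sc$condition, "solution", "liquid", r,
          generate_sample_eem(sc, noise, grid, r, "liquid", components,
                              extract_scale =
                                sc$extraction_efficiency * jitter),
          generate_od(sc$extraction_efficiency * jitter * .od_load0 *
                        sc$realized_fold,
                      substrate_model("solution"), noise,
                      sample_id = lid, replicate = r))
    }
  }
  truth <- do.call(rbind, lapply(scenarios, function(sc) data.frame(
    sample_id = sc$condition, a_cell = sc$a_cell,
    a_complex = sc$a_complex,
    target_fold = if (is.null(sc$target_fold)) NA_real_ else sc$target_fold,
    realized_fold = sc$realized_fold,
    attenuation = sc$substrate$fluor_attenuation,
    extraction_efficiency = sc$extraction_efficiency,
    stringsAsFactors = FALSE)))
  rownames(truth) <- NULL
  out <- structure(list(manifest = do.call(rbind, rows), eems = eems,
                        ods = ods, truth = truth, grid = grid),
                   class = "ars_experiment")
  if (!is.null(dir)) write_experiment(out, dir)
  out
}

#' @export
print.ars_experiment <- function(x, ...) {
  m <- x$manifest[x$manifest$condition != "blank", ]
  cat(sprintf("ARS experiment: %d conditions x %d replicates, %d spectra\n",
              length(unique(m$condition)),
              max(m$replicate), nrow(x$manifest)))
  print(table(condition = m$condition, mode = m$mode))
  invisible(x)
}

#' Write / load an experiment directory
#'
#' Layout: `manifest.csv`, `ground_truth.csv`, and one long-format EEM CSV
#' plus one OD CSV per measurement under `spectra/`.
#'
#' @param exp an `ars_experiment`.
#' @param dir target directory (created if absent).
#' @return `write_experiment()` returns `dir` invisibly; `load_experiment()`
#'   returns the reconstructed `ars_experiment`.
#' @export
write_experiment <- function(exp, dir) {
  stopifnot(inherits(exp, "ars_experiment"))
  dir.create(file.path(dir, "spectra"), recursive = TRUE,
             showWarnings = FALSE)
  man <- exp$manifest
  for (i in seq_len(nrow(man))) {
    id <- man$sample_id[i]
    man$eem_path[i] <- file.path("spectra", paste0(id, "_eem.csv"))
    man$od_path[i] <- file.path("spectra", paste0(id, "_od.csv"))
    write_eem_csv(exp$eems[[id]], file.path(dir, man$eem_path[i]))
    write_od_csv(exp$ods[[id]], file.path(dir, man$od_path[i]))
  }
  write_manifest(man, file.path(dir, "manifest.csv"))
  utils::write.csv(exp$truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_experiment
#' @param manifest_path path to a manifest CSV; spectra paths are resolved
#'   relative to its directory.
#' @export
load_experiment <- function(manifest_path) {
  if (dir.exists(manifest_path))
    manifest_path <- file.path(manifest_path, "manifest.csv")
  if (!file.exists(manifest_path))
    .user_error(sprintf("manifest not found: %s", manifest_path),
                "osteem_io_error")
  root <- dirname(manifest_path)
  man <- read_manifest(manifest_path)
  eems <- list(); ods <- list(); grid <- NULL
  for (i in seq_len(nrow(man))) {
    id <- man$sample_id[i]
    meta <- sample_meta(id, man$condition[i], man$substrate[i], man$mode[i],
                        max(man$replicate[i], 1),
                        if (is.na(man$concentration_mM[i])) NULL
                        else man$concentration_mM[i])
    if (!is.na(man$eem_path[i]) && nzchar(man$eem_path[i])) {
      eems[[id]] <- read_eem_csv(file.path(root, man$eem_path[i]), meta)
      grid <- eems[[id]]$grid
    }
    if (!is.na(man$od_path[i]) && nzchar(man$od_path[i]))
      ods[[id]] <- read_od_csv(file.path(root, man$od_path[i]), meta)
  }
  truth_path <- file.path(root, "ground_truth.csv")
  truth <- if (file.exists(truth_path))
    utils::read.csv(truth_path, stringsAsFactors = FALSE) else NULL
  structure(list(manifest = man, eems = eems, ods = ods, truth = truth,
                 grid = grid), class = "ars_experiment")
}

#' Write / read a dilution series directory
#'
#' Layout: `series.csv` (concentration_mM, eem_path, od_path) plus the
#' member spectra.
#'
#' @param series a [dilution_series()].
#' @param dir target directory.
#' @export
write_dilution_series <- function(series, dir) {
  stopifnot(inherits(series, "dilution_series"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(series$concentrations_mM), function(i) {
    conc <- series$concentrations_mM[i]
    ep <- sprintf("ars_%03d_eem.csv", i)
    op <- sprintf("ars_%03d_od.csv", i)
    write_eem_csv(series$samples[[i]]$eem, file.path(dir, ep))
    write_od_csv(series$samples[[i]]$od, file.path(dir, op))
    data.frame(concentration_mM = conc, eem_path = ep, od_path = op,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), file.path(dir, "series.csv"),
                   row.names = FALSE)
  if (!is.null(series$blank_od))
    write_od_csv(series$blank_od, file.path(dir, "blank_od.csv"))
  invisible(dir)
}

#' @rdname write_dilution_series
#' @export
read_dilution_series <- function(dir) {
  sp <- file.path(dir, "series.csv")
  if (!file.exists(sp))
    .user_error(sprintf("no series.csv under %s", dir), "osteem_io_error")
  df <- utils::read.csv(sp, stringsAsFactors = FALSE)
  samples <- lapply(seq_len(nrow(df)), function(i) {
    meta <- sample_meta(sprintf("ars_%g", df$concentration_mM[i]),
                        "free_ars", "solution", "liquid",
                        concentration_mM = df$concentration_mM[i])
    list(eem = read_eem_csv(file.path(dir, df$eem_path[i]), meta),
         od = read_od_csv(file.path(dir, df$od_path[i]), meta))
  })
  bp <- file.path(dir, "blank_od.csv")
  dilution_series(df$concentration_mM, samples,
                  blank_od = if (file.exists(bp)) read_od_csv(bp) else NULL)
}
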