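# seeded generator: components, noise, substrates, amplitude solving,
# dilution series, full experiments

test_that("component surfaces are unit-amplitude product Gaussians", {
  g <- default_grid()
  comps <- default_components()
  cplx <- component_eem(comps$complex, g)
  # apex (430, 670) is on-grid and valid
  expect_equal(get_intensity(cplx, 430, 670), 1)
  # emission symmetry about the centre
  expect_equal(get_intensity(cplx, 430, 660), get_intensity(cplx, 430, 680))
  # closed form at the index wavelengths for an em 670/45 band
  c45 <- component_eem(component_spectrum("complex", 670, 45, 430, 60), g)
  expect_equal(get_intensity(c45, 420, 560),
               exp(-110^2 / (2 * 45^2)) * exp(-10^2 / (2 * 60^2)),
               tolerance = 1e-12)
  expect_equal(exp(-110^2 / (2 * 45^2)), 0.0504, tolerance = 1e-3)
  expect_error(component_spectrum("complex", 670, -1, 430, 60),
               class = "osteem_parameter_error")
})

test_that("a zero-complex scenario is exactly the cellular component", {
  g <- default_grid()
  sc <- scenario_config("control", "glass", a_complex = 0, target_fold = 1)
  e <- generate_sample_eem(sc, noise_off(), g)
  cell <- component_eem(default_components()$cellular, g)
  expect_cells_equal(e, cell, tol = 1e-12)
})

test_that("identical seeds reproduce identical samples, different seeds differ", {
  g <- default_grid()
  sc <- osteem:::.resolve_scenario(
    scenario_config("om_7d", "glass", target_fold = 2), g)
  a <- generate_sample_eem(sc, noise_model(seed = 5), g, replicate = 2)
  b <- generate_sample_eem(sc, noise_model(seed = 5), g, replicate = 2)
  expect_identical(a$intensity, b$intensity)
  c_ <- generate_sample_eem(sc, noise_model(seed = 6), g, replicate = 2)
  expect_false(identical(a$intensity, c_$intensity))
  # replicate number keys its own stream
  d <- generate_sample_eem(sc, noise_model(seed = 5), g, replicate = 3)
  expect_false(identical(a$intensity, d$intensity))
})

test_that("graphene oxide attenuates fluorescence by a scalar the index ignores", {
  g <- default_grid()
  on_go <- osteem:::.resolve_scenario(
    scenario_config("go_7d", "go", target_fold = 2.7), g)
  on_glass <- on_go
  on_glass$substrate <- substrate_model("glass")
  ego <- generate_sample_eem(on_go, noise_off(), g)
  egl <- generate_sample_eem(on_glass, noise_off(), g)
  expect_cells_equal(eem(ego$intensity / 0.6, g, mask = ego$mask), egl,
                     tol = 1e-12)
  expect_equal(ratio_index(ego)$value, ratio_index(egl)$value,
               tolerance = 1e-12)
})

test_that("OD spectra: flat blank baseline, linearity in load", {
  blank <- generate_od(0, "glass", noise_off())
  expect_true(all(blank$od == 0.02))
  one <- generate_od(1, "glass", noise_off())
  two <- generate_od(2, "glass", noise_off())
  b515 <- function(od) od$od[od$wavelength_nm == 515] - 0.02
  expect_equal(b515(two), 2 * b515(one), tolerance = 1e-12)
  expect_equal(b515(one), 0.3, tolerance = 1e-12)   # k_od per mM
  expect_error(generate_od(-1, "glass"), class = "osteem_parameter_error")
})

test_that("free-dye dilution series scale rigidly and stay saddle-free", {
  ser <- generate_dilution_series(c(0.25, 1, 4), noise_off())
  expect_equal(shape_invariance_score(ser$samples[[1]]$eem,
                                      lapply(ser$samples[-1], `[[`, "eem")),
               0, tolerance = 1e-12)
  f670 <- vapply(ser$samples, function(s) get_intensity(s$eem, 420, 670),
                 numeric(1))
  expect_equal(f670[3] / f670[1], 16, tolerance = 1e-12)
  for (s in ser$samples) expect_null(detect_saddle(s$eem))
  expect_error(generate_dilution_series(c(0, 1), noise_off()),
               class = "osteem_parameter_error")
  # default ladder spans the assay's stated range
  expect_equal(range(default_dilution_ladder()), c(0.00125, 4))
  expect_length(default_dilution_ladder(), 12)
})

test_that("solve_complex_amplitude realizes index folds exactly", {
  g <- default_grid()
  expect_equal(solve_complex_amplitude(1, grid = g), 0)
  expect_error(solve_complex_amplitude(0.5, grid = g),
               class = "osteem_parameter_error")
  idx <- function(a) ratio_index(two_component_eem(a))$value
  base <- idx(0)
  for (fold in c(2.7, 3.5)) {
    a <- solve_complex_amplitude(fold, grid = g)
    expect_equal(idx(a) / base, fold, tolerance = 1e-6)
    # dense grid-search oracle agrees to 4 significant digits
    cand <- seq(0.9 * a, 1.1 * a, length.out = 20001)
    vals <- abs(vapply(cand, idx, numeric(1)) - fold * base)
    expect_equal(cand[which.min(vals)], a, tolerance = 1e-4)
  }
})

test_that("the mineralized surface places its emission minimum near 560 nm", {
  # brute-force scan of the noiseless om_7d profile at 420 nm excitation
  g <- default_grid()
  a <- solve_complex_amplitude(2, grid = g)
  e <- two_component_eem(a)
  i <- match(420, g$excitation_nm)
  keep <- e$mask[i, ]
  em <- g$emission_nm[keep]
  p <- e$intensity[i, keep]
  interior_min <- which(diff(sign(diff(p))) > 0) + 1
  expect_length(interior_min, 1)
  expect_lte(abs(em[interior_min] - 560), 10)
  # and no minimum at all without the complex band
  p0 <- two_component_eem(0)$intensity[i, keep]
  expect_length(which(diff(sign(diff(p0))) > 0), 0)
})

test_that("experiments have full factorial structure and byte-determinism", {
  noise <- noise_model(seed = 9)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  ex <- generate_experiment(noise = noise, dir = d1)
  generate_experiment(noise = noise, dir = d2)
  man <- ex$manifest[ex$manifest$condition != "blank", ]
  # 5 scenarios x 3 replicates x 2 modes, each with an EEM and an OD
  expect_equal(nrow(man), 30)
  expect_equal(length(ex$eems) + length(ex$ods), 2 * (30 + 3))
  expect_setequal(
    ex$manifest$sample_id[ex$manifest$condition == "blank"],
    c("blank_glass", "blank_go", "blank_solution"))
  # ground truth records the generative parameters
  expect_setequal(ex$truth$sample_id,
                  c("control", "om_7d", "om_14d", "go_7d", "go_om_7d"))
  expect_equal(ex$truth$realized_fold[ex$truth$sample_id == "go_7d"], 2.7,
               tolerance = 1e-6)
  # byte-identical files per seed
  f1 <- list.files(d1, recursive = TRUE)
  expect_setequal(f1, list.files(d2, recursive = TRUE))
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  expect_error(generate_experiment(default_scenarios()["om_7d"], noise),
               class = "osteem_specification_error")
})

test_that("control extracts carry no complex band and fold 1", {
  ex <- generate_experiment(noise = noise_off())
  liq <- ex$eems[["control_r1_liquid"]]
  expect_equal(classify_spectrum(liq)$classification,
               "undifferentiated_single_peak")
  mc <- quantify_four_methods(ex, "control")
  expect_true(all(abs(unlist(mc$per_method) - 1) < 1e-9))
})

test_that("experiment directories round-trip through the manifest", {
  d <- withr::local_tempdir()
  ex <- generate_experiment(noise = noise_model(seed = 4), dir = d)
  back <- load_experiment(d)
  expect_setequal(back$manifest$sample_id, ex$manifest$sample_id)
  id <- "om_14d_r2_surface"
  expect_identical(back$eems[[id]]$intensity[back$eems[[id]]$mask],
                   ex$eems[[id]]$intensity[ex$eems[[id]]$mask])
  expect_equal(back$ods[[id]]$od, ex$ods[[id]]$od)
  # and quantification gives identical folds from disk
  expect_equal(quantify_four_methods(back, "om_14d")$per_method,
               quantify_four_methods(ex, "om_14d")$per_method,
               tolerance = 1e-12)
})
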