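# EEM/OD containers, CSV interchange, background subtraction, lookup

test_that("wavelength grids reject non-increasing or ragged axes", {
  expect_error(wavelength_grid(c(400, 400, 420), seq(440, 700, 10)),
               "strictly increasing")
  expect_error(wavelength_grid(c(400, 410, 430), seq(440, 700, 10)),
               "uniform")
  g <- default_grid()
  expect_equal(g$step_nm, 10)
  expect_equal(range(g$excitation_nm), c(400, 580))
  expect_equal(range(g$emission_nm), c(440, 700))
})

test_that("the EEM mask is exactly the emission >= excitation + 40 half plane", {
  g <- default_grid()
  e <- eem_from_fun(function(x, m) 1 + 0 * x, g)
  expect_equal(e$mask, outer(g$excitation_nm, g$emission_nm,
                             function(x, m) m >= x + 40))
  # masked cells are never stored
  expect_true(all(is.na(e$intensity[!e$mask])))
  # negative intensity in the valid region is rejected
  bad <- e$intensity
  bad[e$mask][1] <- -1
  expect_error(eem(bad, g), "negative")
})

test_that("EEM long CSV round-trips every valid cell exactly", {
  set.seed(7)
  g <- default_grid()
  e <- eem_from_fun(function(x, m) exp(-(m - 600)^2 / 5000) * (x / 400), g)
  # perturb to full double precision
  e$intensity[e$mask] <- e$intensity[e$mask] * (1 + runif(sum(e$mask)) * 1e-9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_eem_csv(e, path)
  back <- read_eem_csv(path, meta = sample_meta("s1"))
  expect_identical(back$mask, e$mask)
  expect_identical(back$intensity[back$mask], e$intensity[e$mask])
  expect_equal(back$meta$sample_id, "s1")
})

test_that("only valid cells are emitted, sorted by excitation then emission", {
  g <- wavelength_grid(c(500, 510), c(550, 560))
  m <- matrix(1:4, 2, 2)
  restricted <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)
  e <- eem(ifelse(restricted, m, NA), g, mask = restricted)
  path <- withr::local_tempfile(fileext = ".csv")
  write_eem_csv(e, path)
  lines <- readLines(path)
  expect_length(lines, 3)  # header + 2 valid cells
  expect_equal(lines[2], "500,550,1")
  expect_equal(lines[3], "500,560,3")
})

test_that("EEM CSV parsing flags format and validity violations", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("excitation_nm,emission_nm,count", "420,670,1"), p)
  expect_error(read_eem_csv(p), "missing header")
  writeLines(c("excitation_nm,emission_nm,intensity",
               "420,660,1", "420,670,2", "430,660,3", "430,670,4",
               "420,670,9"), p)
  expect_error(read_eem_csv(p), "duplicate.*row 5")
  writeLines(c("excitation_nm,emission_nm,intensity",
               "420,660,1", "420,670,-2", "430,660,3", "430,670,4"), p)
  expect_error(read_eem_csv(p), "negative")
  writeLines(c("excitation_nm,emission_nm,intensity",
               "420,660,1", "420,670,2", "445,660,3", "445,670,4"), p)
  expect_error(read_eem_csv(p), "ragged")
  writeLines(c("excitation_nm,emission_nm,intensity",
               "500,520,1", "500,530,2", "510,520,3", "510,530,4"), p)
  expect_error(read_eem_csv(p), "scatter mask")
  # a straight parse lands values on the right cells
  writeLines(c("excitation_nm,emission_nm,intensity",
               "420,660,1", "420,670,100.0", "430,660,3", "430,670,4"), p)
  e <- read_eem_csv(p)
  expect_equal(get_intensity(e, 420, 670), 100)
})

test_that("wide CSV export leaves masked cells empty", {
  g <- wavelength_grid(c(500, 510, 520), c(540, 550, 560))
  e <- eem_from_fun(function(x, m) x + m, g)
  path <- withr::local_tempfile(fileext = ".csv")
  write_eem_wide(e, path)
  lines <- readLines(path)
  expect_equal(lines[1], "excitation_nm,540,550,560")
  expect_match(lines[4], "^520,,,1080$")  # only em 560 valid at exc 520
})

test_that("OD spectra round-trip and reject invalid input", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavelength_nm,od", "515,0.8", "520,0.7"), p)
  od <- read_od_csv(p)
  expect_length(od$od, 2)
  write_od_csv(od, p)
  expect_equal(read_od_csv(p)$od, c(0.8, 0.7))
  writeLines(c("wavelength_nm,od", "515,-0.1", "520,0.7"), p)
  expect_error(read_od_csv(p), "negative OD")
  writeLines(c("wavelength_nm,od", "520,0.1", "515,0.7"), p)
  expect_error(read_od_csv(p), "increasing")
})

test_that("background subtraction is cellwise, clipped at zero, grid-checked", {
  g <- default_grid()
  s <- eem_from_fun(function(x, m) 10 + 0 * x, g)
  b <- eem_from_fun(function(x, m) 3 + 0 * x, g)
  d <- subtract_background(s, b)
  expect_true(all(d$intensity[d$mask] == 7))
  expect_identical(d$mask, s$mask)
  # clipping: blank exceeds sample
  d2 <- subtract_background(b, s)
  expect_true(all(d2$intensity[d2$mask] == 0))
  # self-subtraction gives zero; subtracting a zero blank is the identity
  expect_true(all(subtract_background(s, s)$intensity[s$mask] == 0))
  zero <- eem_from_fun(function(x, m) 0 * x, g)
  expect_cells_equal(subtract_background(s, zero), s)
  expect_error(subtract_background(s, eem_from_fun(function(x, m) 1 + 0 * x,
                                                   full_grid())),
               "share grid")
})

test_that("intensity lookup is exact on nodes, bilinear between them", {
  g <- default_grid()
  e <- eem_from_fun(function(x, m) 0 * x, g)
  i <- match(420, g$excitation_nm)
  e$intensity[i, match(660, g$emission_nm)] <- 10
  e$intensity[i, match(670, g$emission_nm)] <- 20
  expect_equal(get_intensity(e, 420, 670), 20)
  expect_equal(get_intensity(e, 420, 665), 15)
  expect_error(get_intensity(e, 500, 520), class = "osteem_domain_error")
  expect_error(get_intensity(e, 420, 710), class = "osteem_domain_error")
})

test_that("interpolation is continuous along a line through the surface", {
  e <- two_component_eem(1)
  em <- seq(470, 695, by = 2.5)
  vals <- get_intensity(e, rep(420, length(em)), em)
  # piecewise-linear: no jump exceeds the local cell-to-cell variation
  expect_lt(max(abs(diff(vals))), 0.05)
  # and node queries reproduce stored cells
  ems <- seq(470, 690, 10)
  stored <- e$intensity[match(420, e$grid$excitation_nm),
                        match(ems, e$grid$emission_nm)]
  expect_equal(get_intensity(e, rep(420, length(ems)), ems), stored)
})

test_that("manifest CSVs round-trip with empty fields allowed", {
  man <- data.frame(sample_id = c("a", "b"), condition = c("control", "blank"),
                    substrate = c("glass", "glass"),
                    mode = c("surface", "surface"), replicate = c(1L, 1L),
                    concentration_mM = c(NA, NA),
                    eem_path = c("a.csv", ""), od_path = c("", "b_od.csv"),
                    stringsAsFactors = FALSE)
  p <- withr::local_tempfile(fileext = ".csv")
  write_manifest(man, p)
  back <- read_manifest(p)
  expect_equal(back$sample_id, man$sample_id)
  expect_true(all(is.na(back$concentration_mM)))
})

test_that("sample metadata enforces the condition contracts", {
  expect_error(sample_meta("x", "free_ars", "solution", "liquid"),
               "concentration")
  expect_error(sample_meta("x", "blank", concentration_mM = 1),
               "blank")
  m <- sample_meta("x", "free_ars", "solution", "liquid",
                   concentration_mM = 0.25)
  expect_equal(m$concentration_mM, 0.25)
})
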