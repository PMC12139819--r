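test_that("ESRI ASCII grids round-trip exactly", {
  m <- matrix(c(1.5, -2.25, NA, 4, 5.125, -16.5), nrow = 2, byrow = TRUE)
  g <- climate_grid(m, xllcorner = -120.5, yllcorner = 48.25,
                    cellsize = 0.25, nodata = -9999,
                    crs = "GEOGCS[\"WGS 84\"]")
  f <- withr::local_tempfile(fileext = ".asc")
  write_climate_grid(g, f)
  g2 <- read_climate_grid(f)
  expect_equal(g2$mcmt, g$mcmt)
  expect_equal(g2$xllcorner, g$xllcorner)
  expect_equal(g2$yllcorner, g$yllcorner)
  expect_equal(g2$cellsize, g$cellsize)
  expect_equal(g2$nodata, g$nodata)
  expect_equal(g2$crs, g$crs)   # via the sidecar .prj
})

test_that("malformed rasters are rejected", {
  f <- withr::local_tempfile(fileext = ".tif")
  writeBin(as.raw(c(0x49, 0x49, 0x2a, 0x00, 0x08)), f)
  expect_error(read_climate_grid(f), "TIFF")
  f2 <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 2", "1 2 3 4"), f2)
  expect_error(read_climate_grid(f2), "cellsize|xllcorner")
  f3 <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize 1", "1 2 3"), f3)
  expect_error(read_climate_grid(f3), "expected 4")
  expect_error(climate_grid(matrix(-9999, 1, 1)), "sentinel")
})

two_genotype_setup <- function() {
  # overall fitness curves crossing once: genotype A (cold-adapted, lower
  # peak growth, better cold survival) vs B (warm-adapted)
  fit <- make_fake_fit(
    c("(Intercept)" = 1.2, gmt = 0.04, gmt2 = -0.006, pc1 = 0.25,
      "pc1:gmt" = 0.08),
    c("(Intercept)" = -2, gmt2 = 0.01))
  genotypes <- data.frame(genotype_id = c("A", "B"),
                          home_mcmt = c(-18, -6),
                          pc1 = c(-1, 1), pc2 = 0, pc3 = 0,
                          ancestry_q = c(0.1, 0.9))
  list(fit = fit, genotypes = genotypes)
}

test_that("a single genotype wins every unmasked cell", {
  s <- two_genotype_setup()
  m <- matrix(seq(-20, 12, length.out = 25), 5)
  g <- climate_grid(m)
  bm <- project_best_genotype(s$fit, s$genotypes[1, ], g,
                              mask_bounds = c(-16.5, 9.8))
  inside <- !bm$masked
  expect_true(all(bm$best_genotype_index[inside] == 1))
  expect_true(all(bm$best_ancestry_q[inside] == 0.1))
  expect_true(all(is.na(bm$best_genotype_index[!inside])))
})

test_that("the argmax map equals per-cell brute force with exact masking", {
  s <- two_genotype_setup()
  set.seed(8)
  m <- matrix(runif(50 * 50, -22, 12), 50)
  m[sample(2500, 30)] <- NA
  g <- climate_grid(m)
  bounds <- c(-16.5, 9.8)
  bm <- project_best_genotype(s$fit, s$genotypes, g, mask_bounds = bounds)
  # brute force: loop over cells, predict both genotypes directly
  tq <- round(m * 100) / 100
  for (idx in sample(2500, 400)) {
    t_cell <- tq[idx]
    if (is.na(t_cell) || t_cell < bounds[1] || t_cell > bounds[2]) {
      expect_true(bm$masked[idx])
      expect_true(is.na(bm$best_genotype_index[idx]))
    } else {
      nd <- data.frame(garden_mcmt = t_cell,
                       home_mcmt = s$genotypes$home_mcmt,
                       pc1 = s$genotypes$pc1, pc2 = 0, pc3 = 0)
      fitv <- predict_components(s$fit, nd)$overall
      expect_equal(bm$best_genotype_index[idx], which.max(fitv))
    }
  }
  # the masked set is exactly the out-of-range-or-missing set
  expect_identical(bm$masked,
                   is.na(tq) | tq < bounds[1] | tq > bounds[2])
})

test_that("widening mask bounds never masks a previously unmasked cell", {
  s <- two_genotype_setup()
  m <- matrix(seq(-25, 15, length.out = 36), 6)
  g <- climate_grid(m)
  narrow <- project_best_genotype(s$fit, s$genotypes, g,
                                  mask_bounds = c(-14, 8))
  wide <- project_best_genotype(s$fit, s$genotypes, g,
                                mask_bounds = c(-18, 11))
  expect_true(all(!wide$masked[!narrow$masked]))
})

test_that("shift summaries count switched cells and translate correctly", {
  s <- two_genotype_setup()
  # locate the crossing point of the two overall curves on a fine grid
  tgrid <- seq(-16.5, 9.8, by = 0.01)
  nd <- function(gn) data.frame(garden_mcmt = tgrid,
                                home_mcmt = gn$home_mcmt, pc1 = gn$pc1,
                                pc2 = 0, pc3 = 0)
  fA <- predict_components(s$fit, nd(s$genotypes[1, ]))$overall
  fB <- predict_components(s$fit, nd(s$genotypes[2, ]))$overall
  cross <- tgrid[which(diff(sign(fA - fB)) != 0)[1]]
  expect_true(is.finite(cross))

  m <- matrix(seq(-16, 4, length.out = 100), 10)
  hist_grid <- climate_grid(m)
  fut_grid <- climate_grid(m + 5)
  bmh <- project_best_genotype(s$fit, s$genotypes, hist_grid)
  bmf <- project_best_genotype(s$fit, s$genotypes, fut_grid)
  expect_equal(shift_summary(bmh, bmh)$switched_fraction, 0)
  sh <- shift_summary(bmh, bmf)
  # cells switching are exactly those crossing t* under the +5 C shift
  comparable <- !bmh$masked & !bmf$masked
  manual <- (m < cross) & (m + 5 >= cross)
  expect_equal(sh$switched[comparable], manual[comparable])
  expect_equal(sh$switched_fraction, mean(manual[comparable]))
  # mismatched grids are refused
  small <- project_best_genotype(s$fit, s$genotypes,
                                 climate_grid(m[1:5, ]))
  expect_error(shift_summary(bmh, small), "shapes")
})

test_that("best-genotype maps write as ASCII layers", {
  s <- two_genotype_setup()
  m <- matrix(seq(-15, 8, length.out = 16), 4)
  bm <- project_best_genotype(s$fit, s$genotypes, climate_grid(m))
  stem <- file.path(withr::local_tempdir(), "map")
  files <- write_best_genotype_map(bm, stem)
  expect_true(all(file.exists(files)))
  back <- read_climate_grid(files[1])
  expect_equal(back$mcmt, bm$best_ancestry_q)
})
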