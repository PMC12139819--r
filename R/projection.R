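#' Climate grid container
#'
#' A single-band raster of mean coldest month temperature (MCMT) with the
#' minimal geospatial metadata of the ESRI ASCII grid format: lower-left
#' corner, square cell size and a missing-value sentinel. Cell (row 1,
#' col 1) is the map's top-left cell, following the on-disk row order.
#'
#' @param mcmt numeric matrix of MCMT values, degrees C; `NA` for missing.
#' @param xllcorner,yllcorner coordinates of the lower-left corner.
#' @param cellsize cell edge length (map units).
#' @param nodata sentinel written for missing cells on output.
#' @param crs free-text coordinate reference identifier (optional).
#' @return a `climate_grid` object.
#' @export
climate_grid <- function(mcmt, xllcorner = 0, yllcorner = 0, cellsize = 1,
                         nodata = -9999, crs = NA_character_) {
  mcmt <- as.matrix(mcmt)
  if (any(is.finite(mcmt) & mcmt == nodata))
    stop("nodata sentinel collides with a valid MCMT value")
  stopifnot(cellsize > 0)
  structure(list(mcmt = mcmt, xllcorner = xllcorner, yllcorner = yllcorner,
                 cellsize = cellsize, nodata = nodata, crs = crs),
            class = "climate_grid")
}

#' Read a climate raster from an ESRI ASCII grid file
#'
#' Parses the plain-text ESRI ASCII grid format (`ncols`/`nrows` header,
#' optional `nodata_value`, whitespace-separated rows from the top of the
#' map down). GeoTIFF input is not supported; convert to ASCII grid
#' upstream (e.g. `gdal_translate -of AAIGrid`).
#'
#' @param path file path; an accompanying `.prj` file, if present, is read
#'   into the `crs` field.
#' @return a `climate_grid`.
#' @export
read_climate_grid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  head_bytes <- readBin(path, "raw", n = 4L)
  if (length(head_bytes) >= 4L &&
      (identical(head_bytes[1:2], as.raw(c(0x49, 0x49))) ||
       identical(head_bytes[1:2], as.raw(c(0x4d, 0x4d)))))
    stop("file looks like a TIFF; only ESRI ASCII grids are supported")
  lines <- readLines(path, warn = FALSE)
  hdr <- list(); i <- 1L
  repeat {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) != 2L || is.na(suppressWarnings(as.numeric(tok[2]))))
      break
    hdr[[tolower(tok[1])]] <- as.numeric(tok[2])
    i <- i + 1L
    if (i > length(lines)) break
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("not an ESRI ASCII grid: header must define ",
         paste(need, collapse = ", "))
  if (!any(c("xllcorner", "xllcenter") %in% names(hdr)))
    stop("not an ESRI ASCII grid: missing xllcorner/xllcenter")
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nc <- hdr$ncols; nr <- hdr$nrows
  if (length(vals) != nc * nr)
    stop("grid body has ", length(vals), " values; expected ", nc * nr)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else
    hdr$xllcenter - hdr$cellsize / 2
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else
    hdr$yllcenter - hdr$cellsize / 2
  prj <- paste0(sub("\\.[^.]*$", "", path), ".prj")
  crs <- if (file.exists(prj)) paste(readLines(prj, warn = FALSE),
                                     collapse = " ") else NA_character_
  climate_grid(m, xll, yll, hdr$cellsize, nodata, crs)
}

#' Write a climate grid (or map layer) as an ESRI ASCII grid
#'
#' @param grid a `climate_grid`, or any object with the same fields.
#' @param path output path.
#' @param layer matrix to write; defaults to `grid$mcmt`.
#' @param digits significant digits for formatting.
#' @return `path`, invisibly.
#' @export
write_climate_grid <- function(grid, path, layer = grid$mcmt, digits = 15) {
  m <- as.matrix(layer)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(m)), paste("nrows", nrow(m)),
               paste("xllcorner", format(grid$xllcorner, digits = digits)),
               paste("yllcorner", format(grid$yllcorner, digits = digits)),
               paste("cellsize", format(grid$cellsize, digits = digits)),
               paste("nodata_value", format(grid$nodata, digits = digits))),
             con)
  body <- apply(m, 1, function(r) {
    r[!is.finite(r)] <- grid$nodata
    paste(format(r, digits = digits, trim = TRUE, scientific = FALSE),
          collapse = " ")
  })
  writeLines(body, con)
  if (!is.na(grid$crs))
    writeLines(grid$crs, paste0(sub("\\.[^.]*$", "", path), ".prj"))
  invisible(path)
}

#' Map the best-performing genotype across a climate raster
#'
#' For every raster cell whose MCMT lies inside `mask_bounds`, predicts the
#' overall fitness proxy (survival times growth) of every genotype at a
#' garden MCMT equal to the cell's value — each genotype keeps its own home
#' climate and genomic PCs, random effects are zero — and records the
#' genotype with the highest fitness together with its species-ancestry
#' proportion. Cells outside the bounds (where the model would
#' extrapolate beyond the climates sampled by the gardens) or with missing
#' MCMT are masked. Cell values are quantized to 0.01 degrees C before
#' prediction, so identical quantized temperatures give identical
#' assignments; argmax ties break toward the lowest genotype index.
#'
#' @param fit a `fitted_zig`.
#' @param genotypes data frame of genotype records (`genotype_id`,
#'   `home_mcmt`, `pc1`..`pc3`, `ancestry_q`).
#' @param grid a `climate_grid`.
#' @param mask_bounds length-2 numeric, degrees C; defaults to the garden
#'   MCMT range of the motivating trials (-16.5 to 9.8).
#' @param transform growth back-transform, see [predict_components()].
#' @return a `best_genotype_map`: matrices `best_genotype_index`,
#'   `best_ancestry_q`, logical `masked`, the genotype id lookup, grid
#'   metadata and a provenance label.
#' @export
project_best_genotype <- function(fit, genotypes, grid,
                                  mask_bounds = c(-16.5, 9.8),
                                  transform = "naive") {
  stopifnot(inherits(fit, "fitted_zig"), inherits(grid, "climate_grid"))
  if (nrow(genotypes) < 1L) stop("empty genotype collection")
  if (mask_bounds[1] >= mask_bounds[2]) stop("mask_bounds must be ordered")
  tq <- round(grid$mcmt * 100) / 100
  masked <- is.na(tq) | tq < mask_bounds[1] | tq > mask_bounds[2]
  uniq <- sort(unique(as.vector(tq[!masked])))
  best_idx <- matrix(NA_integer_, nrow(tq), ncol(tq))
  best_q <- matrix(NA_real_, nrow(tq), ncol(tq))
  if (length(uniq)) {
    ng <- nrow(genotypes)
    nd <- data.frame(
      garden_mcmt = rep(uniq, each = ng),
      home_mcmt = rep(genotypes$home_mcmt, times = length(uniq)),
      pc1 = rep(genotypes$pc1, times = length(uniq)),
      pc2 = rep(genotypes$pc2, times = length(uniq)),
      pc3 = rep(genotypes$pc3, times = length(uniq)))
    pr <- predict_components(fit, nd, transform = transform)
    fitness <- matrix(pr$overall, nrow = ng)     # genotypes x temperatures
    win <- apply(fitness, 2, which.max)          # first max = lowest index
    lookup <- match(as.vector(tq), uniq)
    ok <- !as.vector(masked) & !is.na(lookup)
    best_idx[ok] <- win[lookup[ok]]
    best_q[ok] <- genotypes$ancestry_q[best_idx[ok]]
  }
  structure(list(best_genotype_index = best_idx, best_ancestry_q = best_q,
                 masked = masked,
                 genotype_ids = as.character(genotypes$genotype_id),
                 xllcorner = grid$xllcorner, yllcorner = grid$yllcorner,
                 cellsize = grid$cellsize, nodata = grid$nodata,
                 crs = grid$crs, mask_bounds = mask_bounds,
                 provenance = sprintf("zignorm fit (n=%d), variant=%s",
                                      fit$n_obs, fit$spec$variant)),
            class = "best_genotype_map")
}

#' Summarize best-genotype changes between two climate scenarios
#'
#' @param historic,future `best_genotype_map` objects on the same grid with
#'   the same genotype set.
#' @return list with `delta_q` (future minus historic ancestry of the best
#'   genotype, per cell), `switched` (logical matrix), `switched_fraction`
#'   (over cells unmasked in both maps), `n_comparable`.
#' @export
shift_summary <- function(historic, future) {
  stopifnot(inherits(historic, "best_genotype_map"),
            inherits(future, "best_genotype_map"))
  if (!identical(dim(historic$masked), dim(future$masked)))
    stop("maps have different shapes")
  geo_h <- c(historic$xllcorner, historic$yllcorner, historic$cellsize)
  geo_f <- c(future$xllcorner, future$yllcorner, future$cellsize)
  if (!isTRUE(all.equal(geo_h, geo_f)) ||
      !identical(historic$crs, future$crs))
    stop("maps have different geotransform or CRS")
  if (!identical(historic$genotype_ids, future$genotype_ids))
    stop("maps were built from different genotype sets")
  comparable <- !historic$masked & !future$masked
  delta_q <- future$best_ancestry_q - historic$best_ancestry_q
  delta_q[!comparable] <- NA
  switched <- historic$best_genotype_index != future$best_genotype_index
  switched[!comparable] <- NA
  list(delta_q = delta_q, switched = switched,
       switched_fraction = if (any(comparable))
         mean(switched[comparable]) else NA_real_,
       n_comparable = sum(comparable))
}

#' Write a best-genotype map as ESRI ASCII grids plus a change table
#'
#' Writes `<stem>_ancestry.asc` (ancestry of the winning genotype) and
#' `<stem>_genotype.asc` (winning genotype index); metadata is copied from
#' the input grid unchanged.
#'
#' @param map a `best_genotype_map`.
#' @param stem output path stem.
#' @return character vector of the files written, invisibly.
#' @export
write_best_genotype_map <- function(map, stem) {
  fa <- paste0(stem, "_ancestry.asc")
  fg <- paste0(stem, "_genotype.asc")
  write_climate_grid(map, fa, layer = map$best_ancestry_q)
  gi <- map$best_genotype_index
  write_climate_grid(map, fg, layer = gi)
  invisible(c(fa, fg))
}
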