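#' Raster grid specification
#'
#' A light single- or multi-band raster: regular grid with origin at the
#' lower-left corner, square cells, band values stored as matrices whose
#' first row is the top of the grid (ESRI ASCII convention).
#'
#' @param xmin,ymin coordinates of the lower-left grid corner.
#' @param cellsize cell edge length (> 0).
#' @param nrow,ncol grid dimensions.
#' @param bands list of `nrow x ncol` matrices (default one band of NA).
#' @param nodata value written for missing cells (default -9999).
#' @return object of class `walnut_raster`.
#' @export
raster_grid <- function(xmin, ymin, cellsize, nrow, ncol,
                        bands = NULL, nodata = -9999) {
  stopifnot(cellsize > 0, nrow >= 1, ncol >= 1)
  if (is.null(bands))
    bands <- list(matrix(NA_real_, nrow, ncol))
  for (b in bands)
    if (!all(dim(b) == c(nrow, ncol)))
      stop("band dimensions disagree with the grid")
  structure(list(xmin = xmin, ymin = ymin, cellsize = cellsize,
                 nrow = nrow, ncol = ncol, bands = bands,
                 nodata = nodata),
            class = "walnut_raster")
}

# cell-centre coordinates; row 1 = top
cell_centres <- function(grid) {
  x <- grid$xmin + (seq_len(grid$ncol) - 0.5) * grid$cellsize
  ymax <- grid$ymin + grid$nrow * grid$cellsize
  y <- ymax - (seq_len(grid$nrow) - 0.5) * grid$cellsize
  list(x = x, y = y)
}

#' Inverse-distance-weighted interpolation surface
#'
#' z(cell) = sum(z_i d_i^-p) / sum(d_i^-p) over all sample points: a
#' convex combination of the point values, so the surface reproduces the
#' data at the data points and never leaves their range.
#'
#' @param points data.frame with columns `x`, `y`, `value`.
#' @param grid a [raster_grid()] defining the output surface.
#' @param power IDW exponent p (> 0; default 2).
#' @param great_circle if `TRUE`, distances are great-circle (km) with
#'   `x` = longitude and `y` = latitude in decimal degrees; otherwise
#'   planar Euclidean.
#' @return a one-band [raster_grid()].
#' @export
idw_surface <- function(points, grid, power = 2, great_circle = FALSE) {
  stopifnot(nrow(points) >= 1L, power > 0)
  dup <- duplicated(points[, c("x", "y")])
  if (any(dup)) {
    first <- match(interaction(points$x, points$y)[dup],
                   interaction(points$x, points$y))
    if (any(points$value[dup] != points$value[first]))
      stop("coincident points with different values")
    points <- points[!dup, ]
  }
  cc <- cell_centres(grid)
  vals <- matrix(NA_real_, grid$nrow, grid$ncol)
  eps <- 1e-9
  for (r in seq_len(grid$nrow)) {
    if (great_circle) {
      d <- t(vapply(seq_len(nrow(points)), function(i)
        great_circle_km(points$x[i], points$y[i], cc$x, cc$y[r]),
        numeric(grid$ncol)))
    } else {
      dx <- outer(points$x, cc$x, "-")
      d <- sqrt(dx^2 + (points$y - cc$y[r])^2)
    }
    w <- d^(-power)
    z <- as.numeric(crossprod(w, points$value) / colSums(w))
    hit <- apply(d < eps, 2L, which.max) * (colSums(d < eps) > 0)
    z[hit > 0] <- points$value[hit[hit > 0]]
    vals[r, ] <- z
  }
  raster_grid(grid$xmin, grid$ymin, grid$cellsize, grid$nrow, grid$ncol,
              bands = list(vals), nodata = grid$nodata)
}

great_circle_km <- function(lon1, lat1, lon2, lat2) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad; dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  6371 * 2 * asin(pmin(1, sqrt(a)))
}

#' Composite RGB map from cluster membership surfaces
#'
#' Each cluster receives a fixed colour; a cell's colour is the
#' Q-weighted sum of cluster colours, clipped to [0, 1] per channel.
#'
#' @param surfaces list of K one-band [raster_grid()] objects on a shared
#'   grid (membership proportions).
#' @param colors K x 3 matrix of RGB colours in [0, 1]; default a fixed
#'   palette.
#' @return a three-band [raster_grid()] (R, G, B).
#' @export
composite_map <- function(surfaces, colors = NULL) {
  K <- length(surfaces)
  g1 <- surfaces[[1L]]
  for (s in surfaces[-1L]) {
    if (!isTRUE(all.equal(c(s$xmin, s$ymin, s$cellsize, s$nrow, s$ncol),
                          c(g1$xmin, g1$ymin, g1$cellsize, g1$nrow,
                            g1$ncol))))
      stop("surfaces are not on a common grid")
  }
  if (is.null(colors)) {
    pal <- matrix(c(0.89, 0.10, 0.11,
                    0.22, 0.49, 0.72,
                    0.30, 0.69, 0.29,
                    1.00, 0.50, 0.00,
                    0.60, 0.31, 0.64,
                    1.00, 1.00, 0.20,
                    0.65, 0.34, 0.16,
                    0.97, 0.51, 0.75), ncol = 3L, byrow = TRUE)
    if (K > nrow(pal)) stop("default palette supports up to 8 clusters")
    colors <- pal[seq_len(K), , drop = FALSE]
  }
  rgb <- lapply(1:3, function(ch) {
    acc <- matrix(0, g1$nrow, g1$ncol)
    for (k in seq_len(K))
      acc <- acc + surfaces[[k]]$bands[[1L]] * colors[k, ch]
    pmin(pmax(acc, 0), 1)
  })
  raster_grid(g1$xmin, g1$ymin, g1$cellsize, g1$nrow, g1$ncol,
              bands = rgb, nodata = g1$nodata)
}

#' Write a raster as ESRI ASCII grid(s)
#'
#' One `.asc` file per band (`path`, or `path_b2.asc` etc. for multiband
#' rasters).
#'
#' @param raster a [raster_grid()].
#' @param path output path for the first band.
#' @return invisibly, the vector of files written.
#' @export
write_ascii_grid <- function(raster, path) {
  files <- character(0)
  for (b in seq_along(raster$bands)) {
    f <- if (b == 1L) path else
      sub("(\\.[^.]*)?$", paste0("_b", b, "\\1"), path)
    hdr <- c(paste("ncols", raster$ncol),
             paste("nrows", raster$nrow),
             paste("xllcorner", raster$xmin),
             paste("yllcorner", raster$ymin),
             paste("cellsize", raster$cellsize),
             paste("NODATA_value", raster$nodata))
    m <- raster$bands[[b]]
    m[is.na(m)] <- raster$nodata
    rows <- apply(m, 1L, function(r) paste(format(r, trim = TRUE),
                                           collapse = " "))
    writeLines(c(hdr, rows), f)
    files <- c(files, f)
  }
  invisible(files)
}
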