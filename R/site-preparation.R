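## Static per-cell model inputs derived from the landscape bundle: fertility
## from soil organic carbon, soil-water capacity from a DEM-derived
## topographic wetness index, the planting eligibility mask, and normalized
## wetness for the stratified planting rules.

#' Scale soil organic carbon to a fertility rating
#'
#' Piecewise-linear scaling: SOC at or below 40 t/ha maps to fertility 0.45,
#' at or above 200 t/ha to 1.0, linear in between; missing cells are filled
#' with 0.5 first, then a uniform mean smoothing filter (default 3 x 3) runs
#' over the grid, with edge cells averaging over their available neighbours.
#'
#' @param soc Numeric matrix of SOC (t C ha-1) with \code{NA} for missing
#'   cells.
#' @param smooth_window Odd window size of the mean filter; 1 disables
#'   smoothing.
#' @return Numeric matrix of fertility ratings in [0.45, 1] (0.5 where
#'   filled), smoothed.
#' @export
socToFertility <- function(soc, smooth_window = 3) {
  stopifnot(is.matrix(soc))
  if (any(soc < 0, na.rm = TRUE)) stop("SOC must be >= 0", call. = FALSE)
  if (smooth_window %% 2 != 1 || smooth_window < 1)
    stop("'smooth_window' must be a positive odd integer", call. = FALSE)
  fr <- 0.45 + (1 - 0.45) * pmin(pmax((soc - 40) / (200 - 40), 0), 1)
  fr[is.na(soc)] <- 0.5
  meanFilter(fr, smooth_window)
}

## Uniform mean filter with partial windows at the edges.
meanFilter <- function(m, w) {
  if (w == 1) return(m)
  h <- (w - 1) %/% 2
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  cnt <- matrix(0, nr, nc)
  for (di in -h:h) for (dj in -h:h) {
    ri <- max(1, 1 - di):min(nr, nr - di)
    rj <- max(1, 1 - dj):min(nc, nc - dj)
    out[ri, rj] <- out[ri, rj] + m[ri + di, rj + dj]
    cnt[ri, rj] <- cnt[ri, rj] + 1
  }
  out / cnt
}

#' Topographic wetness index from a DEM
#'
#' Slope by central differences (one-sided at edges), specific catchment
#' area by D8 steepest-descent flow accumulation times the cell size, and
#' TWI = ln(a / tan beta) with tan beta floored at 0.001 on flat cells.
#'
#' @param dem Elevation matrix (>= 3 x 3).
#' @param cellsize Cell edge length (m).
#' @return Numeric matrix of TWI values.
#' @export
computeTWI <- function(dem, cellsize = 100) {
  if (!is.matrix(dem) || nrow(dem) < 3 || ncol(dem) < 3)
    stop("'dem' must be a matrix with at least 3 x 3 cells", call. = FALSE)
  tanb <- pmax(slopeTan(dem, cellsize), 0.001)
  acc <- d8Accumulation(dem)               # cells drained, incl. self
  a <- acc * cellsize                      # specific catchment area, m
  log(a / tanb)
}

## tan(slope) by central differences; edges use one-sided differences.
slopeTan <- function(dem, cellsize) {
  nr <- nrow(dem); nc <- ncol(dem)
  ip <- c(2:nr, nr); im <- c(1, 1:(nr - 1))
  jp <- c(2:nc, nc); jm <- c(1, 1:(nc - 1))
  ddx <- cellsize * matrix(rep(ifelse(seq_len(nc) %in% c(1, nc), 1, 2),
                               each = nr), nr, nc)
  ddy <- cellsize * matrix(rep(ifelse(seq_len(nr) %in% c(1, nr), 1, 2),
                               nc), nr, nc)
  dzdx <- (dem[, jp] - dem[, jm]) / ddx
  dzdy <- (dem[ip, ] - dem[im, ]) / ddy
  sqrt(dzdx^2 + dzdy^2)
}

## D8 flow accumulation: every cell drains to its steepest-descent neighbour
## (drop per unit distance); pits keep what they receive. Returns the number
## of cells drained through each cell, including itself.
d8Accumulation <- function(dem) {
  nr <- nrow(dem); nc <- ncol(dem)
  n <- nr * nc
  acc <- rep(1, n)
  ord <- order(dem, decreasing = TRUE)
  di <- c(-1, -1, -1, 0, 0, 1, 1, 1)
  dj <- c(-1, 0, 1, -1, 1, -1, 0, 1)
  dist <- sqrt(di^2 + dj^2)
  for (idx in ord) {
    i <- (idx - 1) %% nr + 1
    j <- (idx - 1) %/% nr + 1
    best <- 0; bk <- 0L
    for (k in 1:8) {
      ii <- i + di[k]; jj <- j + dj[k]
      if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
      drop <- (dem[i, j] - dem[ii, jj]) / dist[k]
      if (drop > best) { best <- drop; bk <- k }
    }
    if (bk > 0L) {
      tgt <- (j + dj[bk] - 1) * nr + (i + di[bk])
      acc[tgt] <- acc[tgt] + acc[idx]
    }
  }
  matrix(acc, nr, nc)
}

#' Scale a TWI grid to maximum available soil water
#'
#' Monotone linear min-max rescale of TWI onto [100, 300] mm; a constant TWI
#' grid maps to the 200 mm midpoint.
#'
#' @param twi Numeric matrix of finite TWI values.
#' @return Numeric matrix of MASW (mm).
#' @export
twiToMASW <- function(twi) {
  if (any(!is.finite(twi))) stop("TWI values must be finite", call. = FALSE)
  m <- rescaleRange(twi, 100, 300)
  matrix(m, nrow(twi), ncol(twi))
}

#' Planting eligibility mask
#'
#' Eligible cells are shrubland or herbs that were never classified as
#' forest; water, snow/ice, bryoid and rock/rubble cells are always
#' ineligible.
#'
#' @param landcover Character matrix of landcover class names (or integer
#'   codes into \code{\link{landcoverLevels}}).
#' @param forest_history Logical matrix.
#' @return Logical matrix.
#' @export
eligibilityMask <- function(landcover, forest_history) {
  if (is.numeric(landcover)) {
    if (any(!landcover %in% seq_along(LANDCOVER_LEVELS)))
      stop("landcover codes outside the class vocabulary", call. = FALSE)
    landcover <- matrix(LANDCOVER_LEVELS[landcover], nrow(landcover))
  }
  if (!all(landcover %in% LANDCOVER_LEVELS))
    stop("unknown landcover class: ",
         paste(unique(setdiff(landcover, LANDCOVER_LEVELS)), collapse = ", "),
         call. = FALSE)
  if (!identical(dim(landcover), dim(forest_history)))
    stop("grids are not aligned", call. = FALSE)
  landcover %in% c("shrubland", "herbs") & !forest_history &
    !(landcover %in% NONVEGETATED_CLASSES)
}

#' Normalized wetness
#'
#' Min-max normalization of MASW to [0, 1] over the eligible cells (planting
#' decisions concern only eligible land); values for ineligible cells are
#' clamped into [0, 1]. A constant MASW grid maps to 0.5 everywhere.
#'
#' @param masw Numeric MASW matrix (mm).
#' @param eligible Logical matrix; default all cells.
#' @return Numeric matrix of normalized wetness in [0, 1].
#' @export
normalizedWetness <- function(masw, eligible = NULL) {
  stopifnot(is.matrix(masw), all(is.finite(masw)))
  if (is.null(eligible)) eligible <- matrix(TRUE, nrow(masw), ncol(masw))
  vals <- masw[eligible]
  if (!length(vals)) stop("no eligible cells to normalize over", call. = FALSE)
  r <- range(vals)
  nw <- if (r[1] == r[2]) matrix(0.5, nrow(masw), ncol(masw))
        else (masw - r[1]) / (r[2] - r[1])
  pmin(pmax(nw, 0), 1)
}

#' Prepare a site grid from a landscape bundle
#'
#' Runs the full site-preparation chain: SOC to fertility (with smoothing),
#' DEM to TWI to MASW, the eligibility mask, and normalized wetness over the
#' eligible cells.
#'
#' @param bundle A \linkS4class{LandscapeBundle}.
#' @param soil_class Soil texture class applied to every cell (one of
#'   \code{names(soilClassTable())}).
#' @param smooth_window Fertility smoothing window.
#' @return A \linkS4class{SiteGrid}.
#' @export
prepareSite <- function(bundle, soil_class = "sandy_loam",
                        smooth_window = 3) {
  stopifnot(is(bundle, "LandscapeBundle"))
  if (!soil_class %in% names(soilClassTable()))
    stop("unknown soil class: ", soil_class, call. = FALSE)
  fr <- socToFertility(bundle@soc, smooth_window = smooth_window)
  twi <- computeTWI(bundle@dem, cellsize = bundle@cellsize)
  masw <- twiToMASW(twi)
  elig <- eligibilityMask(bundle@landcover, bundle@forest_history)
  nw <- normalizedWetness(masw, elig)
  new("SiteGrid", fr = fr, masw = masw, eligible = elig, nw = nw,
      soil_class = soil_class, cellsize = bundle@cellsize)
}

#' Write a site grid to disk as ASCII rasters
#'
#' @param site A \linkS4class{SiteGrid}.
#' @param outdir Output directory.
#' @return Invisibly, the files written.
#' @export
writeSiteGrid <- function(site, outdir) {
  stopifnot(is(site, "SiteGrid"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cs <- site@cellsize
  invisible(c(
    writeAsciiGrid(site@fr, file.path(outdir, "fertility.asc"), cellsize = cs),
    writeAsciiGrid(site@masw, file.path(outdir, "masw.asc"), cellsize = cs),
    writeAsciiGrid(site@eligible + 0, file.path(outdir, "eligible.asc"),
                   cellsize = cs),
    writeAsciiGrid(site@nw, file.path(outdir, "nw.asc"), cellsize = cs)))
}
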