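#' @importFrom stats rnorm runif pnorm pchisq setNames median sd fft
#' @importFrom utils read.csv write.csv
NULL

#' Days in each calendar month
#'
#' Month lengths used throughout the monthly time step (no leap years: inputs
#' are climate normals, not calendars).
#'
#' @param month Integer month 1-12 (vectorised).
#' @return Integer vector of day counts.
#' @export
daysInMonth <- function(month) {
  stopifnot(all(month %in% 1:12))
  DAYS_IN_MONTH[month]
}

## Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
## RNG stream is untouched.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Derive a stream-specific child seed, kept below 2^31.
childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k) %% 2147483647)
}

## Smooth an n x n white-noise field with a Gaussian kernel via FFT (periodic
## convolution), used by the landscape generators.
gaussianSmoothField <- function(n, sigma) {
  z <- matrix(rnorm(n * n), n, n)
  d <- c(0:(n %/% 2), -((n - (n %/% 2 + 1)):1))
  if (length(d) != n) d <- d[seq_len(n)]
  k <- exp(-outer(d^2, d^2, "+") / (2 * sigma^2))
  k <- k / sum(k)
  Re(fft(fft(z) * fft(k), inverse = TRUE)) / (n * n)
}

## Min-max rescale to [lo, hi]; constant input maps to the midpoint.
rescaleRange <- function(x, lo, hi) {
  r <- range(x, finite = TRUE)
  if (!all(is.finite(r))) stop("no finite values to rescale", call. = FALSE)
  if (r[1] == r[2]) return(array((lo + hi) / 2, dim = dim(x) %||% length(x)))
  lo + (hi - lo) * (x - r[1]) / (r[2] - r[1])
}

#' Read an ESRI ASCII grid
#'
#' Plain-text single-band raster interchange format (ncols/nrows/xllcorner/
#' yllcorner/cellsize/NODATA_value header followed by rows north to south).
#'
#' @param path File path.
#' @return A numeric matrix with attributes \code{cellsize}, \code{xllcorner},
#'   \code{yllcorner}; NODATA cells are \code{NA}.
#' @export
readAsciiGrid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  structure(m, cellsize = hdr$cellsize %||% 1,
            xllcorner = hdr$xllcorner %||% 0,
            yllcorner = hdr$yllcorner %||% 0)
}

#' Write an ESRI ASCII grid
#'
#' @param m Numeric matrix (rows are north to south).
#' @param path Output file path.
#' @param cellsize Cell edge length in metres.
#' @param nodata Value written for \code{NA} cells.
#' @return Invisibly, \code{path}.
#' @export
writeAsciiGrid <- function(m, path, cellsize = 100, nodata = -9999) {
  stopifnot(is.matrix(m))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    "xllcorner 0", "yllcorner 0",
    sprintf("cellsize %.10g", cellsize),
    sprintf("NODATA_value %.10g", nodata)), con)
  m[is.na(m)] <- nodata
  for (r in seq_len(nrow(m)))
    writeLines(paste(format(m[r, ], digits = 10, trim = TRUE),
                     collapse = " "), con)
  invisible(path)
}
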