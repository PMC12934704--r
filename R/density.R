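#' @include weScore.R
NULL

#' Construct a DensityGrid
#'
#' @param values 3-D numeric array.
#' @param origin numeric(3), Angstrom position of voxel (0,0,0).
#' @param spacing voxel size, Angstrom (isotropic).
#' @return a \linkS4class{DensityGrid}.
#' @export
densityGrid <- function(values, origin = c(0, 0, 0), spacing = 0.3) {
  new("DensityGrid", origin = as.numeric(origin),
      spacing = as.numeric(spacing), values = values)
}

#' Grid specification covering a model
#'
#' @param model an \linkS4class{EnsembleModel}.
#' @param spacing voxel size, Angstrom.
#' @param margin padding around the model's bounding box, Angstrom.
#' @return an empty \linkS4class{DensityGrid} covering the model.
#' @export
gridFromModel <- function(model, spacing = 0.3, margin = 3.5) {
  X <- coords(model)
  lo <- apply(X, 2, min) - margin
  hi <- apply(X, 2, max) + margin
  dims <- pmax(8L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  densityGrid(array(0, dim = dims), origin = lo, spacing = spacing)
}

# Gaussian widths: isotropic variance (B + bBase)/(8 pi^2) per coordinate.
atomGaussians <- function(model, bBase = 10) {
  a <- model@atoms
  sig2 <- (a$b + bBase) / (8 * pi^2)
  amp <- a$occ * elementWeight(a$element) / (2 * pi * sig2)^1.5
  list(amp = amp, sig2 = sig2, cutoff = 6 * sqrt(max(sig2)))
}

#' Synthesize real-space density from a model
#'
#' The density is the sum over sites of occupancy-weighted isotropic
#' Gaussians whose variance is (B + bBase)/(8 pi^2) and whose integral is
#' occupancy times the element's electron count. The synthesis is linear
#' in the model, so an ensemble's density is the occupancy-weighted sum of
#' its conformers' densities and is invariant under conformer-letter
#' relabeling.
#'
#' @param model an \linkS4class{EnsembleModel}.
#' @param grid a \linkS4class{DensityGrid} defining origin/spacing/shape,
#'   or NULL to build one with \code{\link{gridFromModel}}.
#' @param spacing,margin grid construction parameters when \code{grid} is
#'   NULL.
#' @param bBase baseline displacement parameter added to atomic B factors,
#'   Angstrom^2.
#' @return a \linkS4class{DensityGrid}.
#' @export
synthesizeDensity <- function(model, grid = NULL, spacing = 0.3,
                              margin = 3.5, bBase = 10) {
  if (is.null(grid)) grid <- gridFromModel(model, spacing, margin)
  g <- atomGaussians(model, bBase)
  dims <- dim(grid@values)
  X <- coords(model)
  lo <- grid@origin + g$cutoff
  hi <- grid@origin + (dims - 1) * grid@spacing - g$cutoff
  inside <- X[, 1] >= lo[1] & X[, 2] >= lo[2] & X[, 3] >= lo[3] &
    X[, 1] <= hi[1] & X[, 2] <= hi[2] & X[, 3] <= hi[3]
  if (!all(inside))
    stopf("%d atom(s) outside the grid margin", sum(!inside))
  v <- cpp_density(X, g$amp, g$sig2, grid@origin, grid@spacing,
                   as.integer(dims), g$cutoff)
  densityGrid(array(v, dim = dims), grid@origin, grid@spacing)
}

#' Real-space density misfit and its coordinate gradient
#'
#' The misfit is \code{scale * sum((rho_model - rho_target)^2) /
#' sum(rho_target^2)}: zero iff the model density equals the target
#' everywhere, and invariant under global conformer-letter swaps (the
#' formal reason density-misfit barrier traps exist). The analytic gradient
#' per atomic coordinate is returned as an attribute.
#'
#' @param model an \linkS4class{EnsembleModel}.
#' @param target a \linkS4class{DensityGrid}.
#' @param scale dimensionless weight applied to the normalized misfit;
#'   the default puts one displaced atom on the scale of a severe
#'   geometry outlier, so density and geometry compete as they do in
#'   refinement.
#' @param bBase baseline B added to atomic B factors, Angstrom^2.
#' @param wantGrad compute the analytic gradient (default TRUE).
#' @return non-negative scalar with attribute \code{gradient} (n x 3).
#' @export
densityMisfit <- function(model, target, scale = 2e6, bBase = 10,
                          wantGrad = TRUE) {
  g <- atomGaussians(model, bBase)
  dims <- dim(target@values)
  X <- coords(model)
  v <- cpp_density(X, g$amp, g$sig2, target@origin, target@spacing,
                   as.integer(dims), g$cutoff)
  tv <- as.numeric(target@values)
  normt <- sum(tv^2)
  if (normt <= 0) stopf("target density is empty")
  diff <- v - tv
  val <- scale * sum(diff^2) / normt
  if (wantGrad) {
    grad <- cpp_density_grad(X, g$amp, g$sig2, target@origin,
                             target@spacing, as.integer(dims), diff,
                             g$cutoff, scale / normt)
    attr(val, "gradient") <- grad
  }
  val
}

#' Difference map and peak list
#'
#' Target minus model density, expressed in units of the difference map's
#' own standard deviation. Peaks are local extrema over the 26-voxel
#' neighborhood with |height| above the threshold, sorted by decreasing
#' |height|.
#'
#' @param model an \linkS4class{EnsembleModel}.
#' @param target a \linkS4class{DensityGrid}.
#' @param threshold minimum |height| in sigma units for the peak list.
#' @param bBase baseline B, Angstrom^2.
#' @return list with \code{map} (a \linkS4class{DensityGrid} in sigma
#'   units) and \code{peaks} (data.frame \code{x}, \code{y}, \code{z},
#'   \code{height}).
#' @export
differenceMap <- function(model, target, threshold = 3, bBase = 10) {
  modelMap <- synthesizeDensity(model, grid = target, bBase = bBase)
  d <- target@values - modelMap@values
  s <- sqrt(mean((d - mean(d))^2))
  if (s <= 0) s <- 1
  d <- d / s
  dims <- dim(d)
  core <- d[2:(dims[1] - 1), 2:(dims[2] - 1), 2:(dims[3] - 1)]
  isMax <- abs(core) >= threshold
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    nb <- d[2:(dims[1] - 1) + dx, 2:(dims[2] - 1) + dy,
            2:(dims[3] - 1) + dz]
    isMax <- isMax & (abs(core) >= abs(nb))
  }
  idx <- which(isMax, arr.ind = TRUE)
  peaks <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      height = numeric(0))
  if (nrow(idx)) {
    pos <- sweep((idx) * target@spacing, 2, target@origin, "+")
    # idx is 1-based into the core block, which starts at voxel 2 (index 1)
    h <- core[idx]
    peaks <- data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3],
                        height = h)
    peaks <- peaks[order(-abs(peaks$height)), , drop = FALSE]
    rownames(peaks) <- NULL
  }
  list(map = densityGrid(d, target@origin, target@spacing), peaks = peaks)
}

#' Add band-limited Gaussian noise to a density grid
#'
#' White voxel noise is smoothed with an isotropic Gaussian kernel (so the
#' noise is resolution-limited, as in an experimental map) and rescaled to
#' the requested standard deviation.
#'
#' @param grid a \linkS4class{DensityGrid}.
#' @param sd target noise standard deviation (absolute units).
#' @param seed integer seed.
#' @param smooth kernel sigma in Angstrom.
#' @return the grid with noise added.
#' @export
addDensityNoise <- function(grid, sd, seed = 1L, smooth = 0.5) {
  if (sd <= 0) return(grid)
  dims <- dim(grid@values)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  noise <- array(rnorm(prod(dims)), dim = dims)
  sv <- smooth / grid@spacing
  half <- max(1L, as.integer(ceiling(3 * sv)))
  kern <- exp(-(seq(-half, half))^2 / (2 * sv^2))
  kern <- kern / sum(kern)
  noise <- convolveAlong(noise, kern, 1)
  noise <- convolveAlong(noise, kern, 2)
  noise <- convolveAlong(noise, kern, 3)
  nsd <- sqrt(mean((noise - mean(noise))^2))
  noise <- noise * (sd / nsd)
  densityGrid(grid@values + noise, grid@origin, grid@spacing)
}

# separable 1-D convolution along one array dimension (zero padding)
convolveAlong <- function(arr, kern, along) {
  dims <- dim(arr)
  perm <- c(along, setdiff(1:3, along))
  x <- aperm(arr, perm)
  d <- dim(x)
  m <- matrix(x, nrow = d[1])
  half <- (length(kern) - 1) / 2
  out <- matrix(0, nrow = d[1], ncol = ncol(m))
  for (k in seq_along(kern)) {
    off <- k - 1 - half
    src <- seq_len(d[1]) + off
    ok <- src >= 1 & src <= d[1]
    out[ok, ] <- out[ok, ] + kern[k] * m[src[ok], ]
  }
  aperm(array(out, dim = d), order(perm))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

# ---- MRC/CCP4 map IO -------------------------------------------------------

#' Read and write CCP4/MRC density maps
#'
#' Minimal MRC2014 mode-2 (float32) IO for orthogonal, isotropic grids: a
#' 1024-byte header followed by x-fastest voxel data, little-endian.
#'
#' @param grid a \linkS4class{DensityGrid}.
#' @param path file path.
#' @return \code{writeMRC} returns the path invisibly; \code{readMRC}
#'   returns a \linkS4class{DensityGrid}.
#' @export
writeMRC <- function(grid, path) {
  dims <- dim(grid@values)
  con <- file(path, "wb")
  on.exit(close(con))
  wInt <- function(x) writeBin(as.integer(x), con, size = 4,
                               endian = "little")
  wFlt <- function(x) writeBin(as.numeric(x), con, size = 4,
                               endian = "little")
  cell <- dims * grid@spacing
  wInt(dims)                  # NX NY NZ
  wInt(2)                     # MODE 2 = float32
  wInt(round(grid@origin / grid@spacing))  # NXSTART..NZSTART
  wInt(dims)                  # MX MY MZ
  wFlt(cell)                  # CELLA
  wFlt(c(90, 90, 90))         # CELLB
  wInt(1:3)                   # MAPC MAPR MAPS
  v <- as.numeric(grid@values)
  wFlt(c(min(v), max(v), mean(v)))  # DMIN DMAX DMEAN
  wInt(c(1, 0))               # ISPG, NSYMBT
  writeBin(raw(100), con)     # EXTRA
  wFlt(grid@origin)           # ORIGIN
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  wFlt(sigmaLevel(grid))      # RMS
  wInt(0)                     # NLABL
  writeBin(raw(800), con)     # labels
  wFlt(v)
  invisible(path)
}

#' @rdname writeMRC
#' @export
readMRC <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rInt <- function(n) readBin(con, "integer", n = n, size = 4,
                              endian = "little")
  rFlt <- function(n) readBin(con, "numeric", n = n, size = 4,
                              endian = "little")
  dims <- rInt(3)
  mode <- rInt(1)
  if (mode != 2) stopf("unsupported MRC mode %d (only float32)", mode)
  rInt(3)                     # NXSTART..NZSTART (origin record is used)
  m <- rInt(3)
  cella <- rFlt(3)
  rFlt(3)                     # cell angles
  mapcrs <- rInt(3)
  if (!identical(mapcrs, 1:3))
    stopf("unsupported MRC axis order")
  rFlt(3)                     # DMIN DMAX DMEAN
  rInt(2)                     # ISPG NSYMBT
  readBin(con, "raw", n = 100)
  origin <- rFlt(3)
  readBin(con, "raw", n = 8)  # MAP + MACHST
  rFlt(1)                     # RMS
  rInt(1)                     # NLABL
  readBin(con, "raw", n = 800)
  v <- rFlt(prod(dims))
  spacing <- cella[1] / m[1]
  densityGrid(array(v, dim = dims), origin = origin, spacing = spacing)
}
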