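#' @include bias-model.R
NULL

#' Build a synthetic gradient scheme
#'
#' Directions start on a spherical Fibonacci lattice and are refined by a
#' fixed number of electrostatic-repulsion steps (with antipodal symmetry,
#' as is standard for diffusion sampling schemes). The construction is
#' fully deterministic: the same arguments always give the same scheme.
#'
#' @param nDirections number of diffusion-weighted directions, >= 6.
#'   Default 30.
#' @param b b-value in s/mm\eqn{^2}. Default 1000.
#' @param nB0 number of b = 0 measurements (first rows). Default 1.
#' @param seed deterministic rotation offset of the initial lattice.
#' @param repulsionSteps repulsion iterations (default 50).
#' @return a [GradientScheme-class] with `nB0 + nDirections` measurements.
#' @examples
#' makeScheme()  # 31 measurements: 1 b=0 + 30 at b=1000
#' @export
makeScheme <- function(nDirections = 30, b = 1000, nB0 = 1, seed = 0L,
                       repulsionSteps = 50) {
  if (nDirections < 6) stop("need at least 6 diffusion directions")
  key <- paste(nDirections, b, nB0, seed, repulsionSteps, sep = "|")
  cached <- .schemeCache[[key]]          # deterministic, so safe to cache
  if (!is.null(cached)) return(cached)
  # Fibonacci lattice on the upper hemisphere (directions are axial, so a
  # half-sphere layout avoids antipodal near-duplicates), then repulsion
  i <- seq_len(nDirections) - 0.5
  z <- 1 - i / nDirections
  th <- pi * (1 + sqrt(5)) * i + as.numeric(seed)
  r <- sqrt(pmax(1 - z^2, 0))
  g <- unname(cbind(r * cos(th), r * sin(th), z))
  steps <- seq(0.05, 0.005, length.out = repulsionSteps)
  for (it in seq_len(repulsionSteps)) {
    Fm <- matrix(0, nDirections, 3)
    for (k in seq_len(nDirections)) {
      d <- sweep(-g, 2, g[k, ], "+")          # g_k - g_j
      d2 <- rowSums(d^2); d2[k] <- Inf
      da <- sweep(g, 2, g[k, ], "+")          # g_k + g_j (antipodes)
      a2 <- rowSums(da^2)
      Fm[k, ] <- colSums(d / d2^1.5) + colSums(da / a2^1.5)
    }
    Fm <- Fm - g * rowSums(Fm * g)            # tangential component
    nrmF <- sqrt(rowSums(Fm^2))
    Fm <- Fm / pmax(nrmF, 1)                  # cap the step length
    g <- g + steps[it] * Fm
    g <- g / sqrt(rowSums(g^2))
  }
  out <- gradientScheme(c(rep(0, nB0), rep(b, nDirections)),
                        rbind(matrix(0, nB0, 3), g))
  .schemeCache[[key]] <- out
  out
}

.schemeCache <- new.env(parent = emptyenv())

#' Create a phantom configuration
#'
#' Defaults emulate periventricular white matter at 2 mm isotropic
#' resolution with typical coherent-fibre diffusivities (axial 1.7,
#' radial 0.3 \eqn{\mu m^2/ms}), perivascular diffusivity 0.15
#' \eqn{\mu m^2/ms} along x (true ALPS 1.5) and no crossing fibres or
#' noise unless requested.
#'
#' @param dims grid shape, nx even >= 12, ny >= 12, nz >= 1.
#' @param voxelSize mm, default 2 mm isotropic.
#' @param drad,dax fibre radial/axial diffusivities (\eqn{\mu m^2/ms}).
#' @param dpv perivascular diffusivity along x (\eqn{\mu m^2/ms}).
#' @param dxxCross crossing-fibre axial (x) diffusivity; transverse = drad.
#' @param fxp,fxa per-voxel crossing fractions in the projection /
#'   association annotation zones (0 disables the insert).
#' @param crossingPattern "full" or "lattice" (see [PhantomConfig-class]).
#' @param csf CSF diffusivity (\eqn{\mu m^2/ms}).
#' @param s0 b = 0 signal.
#' @param snr SNR at b = 0; `Inf` (default) disables noise.
#' @param seed RNG seed for the noise.
#' @return a [PhantomConfig-class].
#' @export
phantomConfig <- function(dims = c(16L, 12L, 3L), voxelSize = c(2, 2, 2),
                          drad = 0.3, dax = 1.7, dpv = 0.15,
                          dxxCross = 1.7, fxp = 0, fxa = 0,
                          crossingPattern = "full", csf = 3.0, s0 = 100,
                          snr = Inf, seed = 1L) {
  new("PhantomConfig", dims = as.integer(dims),
      voxelSize = as.numeric(voxelSize), drad = drad, dax = dax, dpv = dpv,
      dxxCross = dxxCross, fxp = fxp, fxa = fxa,
      crossingPattern = crossingPattern, csf = csf, s0 = s0, snr = snr,
      seed = as.integer(seed))
}

# Region layout of the slab phantom. Returns, per hemisphere and site:
# slab voxel ranges, the 4x4 annotation zone, and the default conventional
# 2x2 ROI corner (the zone centre).
.phantomLayout <- function(dims) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  mid <- nx %/% 2L
  fib <- 2L:(ny - 1L)                     # rows 1 and ny are CSF border
  nf <- length(fib)
  projY <- fib[seq_len(nf %/% 2L)]
  assocY <- fib[(nf %/% 2L + 1L):nf]
  zoneRows <- function(rows) {            # middle 4 rows of a slab
    c0 <- rows[1] + (length(rows) - 4L) %/% 2L
    c0:(c0 + 3L)
  }
  hemiX <- list(left = 1L:mid, right = (mid + 1L):nx)
  zoneX <- lapply(hemiX, function(xs) {
    c0 <- xs[1] + (length(xs) - 4L) %/% 2L
    c0:(c0 + 3L)
  })
  zc <- (nz + 1L) %/% 2L
  sites <- list()
  for (h in c("left", "right")) {
    for (s in c("projection", "association")) {
      ys <- if (s == "projection") projY else assocY
      zy <- zoneRows(ys)
      zx <- zoneX[[h]]
      sites[[paste(h, s, sep = ".")]] <- list(
        hemisphere = h, site = s, x = hemiX[[h]], y = ys,
        zoneX = zx, zoneY = zy,
        roiCorner = c(zx[2], zy[2]),      # central 2x2 of the zone
        label = match(paste(h, s), c("left projection", "left association",
                                     "right projection", "right association")))
    }
  }
  list(sites = sites, projY = projY, assocY = assocY, slice = zc,
       csfY = c(1L, ny), hemiX = hemiX)
}

#' Default conventional ROIs of a phantom grid
#'
#' @param dims grid shape (or a [PhantomConfig-class]).
#' @param hemispheres which hemispheres to return ROIs for.
#' @return named list of [ROISpec-class] pairs:
#'   `left$projection`, `left$association`, etc.
#' @export
phantomRois <- function(dims, hemispheres = c("left", "right")) {
  if (is(dims, "PhantomConfig")) dims <- dims@dims
  lay <- .phantomLayout(dims)
  out <- list()
  for (h in hemispheres) {
    out[[h]] <- list()
    for (s in c("projection", "association")) {
      site <- lay$sites[[paste(h, s, sep = ".")]]
      out[[h]][[s]] <- squareRoi(s, h, site$roiCorner, lay$slice)
    }
  }
  out
}

# ground-truth tensor grid + crossing mask + labels for a config
.phantomTruthArrays <- function(cfg) {
  dm <- cfg@dims
  lay <- .phantomLayout(dm)
  nvox <- prod(dm)
  d6 <- matrix(0, nvox, 6)
  labels <- array(0L, dm)
  crossing <- array(FALSE, dm)
  linIdx <- function(xs, ys, zs) {
    g <- expand.grid(x = xs, y = ys, z = zs)
    g$x + dm[1] * (g$y - 1L) + dm[1] * dm[2] * (g$z - 1L)
  }
  allZ <- seq_len(dm[3])
  # CSF border rows
  csf <- linIdx(seq_len(dm[1]), lay$csfY, allZ)
  d6[csf, 1:3] <- cfg@csf
  dxxFib <- cfg@drad + cfg@dpv
  for (nm in names(lay$sites)) {
    site <- lay$sites[[nm]]
    idx <- linIdx(site$x, site$y, allZ)
    if (site$site == "projection") {
      d6[idx, 1:3] <- rep(c(dxxFib, cfg@drad, cfg@dax), each = length(idx))
    } else {
      d6[idx, 1:3] <- rep(c(dxxFib, cfg@dax, cfg@drad), each = length(idx))
    }
    labels[idx] <- site$label
    fx <- if (site$site == "projection") cfg@fxp else cfg@fxa
    if (fx > 0) {
      zx <- site$zoneX; zy <- site$zoneY
      if (cfg@crossingPattern == "lattice") {
        zx <- zx[c(1, 3)]; zy <- zy[c(1, 3)]
      }
      cIdx <- linIdx(zx, zy, allZ)
      fibRow <- if (site$site == "projection")
        c(dxxFib, cfg@drad, cfg@dax) else c(dxxFib, cfg@dax, cfg@drad)
      crossRow <- c(cfg@dxxCross, cfg@drad, cfg@drad)
      mixRow <- (1 - fx) * fibRow + fx * crossRow
      d6[cIdx, 1:3] <- rep(mixRow, each = length(cIdx))
      crossing[cIdx] <- TRUE
    }
  }
  list(d6 = d6, labels = labels, crossing = crossing, layout = lay)
}

#' Add Rician noise to diffusion-weighted signals
#'
#' Magnitude-MRI noise: \eqn{\sqrt{(S + n_1)^2 + n_2^2}} with independent
#' zero-mean Gaussian \eqn{n_1, n_2} of standard deviation `s0 / snr`
#' (SNR defined at b = 0).
#'
#' @param signals numeric vector/array of noiseless signals.
#' @param snr signal-to-noise ratio at b = 0, > 0. `Inf` returns the input.
#' @param s0 reference b = 0 signal defining the noise SD (default
#'   `max(signals)`).
#' @param seed optional integer; when given, the draw is reproducible and
#'   the caller's RNG state is left untouched.
#' @return noisy signals, same shape as the input.
#' @export
addRicianNoise <- function(signals, snr, s0 = max(signals), seed = NULL) {
  stopifnot(snr > 0)
  if (!is.finite(snr)) return(signals)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  sd <- s0 / snr
  n <- length(signals)
  out <- sqrt((signals + rnorm(n, 0, sd))^2 + rnorm(n, 0, sd)^2)
  if (!is.null(dim(signals))) dim(out) <- dim(signals)
  out
}

#' Generate a synthetic periventricular DWI phantom
#'
#' Builds the ground-truth tensor grid (z-oriented projection slab,
#' y-oriented association slab, CSF border, perivascular Dxx term,
#' optional x-oriented crossing-fibre mixtures), synthesizes
#' monoexponential signals for the scheme, and optionally adds Rician
#' noise.
#'
#' @param cfg a [PhantomConfig-class].
#' @param scheme a [GradientScheme-class]; default [makeScheme()].
#' @return an [AlpsPhantom-class].
#' @seealso [analyzePhantom()]
#' @export
makePhantom <- function(cfg = phantomConfig(), scheme = makeScheme()) {
  validObject(cfg)
  truth <- .phantomTruthArrays(cfg)
  dm <- cfg@dims
  X <- .designMatrix(scheme)
  n <- nrow(X)
  logS <- X %*% rbind(log(cfg@s0), t(truth$d6))   # n x nvox
  dwi <- exp(logS)
  if (is.finite(cfg@snr))
    dwi <- addRicianNoise(dwi, cfg@snr, s0 = cfg@s0, seed = cfg@seed)
  dwi <- array(t(dwi), c(dm, n))
  pt <- new("PhantomTruth", tensors = array(truth$d6, c(dm, 6L)),
            crossing = truth$crossing, labels = truth$labels,
            trueAlps = trueAlps(cfg@dpv, cfg@drad), config = cfg)
  new("AlpsPhantom", dwi = dwi, scheme = scheme, truth = pt,
      mask = array(TRUE, dm))
}

#' Run the full ALPS pipeline on a phantom
#'
#' Fits the tensor field from the phantom's DWI data, flags crossing
#' voxels, and computes conventional and adjusted ALPS per hemisphere
#' using the phantom's default ROI placement.
#'
#' @param phantom an [AlpsPhantom-class].
#' @param threshold crossing-flag threshold (default 1.8).
#' @param adjust "relocate" (default) or "exclude".
#' @param hemispheres hemispheres to process (independently; no bilateral
#'   averaging).
#' @param searchRadius clean-ROI search radius.
#' @return data.frame with one row per hemisphere x mode: ALPS index, the
#'   four contributing diffusivities, per-ROI FA/MD and excluded-voxel
#'   count.
#' @export
analyzePhantom <- function(phantom, threshold = 1.8,
                           adjust = c("relocate", "exclude"),
                           hemispheres = c("left", "right"),
                           searchRadius = 3L) {
  stopifnot(is(phantom, "AlpsPhantom"))
  adjust <- match.arg(adjust)
  cfg <- phantom@truth@config
  field <- fitTensorField(phantom@dwi, phantom@scheme, mask = phantom@mask,
                          voxelSize = cfg@voxelSize,
                          labels = phantom@truth@labels)
  flags <- flagCrossing(field, threshold)
  rois <- phantomRois(cfg@dims, hemispheres)
  rows <- list()
  for (h in hemispheres) {
    res <- computeAlps(field, rois[[h]]$projection, rois[[h]]$association,
                       flags, mode = "both", adjust = adjust,
                       searchRadius = searchRadius)
    for (r in res) rows[[length(rows) + 1L]] <- .alpsResultRow(r)
  }
  do.call(rbind, rows)
}

.alpsResultRow <- function(r) {
  p <- r@projection; a <- r@association
  data.frame(hemisphere = r@hemisphere, mode = r@mode, alps = r@alps,
             dxxProj = p@dxx, dyyProj = p@dyy, dxxAssoc = a@dxx,
             dzzAssoc = a@dzz, faProj = p@fa, faAssoc = a@fa,
             mdProj = p@md, mdAssoc = a@md,
             excludedVoxels = p@nExcluded + a@nExcluded,
             stringsAsFactors = FALSE)
}
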