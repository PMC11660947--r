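#' @include alps.R
NULL

#' Create a crossing-fibre bias-model configuration
#'
#' @param drad fibre radial diffusivity (\eqn{\mu m^2/ms}), > 0.
#' @param dpv perivascular diffusivity along x (\eqn{\mu m^2/ms}), >= 0.
#' @param fxp,fxa crossing-fibre volume fractions at the projection and
#'   association sites, in [0, 1].
#' @param dxxCross crossing-fibre diffusivity along x (\eqn{\mu m^2/ms}).
#' @param dyyCross,dzzCross crossing-fibre transverse diffusivities;
#'   default `drad` (the assumption under which the closed form is exact).
#' @return a [CrossingConfig-class].
#' @export
crossingConfig <- function(drad, dpv = 0, fxp = 0, fxa = 0,
                           dxxCross = 1.7, dyyCross = drad,
                           dzzCross = drad) {
  new("CrossingConfig", drad = drad, dpv = dpv, fxp = fxp, fxa = fxa,
      dxxCross = dxxCross, dyyCross = dyyCross, dzzCross = dzzCross)
}

#' @rdname crossingConfig
#' @param cfg a [CrossingConfig-class].
#' @details `crossingAnisotropy()` returns the anisotropy ratio
#'   \eqn{r = D_{xx,cross}/D_{rad}}.
#' @export
crossingAnisotropy <- function(cfg) cfg@dxxCross / cfg@drad

#' Site diffusivities under the crossing-fibre mixture model
#'
#' Linear mixtures of the fibre and crossing-fibre diffusivities at each
#' site, using the axially symmetric fibre model
#' Dxx,proj = Dxx,assoc = Drad + Dpv, Dyy,proj = Dzz,assoc = Drad:
#' \deqn{D_{xx,proj+cross} = (1-f_{Xp}) D_{xx,proj} + f_{Xp} D_{xx,cross}}
#' and likewise for Dyy,proj, Dxx,assoc and Dzz,assoc with the matching
#' fractions and crossing components.
#'
#' @param cfg a [CrossingConfig-class].
#' @return named numeric(4): `dxxProj`, `dyyProj`, `dxxAssoc`, `dzzAssoc`
#'   (\eqn{\mu m^2/ms}).
#' @export
mixtureDiffusivities <- function(cfg) {
  stopifnot(is(cfg, "CrossingConfig"))
  validObject(cfg)
  dxxFib <- cfg@drad + cfg@dpv
  c(dxxProj  = (1 - cfg@fxp) * dxxFib + cfg@fxp * cfg@dxxCross,
    dyyProj  = (1 - cfg@fxp) * cfg@drad + cfg@fxp * cfg@dyyCross,
    dxxAssoc = (1 - cfg@fxa) * dxxFib + cfg@fxa * cfg@dxxCross,
    dzzAssoc = (1 - cfg@fxa) * cfg@drad + cfg@fxa * cfg@dzzCross)
}

#' Apparent ALPS index in the presence of crossing fibres
#'
#' The ALPS ratio evaluated on the mixture diffusivities:
#' \deqn{ALPS_X = \frac{D_{xx,proj+cross} + D_{xx,assoc+cross}}
#'                     {D_{yy,proj+cross} + D_{zz,assoc+cross}}}
#'
#' @param cfg a [CrossingConfig-class].
#' @return unitless scalar.
#' @examples
#' apparentAlps(crossingConfig(drad = 0.3, fxp = 0.1, dxxCross = 1.7))
#' @export
apparentAlps <- function(cfg) {
  d <- mixtureDiffusivities(cfg)
  den <- d[["dyyProj"]] + d[["dzzAssoc"]]
  if (!(den > 0)) stop("non-positive ALPS denominator")
  (d[["dxxProj"]] + d[["dxxAssoc"]]) / den
}

#' Closed-form apparent ALPS
#'
#' With crossing-fibre transverse diffusivities equal to Drad, the apparent
#' index is an affine pull of the true index towards the crossing-fibre
#' anisotropy \eqn{r = D_{xx,cross}/D_{rad}}:
#' \deqn{ALPS_X = ALPS + \frac{f_X}{2}(r - ALPS)} for crossing at a single
#' site (projection or association), and \eqn{ALPS_X = ALPS + f_X(r - ALPS)}
#' when fibres cross at both sites (the factor doubles).
#'
#' @param trueAlps true ALPS index (unitless, >= 0).
#' @param fx crossing volume fraction in [0, 1].
#' @param r crossing-fibre anisotropy ratio, >= 0.
#' @param sites "one" (default) or "both".
#' @return unitless scalar (vectorized over its numeric arguments).
#' @export
apparentAlpsClosedForm <- function(trueAlps, fx, r, sites = c("one", "both")) {
  sites <- match.arg(sites)
  stopifnot(all(fx >= 0 & fx <= 1), all(r >= 0))
  fac <- if (sites == "one") fx / 2 else fx
  trueAlps + fac * (r - trueAlps)
}

#' Apparent-ALPS surface over crossing fraction and anisotropy
#'
#' @param fxGrid crossing fractions (default 0 to 0.3).
#' @param rGrid anisotropy ratios \eqn{r = D_{xx,cross}/D_{rad}}
#'   (default 1 to 8).
#' @param trueAlps true ALPS index.
#' @param sites "one" or "both".
#' @return matrix (length(fxGrid) x length(rGrid)) of apparent ALPS values,
#'   with dimnames giving the grid.
#' @export
biasSurface <- function(fxGrid = seq(0, 0.3, length.out = 31),
                        rGrid = seq(1, 8, length.out = 29),
                        trueAlps = 1.5, sites = c("one", "both")) {
  sites <- match.arg(sites)
  stopifnot(all(is.finite(fxGrid)), all(is.finite(rGrid)))
  out <- outer(fxGrid, rGrid, function(f, r)
    apparentAlpsClosedForm(trueAlps, f, r, sites))
  dimnames(out) <- list(fx = signif(fxGrid, 8), r = signif(rGrid, 8))
  out
}

#' Relative bias of the apparent ALPS as a function of the true ALPS
#'
#' \eqn{(ALPS_X - ALPS)/ALPS} over a grid of true ALPS values at a fixed
#' crossing fraction. Positive where ALPS < r, zero at ALPS = r, negative
#' above (the apparent index can drop below the true one, in principle
#' below 1, for weakly anisotropic crossing fibres and large true ALPS).
#'
#' @param trueAlpsGrid true ALPS values, all >= 1.
#' @param fx crossing fraction (default 0.1).
#' @param r crossing-fibre anisotropy ratio.
#' @param sites "one" or "both".
#' @return numeric vector of relative biases, named by the grid.
#' @export
relativeBiasCurve <- function(trueAlpsGrid = seq(1, 2, length.out = 21),
                              fx = 0.1, r = 1.7 / 0.3,
                              sites = c("one", "both")) {
  sites <- match.arg(sites)
  stopifnot(all(trueAlpsGrid >= 1))
  ax <- apparentAlpsClosedForm(trueAlpsGrid, fx, r, sites)
  out <- (ax - trueAlpsGrid) / trueAlpsGrid
  names(out) <- signif(trueAlpsGrid, 8)
  out
}
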