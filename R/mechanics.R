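## The core physics inversion: wavelength shift -> vertical displacement
## (fractional peak shift equals fractional thickness change) -> vertical
## stress (incompressible linear elasticity), plus the full strain/stress
## tensor chain, region segmentation and force integration.

#' Vertical displacement map from a wavelength map
#'
#' Inverts the peak-shift relation: \eqn{\Delta D = D (\lambda - \lambda_0) /
#' \lambda_0} per pixel, with \eqn{\lambda_0} the unstrained reflection peak
#' of the substrate. Positive \eqn{\Delta D} is an upward pull (red shift).
#'
#' @param wl a [WavelengthMap-class].
#' @param spec a [SubstrateSpec-class]; its `lambda0` is the unstrained
#'   reference (estimate it with [estimateLambda0()] when unknown).
#' @return a [DisplacementMap-class] (um); invalid pixels propagate.
#' @examples
#' s <- SubstrateSpec()
#' displacementMap(WavelengthMap(matrix(555.5, 1, 1)), s)  # +0.24 um
#' @export
displacementMap <- function(wl, spec) {
  stopifnot(is(wl, "WavelengthMap"), is(spec, "SubstrateSpec"))
  if (spec@lambda0 <= 0) stop("lambda0 must be positive")
  dd <- spec@restD * (wl@values - spec@lambda0) / spec@lambda0
  dd[!wl@valid] <- NA_real_
  DisplacementMap(dd, wl@valid, wl@pixelLength)
}

#' Vertical stress map from a displacement map
#'
#' Incompressible linear elasticity gives the out-of-plane traction
#' \eqn{T_z = \frac{E}{1+\nu} \frac{\Delta D}{D}} per pixel (positive =
#' upward). With E = 20 kPa and nu = 0.49 the prefactor is 13422.8 Pa per
#' unit strain, so a 1.524 um push on a 24 um film is 852 Pa.
#'
#' @param disp a [DisplacementMap-class].
#' @param spec a [SubstrateSpec-class].
#' @return a [StressMap-class] (Pa).
#' @examples
#' s <- SubstrateSpec()
#' m <- verticalStressMap(DisplacementMap(matrix(-1.524, 1, 1)), s)
#' round(abs(mapValues(m)))   # 852
#' @export
verticalStressMap <- function(disp, spec) {
  stopifnot(is(disp, "DisplacementMap"), is(spec, "SubstrateSpec"))
  tz <- spec@youngsE / (1 + spec@poissonNu) * disp@values / spec@restD
  tz[!disp@valid] <- NA_real_
  StressMap(tz, disp@valid, disp@pixelLength)
}

#' Estimate the unstrained peak wavelength from background pixels
#'
#' The unstrained substrate dominates the field of view, so the mode of the
#' wavelength histogram over valid pixels estimates \eqn{\lambda_0}. The
#' histogram uses `binWidth`-nm bins and the estimate is the mean wavelength
#' inside the modal bin.
#'
#' @param wl a [WavelengthMap-class].
#' @param binWidth histogram bin width, nm.
#' @return estimated \eqn{\lambda_0}, nm.
#' @export
estimateLambda0 <- function(wl, binWidth = 0.5) {
  stopifnot(is(wl, "WavelengthMap"))
  v <- wl@values[wl@valid]
  if (!length(v)) stop("no valid pixels to estimate lambda0 from")
  bins <- round(v / binWidth)
  modal <- as.integer(names(which.max(table(bins))))
  mean(v[bins == modal])
}

#' Symmetric strain tensor from a displacement vector field
#'
#' Small-strain symmetric gradient
#' \eqn{e_{ij} = \tfrac12 (\partial u_i / \partial x_j +
#' \partial u_j / \partial x_i)} on the pixel grid, using central
#' differences in the interior and one-sided differences at the edges.
#' Components are supplied as matrices: `ux` (along columns, x), `uy` (along
#' rows, y) and `uz` (out of plane); any may be omitted (treated as zero).
#' The out-of-plane normal strain can instead be supplied directly as
#' `ezz` (e.g. \eqn{\Delta D / D} from the wavelength shift), in which case
#' no z-derivative of `uz` is attempted (a single-plane field has none).
#'
#' @param ux,uy,uz displacement components, um, matrices on one grid.
#' @param spacing grid spacing, um.
#' @param ezz optional out-of-plane normal strain (matrix or scalar),
#'   dimensionless.
#' @return a [StrainField-class] (dimensionless components).
#' @examples
#' ux <- outer(rep(1, 4), 1:4) * 0.1   # u_x = 0.1 x -> e_xx = 0.1
#' mapx <- strainTensor(ux = ux, spacing = 1)
#' @export
strainTensor <- function(ux = NULL, uy = NULL, uz = NULL, spacing = 1,
                         ezz = NULL) {
  comps <- Filter(Negate(is.null), list(ux = ux, uy = uy, uz = uz))
  if (!length(comps) && is.null(ezz))
    stop("at least one displacement component (or ezz) is required")
  d <- if (length(comps)) dim(comps[[1]]) else dim(as.matrix(ezz))
  if (any(d < 2) && length(comps))
    stop("grid must be at least 2 x 2 to differentiate")
  zero <- matrix(0, d[1], d[2])
  if (is.null(ux)) ux <- zero
  if (is.null(uy)) uy <- zero
  if (is.null(uz)) uz <- zero
  ## pracma::gradient returns list(X = d/dx (columns), Y = d/dy (rows))
  gx <- pracma::gradient(ux, spacing, spacing)
  gy <- pracma::gradient(uy, spacing, spacing)
  gz <- pracma::gradient(uz, spacing, spacing)
  exx <- gx$X
  eyy <- gy$Y
  exy <- 0.5 * (gx$Y + gy$X)
  exz <- 0.5 * gz$X        # + du_x/dz, unavailable for a single plane
  eyz <- 0.5 * gz$Y
  ezzM <- if (is.null(ezz)) zero else {
    e <- as.matrix(ezz)
    if (length(e) == 1L) matrix(e, d[1], d[2]) else e
  }
  new("StrainField", xx = exx, yy = eyy, zz = ezzM,
      xy = exy, xz = exz, yz = eyz, spacing = as.numeric(spacing))
}

#' Stress tensor from a strain tensor (isotropic linear elasticity)
#'
#' Full law: \eqn{\sigma_{ij} = \frac{E}{1+\nu}\left(
#' \frac{\nu}{1-2\nu} e_{\alpha\alpha}\,\delta_{ij} + e_{ij}\right)};
#' incompressible simplification: \eqn{\sigma_{ij} = \frac{E}{1+\nu}
#' e_{ij}}. The surface traction with normal `(0, 0, 1)` is
#' \eqn{T_i = n_j \sigma_{ij}}, so the vertical traction is
#' \eqn{T_z = \sigma_{zz}}.
#'
#' @param e a [StrainField-class].
#' @param E Young's modulus, Pa.
#' @param nu Poisson ratio.
#' @param incompressible use the simplified law (default `TRUE`). The full
#'   law is singular at `nu = 0.5`.
#' @return a [StressField-class] (Pa).
#' @export
stressTensor <- function(e, E, nu, incompressible = TRUE) {
  stopifnot(is(e, "StrainField"), E > 0)
  fac <- E / (1 + nu)
  if (incompressible) {
    vol <- 0
  } else {
    if (abs(nu - 0.5) < 1e-12)
      stop("full law is singular at nu = 0.5; use incompressible = TRUE")
    tr <- e@xx + e@yy + e@zz
    vol <- nu / (1 - 2 * nu) * tr
  }
  new("StressField",
      xx = fac * (vol + e@xx), yy = fac * (vol + e@yy),
      zz = fac * (vol + e@zz),
      xy = fac * e@xy, xz = fac * e@xz, yz = fac * e@yz,
      spacing = e@spacing)
}

## merge 4-connected labels that touch diagonally into 8-connected
## components (EBImage::bwlabel is 4-connected)
.merge8 <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  a <- lab[-nr, -nc]; b <- lab[-1, -1]          # down-right diagonal
  p1 <- cbind(a[a > 0 & b > 0 & a != b], b[a > 0 & b > 0 & a != b])
  a <- lab[-1, -nc]; b <- lab[-nr, -1]          # up-right diagonal
  p2 <- cbind(a[a > 0 & b > 0 & a != b], b[a > 0 & b > 0 & a != b])
  pairs <- unique(rbind(p1, p2))
  k <- max(lab)
  if (!nrow(pairs) || k == 0) return(lab)
  g <- igraph::graph_from_edgelist(matrix(as.character(pairs), ncol = 2),
                                   directed = FALSE)
  g <- g + igraph::vertices(setdiff(as.character(seq_len(k)),
                                    igraph::V(g)$name))
  comp <- igraph::components(g)$membership
  remap <- integer(k)
  remap[as.integer(names(comp))] <- comp
  out <- lab
  out[lab > 0] <- remap[lab[lab > 0]]
  out
}

#' Segment deformation regions
#'
#' Connected components (8-connectivity) of pixels whose absolute vertical
#' displacement exceeds `threshold`; components smaller than `minArea`
#' pixels are dropped. Labels are renumbered 1..K (background 0).
#'
#' @param disp a [DisplacementMap-class] (or plain matrix of um values).
#' @param threshold displacement magnitude threshold, um, positive. A
#'   practical default is 3x the background displacement noise SD.
#' @param minArea minimum component area, pixels.
#' @return integer label matrix.
#' @export
segmentRegions <- function(disp, threshold, minArea = 20L) {
  stopifnot(threshold > 0)
  v <- if (is(disp, "DisplacementMap")) {
    x <- disp@values; x[!disp@valid] <- 0; x
  } else as.matrix(disp)
  mask <- abs(v) > threshold
  if (!any(mask)) return(matrix(0L, nrow(v), ncol(v)))
  lab <- EBImage::imageData(EBImage::bwlabel(mask))
  lab <- .merge8(matrix(as.integer(lab), nrow(v), ncol(v)))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= minArea)
  remap <- integer(length(sizes))
  remap[keep] <- seq_along(keep)
  out <- lab
  out[lab > 0] <- remap[lab[lab > 0]]
  matrix(as.integer(out), nrow(v), ncol(v))
}

#' Region-wise vertical force integration
#'
#' For each label, the local vertical force is the pixel sum
#' \eqn{F = \sum T_z \cdot \ell^2} with \eqn{\ell} the pixel edge length.
#' The default report is the magnitude sum \eqn{\sum |T_z| \ell^2}, with the
#' signed upward (pull) and downward (push) components reported separately.
#' A label-0 row summarises the whole field (global force and global average
#' force per area).
#'
#' @param stress a [StressMap-class].
#' @param labels integer label matrix from [segmentRegions()] (or `NULL`
#'   for whole-field only).
#' @param pixelLength pixel edge length, um; defaults to the map's.
#' @return data.frame with one row per label (plus the whole-field row,
#'   `label = 0`): `label`, `area_um2`, `pixels`, `force_nN` (magnitude
#'   sum), `force_up_nN`, `force_down_nN` (signed components),
#'   `stress_min_Pa`, `stress_max_Pa`, `centroid_row`, `centroid_col`,
#'   and for the whole-field row `mean_force_per_area_nN_um2`.
#' @examples
#' s <- StressMap(matrix(852, 10, 10), pixelLength = 0.18)
#' regionForces(s, matrix(1L, 10, 10))$force_nN[2]   # 2.76 nN
#' @export
regionForces <- function(stress, labels = NULL, pixelLength = NULL) {
  stopifnot(is(stress, "StressMap"))
  if (is.null(pixelLength)) pixelLength <- stress@pixelLength
  if (is.na(pixelLength))
    stop("pixelLength is required to integrate forces (um per pixel)")
  if (is.null(labels)) labels <- matrix(0L, nrow(stress@values),
                                        ncol(stress@values))
  if (!identical(dim(labels), dim(stress@values)))
    stop("labels and stress map must share one shape")
  aPix <- (pixelLength * 1e-6)^2 * 1e9    # Pa * m^2 -> nN per pixel
  tz <- stress@values
  tz[!stress@valid] <- NA_real_
  one <- function(sel, label) {
    v <- tz[sel]
    v <- v[!is.na(v)]
    n <- sum(sel)
    idx <- which(sel, arr.ind = TRUE)
    data.frame(label = label,
               area_um2 = n * pixelLength^2,
               pixels = n,
               force_nN = sum(abs(v)) * aPix,
               force_up_nN = sum(v[v > 0]) * aPix,
               force_down_nN = sum(v[v < 0]) * aPix,
               stress_min_Pa = if (length(v)) min(v) else NA_real_,
               stress_max_Pa = if (length(v)) max(v) else NA_real_,
               centroid_row = mean(idx[, 1]),
               centroid_col = mean(idx[, 2]))
  }
  ids <- sort(setdiff(unique(as.vector(labels)), 0L))
  rows <- lapply(ids, function(k) one(labels == k, k))
  field <- one(matrix(TRUE, nrow(tz), ncol(tz)), 0L)
  out <- do.call(rbind, c(list(field), rows))
  out$mean_force_per_area_nN_um2 <- out$force_nN / out$area_um2
  rownames(out) <- NULL
  out
}

#' Fold increase of a force (or any positive quantity)
#'
#' `(fEnd - fStart) / fStart`; e.g. compression forces growing from 159.63
#' to 953.30 nN is a 4.97-fold increase.
#'
#' @param fStart starting value, positive.
#' @param fEnd final value.
#' @return dimensionless fold increase.
#' @export
foldIncrease <- function(fStart, fEnd) {
  if (any(fStart <= 0)) stop("fStart must be positive")
  (fEnd - fStart) / fStart
}

#' Percent relative error against a reference
#'
#' `100 * |measured - reference| / reference`.
#'
#' @param measured measured value(s).
#' @param reference reference value(s), positive.
#' @return percent error.
#' @export
relativeError <- function(measured, reference) {
  if (any(reference <= 0)) stop("reference must be positive")
  100 * abs(measured - reference) / reference
}
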