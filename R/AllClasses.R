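#' @import methods
NULL

.chkPos <- function(x, nm) {
    if (length(x) != 1L || !is.finite(x) || x <= 0)
        sprintf("'%s' must be a single strictly positive finite number", nm)
    else NULL
}

.chkFinite <- function(x, nm) {
    if (length(x) != 1L || !is.finite(x))
        sprintf("'%s' must be a single finite number", nm)
    else NULL
}

#' Tumor transport properties
#'
#' Vascular permeability \code{Lp}, interstitial permeability \code{k} and
#' capillary surface-area-to-volume ratio \code{SV} of the tumor interstitium.
#' Together with the tumor radius they determine the dimensionless
#' spatial-distribution parameter \eqn{\alpha = a\sqrt{(L_p/k)(S/V)}} that
#' controls how sharply interstitial fluid pressure (and hence solid stress)
#' concentrates towards the tumor center.
#'
#' @slot Lp vascular permeability (m Pa^-1 s^-1), > 0.
#' @slot k interstitial permeability (m^2 Pa^-1 s^-1), > 0.
#' @slot SV capillary surface-area-to-volume ratio (m^-1), > 0.
#' @seealso [alphaFromTransport()]
#' @export
setClass("TransportProperties",
    representation(Lp = "numeric", k = "numeric", SV = "numeric"))

setValidity("TransportProperties", function(object) {
    msgs <- c(.chkPos(object@Lp, "Lp"), .chkPos(object@k, "k"),
              .chkPos(object@SV, "SV"))
    if (length(msgs)) msgs else TRUE
})

#' @param Lp,k,SV see slots.
#' @rdname TransportProperties-class
#' @export
TransportProperties <- function(Lp, k, SV)
    new("TransportProperties", Lp = Lp, k = k, SV = SV)

#' Fluid-pressure profile parameters
#'
#' Parameterizes the compression-induced interstitial fluid pressure profile
#' \eqn{p(r) = \Psi (1 - \sinh(\alpha r) / (r \sinh\alpha))} of a spherical
#' poroelastic tumor under creep compression, with \eqn{r = R/a} the
#' normalized radius. \eqn{\Psi} may alternatively be given through the
#' source constant \eqn{W} with \eqn{\Psi = W/\alpha^2}. The center (peak)
#' pressure is \eqn{P_0 = \Psi (1 - \alpha\,\mathrm{cosech}\,\alpha)}.
#'
#' @slot alpha dimensionless spatial-distribution parameter, > 0.
#' @slot psi amplitude \eqn{\Psi} (kPa).
#' @slot a tumor radius (mm), > 0.
#' @slot w optional source constant W (kPa); \code{NA_real_} when unset.
#' @export
setClass("PressureProfileParams",
    representation(alpha = "numeric", psi = "numeric", a = "numeric",
                   w = "numeric"),
    prototype(w = NA_real_))

setValidity("PressureProfileParams", function(object) {
    msgs <- c(.chkPos(object@alpha, "alpha"), .chkPos(object@a, "a"),
              .chkFinite(object@psi, "psi"))
    if (length(msgs)) return(msgs)
    if (!is.na(object@w)) {
        want <- object@w / object@alpha^2
        if (abs(object@psi - want) >
            1e-12 * max(abs(want), .Machine$double.xmin))
            return("psi must equal w / alpha^2 (relative 1e-12)")
    }
    ## P0/psi lies in [0, 1); at very large alpha it rounds to 1.0
    p0rel <- 1 - stableCosechTerm(object@alpha)
    if (!(p0rel >= 0 && p0rel <= 1))
        return("derived P0/psi outside [0, 1)")
    TRUE
})

#' @param alpha,psi,a,w see slots; give exactly one of \code{psi}, \code{w}
#'   (when only \code{w} is given, \code{psi} is derived as \code{w/alpha^2}).
#' @rdname PressureProfileParams-class
#' @export
PressureProfileParams <- function(alpha, psi = NULL, a = 1, w = NULL) {
    if (is.null(psi)) {
        if (is.null(w))
            stop("one of 'psi' or 'w' is required")
        psi <- w / alpha^2
    }
    new("PressureProfileParams", alpha = alpha, psi = psi, a = a,
        w = if (is.null(w)) NA_real_ else w)
}

#' Growth-induced stress profile parameters
#'
#' Boundary (\eqn{\Omega_{bR}}, \eqn{\Omega_{bT}}) and peak-related
#' (\eqn{\Omega_{pR}}, \eqn{\Omega_{pT}}) amplitudes of the radial and
#' circumferential growth-induced solid-stress profiles
#' \eqn{\sigma^g(r) = -\Omega_b - \Omega_p (1 - \sinh(\alpha r)/(r\sinh\alpha))}.
#' The center (peak) stresses are
#' \eqn{S = -\Omega_b - \Omega_p (1 - \alpha\,\mathrm{cosech}\,\alpha)}.
#'
#' @slot omegaBR,omegaPR radial boundary / peak amplitudes (kPa).
#' @slot omegaBT,omegaPT circumferential boundary / peak amplitudes (kPa).
#' @slot alpha dimensionless spatial-distribution parameter, > 0.
#' @slot a tumor radius (mm), > 0.
#' @export
setClass("GrowthStressParams",
    representation(omegaBR = "numeric", omegaPR = "numeric",
                   omegaBT = "numeric", omegaPT = "numeric",
                   alpha = "numeric", a = "numeric"),
    prototype(a = 1))

setValidity("GrowthStressParams", function(object) {
    msgs <- c(.chkPos(object@alpha, "alpha"), .chkPos(object@a, "a"),
              .chkFinite(object@omegaBR, "omegaBR"),
              .chkFinite(object@omegaPR, "omegaPR"),
              .chkFinite(object@omegaBT, "omegaBT"),
              .chkFinite(object@omegaPT, "omegaPT"))
    if (length(msgs)) return(msgs)
    peak <- 1 - stableCosechTerm(object@alpha)
    sR <- -object@omegaBR - object@omegaPR * peak
    sT <- -object@omegaBT - object@omegaPT * peak
    if (!is.finite(sR) || !is.finite(sT))
        return("derived peak stresses are not finite")
    TRUE
})

#' @param omegaBR,omegaPR,omegaBT,omegaPT,alpha,a see slots.
#' @rdname GrowthStressParams-class
#' @export
GrowthStressParams <- function(omegaBR, omegaPR, omegaBT, omegaPT,
                               alpha, a = 1)
    new("GrowthStressParams", omegaBR = omegaBR, omegaPR = omegaPR,
        omegaBT = omegaBT, omegaPT = omegaPT, alpha = alpha, a = a)

#' Radial profile of a scalar field
#'
#' Samples of a stress / pressure / SSn field along the normalized radius
#' \eqn{r = R/a \in [0, 1]} of a spherical tumor. \code{counts} carries
#' per-sample pixel counts when the profile was extracted from a 2-D map by
#' annular binning (0 marks an empty annulus, whose value is \code{NA}).
#'
#' @slot r normalized radii, strictly ascending in [0, 1].
#' @slot values field samples (kPa or dimensionless); \code{NA} in empty bins.
#' @slot units unit label ("kPa" or "dimensionless").
#' @slot counts per-sample observation counts (1 for analytic samples).
#' @export
setClass("RadialProfile",
    representation(r = "numeric", values = "numeric", units = "character",
                   counts = "numeric"))

setValidity("RadialProfile", function(object) {
    r <- object@r
    if (length(r) == 0L) return("profile is empty")
    if (length(object@values) != length(r))
        return("lengths of r and values differ")
    if (length(object@counts) != length(r))
        return("lengths of r and counts differ")
    if (anyNA(r) || any(r < 0) || any(r > 1))
        return("r must lie in [0, 1]")
    if (is.unsorted(r, strictly = TRUE))
        return("r must be strictly ascending")
    if (any(!is.finite(object@values) & object@counts > 0))
        return("non-finite value in a non-empty bin")
    TRUE
})

#' @param r,values,units,counts see slots.
#' @rdname RadialProfile-class
#' @export
RadialProfile <- function(r, values, units = "kPa",
                          counts = rep(1, length(r)))
    new("RadialProfile", r = as.numeric(r), values = as.numeric(values),
        units = units, counts = as.numeric(counts))

#' Elastic properties of a tissue
#'
#' Drained Young's modulus and Poisson's ratio, as estimated by
#' elastography, used by the Eshelby equivalent-inclusion computation of
#' boundary stresses.
#'
#' @slot E Young's modulus (kPa), > 0.
#' @slot nu Poisson's ratio, in [0, 0.5).
#' @export
setClass("ElasticProperties", representation(E = "numeric", nu = "numeric"))

setValidity("ElasticProperties", function(object) {
    msgs <- .chkPos(object@E, "E")
    if (length(object@nu) != 1L || !is.finite(object@nu) ||
        object@nu < 0 || object@nu >= 0.5)
        msgs <- c(msgs, "nu must lie in [0, 0.5) (nu >= 0.5 is incompressible)")
    if (length(msgs)) msgs else TRUE
})

#' @param E,nu see slots.
#' @rdname ElasticProperties-class
#' @export
ElasticProperties <- function(E, nu) new("ElasticProperties", E = E, nu = nu)

#' Axisymmetric stress tensor in cylindrical coordinates
#'
#' The four independent components of an axisymmetric stress state in
#' cylindrical coordinates (r, phi, z), compression negative. The uniform
#' interior field of a spherical inclusion under an axisymmetric remote
#' load has \code{srz = 0}.
#'
#' @slot srr,sphiphi,szz,srz stress components (kPa).
#' @export
setClass("CylStressTensor",
    representation(srr = "numeric", sphiphi = "numeric", szz = "numeric",
                   srz = "numeric"),
    prototype(srz = 0))

setValidity("CylStressTensor", function(object) {
    msgs <- c(.chkFinite(object@srr, "srr"),
              .chkFinite(object@sphiphi, "sphiphi"),
              .chkFinite(object@szz, "szz"), .chkFinite(object@srz, "srz"))
    if (length(msgs)) msgs else TRUE
})

#' @param srr,sphiphi,szz,srz see slots.
#' @rdname CylStressTensor-class
#' @export
CylStressTensor <- function(srr, sphiphi, szz, srz = 0)
    new("CylStressTensor", srr = srr, sphiphi = sphiphi, szz = szz, srz = srz)

#' Boundary stress scalars
#'
#' The radial and circumferential (polar) compression-induced solid-stress
#' scalars at the tumor boundary, \eqn{\sigma_{RR}^a} and
#' \eqn{\sigma_{\theta\theta}^a}, which offset the interior stress profiles.
#'
#' @slot sRRa radial boundary stress (kPa).
#' @slot sThTha circumferential (polar) boundary stress (kPa).
#' @seealso [boundaryStressScalars()]
#' @export
setClass("BoundaryStress",
    representation(sRRa = "numeric", sThTha = "numeric"))

setValidity("BoundaryStress", function(object) {
    msgs <- c(.chkFinite(object@sRRa, "sRRa"),
              .chkFinite(object@sThTha, "sThTha"))
    if (length(msgs)) msgs else TRUE
})

#' @param sRRa,sThTha see slots.
#' @rdname BoundaryStress-class
#' @export
BoundaryStress <- function(sRRa, sThTha)
    new("BoundaryStress", sRRa = sRRa, sThTha = sThTha)

#' 2-D scalar field map
#'
#' A 2-D axisymmetric image of a stress / pressure / SSn field with pixel
#' spacing, a unit label, an optional inclusion-membership mask and free-form
#' metadata (provenance, diagnostics). Out-of-mask pixels of derived maps
#' (e.g. SSn) are \code{NaN}.
#'
#' @slot values numeric matrix of field values.
#' @slot pixelMm pixel spacing (mm), > 0.
#' @slot units unit label.
#' @slot mask logical matrix of inclusion membership (same shape), or a
#'   0-by-0 matrix when absent.
#' @slot metadata named list of free-form metadata.
#' @export
setClass("ScalarMap",
    representation(values = "matrix", pixelMm = "numeric",
                   units = "character", mask = "matrix", metadata = "list"),
    prototype(mask = matrix(logical(0), 0, 0), metadata = list()))

setValidity("ScalarMap", function(object) {
    if (!is.numeric(object@values))
        return("values must be a numeric matrix")
    if (any(is.infinite(object@values)))
        return("values must not be infinite")
    msgs <- .chkPos(object@pixelMm, "pixelMm")
    if (length(msgs)) return(msgs)
    if (length(object@mask)) {
        if (!identical(dim(object@mask), dim(object@values)))
            return("mask shape must equal values shape")
        if (!is.logical(object@mask))
            return("mask must be logical")
        if (any(!is.finite(object@values[object@mask])))
            return("in-mask values must be finite")
    }
    TRUE
})

#' @param values,pixelMm,units,mask,metadata see slots.
#' @rdname ScalarMap-class
#' @export
ScalarMap <- function(values, pixelMm, units = "kPa", mask = NULL,
                      metadata = list()) {
    if (is.null(mask)) mask <- matrix(logical(0), 0, 0)
    new("ScalarMap", values = values, pixelMm = pixelMm, units = units,
        mask = mask, metadata = metadata)
}

#' Phantom configuration
#'
#' Configuration of the synthetic creep-compression stress-map phantom: a
#' spherical poroelastic inclusion, imaged in a plane through its center,
#' whose interior radial stress follows the closed-form compression-stress
#' model plus additive Gaussian noise at a prescribed SNR.
#'
#' @slot gridShape integer (rows, cols) of the pixel grid.
#' @slot pixelMm pixel spacing (mm).
#' @slot centerMm inclusion center (x, y) in mm.
#' @slot radiusMm inclusion radius a (mm).
#' @slot pressureParams a [PressureProfileParams-class] (its \code{a} is the
#'   inclusion radius).
#' @slot boundary a [BoundaryStress-class].
#' @slot backgroundValueKpa constant value outside the inclusion (kPa).
#' @slot snrDb additive-noise SNR in dB (\code{Inf} for noiseless).
#' @slot seed RNG seed (integer).
#' @export
setClass("PhantomConfig",
    representation(gridShape = "integer", pixelMm = "numeric",
                   centerMm = "numeric", radiusMm = "numeric",
                   pressureParams = "PressureProfileParams",
                   boundary = "BoundaryStress",
                   backgroundValueKpa = "numeric", snrDb = "numeric",
                   seed = "integer"))

setValidity("PhantomConfig", function(object) {
    if (length(object@gridShape) != 2L || any(object@gridShape < 1L))
        return("gridShape must be two positive integers")
    msgs <- c(.chkPos(object@pixelMm, "pixelMm"),
              .chkPos(object@radiusMm, "radiusMm"),
              .chkFinite(object@backgroundValueKpa, "backgroundValueKpa"))
    if (length(msgs)) return(msgs)
    if (length(object@centerMm) != 2L || any(!is.finite(object@centerMm)))
        return("centerMm must be two finite numbers")
    if (is.na(object@snrDb) || is.nan(object@snrDb))
        return("snrDb must be a number or Inf")
    ext <- object@gridShape[c(2L, 1L)] * object@pixelMm  # (x, y) extent
    if (any(object@centerMm - object@radiusMm < 0) ||
        any(object@centerMm + object@radiusMm > ext))
        return("inclusion must lie fully inside the grid")
    TRUE
})

#' @param gridShape,pixelMm,centerMm,radiusMm,pressureParams,boundary
#'   see slots.
#' @param backgroundValueKpa,snrDb,seed see slots.
#' @rdname PhantomConfig-class
#' @export
PhantomConfig <- function(gridShape = c(96L, 96L), pixelMm = 0.25,
                          centerMm = NULL, radiusMm = 8,
                          pressureParams = PressureProfileParams(
                              alpha = 5, psi = 1, a = radiusMm),
                          boundary = BoundaryStress(sRRa = -1.2,
                                                    sThTha = -0.75),
                          backgroundValueKpa = 0, snrDb = 20, seed = 1L) {
    gridShape <- as.integer(gridShape)
    if (is.null(centerMm))
        centerMm <- gridShape[c(2L, 1L)] * pixelMm / 2
    new("PhantomConfig", gridShape = gridShape, pixelMm = pixelMm,
        centerMm = centerMm, radiusMm = radiusMm,
        pressureParams = pressureParams, boundary = boundary,
        backgroundValueKpa = backgroundValueKpa, snrDb = snrDb,
        seed = as.integer(seed))
}

#' Longitudinal cohort specification
#'
#' Specification of a synthetic treated/untreated longitudinal cohort of
#' per-tumor alpha estimates: alpha follows a geometric weekly trajectory
#' per arm (growing in the untreated arm, shrinking under treatment) and
#' observations carry multiplicative lognormal measurement noise.
#'
#' @slot nPerArm tumors per arm.
#' @slot weeks number of weekly sessions.
#' @slot alphaStart week-1 true alpha, shared by both arms.
#' @slot weeklyMultiplierUntreated weekly geometric factor, untreated (> 1).
#' @slot weeklyMultiplierTreated weekly geometric factor, treated (< 1).
#' @slot subjectLognormalSd sd of log-scale multiplicative noise (>= 0).
#' @slot seed RNG seed (integer).
#' @export
setClass("CohortSpec",
    representation(nPerArm = "integer", weeks = "integer",
                   alphaStart = "numeric",
                   weeklyMultiplierUntreated = "numeric",
                   weeklyMultiplierTreated = "numeric",
                   subjectLognormalSd = "numeric", seed = "integer"))

setValidity("CohortSpec", function(object) {
    msgs <- c(.chkPos(object@alphaStart, "alphaStart"),
              .chkPos(object@weeklyMultiplierUntreated,
                      "weeklyMultiplierUntreated"),
              .chkPos(object@weeklyMultiplierTreated,
                      "weeklyMultiplierTreated"))
    if (object@nPerArm < 1L) msgs <- c(msgs, "nPerArm must be >= 1")
    if (object@weeks < 1L) msgs <- c(msgs, "weeks must be >= 1")
    if (!is.finite(object@subjectLognormalSd) ||
        object@subjectLognormalSd < 0)
        msgs <- c(msgs, "subjectLognormalSd must be >= 0")
    if (length(msgs)) msgs else TRUE
})

#' @param nPerArm,weeks,alphaStart,weeklyMultiplierUntreated see slots.
#' @param weeklyMultiplierTreated,subjectLognormalSd,seed see slots.
#' @rdname CohortSpec-class
#' @export
CohortSpec <- function(nPerArm = 6L, weeks = 3L, alphaStart = 3,
                       weeklyMultiplierUntreated = 1.5,
                       weeklyMultiplierTreated = 0.7,
                       subjectLognormalSd = 0.1, seed = 0L)
    new("CohortSpec", nPerArm = as.integer(nPerArm),
        weeks = as.integer(weeks), alphaStart = alphaStart,
        weeklyMultiplierUntreated = weeklyMultiplierUntreated,
        weeklyMultiplierTreated = weeklyMultiplierTreated,
        subjectLognormalSd = subjectLognormalSd, seed = as.integer(seed))

#' Result of an alpha fit
#'
#' The fitted spatial-distribution parameter alpha, profile amplitude and
#' boundary offset, the implied peak SSn, and residual diagnostics from
#' fitting the closed-form SSn shape to a measured radial stress profile.
#' \code{flags} may contain \code{"non_identifiable"} (flat profile) or
#' \code{"saturated"} (profile contrast so high that alpha is only
#' lower-bound identifiable).
#'
#' @slot alphaHat fitted alpha (dimensionless).
#' @slot amplitudeHat fitted amplitude \eqn{\Psi} (kPa).
#' @slot boundaryHat fitted boundary stress \eqn{\sigma_{RR}^a} (kPa).
#' @slot ssnPeakHat peak SSn, \eqn{1 - \hat\alpha\,\mathrm{cosech}\,\hat\alpha}.
#' @slot rss weighted residual sum of squares.
#' @slot nBins number of non-empty profile bins used.
#' @slot converged logical convergence flag.
#' @slot flags character vector of diagnostic flags.
#' @slot mode fit mode, \code{"free_scale"} or \code{"known_scale"}.
#' @export
setClass("RecoveryResult",
    representation(alphaHat = "numeric", amplitudeHat = "numeric",
                   boundaryHat = "numeric", ssnPeakHat = "numeric",
                   rss = "numeric", nBins = "integer",
                   converged = "logical", flags = "character",
                   mode = "character"))

setValidity("RecoveryResult", function(object) {
    if (is.finite(object@rss) && object@rss < 0)
        return("rss must be >= 0")
    if (is.finite(object@alphaHat)) {
        want <- peakSSn(object@alphaHat)
        if (abs(object@ssnPeakHat - want) > 1e-12 * max(1, abs(want)))
            return("ssnPeakHat inconsistent with alphaHat")
    }
    TRUE
})
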