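## Boundary stress scalars sigma_RR^a, sigma_thth^a from the applied
## uniaxial creep pressure and the tumor/background elastic contrast:
## Eshelby equivalent-inclusion interior stress of a spherical
## inhomogeneity, rotated from cylindrical to spherical components and
## reduced to scalars over the sphere surface.

## Isotropic stiffness acting on the normal-strain triple (no shears are
## excited by an axisymmetric remote load on a sphere).
.stiffNormal <- function(E, nu) {
    lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
    mu <- E / (2 * (1 + nu))
    matrix(lam, 3, 3) + diag(2 * mu, 3)
}

## Eshelby tensor of a sphere restricted to normal components: diagonal
## S1111 = (7 - 5 nu) / (15 (1 - nu)), off-diagonal
## S1122 = (5 nu - 1) / (15 (1 - nu)); nu is the matrix Poisson ratio.
.eshelbyNormal <- function(nu) {
    d <- (7 - 5 * nu) / (15 * (1 - nu))
    o <- (5 * nu - 1) / (15 * (1 - nu))
    matrix(o, 3, 3) + diag(d - o, 3)
}

#' Interior stress of a spherical inhomogeneity under remote uniaxial load
#'
#' Uniform stress inside a spherical elastic inhomogeneity (the tumor)
#' perfectly bonded to an infinite matrix (background tissue) under a
#' remote uniaxial stress along z, computed by the Eshelby
#' equivalent-inclusion method with the closed-form spherical Eshelby
#' tensor. The interior field is uniform, so it transfers directly to the
#' tumor boundary. Compression is negative.
#'
#' @param sigmaApplied remote uniaxial stress along z (kPa); a creep
#'   pressure of P kPa enters as `-P`.
#' @param incl a [ElasticProperties-class] for the inclusion (tumor).
#' @param bg a [ElasticProperties-class] for the background.
#' @return a [CylStressTensor-class]; `srz = 0` and `srr = sphiphi` by
#'   symmetry.
#' @examples
#' tiss <- ElasticProperties(E = 10, nu = 0.3)
#' eshelbyInteriorStress(-1, tiss, tiss)  # homogeneous: remote stress
#' @export
eshelbyInteriorStress <- function(sigmaApplied, incl, bg) {
    stopifnot(is(incl, "ElasticProperties"), is(bg, "ElasticProperties"))
    if (!is.finite(sigmaApplied))
        stop("'sigmaApplied' must be finite")
    Cm <- .stiffNormal(bg@E, bg@nu)
    Ci <- .stiffNormal(incl@E, incl@nu)
    S <- .eshelbyNormal(bg@nu)
    sigmaInf <- c(0, 0, sigmaApplied)           # (xx, yy, zz)
    epsInf <- solve(Cm, sigmaInf)
    dC <- Ci - Cm
    ## [(Ci - Cm) S + Cm] eps* = -(Ci - Cm) epsInf
    epsStar <- solve(dC %*% S + Cm, -dC %*% epsInf)
    sigmaIn <- sigmaInf + Cm %*% ((S - diag(3)) %*% epsStar)
    CylStressTensor(srr = sigmaIn[1], sphiphi = sigmaIn[2],
                    szz = sigmaIn[3], srz = 0)
}

#' Cylindrical to spherical stress components
#'
#' Rotates an axisymmetric cylindrical stress state to spherical components
#' at polar angle theta from the compression (z) axis, by the standard
#' second-order tensor transformation:
#' \deqn{\sigma_{RR} = \sigma_{zz}\cos^2\theta + \sigma_{rr}\sin^2\theta
#'   + 2\sigma_{rz}\sin\theta\cos\theta}
#' \deqn{\sigma_{\theta\theta} = \sigma_{zz}\sin^2\theta +
#'   \sigma_{rr}\cos^2\theta - 2\sigma_{rz}\sin\theta\cos\theta}
#' \deqn{\sigma_{\phi\phi} = \sigma_{\phi\phi}^{cyl}, \quad
#'   \sigma_{R\theta} = (\sigma_{rr}-\sigma_{zz})\sin\theta\cos\theta +
#'   \sigma_{rz}(\cos^2\theta - \sin^2\theta)}
#'
#' @param t a [CylStressTensor-class].
#' @param theta polar angle(s) from the compression axis, radians, in
#'   \eqn{[0, \pi]} (vectorized).
#' @return numeric matrix, one row per theta, columns
#'   `sRR`, `sThTh`, `sPhPh`, `sRTh` (kPa).
#' @export
cylToSphStress <- function(t, theta) {
    stopifnot(is(t, "CylStressTensor"))
    if (any(!is.finite(theta)) || any(theta < 0) || any(theta > pi))
        stop("'theta' must lie in [0, pi]")
    ct <- cos(theta); st <- sin(theta)
    cbind(sRR = t@szz * ct^2 + t@srr * st^2 + 2 * t@srz * st * ct,
          sThTh = t@szz * st^2 + t@srr * ct^2 - 2 * t@srz * st * ct,
          sPhPh = rep(t@sphiphi, length(theta)),
          sRTh = (t@srr - t@szz) * st * ct + t@srz * (ct^2 - st^2))
}

#' Boundary stress scalars from applied load and elastic contrast
#'
#' Composes [eshelbyInteriorStress()] and [cylToSphStress()] and reduces the
#' theta-dependent spherical components to the single scalars
#' \eqn{\sigma_{RR}^a}, \eqn{\sigma_{\theta\theta}^a} required by the
#' spherically symmetric stress model. The default reduction
#' `"angle_average"` is the surface-area-weighted mean over the sphere
#' (weight \eqn{\sin\theta\,d\theta}), for which
#' \eqn{\overline{\cos^2\theta} = 1/3}; `"axis"` and `"equator"` evaluate
#' at \eqn{\theta = 0} and \eqn{\theta = \pi/2}.
#'
#' @param sigmaApplied remote uniaxial stress (kPa), compression negative.
#' @param incl,bg [ElasticProperties-class] of inclusion and background.
#' @param reduction `"angle_average"`, `"axis"` or `"equator"`.
#' @return a [BoundaryStress-class].
#' @examples
#' t1 <- ElasticProperties(E = 20, nu = 0.3)
#' t2 <- ElasticProperties(E = 10, nu = 0.3)
#' boundaryStressScalars(-2, t1, t2)
#' @export
boundaryStressScalars <- function(sigmaApplied, incl, bg,
                                  reduction = c("angle_average", "axis",
                                                "equator")) {
    if (is.character(reduction) &&
        length(reduction) == 1L &&
        !reduction %in% c("angle_average", "axis", "equator"))
        stop("unknown reduction keyword: '", reduction, "'")
    reduction <- match.arg(reduction)
    t <- eshelbyInteriorStress(sigmaApplied, incl, bg)
    switch(reduction,
        angle_average = {
            ## E[cos^2] = 1/3, E[sin^2] = 2/3 under sin(theta) weighting
            BoundaryStress(sRRa = t@szz / 3 + 2 * t@srr / 3,
                           sThTha = 2 * t@szz / 3 + t@srr / 3)
        },
        axis = {
            s <- cylToSphStress(t, 0)
            BoundaryStress(sRRa = unname(s[1, "sRR"]),
                           sThTha = unname(s[1, "sThTh"]))
        },
        equator = {
            s <- cylToSphStress(t, pi / 2)
            BoundaryStress(sRRa = unname(s[1, "sRR"]),
                           sThTha = unname(s[1, "sThTh"]))
        })
}
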