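## Closed-form forward model: compression-induced fluid pressure, solid
## stress, growth-induced stress, SSn and peak SSn as functions of the
## normalized radius r = R/a. All profiles share the kernel
## sinh(alpha r) / (r sinh alpha), evaluated in an overflow-free form.

## sinh(alpha r) / (r sinh alpha) via exp-differences:
## exp((r-1) alpha) * (1 - exp(-2 alpha r)) / (r * (1 - exp(-2 alpha))).
## Mathematically identical, finite for alpha up to ~1e300. At r = 0 the
## analytic limit is alpha cosech(alpha); a series is used below r = 1e-8.
.sinhRatio <- function(alpha, r) {
    out <- numeric(length(r))
    tiny <- r < 1e-8
    if (any(tiny))
        out[tiny] <- stableCosechTerm(alpha) * (1 + (alpha * r[tiny])^2 / 6)
    if (any(!tiny)) {
        rr <- r[!tiny]
        out[!tiny] <- exp((rr - 1) * alpha) * (-expm1(-2 * alpha * rr)) /
            (rr * (-expm1(-2 * alpha)))
    }
    out
}

## alpha * cosech(alpha) = 2 alpha exp(-alpha) / (1 - exp(-2 alpha)),
## overflow-free; series for alpha -> 0.
stableCosechTerm <- function(alpha) {
    if (alpha < 1e-4)
        return(1 - alpha^2 / 6 + 7 * alpha^4 / 360)
    2 * alpha * exp(-alpha) / (-expm1(-2 * alpha))
}

.checkRadii <- function(r) {
    if (anyNA(r) || any(r < 0) || any(r > 1))
        stop("normalized radii must lie in [0, 1]")
    invisible(r)
}

#' Spatial-distribution parameter alpha from transport properties
#'
#' Computes \eqn{\alpha = a \sqrt{(L_p / k) (S/V)}}, the dimensionless
#' parameter governing how sharply interstitial fluid pressure and solid
#' stress concentrate towards the tumor center. Inputs must be
#' unit-consistent: `a` in the length unit whose inverse square is carried
#' by `(Lp/k) SV` (SI: metres).
#'
#' @param a tumor radius (length), > 0.
#' @param tp a [TransportProperties-class] object.
#' @return alpha (dimensionless), strictly increasing in `a`.
#' @examples
#' alphaFromTransport(1, TransportProperties(Lp = 1, k = 1, SV = 1))
#' @export
alphaFromTransport <- function(a, tp) {
    stopifnot(is(tp, "TransportProperties"))
    if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0)
        stop("'a' must be a single strictly positive finite number")
    a * sqrt((tp@Lp / tp@k) * tp@SV)
}

#' Compression-induced fluid pressure profile
#'
#' Evaluates the creep-compression interstitial fluid-pressure profile of a
#' spherical poroelastic tumor,
#' \eqn{p(r) = \Psi (1 - \sinh(\alpha r) / (r \sinh\alpha))}, on a grid of
#' normalized radii. The profile is zero at the boundary (r = 1) and peaks
#' at the center with \eqn{P_0 = \Psi (1 - \alpha\,\mathrm{cosech}\,\alpha)}.
#'
#' @param p a [PressureProfileParams-class] object.
#' @param r normalized radii in [0, 1], strictly ascending.
#' @return a [RadialProfile-class] in kPa.
#' @examples
#' pp <- PressureProfileParams(alpha = 3, psi = 1)
#' fluidPressureProfile(pp, seq(0, 1, length.out = 11))
#' @export
fluidPressureProfile <- function(p, r) {
    stopifnot(is(p, "PressureProfileParams"))
    .checkRadii(r)
    RadialProfile(r, p@psi * (1 - .sinhRatio(p@alpha, r)), units = "kPa")
}

#' Compression-induced solid stress profiles
#'
#' Radial and circumferential compression-induced solid stress inside the
#' tumor: the boundary stress scalars offset by the fluid-pressure profile,
#' \eqn{\sigma^c_{RR}(r) = \sigma^a_{RR} - p(r)} and
#' \eqn{\sigma^c_{\theta\theta}(r) = \sigma^a_{\theta\theta} - p(r)}. Both
#' equal their boundary scalars at r = 1 since p(1) = 0.
#'
#' @param b a [BoundaryStress-class] object.
#' @param p a [PressureProfileParams-class] object.
#' @param r normalized radii in [0, 1].
#' @return list with [RadialProfile-class] elements `radial` and
#'   `circumferential` (kPa).
#' @export
compressionStressProfiles <- function(b, p, r) {
    stopifnot(is(b, "BoundaryStress"))
    pr <- fluidPressureProfile(p, r)
    list(radial = RadialProfile(r, b@sRRa - pr@values, units = "kPa"),
         circumferential = RadialProfile(r, b@sThTha - pr@values,
                                         units = "kPa"))
}

#' Growth-induced solid stress profiles
#'
#' Radial and circumferential growth-induced solid stress,
#' \eqn{\sigma^g(r) = -\Omega_b - \Omega_p (1 - \sinh(\alpha r)/(r\sinh\alpha))},
#' with the radial (\eqn{\Omega_{bR}, \Omega_{pR}}) and circumferential
#' (\eqn{\Omega_{bT}, \Omega_{pT}}) amplitude pairs. The boundary values
#' (r = 1) are \eqn{-\Omega_{bR}} and \eqn{-\Omega_{bT}}; the center values
#' are the peak stresses \eqn{S_R}, \eqn{S_T}.
#'
#' @param g a [GrowthStressParams-class] object.
#' @param r normalized radii in [0, 1].
#' @return list with [RadialProfile-class] elements `radial` and
#'   `circumferential` (kPa).
#' @examples
#' g <- GrowthStressParams(omegaBR = 0.4, omegaPR = 0.2,
#'                         omegaBT = 0, omegaPT = 0.6, alpha = 33)
#' growthStressProfiles(g, c(0, 0.5, 1))
#' @export
growthStressProfiles <- function(g, r) {
    stopifnot(is(g, "GrowthStressParams"))
    .checkRadii(r)
    shape <- 1 - .sinhRatio(g@alpha, r)
    list(radial = RadialProfile(r, -g@omegaBR - g@omegaPR * shape,
                                units = "kPa"),
         circumferential = RadialProfile(r, -g@omegaBT - g@omegaPT * shape,
                                         units = "kPa"))
}

#' Normalized solid stress profile
#'
#' The dimensionless normalized solid stress
#' \eqn{SS_n(r) = 1 - \sinh(\alpha r) / (r \sinh\alpha)}: the spatial
#' distribution shared by growth-induced and compression-induced solid
#' stress in a spherical tumor. Zero at the boundary, maximal
#' (\eqn{1 - \alpha\,\mathrm{cosech}\,\alpha}) at the center, strictly
#' decreasing in r.
#'
#' @param alpha dimensionless spatial-distribution parameter, > 0.
#' @param r normalized radii in [0, 1].
#' @return a [RadialProfile-class], dimensionless.
#' @examples
#' ssnProfile(3, c(0, 0.5, 1))
#' @export
ssnProfile <- function(alpha, r) {
    if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
        alpha <= 0)
        stop("'alpha' must be a single strictly positive finite number")
    .checkRadii(r)
    RadialProfile(r, 1 - .sinhRatio(alpha, r), units = "dimensionless")
}

#' Peak normalized solid stress
#'
#' \eqn{SS_{n,p} = 1 - \alpha\,\mathrm{cosech}(\alpha)}: the center value of
#' the normalized solid stress. Strictly increasing in alpha, tending to 0
#' as alpha tends to 0 and to 1 as alpha tends to infinity; overflow-safe
#' for arbitrarily large alpha.
#'
#' @param alpha dimensionless spatial-distribution parameter(s), > 0
#'   (vectorized).
#' @return peak SSn in [0, 1).
#' @examples
#' peakSSn(c(0.3, 3, 33))
#' @export
peakSSn <- function(alpha) {
    if (!is.numeric(alpha) || anyNA(alpha) || any(alpha <= 0))
        stop("'alpha' must be strictly positive")
    vapply(alpha, function(a) 1 - stableCosechTerm(a), numeric(1))
}

#' Normalize a growth-stress profile to SSn
#'
#' Applies the normalization \eqn{(\sigma^g + \Omega_b) / (-\Omega_p)} to
#' the growth-stress profile of the chosen component, yielding the
#' dimensionless SSn profile. By construction this equals
#' [ssnProfile()] at the same alpha for either component; the identity is
#' the model's statement that radial and circumferential solid stress share
#' one spatial distribution.
#'
#' @param g a [GrowthStressParams-class] object; the peak amplitude of the
#'   chosen component must be nonzero.
#' @param r normalized radii in [0, 1].
#' @param component `"radial"` or `"circumferential"`.
#' @return a [RadialProfile-class], dimensionless.
#' @export
normalizeGrowthProfile <- function(g, r,
                                   component = c("radial",
                                                 "circumferential")) {
    component <- match.arg(component)
    omegaB <- if (component == "radial") g@omegaBR else g@omegaBT
    omegaP <- if (component == "radial") g@omegaPR else g@omegaPT
    if (omegaP == 0)
        stop("degenerate normalization: zero peak amplitude for the ",
             component, " component")
    prof <- growthStressProfiles(g, r)[[component]]
    RadialProfile(r, (prof@values + omegaB) / (-omegaP),
                  units = "dimensionless")
}
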