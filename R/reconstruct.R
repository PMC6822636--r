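## Imaging pipeline: 2-D compression-stress map + mask -> annular-binned
## radial profile -> bounded multi-start least-squares fit of the SSn
## shape (alpha, and optionally the scale pair sigma_a, Psi) -> SSn map
## and peak SSn.

#' Extract a radial profile from a 2-D map
#'
#' Bins in-mask pixels by their normalized distance \eqn{\rho/a} from the
#' inclusion center into `nBins` equal-width annuli over [0, 1] and returns
#' the per-bin mean value, the per-bin mean normalized radius (a better
#' abscissa than the bin midpoint) and the pixel count. Empty annuli keep
#' the bin midpoint as abscissa, an `NA` value and a count of 0.
#'
#' @param map a [ScalarMap-class]. When a mask is present only in-mask
#'   pixels are used; otherwise all pixels within `radius` of `center`.
#' @param center inclusion center (x, y) in mm; default from map metadata,
#'   else the mask centroid.
#' @param radius inclusion radius a (mm); default from map metadata, else
#'   the equivalent-area radius of the mask.
#' @param nBins number of annuli, >= 4.
#' @return a [RadialProfile-class] with `counts`.
#' @export
extractRadialProfile <- function(map, center = NULL, radius = NULL,
                                 nBins = 15L) {
    stopifnot(is(map, "ScalarMap"))
    if (nBins < 4L) stop("'nBins' must be >= 4")
    hasMask <- length(map@mask) > 0L
    if (is.null(center)) {
        center <- map@metadata$centerMm
        if (is.null(center)) {
            if (!hasMask)
                stop("'center' required when the map has no mask/metadata")
            idx <- which(map@mask, arr.ind = TRUE)
            center <- c((mean(idx[, 2]) - 0.5) * map@pixelMm,
                        (mean(idx[, 1]) - 0.5) * map@pixelMm)
        }
    }
    if (is.null(radius)) {
        radius <- map@metadata$radiusMm
        if (is.null(radius)) {
            if (!hasMask)
                stop("'radius' required when the map has no mask/metadata")
            radius <- sqrt(sum(map@mask) / pi) * map@pixelMm
        }
    }
    if (radius <= 0) stop("'radius' must be > 0")
    rho <- .pixelRho(dim(map@values), map@pixelMm, center)
    sel <- if (hasMask) map@mask & rho <= radius else rho <= radius
    if (!any(sel)) stop("no pixel falls inside the inclusion geometry")
    rn <- rho[sel] / radius
    v <- map@values[sel]
    bin <- pmin(pmax(ceiling(rn * nBins), 1L), nBins)
    counts <- tabulate(bin, nBins)
    sums <- vapply(seq_len(nBins), function(b) sum(v[bin == b]), numeric(1))
    rsums <- vapply(seq_len(nBins), function(b) sum(rn[bin == b]), numeric(1))
    mid <- (seq_len(nBins) - 0.5) / nBins
    rOut <- ifelse(counts > 0, rsums / pmax(counts, 1), mid)
    vOut <- ifelse(counts > 0, sums / pmax(counts, 1), NA_real_)
    ord <- order(rOut)
    RadialProfile(rOut[ord], vOut[ord], units = map@units,
                  counts = counts[ord])
}

## Weighted RSS of the SSn shape against observations at radii r.
## free scale: for fixed alpha profile out (sigma_a, psi) by weighted
## linear LS of v ~ 1 - psi * S(alpha, r); returns list(rss, sigmaA, psi).
.profiledRss <- function(logAlpha, r, v, w, mode, known) {
    S <- 1 - .sinhRatio(exp(logAlpha), r)
    if (mode == "known_scale") {
        obs <- (v - known[1]) / (-known[2])
        return(list(rss = sum(w * (obs - S)^2), sigmaA = known[1],
                    psi = known[2]))
    }
    ## design: v = sigmaA - psi * S
    X <- cbind(1, -S)
    fit <- stats::lm.wfit(X, v, w)
    co <- unname(fit$coefficients)
    if (anyNA(co)) {             # collinear (flat shape): psi unresolved
        co <- c(stats::weighted.mean(v, w), 0)
        res <- v - co[1]
        return(list(rss = sum(w * res^2), sigmaA = co[1], psi = 0))
    }
    list(rss = sum(w * fit$residuals^2), sigmaA = co[1], psi = co[2])
}

#' Fit the spatial-distribution parameter alpha to a radial profile
#'
#' Bounded multi-start nonlinear least squares of the closed-form SSn shape
#' against a measured radial stress profile. In `"known_scale"` mode the
#' profile is first normalized with the supplied boundary stress and
#' amplitude, \eqn{SS_n^{obs}(r) = (\sigma^c(r) - \sigma_a)/(-\Psi)}, and
#' only alpha is fitted; in `"free_scale"` mode \eqn{(\sigma_a, \Psi)} are
#' profiled out by weighted linear least squares at each candidate alpha, so
#' the search is one-dimensional in \eqn{\log\alpha} either way. Nine fixed
#' log-spaced starts over the alpha bounds make the fit deterministic; ties
#' resolve to the smallest alpha. Bins are weighted by pixel counts; empty
#' bins are dropped.
#'
#' @param profile a [RadialProfile-class] with at least 4 non-empty bins.
#' @param mode `"free_scale"` (default) or `"known_scale"`.
#' @param known for `"known_scale"`: numeric `c(sigmaA, psi)` (kPa).
#' @param alphaBounds search interval for alpha.
#' @return a [RecoveryResult-class]. A flat (non-identifiable) profile
#'   yields `converged = FALSE` with flag `"non_identifiable"`, never an
#'   error; a center-to-boundary contrast beyond 0.99 adds flag
#'   `"saturated"` (alpha then only lower-bound identifiable).
#' @examples
#' prof <- ssnProfile(5, seq(0.05, 0.95, length.out = 15))
#' prof@values <- -1 - 1 * prof@values   # sigma_a = -1, psi = 1
#' fitAlpha(prof)
#' @export
fitAlpha <- function(profile, mode = c("free_scale", "known_scale"),
                     known = NULL, alphaBounds = c(1e-3, 1e3)) {
    stopifnot(is(profile, "RadialProfile"))
    mode <- match.arg(mode)
    if (mode == "known_scale") {
        if (is.null(known) || length(known) != 2L || any(!is.finite(known)))
            stop("'known' = c(sigmaA, psi) is required in known_scale mode")
        if (known[2] == 0) stop("degenerate normalization: psi = 0")
    }
    keep <- profile@counts > 0 & is.finite(profile@values)
    r <- profile@r[keep]; v <- profile@values[keep]
    w <- profile@counts[keep]
    if (length(r) < 4L)
        stop("at least 4 non-empty profile bins are required")
    lb <- log(alphaBounds[1]); ub <- log(alphaBounds[2])
    obj <- function(la) .profiledRss(la, r, v, w, mode, known)$rss
    starts <- seq(lb, ub, length.out = 9L)
    best <- NULL
    anyConv <- FALSE
    for (s in starts) {
        o <- tryCatch(
            stats::nlminb(s, obj, lower = lb, upper = ub,
                          control = list(abs.tol = 0, rel.tol = 1e-14,
                                         x.tol = 1e-12, iter.max = 500L)),
            error = function(e) NULL)
        if (is.null(o) || !is.finite(o$objective)) next
        anyConv <- anyConv || o$convergence == 0L
        if (is.null(best) ||
            o$objective < best$objective * (1 - 1e-12) ||
            (abs(o$objective - best$objective) <=
                 1e-12 * max(best$objective, 1e-300) && o$par < best$par))
            best <- o
    }
    if (is.null(best))
        return(new("RecoveryResult", alphaHat = NA_real_,
                   amplitudeHat = NA_real_, boundaryHat = NA_real_,
                   ssnPeakHat = NA_real_, rss = NA_real_,
                   nBins = length(r), converged = FALSE,
                   flags = "optimizer_failure", mode = mode))
    alphaHat <- exp(best$par)
    sol <- .profiledRss(best$par, r, v, w, mode, known)
    flags <- character(0)
    converged <- anyConv
    ## identifiability: profile contrast must exceed numerical noise
    span <- diff(range(v))
    if (mode == "free_scale" &&
        (abs(sol$psi) < 1e-10 * max(1, abs(sol$sigmaA)) || span == 0)) {
        flags <- c(flags, "non_identifiable")
        converged <- FALSE
    }
    pk <- peakSSn(alphaHat)
    if (pk > 0.99)
        flags <- c(flags, "saturated")
    new("RecoveryResult", alphaHat = alphaHat,
        amplitudeHat = sol$psi, boundaryHat = sol$sigmaA,
        ssnPeakHat = pk, rss = sol$rss, nBins = length(r),
        converged = converged, flags = flags, mode = mode)
}

#' Normalized solid stress map
#'
#' Maps every in-mask pixel of a compression-stress map to SSn via the
#' fitted scale, \eqn{(\sigma^c - \hat\sigma_a)/(-\hat\Psi)}. Out-of-mask
#' pixels are set to `NaN` and flagged in the metadata; values outside
#' [-0.2, 1.2] are reported in `metadata$fracOutside` but never clipped.
#'
#' @param map a [ScalarMap-class] with a mask.
#' @param fit a converged [RecoveryResult-class].
#' @return a dimensionless [ScalarMap-class].
#' @export
ssnMap <- function(map, fit) {
    stopifnot(is(map, "ScalarMap"), is(fit, "RecoveryResult"))
    if (!fit@converged)
        stop("fit did not converge; refusing to build an SSn map")
    if (!length(map@mask))
        stop("'map' must carry an inclusion mask")
    if (!is.finite(fit@amplitudeHat) || abs(fit@amplitudeHat) <
        1e-10 * max(1, abs(fit@boundaryHat)))
        stop("degenerate normalization: fitted amplitude is ~0")
    vals <- matrix(NaN, nrow(map@values), ncol(map@values))
    vals[map@mask] <- (map@values[map@mask] - fit@boundaryHat) /
        (-fit@amplitudeHat)
    inm <- vals[map@mask]
    meta <- map@metadata
    meta$fracOutside <- mean(inm < -0.2 | inm > 1.2)
    meta$outOfMask <- "NaN"
    ScalarMap(vals, pixelMm = map@pixelMm, units = "dimensionless",
              mask = map@mask, metadata = meta)
}
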