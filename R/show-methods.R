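#' @describeIn RadialProfile-class compact display
#' @param object object to display.
#' @export
setMethod("show", "RadialProfile", function(object) {
    cat(sprintf("RadialProfile: %d samples in [%g, %g] (%s)\n",
                length(object@r), min(object@r), max(object@r),
                object@units))
    ne <- object@counts > 0
    if (any(ne))
        cat(sprintf("  value range [%g, %g], %d empty bin(s)\n",
                    min(object@values[ne]), max(object@values[ne]),
                    sum(!ne)))
})

#' @describeIn ScalarMap-class compact display
#' @param object object to display.
#' @export
setMethod("show", "ScalarMap", function(object) {
    d <- dim(object@values)
    cat(sprintf("ScalarMap: %d x %d px @ %g mm (%s)%s\n", d[1], d[2],
                object@pixelMm, object@units,
                if (length(object@mask))
                    sprintf(", mask %d px", sum(object@mask)) else ""))
})

#' @describeIn RecoveryResult-class compact display
#' @param object object to display.
#' @export
setMethod("show", "RecoveryResult", function(object) {
    cat(sprintf(paste0("RecoveryResult (%s): alpha = %.6g, psi = %.6g kPa,",
                       " sigma_a = %.6g kPa\n"),
                object@mode, object@alphaHat, object@amplitudeHat,
                object@boundaryHat))
    cat(sprintf("  peak SSn = %.6g, rss = %.4g over %d bins; converged: %s%s\n",
                object@ssnPeakHat, object@rss, object@nBins,
                object@converged,
                if (length(object@flags))
                    paste0(" [", paste(object@flags, collapse = ", "), "]")
                else ""))
})

#' @describeIn PressureProfileParams-class compact display
#' @param object object to display.
#' @export
setMethod("show", "PressureProfileParams", function(object) {
    cat(sprintf(paste0("PressureProfileParams: alpha = %g, psi = %g kPa,",
                       " a = %g mm (P0 = %g kPa)\n"),
                object@alpha, object@psi, object@a,
                object@psi * peakSSn(object@alpha)))
})

#' @describeIn BoundaryStress-class compact display
#' @param object object to display.
#' @export
setMethod("show", "BoundaryStress", function(object) {
    cat(sprintf("BoundaryStress: sigma_RR^a = %g kPa, sigma_thth^a = %g kPa\n",
                object@sRRa, object@sThTha))
})
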