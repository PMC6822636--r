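## Seeded synthetic-data generators: 2-D axisymmetric creep-compression
## stress maps of a spherical inclusion, and longitudinal treated/untreated
## cohorts of alpha estimates for the statistics stage.

## Run expr with a locally seeded RNG, restoring the caller's RNG state.
withLocalSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
    expr
}

## Pixel-center coordinate grids (mm); x runs along columns, y along rows.
.pixelRho <- function(gridShape, pixelMm, centerMm) {
    y <- (seq_len(gridShape[1]) - 0.5) * pixelMm
    x <- (seq_len(gridShape[2]) - 0.5) * pixelMm
    sqrt(outer((y - centerMm[2])^2, (x - centerMm[1])^2, `+`))
}

#' Generate a synthetic compression-stress map
#'
#' Renders the radial compression-induced solid stress
#' \eqn{\sigma^c_{RR}(\rho/a) = \sigma^a_{RR} - p(\rho/a)} of a spherical
#' inclusion on a pixel grid (imaging plane through the sphere center),
#' with a constant background outside the inclusion, then adds zero-mean
#' Gaussian noise calibrated so that
#' \eqn{10\log_{10}(\mathrm{signal\ power\ in\ mask}/\mathrm{noise\ power})}
#' equals `snrDb` (use `snrDb = Inf` for a noiseless map). Same seed, same
#' map, exactly.
#'
#' @param cfg a [PhantomConfig-class].
#' @return list with elements `map` (a [ScalarMap-class] with inclusion
#'   mask) and `truth` (list of the generating [PressureProfileParams-class]
#'   and [BoundaryStress-class], for recovery experiments).
#' @examples
#' ph <- generateSscMap(PhantomConfig(snrDb = Inf))
#' range(ph$map@values[ph$map@mask])
#' @export
generateSscMap <- function(cfg) {
    stopifnot(is(cfg, "PhantomConfig"))
    a <- cfg@radiusMm
    rho <- .pixelRho(cfg@gridShape, cfg@pixelMm, cfg@centerMm)
    mask <- rho <= a
    if (!any(mask))
        stop("inclusion covers no pixel")
    vals <- matrix(cfg@backgroundValueKpa, cfg@gridShape[1], cfg@gridShape[2])
    rNorm <- pmin(rho[mask] / a, 1)
    p <- cfg@pressureParams
    vals[mask] <- cfg@boundary@sRRa -
        p@psi * (1 - .sinhRatio(p@alpha, rNorm))
    if (is.finite(cfg@snrDb)) {
        sigPow <- mean(vals[mask]^2)
        noiseSd <- sqrt(sigPow / 10^(cfg@snrDb / 10))
        noise <- withLocalSeed(cfg@seed,
            matrix(stats::rnorm(length(vals), sd = noiseSd),
                   nrow(vals), ncol(vals)))
        vals <- vals + noise
    }
    map <- ScalarMap(vals, pixelMm = cfg@pixelMm, units = "kPa",
                     mask = mask,
                     metadata = list(centerMm = cfg@centerMm,
                                     radiusMm = a, snrDb = cfg@snrDb,
                                     seed = cfg@seed))
    list(map = map, truth = list(pressure = p, boundary = cfg@boundary))
}

#' Generate a longitudinal treated/untreated cohort
#'
#' Simulates per-tumor alpha trajectories for an untreated arm (alpha grows
#' by a weekly geometric factor > 1) and a treated arm (factor < 1), with
#' multiplicative lognormal measurement noise on each weekly observation.
#'
#' @param spec a [CohortSpec-class].
#' @return data.frame with columns `arm` ("untreated"/"treated"),
#'   `subject`, `week`, `alpha_true`, `alpha_observed`.
#' @examples
#' head(generateCohort(CohortSpec(seed = 0)))
#' @export
generateCohort <- function(spec) {
    stopifnot(is(spec, "CohortSpec"))
    arms <- c(untreated = spec@weeklyMultiplierUntreated,
              treated = spec@weeklyMultiplierTreated)
    grid <- expand.grid(week = seq_len(spec@weeks),
                        subject = seq_len(spec@nPerArm),
                        arm = names(arms),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid <- grid[order(grid$arm == "treated", grid$subject, grid$week), ]
    alphaTrue <- spec@alphaStart * arms[grid$arm]^(grid$week - 1)
    noise <- withLocalSeed(spec@seed,
        exp(stats::rnorm(nrow(grid), 0, spec@subjectLognormalSd)))
    data.frame(arm = grid$arm,
               subject = paste0(substr(grid$arm, 1, 1), grid$subject),
               week = grid$week,
               alpha_true = unname(alphaTrue),
               alpha_observed = unname(alphaTrue * noise),
               stringsAsFactors = FALSE, row.names = NULL)
}
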