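## Independent oracles, deliberately written via different routes than the
## package implementation.

## Naive sinh-ratio profile (valid for moderate alpha only).
oracleSSn <- function(alpha, r)
    ifelse(r == 0, 1 - alpha / sinh(alpha),
           1 - sinh(alpha * r) / (r * sinh(alpha)))

## Interior stress of a spherical inhomogeneity under remote uniaxial szz,
## by hydrostatic/deviatoric decoupling (Goodier-type closed form): the
## spherical Eshelby operator acts as the scalar S_h = (1+nu)/(3(1-nu)) on
## volumetric strain and S_d = 2(4-5nu)/(15(1-nu)) on deviatoric strain,
## so the equivalent-inclusion equation splits into two scalar equations.
oracleEshelbyUniaxial <- function(sigma, Ei, nui, Em, num) {
    K <- function(E, nu) E / (3 * (1 - 2 * nu))
    G <- function(E, nu) E / (2 * (1 + nu))
    Ki <- K(Ei, nui); Gi <- G(Ei, nui)
    Km <- K(Em, num); Gm <- G(Em, num)
    Sh <- (1 + num) / (3 * (1 - num))
    Sd <- 2 * (4 - 5 * num) / (15 * (1 - num))
    ## remote strain, volumetric (epsV = tr) and deviatoric zz part
    epsV <- sigma / (3 * Km)
    sDevZZ <- sigma * 2 / 3                  # deviator of diag(0,0,sigma)
    epsDevZZ <- sDevZZ / (2 * Gm)
    ## equivalent eigenstrain, each mode: ((Ci-Cm) S + Cm) e* = -(Ci-Cm) eInf
    eStarV <- -(3 * Ki - 3 * Km) * epsV / ((3 * Ki - 3 * Km) * Sh + 3 * Km)
    eStarDevZZ <- -(2 * Gi - 2 * Gm) * epsDevZZ /
        ((2 * Gi - 2 * Gm) * Sd + 2 * Gm)
    ## interior stress = sigmaInf + Cm (S - I) e*, mode by mode
    sInMean <- sigma / 3 + Km * (Sh - 1) * eStarV
    sInDevZZ <- sDevZZ + 2 * Gm * (Sd - 1) * eStarDevZZ
    szz <- sInMean + sInDevZZ
    sxx <- sInMean - sInDevZZ / 2
    c(sxx = sxx, szz = szz)
}

## Spherical components at polar angle theta by explicit basis projection
## of the full 3x3 Cartesian tensor (point taken in the x-z plane).
oracleRotate <- function(srr, sphiphi, szz, srz, theta) {
    S <- matrix(c(srr, 0, srz,
                  0, sphiphi, 0,
                  srz, 0, szz), 3, 3, byrow = TRUE)
    R <- c(sin(theta), 0, cos(theta))
    Th <- c(cos(theta), 0, -sin(theta))
    Ph <- c(0, 1, 0)
    c(sRR = drop(R %*% S %*% R), sThTh = drop(Th %*% S %*% Th),
      sPhPh = drop(Ph %*% S %*% Ph), sRTh = drop(R %*% S %*% Th))
}

## Kruskal-Wallis H by the direct rank-sum formula with tie correction.
oracleKwH <- function(values, labels) {
    rk <- rank(values)
    N <- length(values)
    sp <- split(rk, labels)
    H <- 12 / (N * (N + 1)) *
        sum(vapply(sp, function(g) length(g) * (mean(g) - (N + 1) / 2)^2,
                   numeric(1)))
    tt <- table(rk)
    H / (1 - sum(tt^3 - tt) / (N^3 - N))
}
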