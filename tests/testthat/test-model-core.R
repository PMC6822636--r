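test_that("alpha from transport properties scales as a * sqrt((Lp/k) SV)", {
    tp <- TransportProperties(Lp = 1, k = 1, SV = 1)
    expect_equal(alphaFromTransport(1, tp), 1)
    expect_equal(alphaFromTransport(3, tp), 3)
    tp2 <- TransportProperties(Lp = 2e-11, k = 5e-14, SV = 1e4)
    expect_equal(alphaFromTransport(2, tp2), 2 * alphaFromTransport(1, tp2))
    expect_error(alphaFromTransport(-1, tp), "positive")
    expect_error(TransportProperties(Lp = 0, k = 1, SV = 1), "Lp")
})

test_that("fluid pressure profile matches the closed form and its limits", {
    pp <- PressureProfileParams(alpha = 3, psi = 1)
    prof <- fluidPressureProfile(pp, c(0, 0.5, 1))
    v <- fieldValues(prof)
    expect_equal(v[3], 0, tolerance = 1e-14)           # p(1) = 0
    expect_equal(v[2], 0.5749039651, tolerance = 1e-9) # frozen oracle value
    expect_equal(v[1], 1 - 3 / sinh(3), tolerance = 1e-12)  # P0
    ## psi scales linearly
    pp2 <- PressureProfileParams(alpha = 3, psi = 2.5)
    expect_equal(fieldValues(fluidPressureProfile(pp2, c(0, 0.5, 1))),
                 2.5 * v, tolerance = 1e-12)
    expect_error(fluidPressureProfile(pp, c(-0.1, 0.5)), "\\[0, 1\\]")
})

test_that("psi can be given through the source constant w", {
    pp <- PressureProfileParams(alpha = 4, w = 8)
    expect_equal(pp@psi, 0.5)
    expect_error(PressureProfileParams(alpha = 4, psi = 1, w = 8),
                 "w / alpha")
})

test_that("compression stress offsets the boundary scalars by the pressure", {
    b <- BoundaryStress(sRRa = -1, sThTha = -0.3)
    pp <- PressureProfileParams(alpha = 3, psi = 1)
    pr <- compressionStressProfiles(b, pp, c(0, 0.5, 1))
    expect_equal(fieldValues(pr$radial)[3], -1)        # p(1) = 0
    expect_equal(fieldValues(pr$circumferential)[3], -0.3)
    expect_equal(fieldValues(pr$radial)[2], -1.5749039651, tolerance = 1e-9)
    ## psi = 0 degenerates to constants (use tiny psi = 0 via psi slot)
    pp0 <- PressureProfileParams(alpha = 3, psi = 0)
    pr0 <- compressionStressProfiles(b, pp0, c(0, 0.5, 1))
    expect_equal(fieldValues(pr0$radial), rep(-1, 3))
    expect_equal(fieldValues(pr0$circumferential), rep(-0.3, 3))
})

test_that("growth stress boundary and center values match the amplitudes", {
    g <- GrowthStressParams(omegaBR = 0.4, omegaPR = 0.2,
                            omegaBT = 0, omegaPT = 0.6, alpha = 33)
    pr <- growthStressProfiles(g, c(0, 0.5, 1))
    expect_equal(fieldValues(pr$radial)[3], -0.4)          # -Omega_bR
    expect_equal(fieldValues(pr$circumferential)[3], 0)    # -Omega_bT
    ## center: -0.4 - 0.2 (1 - 33 cosech 33); cosech term ~ 3e-13
    expect_equal(fieldValues(pr$radial)[1], -0.6, tolerance = 1e-10)
    ## zero peak amplitudes give constant profiles
    gc <- GrowthStressParams(0.4, 0, 0.1, 0, alpha = 3)
    prc <- growthStressProfiles(gc, c(0, 0.5, 1))
    expect_equal(fieldValues(prc$radial), rep(-0.4, 3))
    expect_equal(fieldValues(prc$circumferential), rep(-0.1, 3))
})

test_that("SSn profile is zero at the boundary, monotone, in [0, peak]", {
    r <- seq(0, 1, length.out = 201)
    for (alpha in c(0.3, 3, 33)) {
        v <- fieldValues(ssnProfile(alpha, r))
        expect_equal(v[201], 0, tolerance = 1e-14)
        expect_true(all(diff(v) < 0))                  # strictly decreasing
        expect_true(all(v >= 0 & v <= peakSSn(alpha)))
        expect_lt(peakSSn(alpha), 1)
        expect_equal(v, oracleSSn(alpha, r), tolerance = 1e-12)
    }
    expect_equal(fieldValues(ssnProfile(3, c(0.25, 0.5)))[2],
                 0.5749039651, tolerance = 1e-9)
})

test_that("peak SSn matches frozen values and is monotone in alpha", {
    expect_equal(peakSSn(3), 0.7005352910, tolerance = 1e-9)
    expect_equal(peakSSn(0.3), 0.0148439810, tolerance = 1e-9)
    ## strictly increasing wherever doubles can resolve 1 - peak (the
    ## plateau value rounds to 1.0 beyond alpha ~ 40), nondecreasing beyond
    expect_true(all(diff(peakSSn(10^seq(-2, log10(30),
                                        length.out = 50))) > 0))
    expect_true(all(diff(peakSSn(10^seq(-2, 2, length.out = 50))) >= 0))
    ## limits
    expect_lt(peakSSn(1e-8), 1e-10)
    expect_equal(peakSSn(1e4), 1, tolerance = 1e-12)
    expect_error(peakSSn(0), "positive")
})

test_that("small-alpha SSn approaches the parabolic closed form", {
    alpha <- 0.05
    r <- seq(0, 1, length.out = 401)
    v <- fieldValues(ssnProfile(alpha, r))
    approx <- alpha^2 / 6 * (1 - r^2)
    expect_lt(max(abs(v - approx)) / v[1], 1e-3)
})

test_that("profiles stay finite up to alpha = 1e4 (interior plateau at 1)", {
    r <- seq(0, 1, length.out = 101)
    v <- fieldValues(ssnProfile(1e4, r))
    expect_true(all(is.finite(v)))
    expect_equal(v[51], 1, tolerance = 1e-12)          # deep interior
    p <- fluidPressureProfile(PressureProfileParams(alpha = 1e4, psi = 2), r)
    expect_true(all(is.finite(fieldValues(p))))
})

test_that("normalized growth and compression profiles reproduce SSn", {
    r <- seq(0, 1, length.out = 41)
    ## printed radial set equals SSn at alpha 33 elementwise
    g33 <- GrowthStressParams(0.4, 0.2, 0, 0.6, alpha = 33)
    expect_equal(fieldValues(normalizeGrowthProfile(g33, r, "radial")),
                 fieldValues(ssnProfile(33, r)), tolerance = 1e-12)
    ## circumferential normalization gives the same profile as radial
    expect_equal(
        fieldValues(normalizeGrowthProfile(g33, r, "circumferential")),
        fieldValues(normalizeGrowthProfile(g33, r, "radial")),
        tolerance = 1e-12)
    expect_error(normalizeGrowthProfile(
        GrowthStressParams(0.4, 0, 0, 0.6, alpha = 3), r, "radial"),
        "degenerate")

    ## randomized draws: growth and compression normalizations both equal
    ## the SSn shape to 1e-12
    set.seed(42)
    for (i in 1:200) {
        alpha <- 10^runif(1, -1, 1.8)
        ob <- runif(2, -1, 1); op <- runif(2, 0.1, 2)
        g <- GrowthStressParams(ob[1], op[1], ob[2], op[2], alpha)
        ssn <- fieldValues(ssnProfile(alpha, r))
        expect_lt(max(abs(
            fieldValues(normalizeGrowthProfile(g, r, "radial")) - ssn)),
            1e-12)
        expect_lt(max(abs(
            fieldValues(normalizeGrowthProfile(g, r, "circumferential")) -
                ssn)), 1e-12)
        b <- BoundaryStress(runif(1, -3, 0), runif(1, -3, 0))
        pp <- PressureProfileParams(alpha = alpha, psi = runif(1, 0.1, 3))
        cs <- compressionStressProfiles(b, pp, r)
        expect_lt(max(abs(
            (fieldValues(cs$radial) - b@sRRa) / (-pp@psi) - ssn)), 1e-12)
        expect_lt(max(abs(
            (fieldValues(cs$circumferential) - b@sThTha) / (-pp@psi) -
                ssn)), 1e-12)
    }
})

test_that("RadialProfile validates its geometry", {
    expect_error(RadialProfile(c(0.5, 0.2), c(1, 2)), "ascending")
    expect_error(RadialProfile(c(0.2, 1.2), c(1, 2)), "\\[0, 1\\]")
    expect_error(RadialProfile(0.5, NA_real_), "non-finite")
    expect_s4_class(RadialProfile(c(0.2, 0.5), c(NA, 2), counts = c(0, 5)),
                    "RadialProfile")
})
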