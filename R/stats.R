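## Nonparametric cohort statistics: Kruskal-Wallis comparisons (chi-square
## and exact-permutation p) and the per-week per-arm longitudinal summary
## with significance stars.

#' Grouped scalar samples
#'
#' Scalar observations partitioned into named groups, the input of
#' [kruskalWallis()].
#'
#' @slot labels group label per observation.
#' @slot values scalar observation per label.
#' @export
setClass("GroupedSamples",
    representation(labels = "character", values = "numeric"))

setValidity("GroupedSamples", function(object) {
    if (length(object@labels) != length(object@values))
        return("labels and values must have equal length")
    if (any(!is.finite(object@values)))
        return("values must be finite")
    if (length(unique(object@labels)) < 2L)
        return("at least 2 groups are required")
    TRUE
})

#' @param values scalar observations.
#' @param labels group label per observation.
#' @rdname GroupedSamples-class
#' @export
GroupedSamples <- function(values, labels)
    new("GroupedSamples", labels = as.character(labels),
        values = as.numeric(values))

## H on a rank assignment (midranks already computed), with tie correction.
.kwH <- function(rk, grp, tieDiv) {
    N <- length(rk)
    rbar <- tapply(rk, grp, mean)
    ni <- tabulate(grp)
    H <- 12 / (N * (N + 1)) * sum(ni * (rbar - (N + 1) / 2)^2)
    H / tieDiv
}

## Enumerate all distinct assignments of group sizes to positions 1..N and
## return the exact permutation p for H >= observed (with tolerance).
.kwExactP <- function(values, grp) {
    N <- length(values)
    rk <- rank(values)
    tt <- table(rk)
    tieDiv <- 1 - sum(tt^3 - tt) / (N^3 - N)
    sizes <- tabulate(grp)
    Hobs <- .kwH(rk, grp, tieDiv)
    Hs <- numeric(0)
    rec <- function(pos, gi) {
        if (gi == length(sizes)) {
            g <- integer(N); g[] <- length(sizes)
            for (j in seq_along(assigned)) g[assigned[[j]]] <- j
            Hs[[length(Hs) + 1L]] <<- .kwH(rk, g, tieDiv)
            return(invisible())
        }
        cmb <- utils::combn(pos, sizes[gi])
        for (k in seq_len(ncol(cmb))) {
            assigned[[gi]] <<- cmb[, k]
            rec(setdiff(pos, cmb[, k]), gi + 1L)
        }
    }
    assigned <- vector("list", length(sizes))
    rec(seq_len(N), 1L)
    mean(Hs >= Hobs - 1e-12)
}

#' Kruskal-Wallis rank test
#'
#' Kruskal-Wallis one-way comparison of two or more groups, the test used
#' to compare treated and untreated cohorts. The statistic uses midranks
#' with the standard tie-correction divisor
#' \eqn{1 - \sum(t^3 - t)/(N^3 - N)}; the p-value comes from the chi-square
#' upper tail with `groups - 1` degrees of freedom, or from exact
#' enumeration of all group assignments when `exact = TRUE` (available for
#' total N <= 10). Identical values across all groups give H = 0, p = 1.
#'
#' @param g a [GroupedSamples-class] object.
#' @param exact use the exact permutation null (N <= 10 only).
#' @return list with `H`, `df`, `p`, and both `p.chisq` and (when computed)
#'   `p.exact`.
#' @examples
#' g <- GroupedSamples(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
#' kruskalWallis(g)
#' kruskalWallis(g, exact = TRUE)
#' @export
kruskalWallis <- function(g, exact = FALSE) {
    stopifnot(is(g, "GroupedSamples"))
    N <- length(g@values)
    if (N < 3L) stop("total N must be >= 3")
    grp <- as.integer(factor(g@labels))
    df <- length(unique(grp)) - 1L
    if (stats::var(g@values) == 0) {
        out <- list(H = 0, df = df, p = 1, p.chisq = 1)
        if (exact) out$p.exact <- 1
        return(out)
    }
    kt <- stats::kruskal.test(g@values, factor(g@labels))
    H <- unname(kt$statistic)
    pChisq <- unname(kt$p.value)
    out <- list(H = H, df = df, p = pChisq, p.chisq = pChisq)
    if (exact) {
        if (N > 10L)
            stop("exact permutation p is available for N <= 10 only")
        out$p.exact <- .kwExactP(g@values, grp)
        out$p <- out$p.exact
    }
    out
}

.stars <- function(p) {
    if (!is.finite(p)) return(NA_character_)
    if (p < 0.001) "***" else if (p < 0.01) "**"
    else if (p < 0.05) "*" else "n.s."
}

#' Per-week cohort summary with arm comparisons
#'
#' Summarizes a longitudinal cohort per week and arm (mean, sd, n) and
#' compares the two arms within each week by the Kruskal-Wallis test, with
#' significance stars at the 0.05 / 0.01 / 0.001 thresholds ("n.s."
#' otherwise). With `metric = "ssn_peak"` the alpha observations are first
#' transformed to peak SSn via [peakSSn()] (the p-values are unchanged,
#' the transform being strictly monotone). An optional Holm correction
#' across weeks is off by default.
#'
#' @param cohort data.frame with columns `arm`, `week` and the value column.
#' @param metric `"alpha"` or `"ssn_peak"`.
#' @param valueCol name of the value column (default `"alpha_observed"`).
#' @param holm apply a Holm correction across weeks before starring.
#' @return data.frame with one row per week: per-arm mean/sd/n, `H`, `p`,
#'   `stars`. A week present in only one arm gets `NA` comparison columns
#'   and stars `"unavailable"`.
#' @export
weeklySummary <- function(cohort, metric = c("alpha", "ssn_peak"),
                          valueCol = "alpha_observed", holm = FALSE) {
    metric <- match.arg(metric)
    need <- c("arm", "week", valueCol)
    if (!all(need %in% names(cohort)))
        stop("cohort must have columns: ", paste(need, collapse = ", "))
    v <- cohort[[valueCol]]
    if (metric == "ssn_peak") v <- peakSSn(v)
    arms <- sort(unique(cohort$arm))
    weeks <- sort(unique(cohort$week))
    rows <- lapply(weeks, function(wk) {
        sel <- cohort$week == wk
        out <- list(week = wk)
        for (a in arms) {
            va <- v[sel & cohort$arm == a]
            out[[paste0("mean_", a)]] <-
                if (length(va)) mean(va) else NA_real_
            out[[paste0("sd_", a)]] <-
                if (length(va) > 1) stats::sd(va) else NA_real_
            out[[paste0("n_", a)]] <- length(va)
        }
        present <- vapply(arms, function(a) any(sel & cohort$arm == a),
                          logical(1))
        if (sum(present) < 2L) {
            out$H <- NA_real_; out$p <- NA_real_
        } else {
            kw <- kruskalWallis(GroupedSamples(v[sel], cohort$arm[sel]))
            out$H <- kw$H; out$p <- kw$p
        }
        as.data.frame(out)
    })
    res <- do.call(rbind, rows)
    padj <- if (holm) stats::p.adjust(res$p, "holm") else res$p
    res$stars <- vapply(seq_along(padj), function(i) {
        if (is.na(res$p[i])) "unavailable" else .stars(padj[i])
    }, character(1))
    res
}
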