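#' Window the genome and attach hit counts, coverage and recombination rate
#'
#' Splits every chromosome of the genome into non-overlapping windows of
#' `windowSize` bp (default 250 kb; the last window of a chromosome may be
#' shorter and is flagged), then attaches per window: the number of hits
#' whose start lies in the window (each hit counted once), the bp covered
#' by the union of hit intervals clipped to the window (bp conserved across
#' window boundaries), and the length-weighted mean recombination rate of
#' the map windows overlapping it.  Chromosomes absent from the map get
#' `rate = NA` and are flagged so fits can exclude them.
#'
#' @param genome A [GenomeSet-class].
#' @param hits `GRanges` of satellite hits.
#' @param map Recombination map `GRanges` with a `rate` column (cM/Mb), as
#'   from [readRecombMap()]; `NULL` leaves rates `NA`.
#' @param windowSize Window size in bp (default 250000).
#' @return A `GRanges` with metadata columns `rate`, `hit_count`,
#'   `covered_bp`, `short` and `rate_missing`.
#' @export
makeWindows <- function(genome, hits, map = NULL, windowSize = 250000) {
    stopifnot(windowSize > 0)
    lens <- chromLengths(genome)
    pieces <- lapply(names(lens), function(chrom) {
        s <- seq(1, lens[[chrom]], by = windowSize)
        GRanges(factor(chrom, levels = names(lens)),
                IRanges(s, pmin(s + windowSize - 1, lens[[chrom]])))
    })
    win <- do.call(c, pieces)
    mcols(win)$short <- width(win) < windowSize

    starts <- GenomicRanges::resize(hits, width = 1L, fix = "start",
                                    ignore.strand = TRUE)
    mcols(win)$hit_count <- GenomicRanges::countOverlaps(
        win, starts, ignore.strand = TRUE)

    covered <- numeric(length(win))
    if (length(hits)) {
        red <- reduce(hits, ignore.strand = TRUE)
        ov <- GenomicRanges::findOverlaps(win, red, ignore.strand = TRUE)
        if (length(ov)) {
            w <- width(IRanges::pintersect(
                IRanges::ranges(win)[S4Vectors::queryHits(ov)],
                IRanges::ranges(red)[S4Vectors::subjectHits(ov)]))
            agg <- tapply(w, S4Vectors::queryHits(ov), sum)
            covered[as.integer(names(agg))] <- agg
        }
    }
    mcols(win)$covered_bp <- covered

    rate <- rep(NA_real_, length(win))
    if (!is.null(map) && length(map)) {
        ov <- GenomicRanges::findOverlaps(win, map, ignore.strand = TRUE)
        if (length(ov)) {
            w <- width(IRanges::pintersect(
                IRanges::ranges(win)[S4Vectors::queryHits(ov)],
                IRanges::ranges(map)[S4Vectors::subjectHits(ov)]))
            r <- mcols(map)$rate[S4Vectors::subjectHits(ov)]
            qh <- S4Vectors::queryHits(ov)
            num <- tapply(w * r, qh, sum)
            den <- tapply(w, qh, sum)
            rate[as.integer(names(num))] <- num / den
        }
    }
    mcols(win)$rate <- rate
    mcols(win)$rate_missing <- is.na(rate)
    # reorder mcols for readability
    mcols(win) <- mcols(win)[, c("rate", "hit_count", "covered_bp", "short",
                                 "rate_missing")]
    win
}

#' Fit the exponential satellite-density model
#'
#' Fits `response = exp(a + b * rate)` over genome windows by Poisson
#' regression with a log link (the form handles zero-count windows and
#' matches the exponential model directly).  For `response = "hits"` the
#' response is the per-window hit count; for `"coverage"` it is the
#' covered bp with `log(window length)` as exposure offset, so the
#' intercept is log coverage *fraction* at rate 0.  A log-least-squares
#' mode (`log(y + 1)` against rate) is provided for sensitivity
#' comparison.
#'
#' @param windows `GRanges` from [makeWindows()]; windows with `NA` rate
#'   are excluded.
#' @param response `"hits"` or `"coverage"`.
#' @param method `"poisson"` (default) or `"loglsq"`.
#' @return An [ExponentialFit-class].
#' @export
fitExponential <- function(windows, response = c("hits", "coverage"),
                           method = c("poisson", "loglsq")) {
    response <- match.arg(response)
    method <- match.arg(method)
    rate <- mcols(windows)$rate
    keep <- !is.na(rate)
    windows <- windows[keep]
    rate <- rate[keep]
    if (length(windows) < 3L)
        stop("need at least 3 windows with a defined recombination rate")
    y <- if (response == "hits") mcols(windows)$hit_count
         else mcols(windows)$covered_bp
    if (all(y == 0))
        stop("degenerate fit: all responses are zero")
    if (length(unique(rate)) == 1L)
        stop("degenerate fit: all rates equal, slope unidentifiable")
    expo <- log(width(windows))
    if (method == "poisson") {
        fit <- if (response == "coverage")
            stats::glm(y ~ rate, family = stats::poisson(),
                       offset = expo)
        else stats::glm(y ~ rate, family = stats::poisson())
        co <- stats::coef(fit)
        se <- sqrt(diag(stats::vcov(fit)))
    } else {
        fit <- if (response == "coverage")
            stats::lm(log(y + 1) ~ rate, offset = expo)
        else stats::lm(log(y + 1) ~ rate)
        co <- stats::coef(fit)
        se <- sqrt(diag(stats::vcov(fit)))
    }
    new("ExponentialFit", response = response,
        intercept = unname(co[1L]), slope = unname(co[2L]),
        se = unname(se), nWindows = length(windows), method = method)
}

#' @describeIn fitExponential Coefficients `c(intercept, slope)`.
#' @param object An `ExponentialFit`.
#' @param ... Ignored.
#' @export
setMethod("coef", "ExponentialFit", function(object, ...) {
    c(intercept = object@intercept, slope = object@slope)
})

#' @describeIn fitExponential Standard errors of the coefficients.
#' @export
fitSE <- function(object) {
    stats::setNames(object@se, c("intercept", "slope"))
}

#' @describeIn fitExponential Expected response at given rates.
#' @param rate Numeric vector of recombination rates (cM/Mb).
#' @export
predictResponse <- function(object, rate) {
    exp(object@intercept + object@slope * rate)
}

setMethod("show", "ExponentialFit", function(object) {
    cat("ExponentialFit (", object@method, "): ", object@response,
        " = e^(", signif(object@intercept, 4),
        if (object@slope >= 0) " + " else " - ",
        signif(abs(object@slope), 4), " * rate)\n",
        "  SE: (", signif(object@se[1L], 3), ", ", signif(object@se[2L], 3),
        "); n = ", object@nWindows, " windows\n", sep = "")
})

#' Predict the focal/background coverage ratio from the fitted model
#'
#' Under the exponential model the expected focal/background density ratio
#' depends only on the slope and the median recombination rates:
#' \deqn{ratio = e^{b (c \cdot \tilde r_{focal} - \tilde r_{background})}}
#' where `c` is a correction on the focal rate (default 4/3, compensating
#' the smaller effective population size of an X chromosome relative to
#' autosomes); the intercept cancels.
#'
#' @param fit An [ExponentialFit-class], or a numeric slope `b`.
#' @param medianFocal,medianBackground Median per-window recombination
#'   rates (cM/Mb) of the focal and background chromosomes.
#' @param correction Multiplier applied to the focal median (default 4/3).
#' @return A list with `median_focal`, `median_background`, `correction`,
#'   `slope` and `predicted_ratio`.
#'
#' @examples
#' predictRatio(1.98, 3.32, 2.78)$predicted_ratio  # ~26.1
#' @export
predictRatio <- function(fit, medianFocal, medianBackground,
                         correction = 4 / 3) {
    stopifnot(medianFocal >= 0, medianBackground >= 0)
    b <- if (methods::is(fit, "ExponentialFit")) fit@slope else as.numeric(fit)
    list(median_focal = medianFocal, median_background = medianBackground,
         correction = correction, slope = b,
         predicted_ratio = exp(b * (correction * medianFocal -
                                    medianBackground)))
}

#' Median per-window recombination rates by group
#'
#' One unweighted value per window (windows with `NA` rate excluded).
#'
#' @param windows `GRanges` from [makeWindows()].
#' @param genome The [GenomeSet-class] (supplies the focal/background
#'   partition).
#' @return A list with numeric `focal` and `background` medians.
#' @export
windowMedianRates <- function(windows, genome) {
    grp <- chromGroup(genome)
    g <- grp[as.character(seqnames(windows))]
    r <- mcols(windows)$rate
    list(focal = stats::median(r[g == "focal"], na.rm = TRUE),
         background = stats::median(r[g == "background"], na.rm = TRUE))
}

#' Rank correlation of satellite abundance with recombination rate
#'
#' Spearman correlation (two-sided) of the per-window response against the
#' window recombination rate, reported alongside the exponential fit.
#'
#' @param windows `GRanges` from [makeWindows()].
#' @param response `"hits"` or `"coverage"`.
#' @return A list with `rho`, `p_value`, `n` and `flag` (`NA`, or an
#'   explanation when the correlation is undefined).
#' @export
correlationReport <- function(windows, response = c("hits", "coverage")) {
    response <- match.arg(response)
    rate <- mcols(windows)$rate
    keep <- !is.na(rate)
    y <- if (response == "hits") mcols(windows)$hit_count[keep]
         else mcols(windows)$covered_bp[keep]
    rate <- rate[keep]
    if (length(rate) < 5L)
        stop("need at least 5 windows with a defined rate")
    if (length(unique(y)) == 1L)
        return(list(rho = NA_real_, p_value = NA_real_, n = length(y),
                    flag = "constant response; correlation undefined"))
    ct <- suppressWarnings(stats::cor.test(y, rate, method = "spearman",
                                           exact = FALSE))
    list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(y),
         flag = NA_character_)
}
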