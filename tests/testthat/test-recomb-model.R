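mkgenome <- function(Lx = 1e6, La = 5e5) {
    GenomeSet(focal = c(X = strrep("A", Lx)),
              background = c(A = strrep("C", La)))
}

test_that("window tiling, the start rule and coverage clipping hold", {
    gs <- mkgenome()
    map <- recombMap(c("X", "X", "X", "X", "A", "A"),
                     c(0, 250000, 500000, 750000, 0, 250000),
                     c(250000, 500000, 750000, 1e6, 250000, 5e5),
                     rep(3.0, 6))
    # a hit straddling the window-1/window-2 boundary: [249900, 250200)
    hits <- GRanges("X", IRanges(249901, 250200))
    win <- makeWindows(gs, hits, map)
    expect_length(win, 6L)                         # 4 on X + 2 on A
    winX <- win[seqnames(win) == "X"]
    expect_equal(mcols(winX)$hit_count, c(1L, 0L, 0L, 0L))   # start rule
    expect_equal(mcols(winX)$covered_bp, c(100, 200, 0, 0))  # clipped bp
    expect_equal(mcols(win)$rate, rep(3.0, 6))               # uniform map
    expect_false(any(mcols(win)$short))

    # totals conserved across windows
    expect_equal(sum(mcols(win)$hit_count), length(hits))
    expect_equal(sum(mcols(win)$covered_bp),
                 sum(width(reduce(hits))))
})

test_that("a trailing short window is flagged and bookkeeping still conserves", {
    gs <- GenomeSet(focal = c(X = strrep("A", 620000)),
                    background = c(A = strrep("C", 250000)))
    set.seed(26)
    hits <- GRanges("X", IRanges(sort(sample.int(6e5, 50)), width = 359))
    win <- makeWindows(gs, hits, map = NULL)
    winX <- win[seqnames(win) == "X"]
    expect_equal(width(winX), c(250000, 250000, 120000))
    expect_equal(mcols(winX)$short, c(FALSE, FALSE, TRUE))
    expect_true(all(mcols(win)$rate_missing))
    expect_equal(sum(mcols(win)$hit_count), 50L)
    expect_equal(sum(mcols(win)$covered_bp), sum(width(reduce(hits))))
})

test_that("windows on chromosomes missing from the map are excluded from fits", {
    gs <- mkgenome()
    map <- recombMap(rep("X", 4), c(0, 250000, 500000, 750000),
                     c(250000, 500000, 750000, 1e6), c(1, 2, 3, 4))
    set.seed(27)
    hits <- GRanges("A", IRanges(sample.int(4e5, 30), width = 100))
    win <- makeWindows(gs, hits, map)
    expect_true(all(mcols(win[seqnames(win) == "A"])$rate_missing))
    # only the A windows carry hits, so the X-only fit is degenerate
    expect_error(fitExponential(win, "hits"), "zero")
})

test_that("rate averaging is length-weighted over overlapping map windows", {
    gs <- GenomeSet(focal = c(X = strrep("A", 250000)),
                    background = c(A = strrep("C", 250000)))
    map <- recombMap(c("X", "X", "A"), c(0, 100000, 0),
                     c(100000, 250000, 250000), c(1.0, 4.0, 2.0))
    win <- makeWindows(gs, GRanges(), map)
    expect_equal(mcols(win)$rate[1], (100000 * 1 + 150000 * 4) / 250000)
    expect_equal(mcols(win)$rate[2], 2.0)
})

test_that("a constant response fits a zero slope and log-mean intercept", {
    win <- GRanges("X", IRanges((0:19) * 250000 + 1, width = 250000),
                   rate = seq(0.5, 5, length.out = 20), hit_count = 5L,
                   covered_bp = 500)
    fit <- fitExponential(win, "hits")
    expect_lt(abs(fit@slope), 1e-8)
    expect_equal(fit@intercept, log(5), tolerance = 1e-6)
    expect_equal(unname(coef(fit)), c(fit@intercept, fit@slope))
})

test_that("degenerate designs are rejected", {
    win <- GRanges("X", IRanges((0:9) * 1000 + 1, width = 1000),
                   rate = rep(2, 10), hit_count = rpois(10, 3),
                   covered_bp = 0)
    expect_error(fitExponential(win, "hits"), "rates equal")
    win2 <- GRanges("X", IRanges((0:9) * 1000 + 1, width = 1000),
                    rate = 1:10, hit_count = 0L, covered_bp = 0)
    expect_error(fitExponential(win2, "hits"), "zero")
    expect_error(fitExponential(win2[1:2], "hits"), "at least 3")
})

test_that("noise-free exponential data is recovered to high precision", {
    rate <- seq(0, 5, length.out = 400)
    y <- round(exp(3 + 1.2 * rate))
    win <- GRanges("X", IRanges(seq_along(rate) * 250000 + 1, width = 250000),
                   rate = rate, hit_count = y, covered_bp = y)
    fit <- fitExponential(win, "hits")
    expect_equal(fit@intercept, 3, tolerance = 1e-3)
    expect_equal(fit@slope, 1.2, tolerance = 1e-3)
})

test_that("the coverage response uses window length as exposure", {
    # coverage fraction exactly exp(-5 + 0.8 r): covered_bp = frac * width
    rate <- seq(0.2, 4, length.out = 300)
    w <- 250000
    covered <- round(exp(-5 + 0.8 * rate) * w)
    win <- GRanges("X", IRanges(seq_along(rate) * w + 1, width = w),
                   rate = rate, hit_count = 0L, covered_bp = covered)
    fit <- fitExponential(win, "coverage")
    expect_equal(fit@intercept, -5, tolerance = 1e-3)
    expect_equal(fit@slope, 0.8, tolerance = 1e-3)
})

test_that("predicted coverage ratios depend only on the slope", {
    # equal medians with no correction: ratio 1, for any fit
    expect_equal(predictRatio(1.98, 3, 3, correction = 1)$predicted_ratio, 1)
    # zero slope: ratio 1 regardless of rates
    expect_equal(predictRatio(0, 3.32, 2.78)$predicted_ratio, 1)
    # the printed-medians case evaluates by direct formula
    res <- predictRatio(1.98, 3.32, 2.78)
    expect_equal(res$predicted_ratio, exp(1.98 * (4 / 3 * 3.32 - 2.78)),
                 tolerance = 1e-12)
    expect_equal(round(res$predicted_ratio, 1), 26.1)

    fit1 <- methods::new("ExponentialFit", response = "coverage",
                         intercept = -11.82, slope = 1.98, se = c(1, 0.1),
                         nWindows = 100L, method = "poisson")
    fit2 <- methods::initialize(fit1, intercept = 5)
    expect_equal(predictRatio(fit1, 3.32, 2.78)$predicted_ratio,
                 predictRatio(fit2, 3.32, 2.78)$predicted_ratio)
})

test_that("median window rates split by chromosome group", {
    gs <- mkgenome(1e6, 5e5)
    map <- recombMap(c(rep("X", 4), rep("A", 2)),
                     c(0, 250000, 500000, 750000, 0, 250000),
                     c(250000, 500000, 750000, 1e6, 250000, 5e5),
                     c(3, 4, 5, 2, 1, 2))
    win <- makeWindows(gs, GRanges(), map)
    med <- windowMedianRates(win, gs)
    expect_equal(med$focal, 3.5)
    expect_equal(med$background, 1.5)
})

test_that("rank correlation reports follow the response", {
    win <- GRanges("X", IRanges((0:9) * 1000 + 1, width = 1000),
                   rate = 1:10, hit_count = (1:10)^2, covered_bp = 1:10)
    rep_ <- correlationReport(win, "hits")
    expect_equal(rep_$rho, 1)
    expect_lt(rep_$p_value, 0.01)

    win2 <- GRanges("X", IRanges((0:9) * 1000 + 1, width = 1000),
                    rate = 1:10, hit_count = 7L, covered_bp = 0)
    expect_match(correlationReport(win2, "hits")$flag, "constant")

    # power at the generating slope over many windows
    set.seed(28)
    rate <- stats::runif(400, 0, 3)
    y <- stats::rpois(400, exp(-4.56 + 2.14 * rate))
    win3 <- GRanges("X", IRanges(seq_along(rate) * 1000 + 1, width = 1000),
                    rate = rate, hit_count = y, covered_bp = y)
    rep3 <- correlationReport(win3, "hits")
    expect_gt(rep3$rho, 0)
    expect_lt(rep3$p_value, 0.01)
})

test_that("null data produce near-nominal correlation p-values", {
    set.seed(29)
    pvals <- vapply(1:200, function(i) {
        rate <- stats::runif(40, 0, 5)
        y <- stats::rpois(40, 3)
        win <- GRanges("X", IRanges(seq_along(rate) * 1000 + 1,
                                    width = 1000),
                       rate = rate, hit_count = y, covered_bp = y)
        correlationReport(win, "hits")$p_value
    }, numeric(1))
    expect_gt(mean(pvals < 0.05), 0.005)
    expect_lt(mean(pvals < 0.05), 0.15)
})
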