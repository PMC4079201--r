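test_that("overlapping counting, N handling and canonical pooling are exact", {
    # 16 bp homopolymer: 16 - 13 + 1 overlapping windows
    tab <- countKmers(c(chr = "AAAAAAAAAAAAAAAA"), k = 13)
    expect_equal(kmerCounts(tab), c(AAAAAAAAAAAAA = 4))

    # windows spanning an N are absent on both sides
    tab <- countKmers("ACGTNACGT", k = 4, canonical = FALSE)
    expect_setequal(names(kmerCounts(tab)), c("ACGT"))
    expect_equal(unname(kmerCounts(tab)["ACGT"]), 2)

    # canonical pooling merges a k-mer with its reverse complement
    tab <- countKmers("AACCGGTT", k = 8, canonical = TRUE)
    expect_equal(kmerCounts(tab), c(AACCGGTT = 1))
    tabBoth <- countKmers(c(a = "AAACCC", b = "GGGTTT"), k = 6,
                          canonical = TRUE)
    expect_equal(kmerCounts(tabBoth), c(AAACCC = 2))

    # k longer than every sequence: empty table with warning
    expect_warning(empty <- countKmers("ACGT", k = 13), "empty")
    expect_length(empty@code, 0L)
})

test_that("counting matches the brute-force substring oracle", {
    set.seed(42)
    for (rep in 1:8) {
        s <- rand_dna(sample(60:2000, 1))
        if (rep %% 2 == 0)  # plant an N to exercise gap handling
            substr(s, nchar(s) %/% 2, nchar(s) %/% 2) <- "N"
        for (k in c(1L, 2L, 13L)) for (canon in c(TRUE, FALSE)) {
            got <- kmerCounts(countKmers(s, k = k, canonical = canon))
            want <- brute_count(s, k, canonical = canon)
            expect_equal(got[order(names(got))], want[order(names(want))])
        }
    }
})

test_that("the relative-frequency formula and its edge cases are honored", {
    expect_equal(relativeFrequency(10, 2, 1e6, 2e6), 10)
    # normalization identity: equal counts, focal length 0.34 x background
    expect_equal(round(relativeFrequency(1, 1, 0.34e6, 1e6), 2), 2.94)
    # zero background count replaced by 1
    expect_equal(relativeFrequency(3, 0, 1e6, 1e6), 3)
})

test_that("identical focal and background sequences profile flat at 1", {
    set.seed(1)
    s <- rand_dna(3000)
    gs <- GenomeSet(focal = c(X = s), background = c(A = s))
    prof <- relativeProfile(gs)
    expect_equal(length(prof), 3000 - 13 + 1)
    expect_true(all(prof@ratio == 1))
    expect_false(any(prof@backgroundAbsent))
    sm <- profileSummary(prof)
    expect_equal(sm$max_ratio, 1)
    expect_equal(sm$fraction_above_1, 0)
})

test_that("swapping focal and background inverts every finite ratio", {
    set.seed(2)
    a <- rand_dna(2000)
    b <- paste0(substr(a, 1, 800), rand_dna(1500))  # shared + private k-mers
    g1 <- GenomeSet(focal = c(A = a), background = c(B = b))
    g2 <- GenomeSet(focal = c(B = b), background = c(A = a))
    d1 <- as.data.frame(relativeProfile(g1))
    d2 <- as.data.frame(relativeProfile(g2))
    d1 <- d1[!d1$background_absent, ]
    m <- match(d1$kmer, d2$kmer)
    expect_false(anyNA(m))
    expect_equal(d1$ratio, 1 / d2$ratio[m], tolerance = 1e-12)
})

test_that("duplicating the background leaves every ratio unchanged", {
    set.seed(3)
    a <- rand_dna(1500)
    b <- paste0(substr(a, 1, 700), rand_dna(1800))  # shared k-mers exist
    g1 <- GenomeSet(focal = c(X = a), background = c(A = b))
    g2 <- GenomeSet(focal = c(X = a), background = c(A = b, A2 = b))
    p1 <- relativeProfile(g1)
    p2 <- relativeProfile(g2)
    expect_equal(p1@backgroundAbsent, p2@backgroundAbsent)
    # invariance applies where the background count actually doubles; at
    # background-absent positions the sentinel denominator does not scale
    present <- !p1@backgroundAbsent
    expect_true(any(present))
    expect_equal(p1@ratio[present], p2@ratio[present], tolerance = 1e-12)
})

test_that("background-absent k-mers are flagged and kept", {
    gs <- GenomeSet(focal = c(X = paste0(strrep("ACGGT", 20), "TTTTTTTTTTTTTTT")),
                    background = c(A = strrep("ACGGT", 40)))
    prof <- relativeProfile(gs, k = 13)
    df <- as.data.frame(prof)
    poly <- df[df$kmer == "AAAAAAAAAAAAA", ]   # canonical form of T13
    expect_true(nrow(poly) > 0)
    expect_true(all(poly$background_absent))
    expect_equal(poly$ratio,
                 poly$k_focal * prof@Lbackground / prof@Lfocal)
})

test_that("mismatched count tables are rejected", {
    gs <- GenomeSet(focal = c(X = rand_dna(200)),
                    background = c(A = rand_dna(200)))
    t13 <- countKmers(gs, k = 13, group = "focal")
    t11 <- countKmers(gs, k = 11, group = "background")
    expect_error(relativeProfile(gs, focalTable = t13, backgroundTable = t11),
                 "different k")
    tGiven <- countKmers(gs, k = 13, canonical = FALSE, group = "background")
    expect_error(relativeProfile(gs, focalTable = t13,
                                 backgroundTable = tGiven),
                 "strand")
})

test_that("profile summaries recompute from values and handle empties", {
    prof <- mk_profile(0:99, c(rep(0.5, 50), rep(30, 40), rep(150, 10)))
    sm <- profileSummary(prof, thresholds = c(1, 20, 100))
    expect_equal(sm$max_ratio, 150)
    expect_equal(sm$fraction_above_1, 0.5)
    expect_equal(unname(sm$n_above), c(50L, 50L, 10L))
    # counts monotonically non-increasing in the threshold
    expect_true(all(diff(sm$n_above) <= 0))

    emptyProf <- restrictProfile(prof, 1000, 2000)
    sme <- profileSummary(emptyProf)
    expect_equal(sme$n_positions, 0L)
    expect_true(is.na(sme$max_ratio))
})

test_that("matched-composition autosome-vs-autosome profiles are flat", {
    set.seed(4)
    gs <- GenomeSet(focal = c(A1 = rand_dna(60000)),
                    background = c(A2 = rand_dna(60000)))
    prof <- relativeProfile(gs)
    expect_lt(abs(stats::median(prof@ratio) - 1), 0.25)
    expect_gte(stats::median(prof@ratio), 0.8)
    expect_lte(stats::median(prof@ratio), 1.25)
})
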