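plant <- function(background, insert, at) {
    substr(background, at, at + nchar(insert) - 1L) <- insert
    background
}

test_that("a verbatim planted monomer yields exactly one perfect hit", {
    set.seed(15)
    unit <- rand_dna(359)
    chrom <- plant(rand_dna(1e5), unit, 40001)
    gs <- GenomeSet(focal = c(X = chrom), background = c(A = rand_dna(5e4)))
    hits <- searchMonomer(unit, gs)
    hitsX <- hits[seqnames(hits) == "X"]
    expect_length(hitsX, 1L)
    expect_equal(start(hitsX), 40001)
    expect_equal(end(hitsX), 40001 + 358)
    expect_equal(mcols(hitsX)$identity, 1.0)
    expect_equal(as.character(strand(hitsX)), "+")
    expect_lt(mcols(hitsX)$evalue, 1e-4)
})

test_that("a reverse-complement insertion is found on the minus strand", {
    set.seed(16)
    unit <- rand_dna(359)
    chrom <- plant(rand_dna(5e4), revcomp_str(unit), 20001)
    gs <- GenomeSet(focal = c(X = chrom), background = c(A = rand_dna(2e4)))
    hits <- searchMonomer(unit, gs)
    hitsX <- hits[seqnames(hits) == "X"]
    expect_length(hitsX, 1L)
    expect_equal(as.character(strand(hitsX)), "-")
    expect_equal(start(hitsX), 20001)
    expect_equal(mcols(hitsX)$identity, 1.0)
})

test_that("random background yields no significant hits at E < 1e-4", {
    set.seed(17)
    unit <- rand_dna(359)
    misses <- vapply(1:20, function(i) {
        gs <- GenomeSet(focal = c(X = rand_dna(5e4)),
                        background = c(A = rand_dna(1e4)))
        length(searchMonomer(unit, gs))
    }, integer(1))
    expect_gte(mean(misses == 0L), 0.95)
})

test_that("hit counts grow roughly linearly with the E-value threshold", {
    set.seed(18)
    unit <- rand_dna(359)
    thresholds <- c(1e-1, 1e-2)
    counts <- c(0, 0)
    for (i in 1:40) {
        gs <- GenomeSet(focal = c(X = rand_dna(5e4)),
                        background = c(A = rand_dna(1e4)))
        for (t in seq_along(thresholds))
            counts[t] <- counts[t] +
                length(searchMonomer(unit, gs,
                                     evalueThreshold = thresholds[t]))
    }
    # E is the expected hit count per search: ~40*t in total, Poisson noise
    expect_gte(counts[1], counts[2])
    expect_lte(counts[1], 3 * 40 * thresholds[1] + 9)
    expect_lte(counts[2], 3 * 40 * thresholds[2] + 6)
})

test_that("divergent planted copies are recovered by extension", {
    set.seed(19)
    unit <- rand_dna(359)
    sim <- simulateLocusCopies(unit, 12, founderDivergence = 0,
                               copyMutation = 0.1, homogenization = 0)
    chrom <- plant(rand_dna(1e5), paste(sim$copies, collapse = ""), 30001)
    gs <- GenomeSet(focal = c(X = chrom), background = c(A = rand_dna(2e4)))
    hits <- searchMonomer(unit, gs)
    copies <- GRanges("X", IRanges(30001 + (0:11) * 359, width = 359))
    overlapped <- GenomicRanges::countOverlaps(copies, hits,
                                               ignore.strand = TRUE) > 0
    expect_gte(mean(overlapped), 0.95)
    covered <- sum(width(GenomicRanges::intersect(
        reduce(hits, ignore.strand = TRUE), copies, ignore.strand = TRUE)))
    expect_lt(abs(covered - 12 * 359) / (12 * 359), 0.1)
})

test_that("coverage percentages and the averaged ratio follow the table rules", {
    gs <- GenomeSet(focal = c(X = strrep("A", 1e5)),
                    background = c(A = strrep("C", 1e5)))
    hits <- GRanges("X", IRanges(1, 3590))
    cov <- coverageTable(hits, gs)
    expect_equal(coveragePerChrom(cov)$percent[1], 3.59)

    # union rule: [100,200) and [150,300) cover 200 bp, not 250
    hits2 <- GRanges(c("X", "X"), IRanges(c(101, 151), c(200, 300)))
    cov2 <- coverageTable(hits2, gs)
    expect_equal(coveragePerChrom(cov2)$covered_bp[1], 200)
    expect_equal(coveragePerChrom(cov2)$hit_count[1], 2)

    # hit beyond the chromosome end is a consistency error
    expect_error(coverageTable(GRanges("X", IRanges(1, 2e5)), gs), "beyond")
    expect_error(coverageTable(GRanges("chrZ", IRanges(1, 10)), gs),
                 "absent")
})

test_that("the averaged X/A coverage ratio matches its direct arithmetic", {
    # five chromosomes with percents 2.91, 0.41, 0.06, 0.03, 0.11
    lens <- c(X = 1e5, `2L` = 1e5, `2R` = 1e5, `3L` = 1e5, `3R` = 1e5)
    cover <- c(2910, 410, 60, 30, 110)
    seqs <- vapply(lens, function(n) strrep("A", n), character(1))
    gs <- GenomeSet(focal = seqs[1], background = seqs[-1])
    hits <- GRanges(names(lens), IRanges(1, cover))
    cov <- coverageTable(hits, gs)
    oracle <- mean(2.91 / c(0.41, 0.06, 0.03, 0.11))
    expect_equal(coverageRatio(cov), oracle, tolerance = 1e-12)
    expect_equal(round(coverageRatio(cov)), 45)
})

test_that("locus grouping applies the 1-kb chaining rule", {
    # 3.5-kb gap: two loci
    h <- GRanges("X", IRanges(c(1001, 5001), c(1500, 5400)))
    expect_length(groupLoci(h), 2L)

    # chained gaps of 500 and 900 bp: one locus
    h <- GRanges("X", IRanges(c(1, 901, 2201), c(400, 1300, 2600)))
    loci <- groupLoci(h)
    expect_length(loci, 1L)
    expect_equal(mcols(loci)$n_members, 3L)

    # single hit: singleton locus
    expect_length(groupLoci(GRanges("X", IRanges(5, 100))), 1L)

    # strand is ignored for grouping
    h <- GRanges("X", IRanges(c(1, 501), c(400, 900)),
                 strand = c("+", "-"))
    expect_length(groupLoci(h), 1L)
})

test_that("locus grouping matches the transitive-closure oracle and is
           translation and order invariant", {
    set.seed(20)
    for (rep in 1:10) {
        n <- sample(3:25, 1)
        h <- GRanges(sample(c("X", "2L"), n, replace = TRUE),
                     IRanges(sample.int(3e4, n), width = sample(50:500, n,
                                                                replace = TRUE)))
        got <- groupLoci(h)
        members <- lapply(seq_along(got),
                          function(i) sort(mcols(got)$members[[i]]))
        members <- members[order(vapply(members, min, integer(1)))]
        expect_equal(members, unname(brute_loci(h)))

        # translation invariance
        sh <- GenomicRanges::shift(h, 7777)
        expect_equal(length(groupLoci(sh)), length(got))

        # input order invariance of the induced partition
        perm <- sample(n)
        got2 <- groupLoci(h[perm])
        members2 <- lapply(seq_along(got2),
                           function(i) sort(perm[mcols(got2)$members[[i]]]))
        members2 <- members2[order(vapply(members2, min, integer(1)))]
        expect_equal(members2, members)
    }
})
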