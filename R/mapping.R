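#' Karlin-Altschul lambda for an ungapped match/mismatch scoring scheme
#'
#' Solves \eqn{\sum_{ij} p_i p_j e^{\lambda s_{ij}} = 1} for uniform base
#' frequencies: the unique positive root of
#' \eqn{\frac{1}{4} e^{\lambda \cdot match} + \frac{3}{4}
#' e^{\lambda \cdot mismatch} = 1}.
#'
#' @param match,mismatch Match reward (> 0) and mismatch penalty (< 0).
#' @return The positive root `lambda`.
#' @export
karlinLambda <- function(match = 1, mismatch = -2) {
    stopifnot(match > 0, mismatch < 0)
    f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1
    stats::uniroot(f, c(1e-9, 20 / match), tol = 1e-12)$root
}

# K for ungapped nucleotide +1/-2 (the standard tabulated value); an exact K
# for other schemes would need the full Karlin-Altschul machinery, so other
# schemes reuse it as an approximation.
.KARLIN_K <- 0.621

#' Map a monomer genome-wide by ungapped seed-and-extend search
#'
#' BLASTN-like homology search: exact `seedLen`-mer matches between the
#' monomer and each chromosome (both strands) are extended ungapped in both
#' directions with an X-drop rule, and surviving high-scoring pairs are
#' assigned Karlin-Altschul expectation values
#' \eqn{E = K m n e^{-\lambda S}} with `m` the monomer length and `n` the
#' total searched genome length.  Hits with `E < evalueThreshold` are kept;
#' when extensions on the same strand overlap, only the highest-scoring one
#' is reported.
#'
#' @param monomer A [Monomer-class] (or a nucleotide string).
#' @param genome A [GenomeSet-class]; all chromosomes (focal and
#'   background) are searched.
#' @param evalueThreshold Report hits with `E` strictly below this
#'   (default `1e-4`).
#' @param seedLen Exact-match seed length (default 11); the monomer must be
#'   at least this long.
#' @param match,mismatch,xdrop Ungapped extension scoring (defaults +1/-2,
#'   X-drop 12, BLASTN-like; recorded in the result's metadata).
#'
#' @return A `GRanges` sorted by (chrom, start) with strand and metadata
#'   columns `name`, `identity` (matches / alignment length), `score`,
#'   `evalue`.  Search parameters are attached via `metadata()`.
#' @export
searchMonomer <- function(monomer, genome, evalueThreshold = 1e-4,
                          seedLen = 11L, match = 1L, mismatch = -2L,
                          xdrop = 12L) {
    query <- if (methods::is(monomer, "Monomer")) monomerSeq(monomer)
             else toupper(as.character(monomer))
    if (nchar(query) < seedLen)
        stop("monomer (", nchar(query), " bp) shorter than seed length ",
             seedLen)
    lambda <- karlinLambda(match, mismatch)
    m <- nchar(query)
    n <- sum(chromLengths(genome))
    rcQuery <- as.character(reverseComplement(DNAString(query)))
    allChroms <- names(chromGroup(genome))
    pieces <- list()
    for (chrom in allChroms) {
        subj <- chromSeq(genome, chrom)
        for (str in c("+", "-")) {
            q <- if (str == "+") query else rcQuery
            df <- .seed_extend(q, subj, as.integer(seedLen),
                               as.integer(match), as.integer(mismatch),
                               as.integer(xdrop))
            if (nrow(df) == 0L) next
            pieces[[length(pieces) + 1L]] <- GRanges(
                factor(chrom, levels = allChroms),
                IRanges(df$sstart + 1, df$send), strand = str,
                score = df$score, identity = df$matches / df$length)
        }
    }
    if (length(pieces) == 0L)
        return(.emptyHits())
    hits <- do.call(c, pieces)
    ev <- .KARLIN_K * m * n * exp(-lambda * mcols(hits)$score)
    mcols(hits)$evalue <- ev
    hits <- hits[ev < evalueThreshold]
    if (length(hits) == 0L)
        return(.emptyHits())
    hits <- .resolveOverlaps(hits)
    hits <- GenomicRanges::sort(hits, ignore.strand = TRUE)
    mcols(hits)$name <- paste0("hit_", seq_along(hits))
    mcols(hits) <- mcols(hits)[, c("name", "identity", "score", "evalue")]
    S4Vectors::metadata(hits) <- list(
        seed_len = seedLen, match = match, mismatch = mismatch,
        xdrop = xdrop, lambda = lambda, K = .KARLIN_K,
        query_length = m, database_length = n,
        evalue_threshold = evalueThreshold)
    hits
}

.emptyHits <- function() {
    GRanges(name = character(0), identity = numeric(0), score = numeric(0),
            evalue = numeric(0))
}

# keep, among same-strand overlapping extensions, the highest-scoring one
.resolveOverlaps <- function(hits) {
    ov <- GenomicRanges::findOverlaps(hits, hits, ignore.strand = FALSE)
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    keepPairs <- qh != sh
    adj <- split(sh[keepPairs], factor(qh[keepPairs],
                                       levels = seq_along(hits)))
    ord <- order(-mcols(hits)$score, start(hits))
    accepted <- logical(length(hits))
    dropped <- logical(length(hits))
    for (i in ord) {
        if (dropped[i]) next
        accepted[i] <- TRUE
        dropped[adj[[i]]] <- TRUE
        dropped[i] <- FALSE
    }
    hits[accepted]
}

#' Per-chromosome hit counts and coverage percentages
#'
#' Computes, per chromosome, the number of hits and the bp covered by the
#' union of hit intervals (overlaps counted once), plus the
#' focal/background coverage ratio: the pooled focal percent divided by
#' each background chromosome's percent, averaged over background
#' chromosomes.
#'
#' @param hits `GRanges` of satellite hits (e.g. from [searchMonomer()]).
#' @param genome The [GenomeSet-class] that was searched.
#' @return A [CoverageTable-class].
#' @export
coverageTable <- function(hits, genome) {
    lens <- chromLengths(genome)
    grp <- chromGroup(genome)
    hc <- as.character(seqnames(hits))
    if (length(hits) && !all(hc %in% names(lens)))
        stop("hits refer to chromosomes absent from the GenomeSet: ",
             paste(unique(setdiff(hc, names(lens))), collapse = ", "))
    if (length(hits) && any(end(hits) > lens[hc]))
        stop("hit extends beyond its chromosome end")
    covered <- counts <- stats::setNames(numeric(length(lens)), names(lens))
    if (length(hits)) {
        red <- reduce(hits, ignore.strand = TRUE)
        covTab <- tapply(width(red), as.character(seqnames(red)), sum)
        covered[names(covTab)] <- covTab
        cntTab <- table(hc)
        counts[names(cntTab)] <- as.numeric(cntTab)
    }
    percent <- 100 * covered / lens
    tab <- data.frame(chrom = names(lens), group = unname(grp[names(lens)]),
                      length = unname(lens), hit_count = unname(counts),
                      covered_bp = unname(covered),
                      percent = unname(percent), stringsAsFactors = FALSE)
    focalPct <- 100 * sum(covered[grp == "focal"]) / sum(lens[grp == "focal"])
    bgPct <- percent[grp[names(lens)] == "background"]
    ratio <- if (length(bgPct)) mean(focalPct / bgPct) else NA_real_
    new("CoverageTable", perChrom = tab, ratio = ratio)
}

#' CoverageTable accessors
#'
#' @param x A [CoverageTable-class].
#' @return `coverageRatio()` the averaged focal/background percent ratio;
#'   `coveragePerChrom()` the per-chromosome `data.frame`.
#' @name coverage-accessors
NULL

#' @rdname coverage-accessors
#' @export
coverageRatio <- function(x) x@ratio

#' @rdname coverage-accessors
#' @export
coveragePerChrom <- function(x) x@perChrom

setMethod("show", "CoverageTable", function(object) {
    cat("CoverageTable (", nrow(object@perChrom), " chromosomes)\n", sep = "")
    print(object@perChrom, row.names = FALSE)
    cat("  focal/background coverage ratio (averaged): ",
        signif(object@ratio, 4), "\n", sep = "")
})

#' Group satellite hits into loci by the 1-kb rule
#'
#' Per chromosome (strand ignored), hits whose consecutive members are
#' separated by at most `maxGap` bp belong to one locus; loci are maximal
#' under this rule (transitive closure of the pairwise proximity
#' relation).
#'
#' @param hits `GRanges` of hits.
#' @param maxGap Maximum between-hit gap in bp (default 1000).
#' @return A `GRanges` of locus spans, sorted, with metadata columns
#'   `name`, `n_members` and `members` (an `IntegerList` of member hit
#'   indices into the input, input order preserved).
#' @export
groupLoci <- function(hits, maxGap = 1000) {
    if (length(hits) == 0L)
        return(GRanges(name = character(0), n_members = integer(0)))
    loci <- reduce(hits, min.gapwidth = maxGap + 1L, ignore.strand = TRUE,
                   with.revmap = TRUE)
    mcols(loci)$members <- mcols(loci)$revmap
    mcols(loci)$revmap <- NULL
    mcols(loci)$n_members <- lengths(mcols(loci)$members)
    mcols(loci)$name <- paste0("locus_", seq_along(loci))
    mcols(loci) <- mcols(loci)[, c("name", "n_members", "members")]
    loci
}
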