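#' Count overlapping k-mers exactly
#'
#' Counts every overlapping window of length `k` over a set of chromosome
#' sequences.  Windows containing a non-ACGT base (assembly gaps, ambiguity
#' codes) are skipped entirely, so gaps can never create artifactual
#' ratios.  With `canonical = TRUE` (the default) a k-mer and its reverse
#' complement are pooled under one canonical key, since satellite arrays
#' occur in both orientations.
#'
#' Counting streams each sequence position by position in compiled code;
#' only the distinct-k-mer table is materialized.
#'
#' @param x A [GenomeSet-class], a `DNAStringSet`, or a character vector of
#'   sequences.  For a `GenomeSet`, `group` selects which chromosomes are
#'   counted.
#' @param k K-mer length, 1--26.  Default 13: long enough to pick out
#'   chromosome-specific sequence, and prime, so the profile is not
#'   dominated by di-/trinucleotide simple repeats.
#' @param canonical Pool each k-mer with its reverse complement.
#' @param group For `GenomeSet` input: `"focal"`, `"background"` or
#'   `"all"`.
#'
#' @return A [KmerCountTable-class].  If `k` exceeds every sequence length
#'   an empty table is returned with a warning.
#'
#' @examples
#' tab <- countKmers(c(chr = "AAAAAAAAAAAAAAAA"), k = 13)
#' kmerCounts(tab)  # AAAAAAAAAAAAA occurs 4 times (16 - 13 + 1)
#' @export
countKmers <- function(x, k = 13L, canonical = TRUE,
                       group = c("all", "focal", "background")) {
    group <- match.arg(group)
    if (methods::is(x, "GenomeSet"))
        x <- switch(group, all = allSeqs(x), focal = focalSeqs(x),
                    background = backgroundSeqs(x))
    if (methods::is(x, "DNAStringSet") || methods::is(x, "DNAString"))
        x <- as.character(x)
    x <- toupper(as.character(x))
    if (length(x) == 0L)
        stop("no sequences to count")
    k <- as.integer(k)
    res <- .kmer_count(x, k, canonical)
    if (res$n_windows == 0)
        warning("no valid window of length k = ", k, "; empty count table")
    new("KmerCountTable", k = k, canonical = canonical,
        code = res$code, count = res$count,
        totalLength = res$total_length, nWindows = res$n_windows)
}

#' Decode a KmerCountTable to a named count vector
#'
#' @param table A [KmerCountTable-class].
#' @return Named numeric vector of occurrence counts, names are k-mer
#'   strings (canonical form if the table is canonical).
#' @export
kmerCounts <- function(table) {
    stats::setNames(table@count, .kmer_decode(table@code, table@k))
}

#' @rdname kmerCounts
#' @export
totalLength <- function(table) table@totalLength

setMethod("show", "KmerCountTable", function(object) {
    cat("KmerCountTable: k = ", object@k,
        if (object@canonical) " (canonical strands)" else " (given strand)",
        "\n  ", length(object@code), " distinct k-mers over ",
        format(object@nWindows, big.mark = ","), " windows (",
        format(object@totalLength, big.mark = ","), " bp)\n", sep = "")
})

#' The chromosome-pair relative-frequency statistic
#'
#' For a k-mer occurring `kFocal` times in the focal group (total length
#' `LFocal`) and `kBackground` times in the background group (total length
#' `LBackground`), the length-normalized relative frequency is
#'
#' \deqn{X/A = \frac{k_X \times L_A}{k_A \times L_X}}
#'
#' A value of `i` means the k-mer is `i` times more frequent per bp on the
#' focal chromosome than on the background.  A background count of 0 is
#' replaced by 1 (the caller flags such positions as background-absent).
#'
#' @param kFocal,kBackground Occurrence counts.
#' @param LFocal,LBackground Group lengths in bp (> 0).
#' @return Numeric vector of ratios.
#'
#' @examples
#' relativeFrequency(10, 2, 1e6, 2e6)     # 10
#' relativeFrequency(1, 1, 0.34e6, 1e6)   # 2.94: equal counts, short focal
#' @export
relativeFrequency <- function(kFocal, kBackground, LFocal, LBackground) {
    stopifnot(LFocal > 0, LBackground > 0)
    (kFocal * LBackground) / (pmax(kBackground, 1) * LFocal)
}

#' Per-position relative-frequency profile of a focal chromosome
#'
#' Walks every valid k-mer start position of one focal chromosome and
#' computes the relative-frequency statistic of its k-mer against the
#' pooled background (see [relativeFrequency()]).  K-mers absent from the
#' background are computed with denominator count 1 and flagged.
#'
#' @param genome A [GenomeSet-class].
#' @param chrom Focal chromosome to profile; default the first focal
#'   chromosome.
#' @param k,canonical Passed to [countKmers()] when tables are not supplied.
#' @param focalTable,backgroundTable Optional precomputed
#'   [KmerCountTable-class] objects for the focal and background groups
#'   (must share `k` and `canonical`).
#'
#' @return A [KmerProfile-class].
#' @export
relativeProfile <- function(genome, chrom = NULL, k = 13L, canonical = TRUE,
                            focalTable = NULL, backgroundTable = NULL) {
    if (is.null(focalTable))
        focalTable <- countKmers(genome, k = k, canonical = canonical,
                                 group = "focal")
    if (is.null(backgroundTable))
        backgroundTable <- countKmers(genome, k = k, canonical = canonical,
                                      group = "background")
    if (focalTable@k != backgroundTable@k)
        stop("focal and background tables were built with different k")
    if (focalTable@canonical != backgroundTable@canonical)
        stop("focal and background tables use different strand conventions")
    if (is.null(chrom))
        chrom <- names(focalSeqs(genome))[1L]
    grp <- chromGroup(genome)
    if (!chrom %in% names(grp) || grp[[chrom]] != "focal")
        stop("'", chrom, "' is not a focal chromosome of this GenomeSet")
    Lf <- focalTable@totalLength
    Lb <- backgroundTable@totalLength
    stopifnot(Lf > 0, Lb > 0)
    scan <- .kmer_scan(chromSeq(genome, chrom), focalTable@k,
                       focalTable@canonical)
    kf <- .kmer_lookup(scan$code, focalTable@code, focalTable@count)
    kb <- .kmer_lookup(scan$code, backgroundTable@code, backgroundTable@count)
    absent <- kb == 0
    ratio <- relativeFrequency(kf, kb, Lf, Lb)
    new("KmerProfile", chrom = chrom, k = focalTable@k,
        canonical = focalTable@canonical, Lfocal = Lf, Lbackground = Lb,
        pos = as.integer(scan$pos), code = scan$code, focalCount = kf,
        backgroundCount = kb, ratio = ratio, backgroundAbsent = absent)
}

#' @describeIn relativeProfile Number of profiled positions.
#' @param x,object A `KmerProfile`.
#' @export
setMethod("length", "KmerProfile", function(x) length(x@pos))

setMethod("show", "KmerProfile", function(object) {
    cat("KmerProfile of ", object@chrom, ": k = ", object@k, ", ",
        length(object@pos), " positions\n",
        "  L_focal = ", format(object@Lfocal, big.mark = ","),
        " bp, L_background = ", format(object@Lbackground, big.mark = ","),
        " bp\n", sep = "")
    if (length(object@pos))
        cat("  ratio: median ", signif(stats::median(object@ratio), 4),
            ", max ", signif(max(object@ratio), 4), "; ",
            sum(object@backgroundAbsent), " background-absent position(s)\n",
            sep = "")
})

#' Convert a KmerProfile to a data.frame
#'
#' @param x A [KmerProfile-class].
#' @param row.names,optional,... Ignored (S3 compatibility).
#' @return `data.frame` with columns `chrom`, `pos` (0-based), `kmer`,
#'   `k_focal`, `k_background`, `ratio`, `background_absent`.
#' @export
as.data.frame.KmerProfile <- function(x, row.names = NULL, optional = FALSE,
                                      ...) {
    data.frame(chrom = x@chrom, pos = x@pos, kmer = .kmer_decode(x@code, x@k),
               k_focal = x@focalCount, k_background = x@backgroundCount,
               ratio = x@ratio, background_absent = x@backgroundAbsent,
               stringsAsFactors = FALSE)
}

setMethod("as.data.frame", "KmerProfile", as.data.frame.KmerProfile)

#' Write a profile as TSV
#'
#' @param profile A [KmerProfile-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeProfile <- function(profile, path) {
    utils::write.table(as.data.frame(profile), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Summary statistics of a profile
#'
#' @param profile A [KmerProfile-class].
#' @param thresholds Ratio thresholds at which positions are counted
#'   (strictly greater than).
#' @return A list with `n_positions`, `max_ratio`, `median_ratio`,
#'   `fraction_above_1`, `n_background_absent` and `n_above` (named by
#'   threshold).  An empty profile returns the sentinel with `n_positions =
#'   0` and `NA` statistics.
#' @export
profileSummary <- function(profile, thresholds = c(1, 20)) {
    if (length(profile@pos) == 0L)
        return(list(n_positions = 0L, max_ratio = NA_real_,
                    median_ratio = NA_real_, fraction_above_1 = NA_real_,
                    n_background_absent = 0L,
                    n_above = stats::setNames(rep(NA_integer_,
                                                  length(thresholds)),
                                              thresholds)))
    list(n_positions = length(profile@pos),
         max_ratio = max(profile@ratio),
         median_ratio = stats::median(profile@ratio),
         fraction_above_1 = mean(profile@ratio > 1),
         n_background_absent = sum(profile@backgroundAbsent),
         n_above = stats::setNames(
             vapply(thresholds, function(t) sum(profile@ratio > t),
                    integer(1)),
             thresholds))
}
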