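#' Call clusters of overrepresented k-mers
#'
#' Detects maximal runs of profile positions whose relative frequency
#' exceeds `threshold` (strictly: ties at the threshold are excluded, i.e.
#' the X/A > 20 rule), merges runs separated by at most `mergeGap` bp, and
#' discards merged runs shorter than `minLen` bp.  Each k-mer position
#' contributes the interval `[pos, pos + k)`, so a run of positions covers
#' the full extent of the underlying sequence.  N-gaps inside an array do
#' not break a cluster unless they exceed `mergeGap`, because runs are
#' defined on valid positions only and merging is purely distance-based.
#'
#' @param profile A [KmerProfile-class].
#' @param genome The [GenomeSet-class] the profile was computed from (used
#'   to extract cluster sequences).
#' @param threshold Detection threshold on the ratio (default 20).
#' @param mergeGap Maximum gap in bp between runs that are merged
#'   (default 200).
#' @param minLen Minimum cluster length in bp after merging (default 500).
#'   The defaults admit ~1-kb arrays, the small end of typical satellite
#'   clusters, while suppressing single-k-mer spikes.
#'
#' @return A `GRanges` on the profiled chromosome (1-based closed, as all
#'   GRanges; BED output converts) with metadata columns `name`,
#'   `peak_ratio`, `mean_ratio` (max/mean ratio over member positions) and
#'   `sequence`.  Sorted by start; empty when nothing exceeds the
#'   threshold.
#'
#' @seealso [writeIntervals()] for BED output, [clusterSeqs()]
#' @export
callClusters <- function(profile, genome, threshold = 20, mergeGap = 200,
                         minLen = 500) {
    stopifnot(threshold > 0, mergeGap >= 0, minLen >= 0)
    hot <- profile@ratio > threshold
    if (!any(hot))
        return(.emptyClusters())
    if (!profile@chrom %in% names(chromGroup(genome)))
        stop("profile chromosome '", profile@chrom,
             "' absent from the GenomeSet")
    pos1 <- profile@pos[hot] + 1L          # 1-based starts
    ir <- IRanges(pos1, width = profile@k)
    merged <- reduce(ir, min.gapwidth = mergeGap + 1L)
    merged <- merged[width(merged) >= minLen]
    if (length(merged) == 0L)
        return(.emptyClusters())
    # per-cluster peak and mean over member (above-threshold) positions
    ov <- IRanges::findOverlaps(IRanges(pos1, width = 1L), merged)
    r <- profile@ratio[hot][S4Vectors::queryHits(ov)]
    grpIdx <- S4Vectors::subjectHits(ov)
    peak <- vapply(split(r, grpIdx), max, numeric(1))
    meanR <- vapply(split(r, grpIdx), mean, numeric(1))
    chromSequence <- chromSeq(genome, profile@chrom)
    seqs <- substring(chromSequence, start(merged), end(merged))
    gr <- GRanges(profile@chrom, merged,
                  name = paste0("cluster_", seq_along(merged)),
                  peak_ratio = as.numeric(peak),
                  mean_ratio = as.numeric(meanR),
                  sequence = seqs)
    GenomicRanges::sort(gr, ignore.strand = TRUE)
}

.emptyClusters <- function() {
    GRanges(name = character(0), peak_ratio = numeric(0),
            mean_ratio = numeric(0), sequence = character(0))
}

#' Extract cluster sequences as a DNAStringSet
#'
#' @param clusters A `GRanges` from [callClusters()].
#' @return A named `DNAStringSet`.
#' @export
clusterSeqs <- function(clusters) {
    if (length(clusters) == 0L)
        return(DNAStringSet())
    stats::setNames(DNAStringSet(mcols(clusters)$sequence),
                    mcols(clusters)$name)
}

#' Restrict a profile to an interval
#'
#' Keeps profile positions whose k-mer start lies within `[from, to)`
#' (0-based half-open), e.g. to re-examine one called cluster.
#'
#' @param profile A [KmerProfile-class].
#' @param from,to 0-based half-open bounds on the k-mer start position.
#' @return A [KmerProfile-class].
#' @export
restrictProfile <- function(profile, from, to) {
    keep <- profile@pos >= from & profile@pos < to
    methods::initialize(profile, pos = profile@pos[keep],
                        code = profile@code[keep],
                        focalCount = profile@focalCount[keep],
                        backgroundCount = profile@backgroundCount[keep],
                        ratio = profile@ratio[keep],
                        backgroundAbsent = profile@backgroundAbsent[keep])
}
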