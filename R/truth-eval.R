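#' Evaluate pipeline outputs against simulation ground truth
#'
#' Compares each supplied pipeline output with the planted truth from
#' [simulateGenome()]: called clusters against planted array intervals
#' (matched when Jaccard >= `jaccard`), inferred monomer periods against
#' the planted monomer length, called loci against planted loci, coverage
#' against planted covered bp, and a fitted density slope against the
#' generating slope.  Every metric is defined even when an output is empty
#' (reported as 0 with a flag).
#'
#' @param truth The `truth` element of a [simulateGenome()] result.
#' @param clusters Optional `GRanges` from [callClusters()].
#' @param monomers Optional list of [Monomer-class] objects.
#' @param hits Optional `GRanges` from [searchMonomer()].
#' @param loci Optional `GRanges` from [groupLoci()].
#' @param fit Optional [ExponentialFit-class].
#' @param trueSlope Generating slope to compare `fit` against (e.g.
#'   `config$density_b`).
#' @param jaccard Interval-matching threshold (default 0.5).
#' @return A list of metric sublists (`clusters`, `monomers`, `loci`,
#'   `coverage`, `fit`), each with a `flag` that is `NA` when well
#'   defined.
#' @export
truthEval <- function(truth, clusters = NULL, monomers = NULL, hits = NULL,
                      loci = NULL, fit = NULL, trueSlope = NULL,
                      jaccard = 0.5) {
    out <- list()
    if (!is.null(clusters)) {
        focalLoci <- truth$loci[as.character(seqnames(truth$loci)) %in%
                                unique(as.character(seqnames(clusters)))]
        if (length(clusters) == 0L || length(focalLoci) == 0L) {
            out$clusters <- list(recall = 0, precision = 0,
                                 flag = "empty clusters or truth")
        } else {
            jac <- .jaccardMatrix(focalLoci, clusters)
            out$clusters <- list(
                recall = mean(apply(jac, 1L, max) >= jaccard),
                precision = mean(apply(jac, 2L, max) >= jaccard),
                flag = NA_character_)
        }
    }
    if (!is.null(monomers)) {
        if (length(monomers) == 0L) {
            out$monomers <- list(period_error = NA_real_,
                                 flag = "no monomers inferred")
        } else {
            errs <- abs(vapply(monomers, function(m) m@period, integer(1)) -
                        nchar(truth$monomer))
            out$monomers <- list(period_error = min(errs),
                                 median_period_error = stats::median(errs),
                                 flag = NA_character_)
        }
    }
    if (!is.null(loci)) {
        if (length(loci) == 0L || length(truth$loci) == 0L) {
            out$loci <- list(accuracy = 0, flag = "empty loci or truth")
        } else {
            nOv <- GenomicRanges::countOverlaps(truth$loci, loci,
                                                ignore.strand = TRUE)
            out$loci <- list(accuracy = mean(nOv == 1L),
                             flag = NA_character_)
        }
    }
    if (!is.null(hits)) {
        trueCov <- sum(width(reduce(truth$copies, ignore.strand = TRUE)))
        estCov <- if (length(hits))
            sum(width(reduce(hits, ignore.strand = TRUE))) else 0
        out$coverage <- list(
            true_bp = trueCov, estimated_bp = estCov,
            relative_error = if (trueCov > 0) abs(estCov - trueCov) / trueCov
                             else NA_real_,
            flag = if (length(hits) == 0L && trueCov > 0)
                "no hits against non-empty truth" else NA_character_)
    }
    if (!is.null(fit)) {
        if (is.null(trueSlope)) {
            out$fit <- list(slope_error = NA_real_,
                            flag = "no generating slope supplied")
        } else {
            out$fit <- list(slope = fit@slope, true_slope = trueSlope,
                            slope_error = abs(fit@slope - trueSlope),
                            flag = NA_character_)
        }
    }
    out
}

# Jaccard index of every (truth, called) interval pair on the same
# chromosome
.jaccardMatrix <- function(a, b) {
    m <- matrix(0, nrow = length(a), ncol = length(b))
    for (i in seq_along(a)) for (j in seq_along(b)) {
        if (as.character(seqnames(a))[i] != as.character(seqnames(b))[j])
            next
        inter <- min(end(a)[i], end(b)[j]) - max(start(a)[i], start(b)[j]) + 1
        if (inter <= 0) next
        uni <- max(end(a)[i], end(b)[j]) - min(start(a)[i], start(b)[j]) + 1
        m[i, j] <- inter / uni
    }
    m
}
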