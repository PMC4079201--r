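#' Align a satellite copy to the family consensus
#'
#' Global alignment (match +1, mismatch -1, linear gap -2) of a copy to the
#' monomer consensus, then projection onto consensus coordinates: columns
#' where the consensus has a gap (insertions in the copy) are dropped, and
#' deletions in the copy become `-`.  Every projected copy therefore has
#' exactly the consensus length, giving a common coordinate system (a star
#' alignment) in which hamming distances are well defined.
#'
#' Copies shorter than half or longer than twice the consensus are not
#' alignable satellite copies and return `NA` (callers filter them with a
#' message).
#'
#' @param copy Nucleotide string.
#' @param monomer A [Monomer-class] (or consensus string).
#' @return A character string of length `period` over `A,C,G,T,N,-`, or
#'   `NA` if the copy is outside the length bounds.
#' @export
alignToConsensus <- function(copy, monomer) {
    consensus <- if (methods::is(monomer, "Monomer")) monomerSeq(monomer)
                 else toupper(as.character(monomer))
    copy <- toupper(as.character(copy))
    if (nchar(copy) < 0.5 * nchar(consensus) ||
        nchar(copy) > 2 * nchar(consensus))
        return(NA_character_)
    sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                   baseOnly = FALSE)
    aln <- Biostrings::pairwiseAlignment(
        DNAString(copy), DNAString(consensus), type = "global",
        substitutionMatrix = sm, gapOpening = 0, gapExtension = 2)
    p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
    s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
    paste(p[s != "-"], collapse = "")
}

#' Align many copies to a consensus
#'
#' @param seqs Character vector (or `DNAStringSet`) of copy sequences.
#' @param locus Character/integer vector of locus ids, parallel to `seqs`.
#' @param monomer A [Monomer-class] or consensus string.
#' @param ids Optional copy ids (default `copy_1`, ...).
#' @return `data.frame` with columns `id`, `locus`, `aligned`; copies
#'   outside the `[0.5, 2] x` consensus length bounds are dropped with a
#'   message.
#' @export
alignCopies <- function(seqs, locus, monomer, ids = NULL) {
    seqs <- as.character(seqs)
    stopifnot(length(seqs) == length(locus))
    if (is.null(ids))
        ids <- paste0("copy_", seq_along(seqs))
    aligned <- vapply(seqs, alignToConsensus, character(1), monomer = monomer,
                      USE.NAMES = FALSE)
    bad <- is.na(aligned)
    if (any(bad))
        message(sum(bad), " cop(ies) outside [0.5, 2] x consensus length; ",
                "filtered")
    data.frame(id = ids[!bad], locus = as.character(locus)[!bad],
               aligned = aligned[!bad], stringsAsFactors = FALSE)
}

#' Pairwise hamming distances between aligned copies
#'
#' For every pair of aligned copies, the distance is the fraction of
#' differing sites among columns where both copies carry an unambiguous
#' base (gap- or N-containing columns are excluded pairwise, not
#' listwise).
#'
#' @param aligned `data.frame` from [alignCopies()] (columns `id`, `locus`,
#'   `aligned`; equal aligned lengths).
#' @return `data.frame` with columns `id1`, `id2`, `locus1`, `locus2`,
#'   `same_locus`, `sites` (compared columns) and `distance`.  Fewer than
#'   two copies yield zero rows with a warning.
#' @export
pairwiseDistances <- function(aligned) {
    n <- nrow(aligned)
    if (n < 2L) {
        warning("fewer than 2 aligned copies; no distances")
        return(data.frame(id1 = character(0), id2 = character(0),
                          locus1 = character(0), locus2 = character(0),
                          same_locus = logical(0), sites = integer(0),
                          distance = numeric(0)))
    }
    lens <- nchar(aligned$aligned)
    if (length(unique(lens)) != 1L)
        stop("aligned copies must have equal length")
    mat <- do.call(rbind, strsplit(aligned$aligned, "", fixed = TRUE))
    isBase <- mat == "A" | mat == "C" | mat == "G" | mat == "T"
    pairs <- utils::combn(n, 2L)
    k <- ncol(pairs)
    sites <- integer(k)
    dist <- numeric(k)
    for (p in seq_len(k)) {
        i <- pairs[1L, p]; j <- pairs[2L, p]
        both <- isBase[i, ] & isBase[j, ]
        sites[p] <- sum(both)
        dist[p] <- if (sites[p] == 0L) NA_real_
                   else sum(mat[i, both] != mat[j, both]) / sites[p]
    }
    data.frame(id1 = aligned$id[pairs[1L, ]], id2 = aligned$id[pairs[2L, ]],
               locus1 = aligned$locus[pairs[1L, ]],
               locus2 = aligned$locus[pairs[2L, ]],
               same_locus = aligned$locus[pairs[1L, ]] ==
                   aligned$locus[pairs[2L, ]],
               sites = sites, distance = dist, stringsAsFactors = FALSE)
}

#' Test for concerted evolution: within- vs between-locus distances
#'
#' One-sided Wilcoxon rank-sum test of the concerted-evolution signature:
#' copies from the same locus are more similar to each other (smaller
#' hamming distance) than copies from different loci.  Exact enumeration is
#' used when both groups have at most 20 values and no ties are present;
#' otherwise the normal approximation with tie correction.
#'
#' @param records `data.frame` from [pairwiseDistances()] (columns
#'   `distance`, `same_locus`), or a list with numeric `within` and
#'   `between`.
#' @param exact `"auto"` (the rule above), `"exact"` or `"approx"`.  The
#'   auto rule: tie-free groups of at most 20 use the exact rank-sum
#'   distribution; tied groups of at most 10 use full permutation
#'   enumeration (ties handled by midranks); anything larger uses the
#'   normal approximation with tie correction and continuity correction.
#' @return A list: `median_within`, `median_between`, `n_within`,
#'   `n_between`, `statistic` (Mann-Whitney U of the within group),
#'   `p_value` (one-sided, within < between), `method`, and `flag` (`NA`
#'   or an explanation when the test is undefined).
#' @export
withinBetweenTest <- function(records, exact = c("auto", "exact", "approx")) {
    exact <- match.arg(exact)
    if (is.data.frame(records)) {
        within <- records$distance[records$same_locus]
        between <- records$distance[!records$same_locus]
    } else {
        within <- records$within
        between <- records$between
    }
    within <- within[is.finite(within)]
    between <- between[is.finite(between)]
    n1 <- length(within); n2 <- length(between)
    base <- list(median_within = stats::median(within),
                 median_between = stats::median(between),
                 n_within = n1, n_between = n2)
    if (n1 == 0L || n2 == 0L)
        return(c(base, list(statistic = NA_real_, p_value = NA_real_,
                            method = NA_character_,
                            flag = "one distance class is empty")))
    ties <- anyDuplicated(c(within, between)) > 0L
    useExact <- switch(exact,
                       auto = (!ties && max(n1, n2) <= 20L) ||
                              (ties && max(n1, n2) <= 10L),
                       exact = TRUE,
                       approx = FALSE)
    if (useExact && ties && max(n1, n2) > 10L)
        stop("exact enumeration with ties is limited to group sizes <= 10")
    if (useExact) {
        res <- .rankSumExact(within, between)
        c(base, list(statistic = res$statistic, p_value = res$p_value,
                     method = "exact", flag = NA_character_))
    } else {
        wt <- suppressWarnings(
            stats::wilcox.test(within, between, alternative = "less",
                               exact = FALSE, correct = TRUE))
        c(base, list(statistic = unname(wt$statistic), p_value = wt$p.value,
                     method = "normal approximation", flag = NA_character_))
    }
}

# Exact one-sided (first group stochastically smaller) rank-sum p-value.
# Tie-free data uses the closed-form Mann-Whitney distribution; tied data
# enumerates all assignments of the pooled midranks to the first group.
.rankSumExact <- function(x, y) {
    n1 <- length(x); n2 <- length(y)
    r <- rank(c(x, y))
    U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    ties <- anyDuplicated(c(x, y)) > 0L
    if (!ties)
        return(list(statistic = U, p_value = stats::pwilcox(U, n1, n2)))
    idx <- utils::combn(n1 + n2, n1)
    Wall <- colSums(matrix(r[idx], nrow = n1))
    Wobs <- sum(r[seq_len(n1)])
    list(statistic = U, p_value = mean(Wall <= Wobs))
}

#' Extract hit sequences and locus assignments as satellite copies
#'
#' Pulls the genomic sequence under each hit (reverse-complemented for
#' minus-strand hits) and labels it with the locus it belongs to, ready for
#' [alignCopies()].
#'
#' @param hits `GRanges` from [searchMonomer()].
#' @param loci `GRanges` from [groupLoci()] on the same hits.
#' @param genome The [GenomeSet-class].
#' @return `data.frame` with columns `id`, `locus`, `seq`.
#' @export
satelliteCopies <- function(hits, loci, genome) {
    if (length(hits) == 0L)
        return(data.frame(id = character(0), locus = character(0),
                          seq = character(0)))
    locusOf <- rep(NA_character_, length(hits))
    for (i in seq_along(loci))
        locusOf[mcols(loci)$members[[i]]] <- mcols(loci)$name[i]
    seqs <- vapply(seq_along(hits), function(i) {
        chrom <- as.character(seqnames(hits))[i]
        s <- substring(chromSeq(genome, chrom), start(hits)[i], end(hits)[i])
        if (as.character(strand(hits))[i] == "-")
            s <- as.character(reverseComplement(DNAString(s)))
        s
    }, character(1))
    nm <- if ("name" %in% colnames(mcols(hits))) mcols(hits)$name
          else paste0("hit_", seq_along(hits))
    data.frame(id = nm, locus = locusOf, seq = seqs, stringsAsFactors = FALSE)
}
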