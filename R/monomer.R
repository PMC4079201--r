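#' Estimate the tandem repeat period of a sequence
#'
#' Autocorrelation of exact seed matches: for each candidate period `p`,
#' the score is the fraction of positions `i` whose `seedLen`-mer recurs
#' exactly at `i + p`.  A perfect tandem array scores 1 at its period (and
#' at every multiple); sub-multiples are resolved by preferring the
#' smallest period whose score is at least `subMultiple` times the best
#' score.  Random sequence scores near `4^-seedLen` per offset, so a best
#' score below `noPeriodScore` is reported as "no period".
#'
#' @param sequence Nucleotide string (cluster sequence).
#' @param minPeriod,maxPeriod Candidate period range in bp.  `maxPeriod`
#'   defaults to `min(1000, floor(n/2))`.  Sequences shorter than
#'   `2 * minPeriod` yield an empty ranking.
#' @param seedLen Seed k-mer length for the autocorrelation (default 8).
#' @param noPeriodScore Best-score floor below which no period is called
#'   (default 0.2, comfortably above the random-sequence null).
#' @param subMultiple Fraction of the best score a smaller period must
#'   reach to be preferred (default 0.9).
#'
#' @return A list with `period` (best period, or `NA` if none), `score`
#'   (its score) and `ranking` (a `data.frame` of `period`, `score` sorted
#'   by decreasing score; zero rows when the sequence is too short).
#'
#' @examples
#' estimatePeriod(strrep("ACGT", 50), minPeriod = 2)$period  # 4
#' @export
estimatePeriod <- function(sequence, minPeriod = 20L, maxPeriod = NULL,
                           seedLen = 8L, noPeriodScore = 0.2,
                           subMultiple = 0.9) {
    sequence <- toupper(as.character(sequence))
    n <- nchar(sequence)
    minPeriod <- as.integer(minPeriod)
    empty <- list(period = NA_integer_, score = NA_real_,
                  ranking = data.frame(period = integer(0),
                                       score = numeric(0)))
    if (n < 2L * minPeriod)
        return(empty)
    if (is.null(maxPeriod))
        maxPeriod <- min(1000L, n %/% 2L)
    maxPeriod <- as.integer(min(maxPeriod, n - seedLen))
    if (maxPeriod < minPeriod)
        return(empty)
    codes <- .kmer_codes_at(sequence, as.integer(seedLen))
    m <- length(codes)
    periods <- minPeriod:maxPeriod
    score <- vapply(periods, function(p) {
        if (p >= m) return(NA_real_)
        a <- codes[seq_len(m - p)]
        b <- codes[seq_len(m - p) + p]
        mean(a == b, na.rm = TRUE)
    }, numeric(1))
    ok <- is.finite(score)
    periods <- periods[ok]
    score <- score[ok]
    if (length(periods) == 0L)
        return(empty)
    ord <- order(-score, periods)
    ranking <- data.frame(period = periods[ord], score = score[ord])
    best <- max(score)
    if (best < noPeriodScore)
        return(list(period = NA_integer_, score = best, ranking = ranking))
    cand <- periods[score >= subMultiple * best]
    p <- min(cand)
    list(period = p, score = score[match(p, periods)], ranking = ranking)
}

#' Build the consensus monomer of a tandem array
#'
#' Cuts the sequence into frames of length `period` (position `i` maps to
#' consensus column `(i - 1) mod period + 1`) and takes the per-column
#' majority base; ties break to the lexicographically smallest base, and
#' columns with no A/C/G/T evidence become `N`.  At least two full copies
#' are required.
#'
#' @param sequence Nucleotide string containing the array.
#' @param period Repeat period in bp (from [estimatePeriod()]).
#' @param id Monomer identifier.
#' @param sourceCluster Identifier of the originating cluster.
#'
#' @return A [Monomer-class] with `copyNumber = nchar(sequence) / period`.
#'
#' @examples
#' m <- buildConsensus("ACGTACGTACGT", 4)
#' monomerSeq(m)    # "ACGT"
#' copyNumber(m)    # 3
#' @export
buildConsensus <- function(sequence, period, id = "monomer_1",
                           sourceCluster = NA_character_) {
    sequence <- toupper(as.character(sequence))
    period <- as.integer(period)
    n <- nchar(sequence)
    if (!is.finite(period) || period < 1L)
        stop("invalid period")
    if (n < 2L * period)
        stop("fewer than 2 full copies: sequence of ", n,
             " bp cannot support period ", period)
    chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
    col <- ((seq_len(n) - 1L) %% period) + 1L
    counts <- table(factor(chars, levels = c("A", "C", "G", "T")),
                    factor(col, levels = seq_len(period)))
    hit <- apply(counts, 2L, function(x) {
        if (all(x == 0)) return("N")
        c("A", "C", "G", "T")[which.max(x)]   # first max = lexicographic tie
    })
    new("Monomer", id = as.character(id),
        consensus = paste(hit, collapse = ""), period = period,
        copyNumber = n / period, sourceCluster = as.character(sourceCluster),
        family = NA_character_)
}

#' Monomer accessors
#'
#' @param monomer A [Monomer-class].
#' @return `monomerSeq()` the consensus string; `period()` the unit length
#'   in bp; `copyNumber()` the copy number in the source cluster;
#'   `monomerFamily()` the family id (or `NA`).
#' @name monomer-accessors
NULL

#' @rdname monomer-accessors
#' @export
monomerSeq <- function(monomer) monomer@consensus

#' @rdname monomer-accessors
#' @export
period <- function(monomer) monomer@period

#' @rdname monomer-accessors
#' @export
copyNumber <- function(monomer) monomer@copyNumber

#' @rdname monomer-accessors
#' @export
monomerFamily <- function(monomer) monomer@family

setMethod("show", "Monomer", function(object) {
    cat("Monomer ", object@id, ": ", object@period, " bp, ",
        signif(object@copyNumber, 4), " copies in source",
        if (!is.na(object@family)) paste0(", family ", object@family),
        "\n  ", if (object@period <= 60L) object@consensus
               else paste0(substr(object@consensus, 1L, 57L), "..."),
        "\n", sep = "")
})

#' Best circular, strand-aware identity between two monomers
#'
#' Locally aligns `a` (forward and reverse complement) against `b`
#' concatenated with itself, so any circular rotation of either unit can
#' match end-to-end.  Identity is the number of aligned matches divided by
#' the shorter monomer length.
#'
#' @param a,b Nucleotide strings.
#' @return Identity in `[0, 1]`.
#' @export
monomerIdentity <- function(a, b) {
    a <- toupper(as.character(a)); b <- toupper(as.character(b))
    if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
    doubled <- DNAString(paste0(b, b))
    sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                   baseOnly = FALSE)
    best <- 0
    for (qry in c(a, as.character(reverseComplement(DNAString(a))))) {
        aln <- Biostrings::pairwiseAlignment(
            DNAString(qry), doubled, type = "local",
            substitutionMatrix = sm, gapOpening = 0, gapExtension = 2)
        best <- max(best, Biostrings::nmatch(aln))
    }
    best / min(nchar(a), nchar(b))
}

#' Group monomers into families by reciprocal identity
#'
#' Single-linkage clustering of monomers whose pairwise circular,
#' strand-aware identity (see [monomerIdentity()]) exceeds
#' `identityThreshold`.  Each family's representative is its longest member
#' (ties break to the lexicographically smallest id).  The partition, the
#' family labels and the representatives are invariant to input order:
#' families are numbered by their lexicographically smallest member id.
#'
#' @param monomers A list of [Monomer-class] objects.
#' @param identityThreshold Linking threshold (default 0.7; random
#'   same-length sequence pairs stay well below it).
#'
#' @return A list with `monomers` (input monomers with the `family` slot
#'   filled) and `assignment` (a `data.frame` of `id`, `period`, `family`,
#'   `representative`).
#' @export
groupFamilies <- function(monomers, identityThreshold = 0.7) {
    if (length(monomers) == 0L)
        stop("need at least one monomer")
    ids <- vapply(monomers, function(m) m@id, character(1))
    if (anyDuplicated(ids))
        stop("monomer ids must be unique")
    n <- length(monomers)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    if (n > 1L) {
        for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
            if (monomerIdentity(monomers[[i]]@consensus,
                                monomers[[j]]@consensus) > identityThreshold) {
                ri <- find(i); rj <- find(j)
                if (ri != rj) parent[rj] <- ri
            }
        }
    }
    root <- vapply(seq_len(n), find, integer(1))
    # canonical family numbering: by smallest member id within each component
    comp <- split(seq_len(n), root)
    minId <- vapply(comp, function(ix) min(ids[ix]), character(1))
    comp <- comp[order(minId)]
    fam <- character(n)
    rep_ <- logical(n)
    for (f in seq_along(comp)) {
        ix <- comp[[f]]
        fam[ix] <- paste0("family_", f)
        lens <- vapply(ix, function(i) monomers[[i]]@period, integer(1))
        cands <- ix[lens == max(lens)]
        rep_[cands[order(ids[cands])][1L]] <- TRUE
    }
    monomers <- lapply(seq_len(n), function(i) {
        m <- monomers[[i]]; m@family <- fam[i]; m
    })
    list(monomers = monomers,
         assignment = data.frame(
             id = ids,
             period = vapply(monomers, function(m) m@period, integer(1)),
             family = fam, representative = rep_,
             stringsAsFactors = FALSE))
}

#' Infer monomers for every called cluster
#'
#' Convenience wrapper: runs [estimatePeriod()] and [buildConsensus()] on
#' each cluster sequence and returns the monomers of clusters with a
#' detectable period.
#'
#' @param clusters `GRanges` from [callClusters()].
#' @param minPeriod,maxPeriod,seedLen Passed to [estimatePeriod()].
#' @return A list of [Monomer-class] objects (possibly empty); names are
#'   cluster names.
#' @export
clusterMonomers <- function(clusters, minPeriod = 20L, maxPeriod = NULL,
                            seedLen = 8L) {
    out <- list()
    for (i in seq_along(clusters)) {
        sq <- mcols(clusters)$sequence[i]
        nm <- mcols(clusters)$name[i]
        est <- estimatePeriod(sq, minPeriod = minPeriod,
                              maxPeriod = maxPeriod, seedLen = seedLen)
        if (is.na(est$period) || nchar(sq) < 2L * est$period)
            next
        out[[nm]] <- buildConsensus(sq, est$period,
                                    id = paste0("monomer_", nm),
                                    sourceCluster = nm)
    }
    out
}
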