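#' @useDynLib oligoSat, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats coef
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom IRanges IRanges reduce
#' @importFrom GenomicRanges GRanges seqnames start end width strand granges
#' @importFrom Biostrings DNAStringSet DNAString reverseComplement
#'   readDNAStringSet writeXStringSet subseq
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' GenomeSet: chromosomes partitioned into a focal and a background group
#'
#' Container for the chromosome partition the profiling statistic is defined
#' on: a focal group (e.g. the X chromosome, or the dot chromosome) and a
#' pooled background group (e.g. the autosomes).  Sequences are held as a
#' [Biostrings::DNAStringSet] and uppercased on construction; group lengths
#' `L_focal` and `L_background` are the sums of the member chromosome
#' lengths.
#'
#' @slot species Species or assembly label.
#' @slot sequences A `DNAStringSet`, one entry per chromosome, unique names.
#' @slot group Character vector parallel to `sequences`, each element
#'   `"focal"` or `"background"`.
#'
#' @seealso [GenomeSet()], [readGenomeSet()], [focalSeqs()],
#'   [backgroundSeqs()]
#' @export
setClass("GenomeSet", representation(
    species = "character",
    sequences = "DNAStringSet",
    group = "character"
))

setValidity("GenomeSet", function(object) {
    nm <- names(object@sequences)
    if (is.null(nm) || anyNA(nm) || any(nm == ""))
        return("all chromosomes must be named")
    if (anyDuplicated(nm))
        return("chromosome names must be unique")
    if (length(object@group) != length(object@sequences))
        return("'group' must be parallel to 'sequences'")
    if (!all(object@group %in% c("focal", "background")))
        return("'group' entries must be 'focal' or 'background'")
    TRUE
})

#' KmerCountTable: exact overlapping k-mer occurrence counts
#'
#' Occurrence counts of every k-mer (overlapping windows; windows containing
#' a non-ACGT base are skipped on both sides of any ratio) over a set of
#' chromosomes.  K-mers are stored 2-bit encoded; use [kmerCounts()] to
#' obtain a decoded named vector.
#'
#' @slot k K-mer length (1--26).
#' @slot canonical If `TRUE`, a k-mer and its reverse complement share one
#'   canonical key (the lexicographically smaller of the two).
#' @slot code Numeric vector of 2-bit k-mer codes present at least once.
#' @slot count Occurrence count per code (all >= 1).
#' @slot totalLength Total bp of the counted chromosomes.
#' @slot nWindows Number of valid (non-N) windows counted.
#'
#' @seealso [countKmers()], [kmerCounts()]
#' @export
setClass("KmerCountTable", representation(
    k = "integer",
    canonical = "logical",
    code = "numeric",
    count = "numeric",
    totalLength = "numeric",
    nWindows = "numeric"
))

setValidity("KmerCountTable", function(object) {
    if (length(object@k) != 1L || object@k < 1L || object@k > 26L)
        return("k must be a single integer in [1, 26]")
    if (length(object@code) != length(object@count))
        return("'code' and 'count' must be parallel")
    if (length(object@count) && any(object@count < 1))
        return("stored counts must all be >= 1")
    TRUE
})

#' KmerProfile: per-position relative k-mer frequency along a chromosome
#'
#' The oligonucleotide profile of one focal chromosome against the pooled
#' background: for every valid k-mer start position `p` carrying k-mer `w`,
#'
#' \deqn{ratio(p) = \frac{k_{focal}(w) \times L_{background}}
#'                       {k_{background}(w) \times L_{focal}}}
#'
#' Positions whose k-mer is absent from the background are computed with a
#' denominator count of 1 and flagged `backgroundAbsent` (these are the most
#' focal-specific signals and must not be dropped).
#'
#' @slot chrom Focal chromosome name.
#' @slot k K-mer length.
#' @slot canonical Strand convention used for the counts.
#' @slot Lfocal,Lbackground Group lengths (bp) used in the normalization.
#' @slot pos Integer vector of 0-based k-mer start positions, increasing.
#' @slot code 2-bit k-mer code at each position.
#' @slot focalCount,backgroundCount Occurrence counts at each position.
#' @slot ratio Relative-frequency value at each position.
#' @slot backgroundAbsent Logical flag per position.
#'
#' @seealso [relativeProfile()], [profileSummary()], [callClusters()]
#' @export
setClass("KmerProfile", representation(
    chrom = "character",
    k = "integer",
    canonical = "logical",
    Lfocal = "numeric",
    Lbackground = "numeric",
    pos = "integer",
    code = "numeric",
    focalCount = "numeric",
    backgroundCount = "numeric",
    ratio = "numeric",
    backgroundAbsent = "logical"
))

setValidity("KmerProfile", function(object) {
    n <- length(object@pos)
    if (length(object@ratio) != n || length(object@code) != n ||
        length(object@focalCount) != n || length(object@backgroundCount) != n ||
        length(object@backgroundAbsent) != n)
        return("per-position slots must have equal length")
    if (n > 1L && any(diff(object@pos) <= 0L))
        return("positions must be strictly increasing")
    if (n && any(object@ratio < 0))
        return("ratios must be >= 0")
    TRUE
})

#' Monomer: the elementary repeating unit of a satellite array
#'
#' A satellite monomer inferred from an overrepresented cluster: the
#' consensus repeating unit (e.g. the 359-bp unit of the classical
#' X-chromosomal satellite in *D. melanogaster*), its period, and the copy
#' number observed in the source cluster.
#'
#' @slot id Monomer identifier.
#' @slot consensus Consensus nucleotide string; `period == nchar(consensus)`.
#' @slot period Repeat unit length in bp.
#' @slot copyNumber Copy number in the source cluster (sequence length /
#'   period; >= 2).
#' @slot sourceCluster Identifier of the originating cluster (or `NA`).
#' @slot family Family identifier assigned by [groupFamilies()] (or `NA`).
#'
#' @seealso [buildConsensus()], [estimatePeriod()], [groupFamilies()]
#' @export
setClass("Monomer", representation(
    id = "character",
    consensus = "character",
    period = "integer",
    copyNumber = "numeric",
    sourceCluster = "character",
    family = "character"
))

setValidity("Monomer", function(object) {
    if (nchar(object@consensus) != object@period)
        return("period must equal consensus length")
    if (object@period < 1L)
        return("period must be >= 1")
    TRUE
})

#' CoverageTable: per-chromosome satellite hit counts and coverage
#'
#' Per-chromosome hit count, covered bp (union of hit intervals, overlaps
#' not double counted) and percent covered, together with the
#' focal/background coverage ratio: the focal percent divided by each
#' background chromosome's percent, averaged over background chromosomes.
#'
#' @slot perChrom `data.frame` with columns `chrom`, `group`, `length`,
#'   `hit_count`, `covered_bp`, `percent`.
#' @slot ratio Mean over background chromosomes of
#'   `percent_focal / percent_background` (`NA` when undefined).
#'
#' @seealso [coverageTable()]
#' @export
setClass("CoverageTable", representation(
    perChrom = "data.frame",
    ratio = "numeric"
))

#' ExponentialFit: exponential model of satellite density vs recombination
#'
#' The fitted model `response = exp(a + b * rate)` relating per-window
#' satellite abundance (hit count, or covered bp with window length as
#' exposure) to the local recombination rate, estimated by Poisson
#' regression with a log link (or log-least-squares for sensitivity
#' analysis).
#'
#' @slot response `"hits"` or `"coverage"`.
#' @slot intercept,slope Fitted coefficients `a` and `b`.
#' @slot se Standard errors of `(a, b)`.
#' @slot nWindows Number of windows used in the fit.
#' @slot method `"poisson"` or `"loglsq"`.
#'
#' @seealso [fitExponential()], [predictRatio()]
#' @export
setClass("ExponentialFit", representation(
    response = "character",
    intercept = "numeric",
    slope = "numeric",
    se = "numeric",
    nWindows = "integer",
    method = "character"
))

setValidity("ExponentialFit", function(object) {
    if (!is.finite(object@intercept) || !is.finite(object@slope))
        return("coefficients must be finite")
    if (object@nWindows < 3L)
        return("a fit needs at least 3 windows")
    TRUE
})
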