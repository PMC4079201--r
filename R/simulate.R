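#' Configuration for the synthetic satellite genome generator
#'
#' Defaults emulate the satellite landscape the pipeline targets, at desk
#' scale: a focal chromosome strongly enriched for dispersed tandem arrays
#' of a ~359-bp monomer against a pooled autosomal background four times
#' its length, within-locus homogenization (concerted evolution) against
#' between-locus founder divergence, and a piecewise-constant
#' recombination landscape in which insertion intensity follows
#' `exp(b * rate)`.
#'
#' @param seed Integer RNG seed; seeded runs are bit-reproducible.
#' @param focal_name,background_names Chromosome names.
#' @param focal_length,background_lengths Chromosome lengths in bp.
#' @param base_comp Background base composition (named, sums to 1).
#' @param monomer Explicit monomer string, or `NULL` to draw a random one.
#' @param monomer_length Monomer length when drawn (default 359 bp).
#' @param n_loci_focal Number of satellite loci on the focal chromosome.
#' @param n_loci_background Loci per background chromosome.
#' @param copies_min,copies_max Copies per locus, uniform integer draw
#'   (defaults 8--40: arrays of ~2.9--14.4 kb, the typical cluster scale).
#' @param between_divergence Founder substitutions/site between loci
#'   (in `[0, 0.3]`).
#' @param copy_mutation Per-copy substitutions/site applied after the
#'   founder.
#' @param homogenization `h` in `[0, 1]`: probability per site that a copy
#'   mutation is homogenized back to the locus founder state (the
#'   phenomenological concerted-evolution dial; `h = 1` makes same-locus
#'   copies identical).
#' @param density_b Slope linking window recombination rate to insertion
#'   intensity (`weight` proportional to `exp(density_b * rate)`).
#' @param rate_focal_range,rate_background_range Uniform ranges the
#'   per-window rates are drawn from (cM/Mb); the defaults give medians
#'   near 3.3 (focal) and 2.8 (background), the X-vs-autosome contrast
#'   scale.
#' @param window Recombination landscape window size in bp (piecewise
#'   constant; default 250 kb so the density model is exactly
#'   well-specified at the analysis window size).
#' @param spacing Minimum bp between planted loci (keeps arrays distinct).
#' @param max_retries Placement retries before giving up on a chromosome.
#'
#' @return A validated list of class `satSimConfig`.
#' @seealso [simulateGenome()]
#' @export
simConfig <- function(seed = 1L,
                      focal_name = "X", background_names = c("2L", "2R"),
                      focal_length = 1e6, background_lengths = c(2e6, 2e6),
                      base_comp = c(A = 0.29, C = 0.21, G = 0.21, T = 0.29),
                      monomer = NULL, monomer_length = 359L,
                      n_loci_focal = 10L, n_loci_background = 1L,
                      copies_min = 8L, copies_max = 40L,
                      between_divergence = 0.05, copy_mutation = 0.02,
                      homogenization = 0.9, density_b = 2.14,
                      rate_focal_range = c(1.3, 5.3),
                      rate_background_range = c(0.6, 5.0),
                      window = 250000, spacing = 2000L,
                      max_retries = 1000L) {
    cfg <- list(seed = as.integer(seed), focal_name = focal_name,
                background_names = background_names,
                focal_length = focal_length,
                background_lengths = background_lengths,
                base_comp = base_comp, monomer = monomer,
                monomer_length = as.integer(monomer_length),
                n_loci_focal = as.integer(n_loci_focal),
                n_loci_background = as.integer(n_loci_background),
                copies_min = as.integer(copies_min),
                copies_max = as.integer(copies_max),
                between_divergence = between_divergence,
                copy_mutation = copy_mutation,
                homogenization = homogenization, density_b = density_b,
                rate_focal_range = rate_focal_range,
                rate_background_range = rate_background_range,
                window = window, spacing = as.integer(spacing),
                max_retries = as.integer(max_retries))
    stopifnot(cfg$focal_length > 0, all(cfg$background_lengths > 0),
              abs(sum(cfg$base_comp) - 1) < 1e-8,
              cfg$between_divergence >= 0, cfg$between_divergence <= 0.3,
              cfg$copy_mutation >= 0, cfg$copy_mutation <= 0.3,
              cfg$homogenization >= 0, cfg$homogenization <= 1,
              cfg$copies_min >= 2L, cfg$copies_max >= cfg$copies_min)
    class(cfg) <- "satSimConfig"
    cfg
}

.BASES <- c("A", "C", "G", "T")

# substitute sites (1-based indices) of a char vector with a random
# different base
.substitute <- function(chars, sites) {
    for (i in sites)
        chars[i] <- sample(setdiff(.BASES, chars[i]), 1L)
    chars
}

#' Simulate the copies of one satellite locus
#'
#' Applies the generator's concerted-evolution model to a single locus:
#' a locus founder is derived from the monomer by `founderDivergence`
#' substitutions/site, then each copy receives substitutions at
#' `copyMutation`/site, each of which is homogenized back to the founder
#' state with probability `homogenization` (gene-conversion-like
#' within-locus homogenization).  Uses the current RNG state.
#'
#' @param monomer Monomer string.
#' @param nCopies Number of tandem copies.
#' @param founderDivergence,copyMutation Substitution rates per site.
#' @param homogenization `h` in `[0, 1]`.
#' @return A list: `copies` (character vector), `founder` (string), and
#'   `n_mutations` (retained copy mutations per copy).
#' @export
simulateLocusCopies <- function(monomer, nCopies, founderDivergence,
                                copyMutation, homogenization) {
    chars <- strsplit(toupper(monomer), "", fixed = TRUE)[[1L]]
    L <- length(chars)
    founder <- .substitute(chars, which(stats::runif(L) < founderDivergence))
    copies <- character(nCopies)
    nmut <- integer(nCopies)
    for (i in seq_len(nCopies)) {
        sites <- which(stats::runif(L) < copyMutation)
        sites <- sites[stats::runif(length(sites)) >= homogenization]
        copies[i] <- paste(.substitute(founder, sites), collapse = "")
        nmut[i] <- length(sites)
    }
    list(copies = copies, founder = paste(founder, collapse = ""),
         n_mutations = nmut)
}

# Sample non-overlapping locus start positions (1-based) on a chromosome
# with per-window weight ~ width * exp(b * rate).
.placeLoci <- function(chromLength, winStart, winEnd, rate, b, arrayLens,
                       spacing, maxRetries, chromName = "?") {
    weight <- (winEnd - winStart + 1) * exp(b * rate)
    placed <- integer(0)
    placedEnd <- integer(0)
    starts <- integer(length(arrayLens))
    for (i in seq_along(arrayLens)) {
        a <- arrayLens[i]
        ok <- FALSE
        for (try in seq_len(maxRetries)) {
            w <- sample.int(length(weight), 1L, prob = weight)
            hi <- min(winEnd[w], chromLength - a + 1L)
            if (hi < winStart[w]) next
            s <- winStart[w] + floor(stats::runif(1L) * (hi - winStart[w] + 1L))
            e <- s + a - 1L
            if (length(placed) == 0L ||
                all(s > placedEnd + spacing | e < placed - spacing)) {
                ok <- TRUE
                break
            }
        }
        if (!ok)
            stop("could not place locus ", i, " on crowded chromosome ",
                 chromName)
        placed <- c(placed, s)
        placedEnd <- c(placedEnd, e)
        starts[i] <- s
    }
    starts
}

#' Simulate a genome with planted satellite arrays and full ground truth
#'
#' Generates i.i.d. background chromosomes, a piecewise-constant
#' recombination landscape, and dispersed tandem-array loci of a monomer,
#' strongly biased toward the focal chromosome, with locus positions drawn
#' with intensity proportional to `exp(density_b * rate)`.  Within-locus
#' homogenization versus between-locus founder divergence emulates
#' concerted evolution (see [simulateLocusCopies()]).
#'
#' @param config A [simConfig()] list.
#' @return A list with elements `genome` (a [GenomeSet-class]), `map`
#'   (recombination `GRanges` with `rate`), `truth` (list: `monomer` string,
#'   `copies` `GRanges` with mcols `locus`, `copy`, `n_mutations`; `loci`
#'   `GRanges` with mcols `locus`, `n_copies`, `founder`; `windows` the map
#'   with placement `weight`), and `config`.
#' @export
simulateGenome <- function(config = simConfig()) {
    stopifnot(inherits(config, "satSimConfig"))
    set.seed(config$seed)
    monomer <- config$monomer
    if (is.null(monomer))
        monomer <- paste(sample(.BASES, config$monomer_length, replace = TRUE,
                                prob = config$base_comp), collapse = "")
    monomer <- toupper(monomer)

    chromNames <- c(config$focal_name, config$background_names)
    chromLens <- c(config$focal_length, config$background_lengths)
    nLoci <- c(config$n_loci_focal,
               rep(config$n_loci_background,
                   length(config$background_names)))
    seqs <- character(length(chromNames))
    mapPieces <- list()
    copyPieces <- list()
    locusPieces <- list()
    locusCounter <- 0L

    for (ci in seq_along(chromNames)) {
        chrom <- chromNames[ci]
        L <- as.integer(chromLens[ci])
        sq <- paste(sample(.BASES, L, replace = TRUE,
                           prob = config$base_comp), collapse = "")
        ws <- as.integer(seq(1L, L, by = config$window))
        we <- as.integer(pmin(ws + config$window - 1, L))
        rng <- if (ci == 1L) config$rate_focal_range
               else config$rate_background_range
        rate <- stats::runif(length(ws), rng[1L], rng[2L])
        chromF <- factor(chrom, levels = chromNames)
        mapPieces[[ci]] <- GRanges(chromF, IRanges(ws, we), rate = rate,
                                   weight = (we - ws + 1) *
                                       exp(config$density_b * rate))
        if (nLoci[ci] > 0L) {
            copies <- sample(config$copies_min:config$copies_max, nLoci[ci],
                             replace = TRUE)
            arrayLens <- copies * nchar(monomer)
            starts <- .placeLoci(L, ws, we, rate, config$density_b,
                                 arrayLens, config$spacing,
                                 config$max_retries, chrom)
            for (li in seq_len(nLoci[ci])) {
                locusCounter <- locusCounter + 1L
                locusId <- paste0("locus_", locusCounter)
                sim <- simulateLocusCopies(monomer, copies[li],
                                           config$between_divergence,
                                           config$copy_mutation,
                                           config$homogenization)
                arr <- paste(sim$copies, collapse = "")
                s <- starts[li]
                substr(sq, s, s + nchar(arr) - 1L) <- arr
                cs <- s + (seq_len(copies[li]) - 1L) * nchar(monomer)
                copyPieces[[length(copyPieces) + 1L]] <- GRanges(
                    chromF, IRanges(cs, width = nchar(monomer)),
                    locus = locusId, copy = seq_len(copies[li]),
                    n_mutations = sim$n_mutations)
                locusPieces[[length(locusPieces) + 1L]] <- GRanges(
                    chromF, IRanges(s, width = nchar(arr)), locus = locusId,
                    n_copies = copies[li], founder = sim$founder)
            }
        }
        seqs[ci] <- sq
    }
    names(seqs) <- chromNames
    genome <- GenomeSet(seqs[1L], seqs[-1L], species = "synthetic")
    list(genome = genome,
         map = do.call(c, mapPieces),
         truth = list(monomer = monomer,
                      copies = if (length(copyPieces)) do.call(c, copyPieces)
                               else GRanges(),
                      loci = if (length(locusPieces)) do.call(c, locusPieces)
                             else GRanges(),
                      windows = do.call(c, mapPieces)),
         config = config)
}
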