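#' Construct a GenomeSet from focal and background sequences
#'
#' @param focal,background Named [Biostrings::DNAStringSet] objects (or
#'   named character vectors) holding the focal and background chromosomes.
#'   Names must be unique across the two groups.
#' @param species Optional species/assembly label.
#'
#' @return A [GenomeSet-class] object.  Sequences are uppercased.
#'
#' @examples
#' gs <- GenomeSet(
#'     focal = c(X = "ACGTACGTACGT"),
#'     background = c(`2L` = "ACACACACACAC", `2R` = "GTGTGTGTGTGT")
#' )
#' focalLength(gs)
#' @export
GenomeSet <- function(focal, background, species = NA_character_) {
    focal <- .asDNAStringSet(focal)
    background <- .asDNAStringSet(background)
    if (length(focal) == 0L)
        stop("focal group is empty")
    if (length(background) == 0L)
        stop("background group is empty")
    seqs <- c(focal, background)
    new("GenomeSet", species = as.character(species), sequences = seqs,
        group = rep(c("focal", "background"),
                    c(length(focal), length(background))))
}

.asDNAStringSet <- function(x) {
    if (!methods::is(x, "DNAStringSet"))
        x <- DNAStringSet(x)
    # uppercase on ingest: DNAStringSet normalizes case already for the DNA
    # alphabet, but character input may carry lowercase through masks
    DNAStringSet(toupper(as.character(x)))
}

#' Read a multi-FASTA file into a GenomeSet using a grouping map
#'
#' Records whose name is mapped to `"focal"` or `"background"` are kept;
#' records mapped to `"ignore"` or absent from `grouping` are dropped with a
#' warning.
#'
#' @param path Path to a FASTA file.
#' @param grouping Named character vector mapping record names (first
#'   whitespace-delimited token of the header) to `"focal"`,
#'   `"background"` or `"ignore"`.
#' @param species Optional species label.
#'
#' @return A [GenomeSet-class].
#' @export
readGenomeSet <- function(path, grouping, species = NA_character_) {
    if (!file.exists(path))
        stop("FASTA file not found: ", path)
    seqs <- readDNAStringSet(path)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    role <- grouping[names(seqs)]
    role[is.na(role)] <- "ignore"
    if (any(role == "ignore"))
        warning(sum(role == "ignore"), " FASTA record(s) not in grouping; ",
                "dropped: ",
                paste(utils::head(names(seqs)[role == "ignore"], 5),
                      collapse = ", "))
    if (!any(role == "focal"))
        stop("grouping matched no focal record in ", path)
    if (!any(role == "background"))
        stop("grouping matched no background record in ", path)
    GenomeSet(seqs[role == "focal"], seqs[role == "background"],
              species = species)
}

#' Write a GenomeSet to FASTA
#'
#' @param genome A [GenomeSet-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeGenomeSet <- function(genome, path) {
    writeXStringSet(allSeqs(genome), path)
    invisible(path)
}

# ---- accessors ------------------------------------------------------------

#' GenomeSet accessors
#'
#' `focalSeqs()` / `backgroundSeqs()` return the group's chromosomes as a
#' `DNAStringSet`; `allSeqs()` returns both groups; `focalLength()` /
#' `backgroundLength()` return the summed group lengths in bp;
#' `chromGroup()` returns the named group vector; `chromSeq()` extracts one
#' chromosome's sequence as a character string.
#'
#' @param genome A [GenomeSet-class].
#' @param chrom A chromosome name.
#' @return See description.
#' @name genomeset-accessors
NULL

#' @rdname genomeset-accessors
#' @export
focalSeqs <- function(genome) genome@sequences[genome@group == "focal"]

#' @rdname genomeset-accessors
#' @export
backgroundSeqs <- function(genome) genome@sequences[genome@group == "background"]

#' @rdname genomeset-accessors
#' @export
allSeqs <- function(genome) genome@sequences

#' @rdname genomeset-accessors
#' @export
focalLength <- function(genome) sum(Biostrings::width(focalSeqs(genome)))

#' @rdname genomeset-accessors
#' @export
backgroundLength <- function(genome) sum(Biostrings::width(backgroundSeqs(genome)))

#' @rdname genomeset-accessors
#' @export
chromGroup <- function(genome) {
    stats::setNames(genome@group, names(genome@sequences))
}

#' @rdname genomeset-accessors
#' @export
chromSeq <- function(genome, chrom) {
    if (!chrom %in% names(genome@sequences))
        stop("chromosome not in GenomeSet: ", chrom)
    as.character(genome@sequences[[chrom]])
}

#' @rdname genomeset-accessors
#' @export
chromLengths <- function(genome) {
    stats::setNames(Biostrings::width(genome@sequences),
                    names(genome@sequences))
}

setMethod("show", "GenomeSet", function(object) {
    cat("GenomeSet", if (!is.na(object@species)) paste0("(", object@species, ")"),
        "\n  focal:     ", sum(object@group == "focal"), " chromosome(s), ",
        focalLength(object), " bp\n",
        "  background: ", sum(object@group == "background"),
        " chromosome(s), ", backgroundLength(object), " bp\n", sep = "")
})

# ---- recombination map ----------------------------------------------------

#' Read a recombination-rate map
#'
#' Reads a tab-separated windows file (`chrom`, `start`, `end`, `rate` in
#' cM/Mb; 0-based half-open coordinates, no header) into a `GRanges` with a
#' `rate` metadata column.  Windows are validated: per chromosome they must
#' be non-overlapping, with `start < end` and `rate >= 0`.
#'
#' @param path Path to the TSV file.
#' @return A `GRanges` sorted by (chrom, start) with numeric `mcols()$rate`,
#'   or a zero-length `GRanges` (with a warning) for an empty file.
#' @export
readRecombMap <- function(path) {
    if (!file.exists(path))
        stop("recombination map not found: ", path)
    if (file.size(path) == 0L || length(readLines(path, n = 1L)) == 0L) {
        warning("empty recombination map: ", path)
        return(GRanges(rate = numeric(0)))
    }
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
    if (ncol(tab) < 4L)
        stop("recombination map needs >= 4 columns (chrom, start, end, rate)")
    recombMap(chrom = as.character(tab[[1L]]), start = as.numeric(tab[[2L]]),
              end = as.numeric(tab[[3L]]), rate = as.numeric(tab[[4L]]))
}

#' Build and validate a recombination map in memory
#'
#' @param chrom,start,end,rate Parallel vectors; `start`/`end` are 0-based
#'   half-open bp coordinates, `rate` is in cM/Mb.
#' @return A validated, sorted `GRanges` with a `rate` metadata column.
#' @export
recombMap <- function(chrom, start, end, rate) {
    if (any(start >= end))
        stop("recombination map windows must satisfy start < end")
    if (any(rate < 0))
        stop("recombination rates must be >= 0")
    gr <- GRanges(chrom, IRanges(start + 1, end), rate = as.numeric(rate))
    gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
    red <- reduce(gr, ignore.strand = TRUE)
    if (sum(width(red)) != sum(width(gr))) {
        byChrom <- split(gr, as.character(seqnames(gr)))
        for (g in byChrom) {
            if (length(g) < 2L) next
            ov <- which(start(g)[-1L] <= end(g)[-length(g)])
            if (length(ov))
                stop("overlapping recombination windows on ",
                     as.character(seqnames(g))[1L], ": [",
                     start(g)[ov[1L]] - 1L, ",", end(g)[ov[1L]], ") and [",
                     start(g)[ov[1L] + 1L] - 1L, ",", end(g)[ov[1L] + 1L], ")")
        }
    }
    gr
}

#' Write a recombination map to TSV
#'
#' @param map A `GRanges` with a `rate` metadata column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeRecombMap <- function(map, path) {
    utils::write.table(
        data.frame(chrom = as.character(seqnames(map)), start = start(map) - 1L,
                   end = end(map), rate = mcols(map)$rate),
        path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    invisible(path)
}

# ---- BED interval output --------------------------------------------------

#' Write clusters, hits or loci as BED
#'
#' Writes a 6-column BED file (0-based half-open): `chrom`, `start`, `end`,
#' `name`, `score`, `strand`.  The score column carries the peak ratio for
#' clusters, the percent identity (0--1) for hits, and the member count for
#' loci; features are sorted by (chrom, start).  BED's usual 0--1000 score
#' convention is deliberately not enforced, so these files round-trip
#' through [readIntervalsBed()] losslessly.
#'
#' @param items A `GRanges` (e.g. from [callClusters()], [searchMonomer()]
#'   or [groupLoci()]).  The score is taken from the first of the
#'   `peak_ratio`, `identity`, `n_members` or `score` metadata columns
#'   present; names from a `name` column or `cluster_`/`hit_`/`locus_`
#'   running ids.
#' @param path Output path.
#' @param prefix Feature-name prefix used when no `name` column is present.
#' @return `path`, invisibly.
#' @export
writeIntervals <- function(items, path, prefix = "feature") {
    if (length(items) == 0L) {
        file.create(path)
        return(invisible(path))
    }
    items <- GenomicRanges::sort(items, ignore.strand = TRUE)
    mc <- mcols(items)
    scoreCol <- intersect(c("peak_ratio", "identity", "n_members", "score"),
                          colnames(mc))
    score <- if (length(scoreCol)) mc[[scoreCol[1L]]] else 0
    nm <- if ("name" %in% colnames(mc)) mc$name
          else paste0(prefix, "_", seq_along(items))
    str <- as.character(strand(items))
    str[str == "*"] <- "."
    utils::write.table(
        data.frame(chrom = as.character(seqnames(items)),
                   start = start(items) - 1L, end = end(items), name = nm,
                   score = score, strand = str),
        path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read a BED file written by writeIntervals
#'
#' @param path Path to a BED file (>= 3 columns, 0-based half-open).
#' @return A `GRanges` with `name` and `score` metadata columns when
#'   present.
#' @export
readIntervalsBed <- function(path) {
    if (!file.exists(path))
        stop("BED file not found: ", path)
    if (file.size(path) == 0L)
        return(GRanges())
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
    gr <- GRanges(as.character(tab[[1L]]),
                  IRanges(as.numeric(tab[[2L]]) + 1, as.numeric(tab[[3L]])),
                  strand = if (ncol(tab) >= 6L) {
                      s <- as.character(tab[[6L]]); s[s == "."] <- "*"; s
                  } else "*")
    if (ncol(tab) >= 4L) mcols(gr)$name <- as.character(tab[[4L]])
    if (ncol(tab) >= 5L) mcols(gr)$score <- as.numeric(tab[[5L]])
    gr
}
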