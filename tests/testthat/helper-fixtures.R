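suppressPackageStartupMessages({
    library(GenomicRanges)
    library(S4Vectors)
    library(IRanges)
    library(Biostrings)
})

rand_dna <- function(n, comp = c(A = 0.29, C = 0.21, G = 0.21, T = 0.29)) {
    paste(sample(names(comp), n, replace = TRUE, prob = comp),
          collapse = "")
}

revcomp_str <- function(x) {
    vapply(x, function(s) {
        paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "",
                           fixed = TRUE)[[1L]]), collapse = "")
    }, character(1), USE.NAMES = FALSE)
}

# quadratic brute-force k-mer counting oracle: every substring of length k,
# windows containing non-ACGT skipped, optional canonical pooling
brute_count <- function(seqs, k, canonical = TRUE) {
    words <- unlist(lapply(seqs, function(s) {
        n <- nchar(s)
        if (n < k) return(character(0))
        w <- substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
        w[!grepl("[^ACGT]", w)]
    }))
    if (canonical) {
        rc <- revcomp_str(words)
        words <- ifelse(words <= rc, words, rc)
    }
    tab <- table(words)
    stats::setNames(as.numeric(tab), names(tab))
}

# hand-built profile over dummy k-mer codes, for cluster-caller tests
mk_profile <- function(pos0, ratio, chrom = "X", k = 13L,
                       Lf = 1e6, Lb = 2e6) {
    n <- length(pos0)
    methods::new("KmerProfile", chrom = chrom, k = as.integer(k),
                 canonical = TRUE, Lfocal = Lf, Lbackground = Lb,
                 pos = as.integer(pos0), code = numeric(n),
                 focalCount = rep(1, n), backgroundCount = rep(1, n),
                 ratio = as.numeric(ratio), backgroundAbsent = rep(FALSE, n))
}

# transitive-closure oracle for the 1-kb locus rule: returns the partition
# of hit indices as a sorted list of sorted integer vectors
brute_loci <- function(hits, maxGap = 1000) {
    n <- length(hits)
    if (n == 0L) return(list())
    chrom <- as.character(seqnames(hits))
    s <- start(hits); e <- end(hits)
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (chrom[i] != chrom[j]) next
        gap <- max(s[j] - e[i] - 1L, s[i] - e[j] - 1L, 0L)
        adj[i, j] <- gap <= maxGap
    }
    comp <- rep(NA_integer_, n)
    cur <- 0L
    for (i in seq_len(n)) {
        if (!is.na(comp[i])) next
        cur <- cur + 1L
        frontier <- i
        comp[i] <- cur
        while (length(frontier)) {
            nxt <- which(adj[frontier[1L], ] & is.na(comp))
            comp[nxt] <- cur
            frontier <- c(frontier[-1L], nxt)
        }
    }
    parts <- lapply(split(seq_len(n), comp), sort)
    parts[order(vapply(parts, min, integer(1)))]
}

# memoized default-condition simulation shared by heavier tests
.sim_cache <- new.env(parent = emptyenv())
default_sim <- function() {
    if (is.null(.sim_cache$sim))
        .sim_cache$sim <- simulateGenome(simConfig(seed = 20140519))
    .sim_cache$sim
}
default_profile <- function() {
    if (is.null(.sim_cache$profile))
        .sim_cache$profile <- relativeProfile(default_sim()$genome)
    .sim_cache$profile
}
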