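# Independent reference implementations used to check the package's
# statistics. Deliberately written with different primitives than the
# implementations they verify.

# Two-sided Fisher P by direct enumeration of the hypergeometric support
# with choose() ratios (no log-space, no dhyper).
bruteFisherP <- function(a, b, c, d) {
    m <- a + b
    n <- c + d
    k <- a + c
    N <- m + n
    xs <- max(0, k - n):min(k, m)
    pr <- choose(m, xs) * choose(n, k - xs) / choose(N, k)
    obs <- choose(m, a) * choose(n, c) / choose(N, k)
    min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

# Literal Benjamini-Hochberg step-up adjustment: for sorted p(j),
# adj(j) = min over k >= j of min(1, m * p(k) / k), returned in input
# order. Quadratic on purpose -- a direct transcription of the rule.
bhStepUpReference <- function(p) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    adj <- numeric(m)
    for (j in seq_len(m))
        adj[j] <- min(1, min(m * ps[j:m] / (j:m)))
    out <- numeric(m)
    out[o] <- adj
    out
}

# Classic BH step-up rejection set at level alpha: reject the j smallest
# p-values where j is the largest index with p(j) <= alpha * j / m.
bhRejectReference <- function(p, alpha) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    ok <- which(ps <= alpha * seq_len(m) / m)
    rej <- logical(m)
    if (length(ok))
        rej[o[seq_len(max(ok))]] <- TRUE
    rej
}

# All-pairs containment check for insertion-to-gene assignment.
bruteMapCounts <- function(sites, annotation) {
    sChr <- as.character(GenomeInfoDb::seqnames(sites))
    sPos <- BiocGenerics::start(sites)
    sStr <- as.character(BiocGenerics::strand(sites))
    counts <- integer(length(annotation))
    hit <- logical(length(sites))
    for (g in seq_along(annotation)) {
        gChr <- as.character(GenomeInfoDb::seqnames(annotation))[g]
        gs <- BiocGenerics::start(annotation)[g]
        ge <- BiocGenerics::end(annotation)[g]
        gStr <- as.character(BiocGenerics::strand(annotation))[g]
        inGene <- sChr == gChr & sPos >= gs & sPos <= ge & sStr == gStr
        counts[g] <- sum(inGene)
        hit <- hit | inGene
    }
    list(counts = stats::setNames(counts, names(annotation)),
         totalMapped = sum(hit))
}

# Small screen configuration used across tests where the exact scale is
# not the point.
smallConfig <- function(...) {
    defaults <- list(nGenes = 50L, geneLength = 2000L,
                     intergenicFraction = 0.25, nCells = 20000L,
                     seed = 11L)
    args <- utils::modifyList(defaults, list(...))
    do.call(ScreenSimConfig, args)
}
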