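suppressPackageStartupMessages({
    library(GenomicRanges)
    library(S4Vectors)
})

mkExons <- function(chrom, starts, ends, strand) {
    GRanges(chrom, IRanges::IRanges(starts, ends), strand = strand)
}

mkSites <- function(chrom, pos, strand, ids = paste0("s", seq_along(pos))) {
    gr <- GRanges(chrom, IRanges::IRanges(pos, width = 1L), strand = strand)
    gr$site_id <- ids
    gr
}

# Build TranscriptModels in code. exons/utr3: named lists of GRanges
# (utr3 entries may be missing -> empty); txGene: named character vector
# transcript_id -> gene_id.
mkModels <- function(exons, txGene, utr3 = list()) {
    ids <- sort(names(exons), method = "radix")
    exl <- sort(GRangesList(exons)[ids])
    u3 <- lapply(ids, function(tx)
        if (!is.null(utr3[[tx]])) utr3[[tx]] else GRanges())
    names(u3) <- ids
    u3 <- GRangesList(u3)
    tg <- DataFrame(transcript_id = ids, gene_id = unname(txGene[ids]),
                    row.names = ids)
    new("TranscriptModels", exons = exl, utr3 = u3, txGene = tg)
}

# One-transcript-per-gene convenience: genes = list(gene_id = list(exons=,
# utr3=, strand inferred from exons))
mkGeneModels <- function(genes) {
    exons <- list(); utr3 <- list(); txg <- character()
    for (g in names(genes)) {
        tx <- paste0(g, ".t1")
        exons[[tx]] <- genes[[g]]$exons
        if (!is.null(genes[[g]]$utr3)) utr3[[tx]] <- genes[[g]]$utr3
        txg[tx] <- g
    }
    mkModels(exons, txg, utr3)
}

# Independent two-sided Fisher oracle: exhaustive enumeration of the
# hypergeometric distribution via binomial-coefficient log-probabilities
# (lchoose), summing tables no more probable than the observed one.
fisherOracle <- function(a, b, c, d) {
    n <- length(a)
    p <- rep(NA_real_, n)
    for (i in seq_len(n)) {
        r1 <- a[i] + b[i]; r2 <- c[i] + d[i]
        c1 <- a[i] + c[i]; c2 <- b[i] + d[i]
        if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) next
        N <- r1 + r2
        k <- max(0, r1 - c2):min(r1, c1)
        logp <- lchoose(c1, k) + lchoose(c2, r1 - k) - lchoose(N, r1)
        pk <- exp(logp)
        pobs <- exp(lchoose(c1, a[i]) + lchoose(c2, b[i]) - lchoose(N, r1))
        p[i] <- min(1, sum(pk[pk <= pobs * (1 + 1e-7)]))
    }
    p
}

# One-sided hypergeometric upper-tail oracle for enrichment:
# P(X >= a) with X ~ Hypergeom(overlapTotal, N - overlapTotal, targetSize)
hyperTailOracle <- function(a, overlapTotal, N, targetSize) {
    k <- a:min(targetSize, overlapTotal)
    sum(choose(overlapTotal, k) * choose(N - overlapTotal, targetSize - k)) /
        choose(N, targetSize)
}

# Per-gene stats row with an explicit p-value vector, for classifier tests.
mkStats <- function(gene = "g1", mMb = 1, mMc = 2, roar = mMc / mMb,
                    p = rep(0.01, 9), fpkmB = 10, fpkmC = 10, flag = "ok") {
    out <- DataFrame(gene_id = gene, mM_baseline = mMb, mM_contrast = mMc,
                     roar = roar, pvalues = I(matrix(p, nrow = 1)),
                     fpkm_baseline = fpkmB, fpkm_contrast = fpkmC,
                     flag = flag, row.names = gene)
    metadata(out) <- list(baseline = "T0", contrast = "T1",
                          n_pairings = length(p))
    out
}

rbindStats <- function(...) {
    xs <- list(...)
    out <- do.call(rbind, xs)
    metadata(out) <- metadata(xs[[1]])
    out
}

# Minimal SAM text for a set of single-end reads.
mkSam <- function(chrom, pos, width, seqlen = 100000L, qname = NULL,
                  flag = 0L) {
    n <- length(pos)
    if (is.null(qname)) qname <- paste0("r", seq_len(n))
    flag <- rep_len(flag, n)
    c("@HD\tVN:1.6\tSO:unknown",
      sprintf("@SQ\tSN:%s\tLN:%d", unique(chrom), seqlen),
      sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
              qname, flag, rep_len(chrom, n), pos, width,
              vapply(rep_len(width, n), function(k) strrep("A", k), "")))
}

writeSam <- function(lines) {
    f <- tempfile(fileext = ".sam")
    writeLines(lines, f)
    f
}

# A tiny fixed segmentation: two genes on opposite strands.
tinySeg <- function() {
    models <- mkGeneModels(list(
        gA = list(exons = mkExons("chr1", 1001, 3000, "+"),
                  utr3 = mkExons("chr1", 2501, 3000, "+")),
        gB = list(exons = mkExons("chr1", 10001, 12000, "-"),
                  utr3 = mkExons("chr1", 10001, 10500, "-"))))
    sites <- mkSites("chr1", c(2701, 10301), c("+", "-"), c("paA", "paB"))
    buildAllSegmentations(models, sites)
}
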