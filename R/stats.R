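# Vectorized two-sided Fisher exact p for 2x2 tables [[a,b],[c,d]].
# Conditional on the margins, a ~ hypergeometric; the two-sided p sums the
# probabilities of all tables no more likely than the observed one, with the
# customary (1 + 1e-7) relative tolerance on the equality comparison.
# Tables with an all-zero row or column get NA.
fisher2x2 <- function(a, b, c, d) {
    n <- max(length(a), length(b), length(c), length(d))
    a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
    c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
    r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
    ok <- r1 > 0 & r2 > 0 & c1 > 0 & c2 > 0
    p <- rep(NA_real_, n)
    if (!any(ok)) return(p)
    ia <- a[ok]; ic1 <- c1[ok]; ic2 <- c2[ok]; ir1 <- r1[ok]
    lo <- pmax(0, ir1 - ic2); hi <- pmin(ir1, ic1)
    ns <- hi - lo + 1
    id <- rep(seq_along(ia), ns)
    k <- sequence(ns, from = lo, by = 1)
    dk <- stats::dhyper(k, ic1[id], ic2[id], ir1[id])
    dobs <- stats::dhyper(ia, ic1, ic2, ir1)
    keep <- dk <= dobs[id] * (1 + 1e-7)
    p[ok] <- pmin(as.numeric(rowsum(dk * keep, id)), 1)
    p
}

#' Two-sided Fisher exact test on PRE/POST counts of two samples
#'
#' Tests the 2x2 table \code{[[preA, postA], [preB, postB]]} for an imbalance
#' in the PRE:POST ratio between two samples, i.e. a difference in proximal
#' polyA site usage. The p-value is the exact two-sided probability: the sum of
#' hypergeometric probabilities of all tables (given the margins) that are no
#' more probable than the observed one. Tables with an all-zero row or column
#' return \code{NA}.
#'
#' @param preA,postA,preB,postB non-negative integer counts (vectorized).
#' @return p-value(s) in \code{[0, 1]} or \code{NA}.
#' @export
fisherPrePost <- function(preA, postA, preB, postB) {
    cnt <- c(preA, postA, preB, postB)
    if (anyNA(cnt) || any(cnt < 0) || any(cnt != round(cnt)))
        stop("counts must be non-negative integers")
    fisher2x2(preA, postA, preB, postB)
}

#' Short-to-long isoform molar ratio (m/M) from PRE/POST counts
#'
#' Per-base PRE coverage reflects short + long molecules and per-base POST
#' coverage long molecules only, so
#' \code{m/M = (pre/preLength) / (post/postLength) - 1}. The estimate is
#' \code{NA} (undefined) when \code{post == 0}; negative values indicate data
#' inconsistent with the two-isoform model and are flagged downstream rather
#' than clamped.
#'
#' @param preCount,postCount non-negative counts (vectorized).
#' @param preLength,postLength region lengths in bases (> 0).
#' @return numeric vector of m/M estimates.
#' @export
mOverM <- function(preCount, postCount, preLength, postLength) {
    if (any(preLength <= 0) || any(postLength <= 0))
        stop("region lengths must be > 0")
    if (any(c(preCount, postCount) < 0)) stop("counts must be >= 0")
    ifelse(postCount == 0, NA_real_,
           (preCount / preLength) / (postCount / postLength) - 1)
}

#' Ratio of m/M between two conditions (the roar value)
#'
#' \code{roar = mM_contrast / mM_baseline}, with contrast the
#' later/differentiated condition, so a roar value > 1 means 3'UTR shortening
#' during the transition and < 1 lengthening. Undefined (\code{NA}) unless both
#' inputs are defined and positive.
#'
#' @param mMBaseline,mMContrast m/M estimates (vectorized).
#' @return numeric vector of roar values.
#' @export
roarValue <- function(mMBaseline, mMContrast) {
    ifelse(!is.na(mMBaseline) & !is.na(mMContrast) &
           mMBaseline > 0 & mMContrast > 0,
           mMContrast / mMBaseline, NA_real_)
}

conditionColumns <- function(counts, condition) {
    idx <- which(sampleConditions(counts) == condition)
    if (!length(idx)) stop("no samples with condition: ", condition)
    idx
}

#' Fisher p-values for all baseline x contrast replicate pairings of one gene
#'
#' One two-sided \code{\link{fisherPrePost}} p-value per (baseline replicate,
#' contrast replicate) pair, ordered by (baseline index, contrast index).
#'
#' @param counts An \linkS4class{ApaCounts}.
#' @param geneId gene to test.
#' @param baseline,contrast condition labels.
#' @return numeric vector of length nBaseline x nContrast.
#' @export
allPairingsPvalues <- function(counts, geneId, baseline, contrast) {
    if (!geneId %in% rownames(counts))
        stop("gene/sample mismatch: gene ", geneId, " absent from counts")
    bi <- conditionColumns(counts, baseline)
    ci <- conditionColumns(counts, contrast)
    pre <- preCounts(counts)[geneId, ]
    post <- postCounts(counts)[geneId, ]
    grid <- expand.grid(ci = ci, bi = bi)  # contrast fastest, per (b, c) order
    fisher2x2(pre[grid$bi], post[grid$bi], pre[grid$ci], post[grid$ci])
}

poolCondition <- function(counts, condition) {
    idx <- conditionColumns(counts, condition)
    list(pre = rowSums(preCounts(counts)[, idx, drop = FALSE]),
         post = rowSums(postCounts(counts)[, idx, drop = FALSE]),
         lib = sum(librarySize(counts)[idx]))
}

#' Per-gene APA statistics for one comparison
#'
#' For every gene: m/M in each condition and the roar value on counts pooled
#' across replicates within the condition; the FPKM of the PRE (common) region
#' per condition on pooled counts and pooled library sizes; and the matrix of
#' per-pairing Fisher p-values (one per baseline x contrast replicate pair).
#' A validity flag marks genes whose counts defeat the two-isoform model:
#' \code{zero_post} / \code{zero_pre} (a pooled region count of 0 in either
#' condition), \code{negative_mM} (PRE per-base rate below POST), or
#' \code{undefined_roar}; all others are \code{ok}.
#'
#' @param counts An \linkS4class{ApaCounts} covering both conditions.
#' @param seg An \linkS4class{ApaSegmentation} providing region lengths.
#' @param baseline,contrast condition labels (baseline = reference state,
#'   e.g. proliferating; contrast = the differentiated/later state).
#' @return A \code{DataFrame} (one row per gene): \code{gene_id},
#'   \code{mM_baseline}, \code{mM_contrast}, \code{roar}, \code{pvalues}
#'   (matrix column), \code{fpkm_baseline}, \code{fpkm_contrast}, \code{flag};
#'   metadata carries the condition labels and pairing count.
#' @export
apaStats <- function(counts, seg, baseline, contrast) {
    genes <- intersect(rownames(counts), names(seg))
    if (!length(genes))
        stop("counts and segmentation share no genes")
    counts <- counts[genes, ]
    gi <- geneInfo(seg)[genes, ]

    pb <- poolCondition(counts, baseline)
    pc <- poolCondition(counts, contrast)
    mMb <- mOverM(pb$pre, pb$post, gi$pre_length, gi$post_length)
    mMc <- mOverM(pc$pre, pc$post, gi$pre_length, gi$post_length)
    roar <- roarValue(mMb, mMc)
    fpkmB <- fpkm(pb$pre, gi$pre_length, pb$lib)
    fpkmC <- fpkm(pc$pre, gi$pre_length, pc$lib)

    bi <- conditionColumns(counts, baseline)
    ci <- conditionColumns(counts, contrast)
    preM <- preCounts(counts); postM <- postCounts(counts)
    pv <- matrix(NA_real_, nrow = length(genes),
                 ncol = length(bi) * length(ci))
    k <- 0L
    for (b in bi) for (cc in ci) {
        k <- k + 1L
        pv[, k] <- fisher2x2(preM[, b], postM[, b], preM[, cc], postM[, cc])
    }
    colnames(pv) <- paste0("p_", seq_len(k))

    flag <- rep("ok", length(genes))
    flag[(!is.na(mMb) & mMb < 0) | (!is.na(mMc) & mMc < 0)] <- "negative_mM"
    flag[flag == "ok" & is.na(roar)] <- "undefined_roar"
    flag[pb$pre == 0 | pc$pre == 0] <- "zero_pre"
    flag[pb$post == 0 | pc$post == 0] <- "zero_post"

    out <- S4Vectors::DataFrame(
        gene_id = genes, mM_baseline = mMb, mM_contrast = mMc, roar = roar,
        pvalues = I(pv), fpkm_baseline = fpkmB, fpkm_contrast = fpkmC,
        flag = flag, row.names = genes)
    S4Vectors::metadata(out) <- list(baseline = baseline, contrast = contrast,
                                     n_pairings = k)
    out
}

#' Write a per-gene APA statistics table
#'
#' TSV with columns \code{gene_id}, \code{mM_baseline}, \code{mM_contrast},
#' \code{roar}, \code{p_1..p_k}, \code{fpkm_baseline}, \code{fpkm_contrast},
#' \code{flag}, sorted by gene id.
#'
#' @param stats Result of \code{\link{apaStats}}.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
writeStatsTable <- function(stats, path) {
    df <- data.frame(gene_id = stats$gene_id,
                     mM_baseline = stats$mM_baseline,
                     mM_contrast = stats$mM_contrast,
                     roar = stats$roar)
    df <- cbind(df, as.data.frame(unclass(stats$pvalues)))
    df$fpkm_baseline <- stats$fpkm_baseline
    df$fpkm_contrast <- stats$fpkm_contrast
    df$flag <- stats$flag
    df <- df[order(df$gene_id, method = "radix"), ]
    writeTsv(df, path)
}
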