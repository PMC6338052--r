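#' Read CLIP binding sites from a BED-like TSV
#'
#' Expects a header and columns \code{chrom}, \code{start}, \code{end}
#' (0-based half-open), with optional \code{name}, \code{strand}, \code{fdr}
#' and \code{bc} (cluster biological-complexity score) columns. Missing
#' optional columns become \code{NA}/\code{*}.
#'
#' @param path Input TSV path.
#' @return \code{GRanges} with mcols \code{fdr} and \code{bc}.
#' @export
readBindingSites <- function(path) {
    checkFileExists(path, "binding sites")
    df <- utils::read.delim(path, header = TRUE)
    need <- c("chrom", "start", "end")
    if (!all(need %in% colnames(df)))
        apaInputError("binding sites need columns chrom, start, end")
    if (any(df$end <= df$start))
        apaInputError("binding-site intervals must be non-empty")
    gr <- GenomicRanges::GRanges(df$chrom,
        IRanges::IRanges(df$start + 1L, df$end),
        strand = if ("strand" %in% colnames(df)) df$strand else "*")
    gr$fdr <- if ("fdr" %in% colnames(df)) as.numeric(df$fdr) else NA_real_
    gr$bc <- if ("bc" %in% colnames(df)) as.numeric(df$bc) else NA_real_
    gr
}

#' Keep robust binding-site clusters
#'
#' Retains sites with \code{fdr < fdrMax} OR \code{bc >= bcMin} (a missing
#' score fails its clause). Sites missing both scores are dropped and their
#' count reported via \code{message}. Filtering is idempotent.
#'
#' @param sites \code{GRanges} with mcols \code{fdr}, \code{bc}.
#' @param fdrMax,bcMin robustness thresholds (defaults 0.01 and 5).
#' @return The filtered \code{GRanges}.
#' @export
filterRobustSites <- function(sites, fdrMax = 0.01, bcMin = 5) {
    if (!length(sites)) return(sites)
    fdr <- sites$fdr
    bc <- sites$bc
    if (is.null(fdr)) fdr <- rep(NA_real_, length(sites))
    if (is.null(bc)) bc <- rep(NA_real_, length(sites))
    noScore <- is.na(fdr) & is.na(bc)
    if (any(noScore))
        message(sum(noScore), " site(s) without fdr or bc score dropped")
    keep <- (!is.na(fdr) & fdr < fdrMax) | (!is.na(bc) & bc >= bcMin)
    sites[!noScore & keep]
}

#' Genomic spans of segmented genes
#'
#' One interval per gene: the full genomic span (minimum start to maximum end)
#' of the canonical transcript's exons, i.e. PRE plus POST plus the introns
#' between them.
#'
#' @param seg An \linkS4class{ApaSegmentation}.
#' @return \code{GRanges} named by gene id.
#' @export
geneSpans <- function(seg) {
    gi <- geneInfo(seg)
    s <- pmin(min(GenomicRanges::start(seg@pre)),
              min(GenomicRanges::start(seg@post)))
    e <- pmax(max(GenomicRanges::end(seg@pre)),
              max(GenomicRanges::end(seg@post)))
    gr <- GenomicRanges::GRanges(gi$chrom, IRanges::IRanges(s, e),
                                 strand = gi$strand)
    names(gr) <- gi$gene_id
    gr
}

#' Flag genes overlapped by at least one binding site
#'
#' Overlap is on the entire genomic span and ignores strand (position-only
#' matching), one base of overlap suffices.
#'
#' @param spans \code{GRanges} of gene spans (see \code{\link{geneSpans}}).
#' @param sites \code{GRanges} of (filtered) binding sites.
#' @return Named logical vector over the genes.
#' @export
geneOverlaps <- function(spans, sites) {
    shared <- union(GenomeInfoDb::seqlevels(spans),
                    GenomeInfoDb::seqlevels(sites))
    GenomeInfoDb::seqlevels(spans) <- shared
    GenomeInfoDb::seqlevels(sites) <- shared
    ov <- IRanges::overlapsAny(spans, sites, ignore.strand = TRUE)
    names(ov) <- names(spans)
    ov
}

#' Binding-site enrichment of a gene set
#'
#' One-sided (greater) Fisher exact test for over-representation of
#' site-overlapping genes in \code{target} relative to the remaining universe;
#' \code{alternative = "two.sided"} is available. The odds ratio reported is
#' the sample odds ratio (ad/bc), infinite allowed.
#'
#' @param target Character vector of target gene ids (non-empty, subset of the
#'   universe).
#' @param universe Character vector of all analyzed gene ids.
#' @param overlap Named logical vector over the universe (see
#'   \code{\link{geneOverlaps}}).
#' @param alternative \code{"greater"} (default) or \code{"two.sided"}.
#' @return list with \code{table} (2x2 matrix), \code{odds_ratio},
#'   \code{p_value}, \code{alternative}.
#' @export
enrichmentTest <- function(target, universe, overlap,
                           alternative = c("greater", "two.sided")) {
    alternative <- match.arg(alternative)
    target <- unique(target); universe <- unique(universe)
    if (!length(target)) stop("empty target set")
    if (!all(target %in% universe)) stop("target is not a subset of universe")
    if (!all(universe %in% names(overlap)))
        stop("overlap flags missing for some universe genes")
    ov <- overlap[universe]
    isT <- universe %in% target
    a <- sum(isT & ov); b <- sum(isT & !ov)
    c <- sum(!isT & ov); d <- sum(!isT & !ov)
    tab <- matrix(c(a, c, b, d), 2, 2,
                  dimnames = list(c("target", "rest"),
                                  c("overlap", "no_overlap")))
    p <- stats::fisher.test(tab, alternative = alternative)$p.value
    or <- (a * d) / (b * c)  # sample odds ratio; may be Inf or NaN
    list(table = tab, odds_ratio = or, p_value = p, alternative = alternative)
}
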