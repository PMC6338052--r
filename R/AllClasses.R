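#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom GenomicRanges GRanges GRangesList
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom GenomicRanges GRanges GRangesList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Transcript models parsed from a GTF
#'
#' Holds, for every transcript, its exon structure and (when derivable) its
#' 3'UTR, plus the transcript-to-gene map. Exon ranges are 1-based closed
#' \link[GenomicRanges]{GRanges}, sorted by genomic start within each
#' transcript. A transcript whose 3'UTR cannot be determined has a zero-length
#' element in \code{utr3}.
#'
#' @slot exons \code{GRangesList}, one element per transcript, named by
#'   transcript id.
#' @slot utr3 \code{GRangesList} parallel to \code{exons}; 3'UTR exonic
#'   intervals (possibly empty).
#' @slot txGene \code{DataFrame} with columns \code{transcript_id},
#'   \code{gene_id}.
#' @aliases TranscriptModels
#' @exportClass TranscriptModels
setClass("TranscriptModels",
    slots = c(exons = "GRangesList", utr3 = "GRangesList", txGene = "DataFrame"))

setValidity("TranscriptModels", function(object) {
    msg <- NULL
    if (!identical(names(object@exons), object@txGene$transcript_id))
        msg <- c(msg, "names(exons) must equal txGene$transcript_id")
    if (!identical(names(object@exons), names(object@utr3)))
        msg <- c(msg, "exons and utr3 must share names")
    if (anyDuplicated(object@txGene$transcript_id))
        msg <- c(msg, "duplicated transcript ids")
    if (any(sum(IRanges::width(object@exons)) == 0L))
        msg <- c(msg, "every transcript needs positive exonic length")
    if (is.null(msg)) TRUE else msg
})

#' PRE/POST segmentation of genes at their proximal polyA site
#'
#' For every retained gene, the exonic intervals of the canonical transcript
#' are partitioned into a PRE region (shared by the short and the long 3'UTR
#' isoform: transcript 5' end up to the proximal polyadenylation site) and a
#' POST region (present only in the long isoform: proximal site to the
#' canonical 3' end). Genes for which no usable segmentation exists are listed
#' in \code{exclusions} with a machine-readable reason.
#'
#' @slot pre \code{GRangesList} of PRE exonic intervals, named by gene id.
#' @slot post \code{GRangesList} of POST exonic intervals, same names.
#' @slot geneInfo \code{DataFrame}: \code{gene_id}, \code{transcript_id}
#'   (canonical), \code{chrom}, \code{strand}, \code{pre_length},
#'   \code{post_length}, \code{proximal_pos} (1-based coordinate of the
#'   proximal site), \code{canonical_end} (1-based coordinate of the canonical
#'   3'-terminal base).
#' @slot exclusions \code{DataFrame}: \code{gene_id}, \code{reason} in
#'   \code{no_apa_site}, \code{degenerate_pre}, \code{degenerate_post}.
#' @aliases ApaSegmentation
#' @exportClass ApaSegmentation
setClass("ApaSegmentation",
    slots = c(pre = "GRangesList", post = "GRangesList",
              geneInfo = "DataFrame", exclusions = "DataFrame"))

setValidity("ApaSegmentation", function(object) {
    gi <- object@geneInfo
    msg <- NULL
    if (!identical(as.character(names(object@pre)), as.character(gi$gene_id)) ||
        !identical(as.character(names(object@post)), as.character(gi$gene_id)))
        msg <- c(msg, "pre/post names must equal geneInfo$gene_id")
    if (length(object@pre)) {
        preLen <- sum(IRanges::width(object@pre))
        postLen <- sum(IRanges::width(object@post))
        if (!all(preLen > 0L) || !all(postLen > 0L))
            msg <- c(msg, "pre_length and post_length must be positive")
        if (!identical(unname(preLen), as.integer(gi$pre_length)) ||
            !identical(unname(postLen), as.integer(gi$post_length)))
            msg <- c(msg, "geneInfo lengths disagree with interval widths")
        ov <- sum(IRanges::width(GenomicRanges::intersect(
            object@pre, object@post)))
        if (any(ov > 0L))
            msg <- c(msg, "pre and post intervals must be disjoint")
    }
    if (is.null(msg)) TRUE else msg
})

#' Per-sample PRE/POST read counts
#'
#' A \link[SummarizedExperiment]{SummarizedExperiment} with two integer assays,
#' \code{pre} and \code{post} (genes x samples), and column data carrying
#' \code{sample_id}, \code{condition} and \code{library_size} (the number of
#' primary mapped alignments in the sample, used for FPKM).
#'
#' @aliases ApaCounts
#' @exportClass ApaCounts
setClass("ApaCounts", contains = "SummarizedExperiment")

setValidity("ApaCounts", function(object) {
    msg <- NULL
    an <- SummarizedExperiment::assayNames(object)
    if (!all(c("pre", "post") %in% an))
        msg <- c(msg, "assays 'pre' and 'post' are required")
    cd <- SummarizedExperiment::colData(object)
    need <- c("sample_id", "condition", "library_size")
    if (!all(need %in% colnames(cd)))
        msg <- c(msg, paste("colData must have:", paste(need, collapse = ", ")))
    else {
        if (any(cd$library_size <= 0)) msg <- c(msg, "library_size must be > 0")
        if (anyDuplicated(cd$sample_id)) msg <- c(msg, "duplicated sample_id")
    }
    if (all(c("pre", "post") %in% an)) {
        for (a in c("pre", "post")) {
            m <- SummarizedExperiment::assay(object, a)
            if (any(m < 0) || any(m != round(m)))
                msg <- c(msg, sprintf("assay '%s' must hold integers >= 0", a))
        }
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct an ApaCounts object
#'
#' @param pre,post integer matrices (genes x samples) of PRE/POST counts with
#'   identical dimnames.
#' @param sampleId,condition character vectors, one entry per column.
#' @param librarySize positive numeric vector of total primary mapped
#'   alignments per sample.
#' @return An \linkS4class{ApaCounts} object.
#' @export
ApaCounts <- function(pre, post, sampleId, condition, librarySize) {
    pre <- as.matrix(pre); post <- as.matrix(post)
    stopifnot(identical(dim(pre), dim(post)),
              identical(dimnames(pre), dimnames(post)))
    mode(pre) <- "integer"; mode(post) <- "integer"
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(pre = pre, post = post),
        colData = S4Vectors::DataFrame(
            sample_id = as.character(sampleId),
            condition = as.character(condition),
            library_size = as.numeric(librarySize),
            row.names = as.character(sampleId)))
    new("ApaCounts", se)
}

#' Consensus of APA calls across comparisons
#'
#' Set algebra over per-comparison shortened/lengthened call sets: the genes
#' called in every comparison ("always" sets) and exact Venn region counts
#' keyed by the combination of comparisons a gene appears in.
#'
#' @slot comparisons character vector of comparison labels.
#' @slot calls \code{DataFrame} of calls, genes x comparisons.
#' @slot alwaysShortened,alwaysLengthened character vectors of gene ids.
#' @slot vennShortened,vennLengthened named integer vectors; names are
#'   "&"-joined comparison combinations, values the number of genes called in
#'   exactly that combination.
#' @aliases ApaConsensus
#' @exportClass ApaConsensus
setClass("ApaConsensus",
    slots = c(comparisons = "character", calls = "DataFrame",
              alwaysShortened = "character", alwaysLengthened = "character",
              vennShortened = "integer", vennLengthened = "integer"))

setValidity("ApaConsensus", function(object) {
    msg <- NULL
    if (!identical(colnames(object@calls), object@comparisons))
        msg <- c(msg, "calls columns must match comparisons")
    if (sum(object@vennShortened) !=
        length(unique(unlist(lapply(object@comparisons, function(cc)
            rownames(object@calls)[object@calls[[cc]] == "SHORTENED"])))))
        msg <- c(msg, "vennShortened counts must sum to the union size")
    if (is.null(msg)) TRUE else msg
})

#' Synthetic APA genome with ground truth
#'
#' Output of \code{\link{simulateApaGenome}}: synthetic transcript models and
#' polyA sites together with the generating truth (per-gene long-isoform
#' fraction per condition, true class, expected relative expression, and the
#' PRE/POST lengths implied by the planted proximal site).
#'
#' @slot models \linkS4class{TranscriptModels}.
#' @slot sites \code{GRanges} of polyA sites (width 1, named \code{site_id}).
#' @slot truth \code{DataFrame}, one row per gene.
#' @slot conditions character vector of condition labels.
#' @aliases SyntheticApaGenome
#' @exportClass SyntheticApaGenome
setClass("SyntheticApaGenome",
    slots = c(models = "TranscriptModels", sites = "GRanges",
              truth = "DataFrame", conditions = "character"))
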