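#' @rdname ApaSegmentation-class
#' @export
setMethod("preRegions", "ApaSegmentation", function(x) x@pre)

#' @rdname ApaSegmentation-class
#' @export
setMethod("postRegions", "ApaSegmentation", function(x) x@post)

#' @rdname ApaSegmentation-class
#' @export
setMethod("geneInfo", "ApaSegmentation", function(x) x@geneInfo)

#' @rdname ApaSegmentation-class
#' @export
setMethod("exclusions", "ApaSegmentation", function(x) x@exclusions)

#' @rdname ApaSegmentation-class
#' @export
setMethod("length", "ApaSegmentation", function(x) length(x@pre))

#' @rdname ApaSegmentation-class
#' @export
setMethod("names", "ApaSegmentation", function(x) names(x@pre))

setMethod("show", "ApaSegmentation", function(object) {
    cat("ApaSegmentation with", length(object), "genes and",
        nrow(object@exclusions), "exclusions\n")
    if (length(object)) {
        gi <- object@geneInfo
        cat("  pre_length:", paste(range(gi$pre_length), collapse = "-"),
            " post_length:", paste(range(gi$post_length), collapse = "-"), "\n")
    }
    if (nrow(object@exclusions)) {
        tab <- table(object@exclusions$reason)
        cat("  exclusions:", paste(names(tab), tab, sep = "=", collapse = ", "),
            "\n")
    }
})

#' @rdname ApaCounts-class
#' @export
setMethod("preCounts", "ApaCounts", function(x)
    SummarizedExperiment::assay(x, "pre"))

#' @rdname ApaCounts-class
#' @export
setMethod("postCounts", "ApaCounts", function(x)
    SummarizedExperiment::assay(x, "post"))

#' @rdname ApaCounts-class
#' @export
setMethod("librarySize", "ApaCounts", function(x) {
    ls <- SummarizedExperiment::colData(x)$library_size
    names(ls) <- colnames(x)
    ls
})

#' @rdname ApaCounts-class
#' @export
setMethod("sampleConditions", "ApaCounts", function(x) {
    cc <- SummarizedExperiment::colData(x)$condition
    names(cc) <- colnames(x)
    cc
})

#' @rdname SyntheticApaGenome-class
#' @export
setMethod("truthTable", "SyntheticApaGenome", function(x) x@truth)

#' @rdname SyntheticApaGenome-class
#' @export
setMethod("transcriptModels", "SyntheticApaGenome", function(x) x@models)

#' @rdname SyntheticApaGenome-class
#' @export
setMethod("polyASites", "SyntheticApaGenome", function(x) x@sites)

setMethod("show", "SyntheticApaGenome", function(object) {
    cat("SyntheticApaGenome:", nrow(object@truth), "genes,",
        length(object@sites), "polyA sites,",
        length(object@conditions), "conditions (",
        paste(object@conditions, collapse = ", "), ")\n")
    cat("  true classes:",
        paste(names(table(object@truth$true_class)),
              table(object@truth$true_class), sep = "=", collapse = ", "), "\n")
})

#' @rdname ApaConsensus-class
#' @export
setMethod("alwaysShortened", "ApaConsensus", function(x) x@alwaysShortened)

#' @rdname ApaConsensus-class
#' @export
setMethod("alwaysLengthened", "ApaConsensus", function(x) x@alwaysLengthened)

#' @rdname ApaConsensus-class
#' @export
setMethod("vennCounts", "ApaConsensus", function(x)
    list(SHORTENED = x@vennShortened, LENGTHENED = x@vennLengthened))

setMethod("show", "ApaConsensus", function(object) {
    cat("ApaConsensus over", length(object@comparisons), "comparisons:",
        paste(object@comparisons, collapse = ", "), "\n")
    cat("  always shortened:", length(object@alwaysShortened),
        " always lengthened:", length(object@alwaysLengthened), "\n")
})
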