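#' @rdname ApaSegmentation-class
#' @param x,object an object.
#' @export
setGeneric("preRegions", function(x) standardGeneric("preRegions"))

#' @rdname ApaSegmentation-class
#' @export
setGeneric("postRegions", function(x) standardGeneric("postRegions"))

#' @rdname ApaSegmentation-class
#' @export
setGeneric("geneInfo", function(x) standardGeneric("geneInfo"))

#' @rdname ApaSegmentation-class
#' @export
setGeneric("exclusions", function(x) standardGeneric("exclusions"))

#' @rdname ApaCounts-class
#' @param x an object.
#' @export
setGeneric("preCounts", function(x) standardGeneric("preCounts"))

#' @rdname ApaCounts-class
#' @export
setGeneric("postCounts", function(x) standardGeneric("postCounts"))

#' @rdname ApaCounts-class
#' @export
setGeneric("librarySize", function(x) standardGeneric("librarySize"))

#' @rdname ApaCounts-class
#' @export
setGeneric("sampleConditions", function(x) standardGeneric("sampleConditions"))

#' @rdname SyntheticApaGenome-class
#' @param x an object.
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))

#' @rdname SyntheticApaGenome-class
#' @export
setGeneric("transcriptModels", function(x) standardGeneric("transcriptModels"))

#' @rdname SyntheticApaGenome-class
#' @export
setGeneric("polyASites", function(x) standardGeneric("polyASites"))

#' @rdname ApaConsensus-class
#' @param x an object.
#' @export
setGeneric("alwaysShortened", function(x) standardGeneric("alwaysShortened"))

#' @rdname ApaConsensus-class
#' @export
setGeneric("alwaysLengthened", function(x) standardGeneric("alwaysLengthened"))

#' @rdname ApaConsensus-class
#' @export
setGeneric("vennCounts", function(x) standardGeneric("vennCounts"))
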