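#' Count aligned reads into PRE and POST regions
#'
#' Assigns every primary, mapped alignment overlapping a gene's PRE or POST
#' region by at least one base. Under the default boundary rule
#' (\code{boundary = "post"}) a read overlapping both regions of a gene is
#' assigned to POST only, since such reads can only originate from the long
#' isoform; \code{boundary = "both"} counts it in both regions. Secondary,
#' supplementary and unmapped alignments are ignored; duplicates are kept. A
#' read overlapping the regions of two genes is counted for both (a message
#' reports how many). The library size is the number of primary mapped
#' alignments in the file. Files that htslib cannot parse are rejected.
#'
#' @param file SAM or BAM file (SAM is converted on the fly).
#' @param seg An \linkS4class{ApaSegmentation}.
#' @param sampleId,condition sample annotation for the resulting column.
#' @param stranded \code{"none"} (default; read strand ignored),
#'   \code{"forward"} (read strand must match the gene) or \code{"reverse"}.
#' @param boundary \code{"post"} (default) or \code{"both"}; see above.
#' @return A one-sample \linkS4class{ApaCounts}; combine samples with
#'   \code{cbind}.
#' @export
countReads <- function(file, seg, sampleId, condition,
                       stranded = c("none", "forward", "reverse"),
                       boundary = c("post", "both")) {
    stranded <- match.arg(stranded)
    boundary <- match.arg(boundary)
    checkFileExists(file, "alignment")
    if (length(seg) == 0L) stop("empty segmentation")
    if (grepl("\\.sam$", file, ignore.case = TRUE)) {
        dest <- tempfile(fileext = "")
        file <- Rsamtools::asBam(file, dest, overwrite = TRUE,
                                 indexDestination = FALSE)
    }
    param <- Rsamtools::ScanBamParam(flag = Rsamtools::scanBamFlag(
        isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
        isSupplementaryAlignment = FALSE))
    aln <- GenomicAlignments::readGAlignments(file, param = param)
    lib <- length(aln)
    if (lib == 0L) stop("no usable alignments in ", file)
    reads <- GenomicRanges::granges(aln)

    genes <- names(seg)
    gStrand <- geneInfo(seg)$strand
    pairsFor <- function(grl) {
        h <- GenomicRanges::findOverlaps(reads, grl, ignore.strand = TRUE)
        q <- S4Vectors::queryHits(h); s <- S4Vectors::subjectHits(h)
        if (stranded != "none") {
            rs <- as.character(GenomicRanges::strand(reads))[q]
            keep <- if (stranded == "forward") rs == gStrand[s]
                    else rs != gStrand[s]
            q <- q[keep]; s <- s[keep]
        }
        unique(q * (length(genes) + 1) + s)  # encoded (read, gene) pairs
    }
    postKeys <- pairsFor(seg@post)
    preKeys <- pairsFor(seg@pre)
    if (boundary == "post") preKeys <- setdiff(preKeys, postKeys)

    nMulti <- sum(duplicated(floor(c(preKeys, postKeys) / (length(genes) + 1))))
    if (nMulti > 0)
        message(nMulti, " read(s) assigned to more than one gene")

    decode <- function(keys) tabulate(keys %% (length(genes) + 1),
                                      nbins = length(genes))
    pre <- matrix(decode(preKeys), ncol = 1, dimnames = list(genes, sampleId))
    post <- matrix(decode(postKeys), ncol = 1, dimnames = list(genes, sampleId))
    ApaCounts(pre, post, sampleId, condition, lib)
}

#' Write a single-sample PRE/POST counts table
#'
#' The dialect is a one-line header comment carrying the sample annotation,
#' \preformatted{# sample_id=<id> condition=<cond> library_size=<n>}
#' followed by a TSV with columns \code{gene_id}, \code{pre_count},
#' \code{post_count}.
#'
#' @param counts An \linkS4class{ApaCounts}.
#' @param sample Column (sample id or index) to write.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeCountsTable <- function(counts, sample, path) {
    x <- counts[, sample]
    cd <- SummarizedExperiment::colData(x)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# sample_id=%s condition=%s library_size=%d",
                       cd$sample_id, cd$condition,
                       as.integer(cd$library_size)), con)
    df <- data.frame(gene_id = rownames(x),
                     pre_count = as.integer(preCounts(x)),
                     post_count = as.integer(postCounts(x)))
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a single-sample PRE/POST counts table
#'
#' Inverse of \code{\link{writeCountsTable}}. Duplicate gene rows, negative or
#' non-integer counts are rejected.
#'
#' @param path Counts TSV path.
#' @return A one-sample \linkS4class{ApaCounts}.
#' @export
readCountsTable <- function(path) {
    checkFileExists(path, "counts table")
    hdr <- readLines(path, n = 1L)
    m <- regmatches(hdr, regexec(
        "^#\\s*sample_id=(\\S+)\\s+condition=(\\S+)\\s+library_size=(\\S+)\\s*$",
        hdr))[[1]]
    if (length(m) != 4L)
        apaInputError(paste0("counts table lacks the sample header line: ", path))
    df <- utils::read.delim(path, skip = 1L, header = TRUE,
                            colClasses = "character")
    if (!identical(colnames(df), c("gene_id", "pre_count", "post_count")))
        apaInputError("counts table needs columns gene_id, pre_count, post_count")
    if (anyDuplicated(df$gene_id))
        apaInputError(paste0("duplicated gene_id in counts table: ", path))
    df$pre_count <- suppressWarnings(as.numeric(df$pre_count))
    df$post_count <- suppressWarnings(as.numeric(df$post_count))
    cnt <- c(df$pre_count, df$post_count)
    if (anyNA(cnt) || any(cnt < 0) || any(cnt != round(cnt)))
        apaInputError(paste0("malformed counts in ", path))
    lib <- suppressWarnings(as.numeric(m[4]))
    if (is.na(lib) || lib <= 0)
        apaInputError(paste0("malformed library_size in ", path))
    ApaCounts(matrix(as.integer(df$pre_count), ncol = 1,
                     dimnames = list(df$gene_id, m[2])),
              matrix(as.integer(df$post_count), ncol = 1,
                     dimnames = list(df$gene_id, m[2])),
              sampleId = m[2], condition = m[3], librarySize = lib)
}

#' Read and combine several counts tables
#'
#' @param paths Counts TSV paths; all tables must cover the same genes.
#' @return A multi-sample \linkS4class{ApaCounts}.
#' @export
readCountsTables <- function(paths) {
    xs <- lapply(paths, readCountsTable)
    g <- rownames(xs[[1]])
    for (x in xs[-1]) {
        if (!setequal(rownames(x), g))
            apaInputError("counts tables cover different gene sets")
    }
    xs <- lapply(xs, function(x) x[g, ])
    do.call(SummarizedExperiment::cbind, xs)
}

#' Fragments per kilobase per million mapped reads
#'
#' \code{fpkm = count / ((length/1000) * (librarySize/1e6))}. Used as the
#' expression filter on the PRE (common) region.
#'
#' @param count numeric vector of fragment counts (>= 0).
#' @param length region length in bases (> 0).
#' @param librarySize total mapped reads (> 0).
#' @return numeric vector of FPKM values.
#' @export
fpkm <- function(count, length, librarySize) {
    if (any(length <= 0)) stop("length must be > 0")
    if (any(librarySize <= 0)) stop("librarySize must be > 0")
    if (any(count < 0)) stop("count must be >= 0")
    count / ((length / 1000) * (librarySize / 1e6))
}
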