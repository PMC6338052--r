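#' Read transcript models from a GTF/GFF file
#'
#' Parses exon features (requiring \code{gene_id} and \code{transcript_id}
#' attributes) and determines each transcript's 3'UTR: an explicit
#' \code{three_prime_utr}/\code{3UTR}/\code{UTR3} feature is used when present;
#' otherwise the 3'UTR is inferred as the exonic bases 3' of the CDS (including
#' any separate \code{stop_codon} feature). Transcripts with neither carry an
#' empty 3'UTR and rely on the proximal-site fallback rule downstream.
#'
#' GTF coordinates (1-based closed) are kept as-is in \code{GRanges}; BED
#' interfaces convert to/from 0-based half-open at the file boundary.
#'
#' @param path GTF/GFF file.
#' @return A \linkS4class{TranscriptModels} object.
#' @export
readTranscriptModels <- function(path) {
    checkFileExists(path, "annotation")
    gr <- rtracklayer::import(path)
    mc <- S4Vectors::mcols(gr)
    if (!"type" %in% colnames(mc))
        apaInputError("annotation has no feature type column")
    type <- as.character(gr$type)
    ex <- gr[type == "exon"]
    if (!length(ex)) apaInputError("annotation has no exon features")
    if (is.null(ex$transcript_id) || is.null(ex$gene_id) ||
        anyNA(ex$transcript_id) || anyNA(ex$gene_id))
        apaInputError("exon features need gene_id and transcript_id")
    txIds <- radixSort(unique(ex$transcript_id))
    exl <- sort(S4Vectors::splitAsList(
        GenomicRanges::granges(ex), factor(ex$transcript_id, levels = txIds)))
    str1 <- unlist(S4Vectors::runValue(GenomicRanges::strand(exl)))
    if (length(str1) != length(txIds) || any(!str1 %in% c("+", "-")))
        apaInputError("each transcript must lie on a single +/- strand")

    tg <- unique(data.frame(transcript_id = ex$transcript_id,
                            gene_id = ex$gene_id))
    if (anyDuplicated(tg$transcript_id))
        apaInputError("a transcript_id maps to more than one gene_id")
    tg <- tg[order(tg$transcript_id, method = "radix"), , drop = FALSE]

    # explicit 3'UTR features
    utrType <- c("three_prime_utr", "three_prime_UTR", "3UTR", "UTR3")
    u <- gr[type %in% utrType]
    explicitTx <- unique(u$transcript_id)
    u3l <- S4Vectors::splitAsList(GenomicRanges::granges(u),
                                  factor(u$transcript_id, levels = txIds))

    # inference from CDS/stop_codon for the remaining transcripts
    cds <- gr[type %in% c("CDS", "stop_codon")]
    inferTx <- setdiff(intersect(txIds, unique(cds$transcript_id)), explicitTx)
    if (length(inferTx)) {
        cdsl <- S4Vectors::splitAsList(GenomicRanges::granges(cds),
            factor(cds$transcript_id, levels = inferTx))
        isPlus <- as.character(str1[match(inferTx, txIds)]) == "+"
        cdsEnd <- unname(max(GenomicRanges::end(cdsl)))
        cdsStart <- unname(min(GenomicRanges::start(cdsl)))
        inf <- lapply(seq_along(inferTx), function(i) {
            e <- exl[[inferTx[i]]]
            if (isPlus[i])
                GenomicRanges::restrict(e, start = cdsEnd[i] + 1L)
            else
                GenomicRanges::restrict(e, end = cdsStart[i] - 1L)
        })
        u3l[inferTx] <- GenomicRanges::GRangesList(inf)
    }
    u3l <- sort(u3l)

    new("TranscriptModels", exons = exl, utr3 = u3l,
        txGene = S4Vectors::DataFrame(tg, row.names = tg$transcript_id))
}

#' Read polyA sites from a 6-column BED file
#'
#' Each record is a single-base site; the BED name column is the site id and
#' column 6 its strand (required). Import converts to 1-based coordinates.
#'
#' @param path BED file.
#' @return \code{GRanges} with an mcol \code{site_id}.
#' @export
readPolyASites <- function(path) {
    checkFileExists(path, "polyA sites")
    gr <- rtracklayer::import(path, format = "BED")
    if (any(as.character(GenomicRanges::strand(gr)) == "*"))
        apaInputError("polyA sites must carry a +/- strand (BED column 6)")
    id <- gr$name
    if (is.null(id) || anyNA(id)) id <- paste0("site_", seq_along(gr))
    gr <- GenomicRanges::granges(gr)
    gr$site_id <- id
    gr
}

exonicLength <- function(models, txIds = names(models@exons)) {
    len <- sum(IRanges::width(models@exons))
    len[txIds]
}

#' Select the canonical transcript of a gene
#'
#' The canonical transcript is the one with the largest exonic length (the
#' gene's "longest transcript"); ties break to the lexicographically smallest
#' transcript id for reproducibility.
#'
#' @param models A \linkS4class{TranscriptModels} object.
#' @param geneId Gene identifier.
#' @return The canonical transcript id.
#' @export
selectCanonicalTranscript <- function(models, geneId) {
    tx <- models@txGene$transcript_id[models@txGene$gene_id == geneId]
    if (!length(tx)) stop("no transcripts for gene: ", geneId)
    len <- exonicLength(models, tx)
    radixSort(tx[len == max(len)])[1L]
}

#' Choose the proximal polyA site of a transcript
#'
#' Among the supplied sites on the transcript's chromosome and strand, returns
#' the most 5'-proximal site (smallest coordinate on +, largest on -) falling
#' inside the transcript's 3'UTR. If the 3'UTR contains no site, the same rule
#' is applied over the transcript's full genomic span (fallback). Ties at the
#' same position break to the smallest site id. Returns \code{NULL} when no
#' usable site exists.
#'
#' @param models A \linkS4class{TranscriptModels} object.
#' @param txId Transcript id.
#' @param sites \code{GRanges} of polyA sites (see \code{\link{readPolyASites}}).
#' @return A length-1 \code{GRanges}, or \code{NULL}.
#' @export
chooseProximalSite <- function(models, txId, sites) {
    ex <- models@exons[[txId]]
    if (is.null(ex)) stop("unknown transcript: ", txId)
    str <- as.character(S4Vectors::runValue(GenomicRanges::strand(ex)))[1L]
    chr <- as.character(S4Vectors::runValue(GenomicRanges::seqnames(ex)))[1L]
    s <- sites[as.character(GenomicRanges::seqnames(sites)) == chr &
               as.character(GenomicRanges::strand(sites)) == str]
    if (!length(s)) return(NULL)
    u3 <- models@utr3[[txId]]
    cand <- if (length(u3))
        s[IRanges::overlapsAny(IRanges::ranges(s), IRanges::ranges(u3))]
    else s[0]
    if (!length(cand)) {
        span <- range(IRanges::ranges(ex))
        cand <- s[IRanges::overlapsAny(IRanges::ranges(s), span)]
    }
    if (!length(cand)) return(NULL)
    key <- if (str == "+") GenomicRanges::start(cand)
           else -GenomicRanges::start(cand)
    cand[order(key, cand$site_id, method = "radix")][1L]
}

# Split sorted exon ranges at a genomic point P (1-based): bases with
# coordinate < P form the genomically-left part, bases >= P the right part.
# The 5'-side part (left on +, right on -) is PRE.
splitExonsAt <- function(exons, P) {
    str <- as.character(S4Vectors::runValue(GenomicRanges::strand(exons)))[1L]
    left <- GenomicRanges::restrict(exons, end = P - 1L)
    right <- GenomicRanges::restrict(exons, start = P)
    if (str == "+") list(pre = left, post = right)
    else list(pre = right, post = left)
}

#' Build the PRE/POST segmentation of one transcript
#'
#' Partitions the transcript's exonic bases at the proximal polyA site: PRE is
#' the 5' part (shared by short and long isoforms), POST the remainder up to
#' the canonical 3' end (long isoform only). The split point is the site's
#' genomic start coordinate; bases genomically left of it go to the 5'-side
#' region on the + strand and to the 3'-side region on the - strand.
#'
#' @param exons \code{GRanges} of one transcript's exons (single chrom/strand).
#' @param proximal A length-1 \code{GRanges} (the site) or a 1-based numeric
#'   genomic coordinate.
#' @return \code{list(pre, post)} of \code{GRanges}; errors with
#'   \code{"degenerate PRE"} / \code{"degenerate POST"} when the split leaves
#'   either region empty.
#' @export
buildSegmentation <- function(exons, proximal) {
    if (is(proximal, "GRanges")) {
        stopifnot(length(proximal) == 1L)
        if (as.character(GenomicRanges::seqnames(proximal)) !=
            as.character(S4Vectors::runValue(GenomicRanges::seqnames(exons)))[1L])
            stop("proximal site on a different chromosome than the transcript")
        P <- GenomicRanges::start(proximal)
    } else {
        P <- as.integer(proximal)
    }
    parts <- splitExonsAt(exons, P)
    if (sum(IRanges::width(parts$pre)) == 0L) stop("degenerate PRE")
    if (sum(IRanges::width(parts$post)) == 0L) stop("degenerate POST")
    parts
}

#' Build PRE/POST segmentations for all genes
#'
#' For every gene: pick the canonical (longest) transcript, choose the most
#' 5'-proximal polyA site in its 3'UTR (falling back to the transcript span),
#' and split the exonic bases into PRE and POST. Genes without a usable site or
#' whose split is degenerate are excluded with a machine-readable reason
#' (\code{no_apa_site}, \code{degenerate_pre}, \code{degenerate_post}) rather
#' than raising an error.
#'
#' @param models A \linkS4class{TranscriptModels} object.
#' @param sites \code{GRanges} of polyA sites.
#' @return An \linkS4class{ApaSegmentation} object.
#' @export
buildAllSegmentations <- function(models, sites) {
    tg <- models@txGene
    genes <- radixSort(unique(tg$gene_id))

    # canonical transcript per gene (max exonic length, ties to smallest id)
    txLen <- exonicLength(models, tg$transcript_id)
    o <- order(tg$gene_id, -txLen, tg$transcript_id, method = "radix")
    firstHit <- !duplicated(tg$gene_id[o])
    canonTx <- tg$transcript_id[o][firstHit]
    names(canonTx) <- tg$gene_id[o][firstHit]
    canonTx <- canonTx[genes]

    exSel <- models@exons[canonTx]
    names(exSel) <- genes
    u3Sel <- models@utr3[canonTx]
    names(u3Sel) <- genes
    spans <- unlist(range(exSel), use.names = FALSE)
    geneStrand <- as.character(GenomicRanges::strand(spans))
    geneChrom <- as.character(GenomicRanges::seqnames(spans))

    shared <- union(GenomeInfoDb::seqlevels(exSel),
                    GenomeInfoDb::seqlevels(sites))
    GenomeInfoDb::seqlevels(sites) <- shared
    GenomeInfoDb::seqlevels(exSel) <- shared
    GenomeInfoDb::seqlevels(u3Sel) <- shared
    GenomeInfoDb::seqlevels(spans) <- shared

    hitU <- GenomicRanges::findOverlaps(sites, u3Sel)
    hitS <- GenomicRanges::findOverlaps(sites, spans)
    dfU <- data.frame(g = S4Vectors::subjectHits(hitU),
                      s = S4Vectors::queryHits(hitU))
    dfS <- data.frame(g = S4Vectors::subjectHits(hitS),
                      s = S4Vectors::queryHits(hitS))
    dfS <- dfS[!(dfS$g %in% unique(dfU$g)), , drop = FALSE]
    cand <- rbind(dfU, dfS)

    excl <- data.frame(gene_id = character(), reason = character())
    if (nrow(cand)) {
        pos <- GenomicRanges::start(sites)[cand$s]
        key <- ifelse(geneStrand[cand$g] == "+", pos, -pos)
        oc <- order(cand$g, key, sites$site_id[cand$s], method = "radix")
        cand <- cand[oc, , drop = FALSE]
        pick <- cand[!duplicated(cand$g), , drop = FALSE]
    } else {
        pick <- cand
    }
    noSite <- setdiff(seq_along(genes), pick$g)
    if (length(noSite))
        excl <- rbind(excl, data.frame(gene_id = genes[noSite],
                                       reason = "no_apa_site"))

    keptGenes <- character(); preGRL <- GenomicRanges::GRangesList()
    postGRL <- preGRL
    gi <- S4Vectors::DataFrame(gene_id = character(), transcript_id = character(),
        chrom = character(), strand = character(), pre_length = integer(),
        post_length = integer(), proximal_pos = integer(),
        canonical_end = integer(), proximal_site = character())
    if (nrow(pick)) {
        gIdx <- pick$g
        P <- GenomicRanges::start(sites)[pick$s]
        exPick <- exSel[gIdx]
        nEx <- S4Vectors::elementNROWS(exPick)
        exu <- unlist(exPick, use.names = FALSE)
        row <- rep(seq_along(gIdx), nEx)
        Bv <- rep(P - 1L, nEx); Pv <- rep(P, nEx)
        ls <- GenomicRanges::start(exu); le <- pmin(GenomicRanges::end(exu), Bv)
        rs <- pmax(GenomicRanges::start(exu), Pv); re <- GenomicRanges::end(exu)
        wL <- pmax(le - ls + 1L, 0L); wR <- pmax(re - rs + 1L, 0L)
        leftLen <- as.integer(rowsum(wL, row))
        rightLen <- as.integer(rowsum(wR, row))
        plus <- geneStrand[gIdx] == "+"
        preLen <- ifelse(plus, leftLen, rightLen)
        postLen <- ifelse(plus, rightLen, leftLen)

        bad <- preLen == 0L | postLen == 0L
        if (any(bad))
            excl <- rbind(excl, data.frame(
                gene_id = genes[gIdx[bad]],
                reason = ifelse(preLen[bad] == 0L,
                                "degenerate_pre", "degenerate_post")))
        ok <- which(!bad)
        if (length(ok)) {
            keptGenes <- genes[gIdx[ok]]
            keepRow <- row %in% ok
            rowK <- match(row[keepRow], ok)
            geneK <- keptGenes[rowK]
            chrK <- geneChrom[gIdx[ok]][rowK]
            strK <- geneStrand[gIdx[ok]][rowK]
            plusK <- strK == "+"
            mkGRL <- function(s, e) {
                keep <- s <= e
                gr <- GenomicRanges::GRanges(chrK[keep],
                    IRanges::IRanges(s[keep], e[keep]), strand = strK[keep],
                    seqinfo = GenomeInfoDb::seqinfo(exSel))
                sort(S4Vectors::splitAsList(gr, factor(geneK[keep],
                                                       levels = keptGenes)))
            }
            lsK <- ls[keepRow]; leK <- le[keepRow]
            rsK <- rs[keepRow]; reK <- re[keepRow]
            # the 5'-side (genomically left on +, right on -) is PRE
            preGRL <- mkGRL(ifelse(plusK, lsK, rsK), ifelse(plusK, leK, reK))
            postGRL <- mkGRL(ifelse(plusK, rsK, lsK), ifelse(plusK, reK, leK))

            gi <- S4Vectors::DataFrame(
                gene_id = keptGenes,
                transcript_id = unname(canonTx[gIdx[ok]]),
                chrom = geneChrom[gIdx[ok]],
                strand = geneStrand[gIdx[ok]],
                pre_length = preLen[ok],
                post_length = postLen[ok],
                proximal_pos = P[ok],
                canonical_end = ifelse(geneStrand[gIdx[ok]] == "+",
                    GenomicRanges::end(spans)[gIdx[ok]],
                    GenomicRanges::start(spans)[gIdx[ok]]),
                proximal_site = sites$site_id[pick$s[ok]],
                row.names = keptGenes)
        }
    }
    if (nrow(excl))
        excl <- excl[order(excl$gene_id, method = "radix"), , drop = FALSE]
    new("ApaSegmentation", pre = preGRL, post = postGRL, geneInfo = gi,
        exclusions = S4Vectors::DataFrame(excl))
}

#' Write a segmentation as 6-column BED
#'
#' One line per PRE/POST interval piece, named \code{geneID|PRE} /
#' \code{geneID|POST}, 0-based half-open coordinates, score 0, strand in column
#' 6. Output is sorted (gene, PRE before POST, start) and byte-deterministic.
#'
#' @param seg An \linkS4class{ApaSegmentation}.
#' @param path Output BED path.
#' @return The path, invisibly.
#' @export
writeSegmentationBed <- function(seg, path) {
    rows <- function(grl, tag) {
        gr <- unlist(grl, use.names = FALSE)
        g <- rep(names(grl), S4Vectors::elementNROWS(grl))
        data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   name = paste0(g, "|", tag), score = 0L,
                   strand = as.character(GenomicRanges::strand(gr)),
                   gene = g, tag = tag)
    }
    df <- rbind(rows(seg@pre, "PRE"), rows(seg@post, "POST"))
    df <- df[order(df$gene, df$tag == "POST", df$start, method = "radix"), ]
    utils::write.table(df[, 1:6], path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Write the exclusion table of a segmentation
#'
#' @param seg An \linkS4class{ApaSegmentation}.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
writeExclusionsTable <- function(seg, path) {
    writeTsv(as.data.frame(seg@exclusions), path)
}
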