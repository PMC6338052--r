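# genomic coordinate (1-based) of the exonic base at 0-based transcript
# offset t; exons sorted by genomic start, transcript read 5'->3'
txOffsetToGenomic <- function(starts, ends, strand, t) {
    w <- ends - starts + 1L
    if (strand == "+") {
        cum <- cumsum(w)
        i <- findInterval(t, c(0L, cum), rightmost.closed = FALSE)
        starts[i] + (t - c(0L, cum)[i])
    } else {
        wRev <- rev(w)
        cum <- cumsum(wRev)
        j <- findInterval(t, c(0L, cum), rightmost.closed = FALSE)
        rev(ends)[j] - (t - c(0L, cum)[j])
    }
}

#' Simulate an annotated genome with known APA ground truth
#'
#' Generates \code{nGenes} synthetic genes (both strands, 1-4 exons of
#' 300-1500 bp and at least 1500 exonic bases total, separated by 100-2000 bp
#' introns, laid out with 5 kb gaps on four synthetic chromosomes). Each gene
#' has a 3'UTR spanning 30-50\% of its exonic length (clipped to 600-2500
#' bases — the long 3'UTRs typical of neuronal transcripts), one canonical 3'
#' end, and one proximal polyA site placed so that the POST (distal,
#' long-isoform-only) region covers 40-80\% of the 3'UTR. For a fraction
#' \code{fracNoUtr3Apa} of genes the polyA site is placed in the exonic region
#' upstream of the 3'UTR, exercising the annotation fallback rule. About 20\%
#' of multi-exon genes carry a second, shorter transcript so canonical
#' selection is exercised. Every gene gets a true class and a long-isoform
#' fraction trajectory across \code{conditions}: UNCHANGED genes keep their
#' baseline fraction; LENGTHENED genes shift to \code{lf + 0.75(1 - lf)} and
#' SHORTENED genes to \code{max(0.08, 0.3 lf)} from the second condition
#' onward (a uniform shift across the time course). Relative expression is
#' lognormal(0, 0.5). Fully deterministic given \code{seed}.
#'
#' @param nGenes number of genes (>= 1).
#' @param conditions condition labels (default the four-time-point preset).
#' @param fracNoUtr3Apa fraction of genes without a 3'UTR polyA site
#'   (default 0.067).
#' @param classProbs named probabilities for UNCHANGED/SHORTENED/LENGTHENED.
#' @param trueClass optional explicit class per gene (overrides
#'   \code{classProbs}).
#' @param longFractions optional nGenes x nConditions matrix of long-isoform
#'   fractions in (0, 1] (overrides the generated trajectories).
#' @param seed RNG seed.
#' @return A \linkS4class{SyntheticApaGenome}.
#' @export
simulateApaGenome <- function(nGenes,
                              conditions = c("T0", "T1", "T2", "T3"),
                              fracNoUtr3Apa = 0.067,
                              classProbs = c(UNCHANGED = 0.8, SHORTENED = 0.1,
                                             LENGTHENED = 0.1),
                              trueClass = NULL, longFractions = NULL,
                              seed = NULL) {
    stopifnot(nGenes >= 1, length(conditions) >= 1)
    if (fracNoUtr3Apa < 0 || fracNoUtr3Apa > 1)
        stop("fracNoUtr3Apa must be in [0, 1]")
    if (!setequal(names(classProbs),
                  c("UNCHANGED", "SHORTENED", "LENGTHENED")) ||
        any(classProbs < 0) || abs(sum(classProbs) - 1) > 1e-8)
        stop("classProbs must be named probabilities summing to 1")
    if (!is.null(trueClass)) stopifnot(length(trueClass) == nGenes,
        all(trueClass %in% c("UNCHANGED", "SHORTENED", "LENGTHENED")))
    if (!is.null(longFractions)) {
        longFractions <- as.matrix(longFractions)
        stopifnot(nrow(longFractions) == nGenes,
                  ncol(longFractions) == length(conditions),
                  all(longFractions > 0), all(longFractions <= 1))
    }
    nC <- length(conditions)
    withSeed(seed, {
        geneIds <- sprintf("g%04d", seq_len(nGenes))
        nFallback <- round(nGenes * fracNoUtr3Apa)
        fallback <- seq_len(nGenes) <= nFallback  # deterministic subset

        chromOf <- paste0("chrS", (seq_len(nGenes) - 1L) %% 4L + 1L)
        offset <- integer(4); names(offset) <- paste0("chrS", 1:4)

        exRows <- list(); utrRows <- list(); txRows <- list()
        sitePos <- integer(nGenes); strandOf <- character(nGenes)
        preLen <- integer(nGenes); postLen <- integer(nGenes)
        canonEnd <- integer(nGenes)
        for (i in seq_len(nGenes)) {
            strand <- sample(c("+", "-"), 1L)
            nEx <- sample(1:4, 1L)
            w <- sample(300:1500, nEx, replace = TRUE)
            if (sum(w) < 1500L) w[1L] <- w[1L] + (1500L - sum(w))
            gaps <- if (nEx > 1L) sample(100:2000, nEx - 1L, replace = TRUE)
                    else integer()
            chrom <- chromOf[i]
            gStart <- offset[chrom] + 5000L
            starts <- gStart + cumsum(c(0L, w[-nEx] + gaps))
            ends <- starts + w - 1L
            offset[chrom] <- ends[nEx]
            L <- sum(w)
            u3 <- max(600L, min(2500L,
                                as.integer(round(L * stats::runif(1, 0.3, 0.5)))))
            # proximal site inside the 3'UTR so that POST (the long-only
            # distal extension) spans 40-80% of the UTR
            pl <- if (fallback[i]) sample(100:(L - u3 - 30L), 1L)
                  else L - as.integer(round(u3 * stats::runif(1, 0.4, 0.8)))
            tOff <- if (strand == "+") pl else pl - 1L
            sitePos[i] <- txOffsetToGenomic(starts, ends, strand, tOff)
            strandOf[i] <- strand
            preLen[i] <- pl; postLen[i] <- L - pl
            canonEnd[i] <- if (strand == "+") ends[nEx] else starts[1L]

            txId <- paste0(geneIds[i], ".t1")
            exRows[[length(exRows) + 1L]] <- data.frame(
                chrom = chrom, start = starts, end = ends, strand = strand,
                type = "exon", gene_id = geneIds[i], transcript_id = txId)
            # 3'UTR: exonic bases at transcript offsets [L - u3, L)
            uB <- txOffsetToGenomic(starts, ends, strand, L - u3)
            uS <- if (strand == "+") pmax(starts, uB) else starts
            uE <- if (strand == "+") ends else pmin(ends, uB)
            keep <- uS <= uE
            utrRows[[length(utrRows) + 1L]] <- data.frame(
                chrom = chrom, start = uS[keep], end = uE[keep],
                strand = strand, type = "three_prime_utr",
                gene_id = geneIds[i], transcript_id = txId)
            hasT2 <- nEx >= 2L && stats::runif(1) < 0.2
            if (hasT2) {
                exRows[[length(exRows) + 1L]] <- data.frame(
                    chrom = chrom, start = starts[-nEx], end = ends[-nEx],
                    strand = strand, type = "exon", gene_id = geneIds[i],
                    transcript_id = paste0(geneIds[i], ".t2"))
            }
        }

        exprRel <- stats::rlnorm(nGenes, 0, 0.5)
        cls <- if (!is.null(trueClass)) trueClass
               else sample(names(classProbs), nGenes, replace = TRUE,
                           prob = classProbs)
        if (is.null(longFractions)) {
            lf0 <- stats::runif(nGenes, 0.35, 0.85)
            lfEnd <- ifelse(cls == "LENGTHENED", lf0 + 0.75 * (1 - lf0),
                     ifelse(cls == "SHORTENED", pmax(0.08, 0.3 * lf0), lf0))
            # shifted genes move in full from the second condition onward:
            # uniform shifts across the time course
            frac <- c(0, rep(1, nC - 1L))
            longFractions <- outer(lf0, rep(1, nC)) +
                outer(lfEnd - lf0, frac)
        } else if (is.null(trueClass)) {
            d <- longFractions[, nC] - longFractions[, 1L]
            cls <- ifelse(d > 0, "LENGTHENED",
                   ifelse(d < 0, "SHORTENED", "UNCHANGED"))
        }
        colnames(longFractions) <- paste0("lf_", conditions)

        feat <- rbind(do.call(rbind, exRows), do.call(rbind, utrRows))
        gr <- GenomicRanges::GRanges(feat$chrom,
            IRanges::IRanges(feat$start, feat$end), strand = feat$strand)
        gr$type <- feat$type
        gr$gene_id <- feat$gene_id
        gr$transcript_id <- feat$transcript_id
        sl <- offset + 10000L
        GenomeInfoDb::seqlevels(gr) <- names(sl)
        GenomeInfoDb::seqlengths(gr) <- unname(sl)

        sites <- GenomicRanges::GRanges(chromOf,
            IRanges::IRanges(sitePos, width = 1L), strand = strandOf,
            seqlengths = sl)
        sites$site_id <- paste0("pa_", geneIds)

        models <- grToModels(gr)
        truth <- S4Vectors::DataFrame(
            gene_id = geneIds, chrom = chromOf, strand = strandOf,
            true_class = cls, expression_level = exprRel,
            pre_length = preLen, post_length = postLen,
            proximal_pos = sitePos, canonical_end = canonEnd,
            longFractions, row.names = geneIds)
        new("SyntheticApaGenome", models = models, sites = sites,
            truth = truth, conditions = as.character(conditions))
    })
}

# Build TranscriptModels from an in-memory feature GRanges (type, gene_id,
# transcript_id mcols) - same contract as readTranscriptModels.
grToModels <- function(gr) {
    tmp <- tempfile(fileext = ".gtf")
    on.exit(unlink(tmp))
    rtracklayer::export(gr, tmp, format = "gtf")
    readTranscriptModels(tmp)
}

#' Export a synthetic genome to standard files
#'
#' Writes \code{genes.gtf}, \code{sites.bed} (polyA sites) and
#' \code{truth.tsv} into \code{dir}.
#'
#' @param genome A \linkS4class{SyntheticApaGenome}.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
exportGenomeFiles <- function(genome, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    gtf <- file.path(dir, "genes.gtf")
    bed <- file.path(dir, "sites.bed")
    tsv <- file.path(dir, "truth.tsv")
    m <- genome@models
    ex <- unlist(m@exons, use.names = FALSE)
    ex$type <- "exon"
    ex$transcript_id <- rep(names(m@exons), S4Vectors::elementNROWS(m@exons))
    u3 <- unlist(m@utr3, use.names = FALSE)
    u3$type <- "three_prime_utr"
    u3$transcript_id <- rep(names(m@utr3), S4Vectors::elementNROWS(m@utr3))
    feat <- c(ex, u3)
    feat$gene_id <- m@txGene[feat$transcript_id, "gene_id"]
    rtracklayer::export(feat, gtf, format = "gtf")

    sites <- genome@sites
    names(sites) <- sites$site_id
    sites$score <- 0L
    rtracklayer::export(sites, bed, format = "BED")

    writeTsv(as.data.frame(genome@truth), tsv)
    invisible(c(gtf = gtf, bed = bed, truth = tsv))
}

#' Simulate replicate PRE/POST counts from a synthetic genome
#'
#' For each gene, condition and replicate, the total fragment count is drawn
#' from a negative binomial with mean \code{expression_level * meanDepth} and
#' variance \code{mean + dispersion * mean^2} (\code{dispersion = 0} degenerates
#' to Poisson). Fragments fall into PRE with probability
#' \code{preLength / (preLength + lf * postLength)} where \code{lf} is the
#' condition's long-isoform fraction — per-base PRE coverage is then
#' proportional to short + long molecules and POST coverage to long molecules,
#' as the m/M estimator assumes. Library size is the sample's total assigned
#' count.
#'
#' @param genome A \linkS4class{SyntheticApaGenome}.
#' @param nReplicates replicates per condition: a scalar or a vector parallel
#'   to the conditions. Default 3 per condition, except the four-time-point
#'   preset T0-T3 which uses 3,3,3,2.
#' @param meanDepth expected fragments per gene at relative expression 1.
#' @param dispersion negative-binomial dispersion (>= 0).
#' @param seed RNG seed.
#' @return An \linkS4class{ApaCounts} with samples named
#'   \code{<condition>_r<i>}.
#' @export
simulateApaCounts <- function(genome, nReplicates = NULL, meanDepth = 150,
                              dispersion = 0.1, seed = NULL) {
    stopifnot(meanDepth > 0, dispersion >= 0)
    conds <- genome@conditions
    if (is.null(nReplicates))
        nReplicates <- if (identical(conds, c("T0", "T1", "T2", "T3")))
            c(3L, 3L, 3L, 2L) else rep(3L, length(conds))
    if (length(nReplicates) == 1L)
        nReplicates <- rep(as.integer(nReplicates), length(conds))
    stopifnot(length(nReplicates) == length(conds), all(nReplicates >= 1))

    tr <- genome@truth
    nG <- nrow(tr)
    mu <- tr$expression_level * meanDepth
    withSeed(seed, {
        preM <- NULL; postM <- NULL; ids <- character(); cc <- character()
        for (ci in seq_along(conds)) {
            lf <- tr[[paste0("lf_", conds[ci])]]
            pPre <- tr$pre_length / (tr$pre_length + lf * tr$post_length)
            for (r in seq_len(nReplicates[ci])) {
                N <- if (dispersion > 0)
                    stats::rnbinom(nG, mu = mu, size = 1 / dispersion)
                else stats::rpois(nG, mu)
                pre <- stats::rbinom(nG, N, pPre)
                post <- N - pre
                preM <- cbind(preM, pre); postM <- cbind(postM, post)
                ids <- c(ids, paste0(conds[ci], "_r", r))
                cc <- c(cc, conds[ci])
            }
        }
        dimnames(preM) <- dimnames(postM) <- list(tr$gene_id, ids)
        ApaCounts(preM, postM, ids, cc,
                  librarySize = pmax(colSums(preM + postM), 1))
    })
}

#' Write a sample's counts as single-end SAM alignments
#'
#' Places, for every gene, \code{pre_count} reads fully inside the PRE
#' intervals and \code{post_count} reads fully inside the POST intervals
#' (uniformly across interval pieces weighted by width, uniform start within
#' the piece), so that \code{\link{countReads}} with the default boundary rule
#' reproduces the counts exactly. Reads longer than their interval piece are
#' shortened to the piece (reported via \code{message}).
#'
#' @param seg An \linkS4class{ApaSegmentation} covering the counted genes.
#' @param counts An \linkS4class{ApaCounts}.
#' @param sample column (sample id) to emit.
#' @param path output SAM path.
#' @param readLength read length in bases (default 50).
#' @param seed RNG seed.
#' @return The path, invisibly.
#' @export
emitAlignments <- function(seg, counts, sample, path, readLength = 50L,
                           seed = NULL) {
    x <- counts[, sample]
    genes <- rownames(x)
    if (!all(genes %in% names(seg)))
        stop("segmentation missing genes present in counts")
    sl <- GenomeInfoDb::seqlengths(seg@pre)
    if (anyNA(sl)) {
        mx <- max(GenomicRanges::end(unlist(seg@post, use.names = FALSE)),
                  GenomicRanges::end(unlist(seg@pre, use.names = FALSE)))
        sl[is.na(sl)] <- mx + 1000L
    }
    gi <- geneInfo(seg)
    nShort <- 0L

    lines <- c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", names(sl), sl))
    recs <- withSeed(seed, {
        out <- list()
        for (tag in c("pre", "post")) {
            grl <- if (tag == "pre") seg@pre else seg@post
            cnt <- if (tag == "pre") preCounts(x)[, 1L] else postCounts(x)[, 1L]
            for (g in genes) {
                n <- cnt[g]
                if (n == 0L) next
                pieces <- grl[[g]]
                w <- GenomicRanges::width(pieces)
                pi <- sample.int(length(pieces), n, replace = TRUE, prob = w)
                pw <- w[pi]
                rl <- pmin(readLength, pw)
                nShort <- nShort + sum(pw < readLength)
                maxOff <- pw - rl
                off <- floor(stats::runif(n) * (maxOff + 1L))
                pos <- GenomicRanges::start(pieces)[pi] + as.integer(off)
                flag <- if (gi[g, "strand"] == "+") 0L else 16L
                out[[length(out) + 1L]] <- sprintf(
                    "%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
                    paste0(g, ":", tag, ":", seq_len(n)), flag,
                    gi[g, "chrom"], pos, rl,
                    vapply(rl, function(k) strrep("A", k), ""))
            }
        }
        out
    })
    if (nShort > 0L)
        message(nShort, " read(s) shortened to fit their region piece")
    writeLines(c(lines, unlist(recs)), path)
    invisible(path)
}
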