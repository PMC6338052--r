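defaultThresholds <- function() {
    list(alpha = 0.05, fpkm_min = 1, roar_boundary = 1,
         fdr_max = 0.01, bc_min = 5)
}

#' Validate a pipeline configuration
#'
#' The configuration is a YAML file (or an equivalent list) with keys:
#' \describe{
#'   \item{annotation}{GTF path (required).}
#'   \item{polya_sites}{polyA-site BED path (required).}
#'   \item{samples}{list of records with \code{id}, \code{condition} and
#'     exactly one of \code{counts} (TSV) or \code{alignments} (SAM/BAM)
#'     (required).}
#'   \item{baseline}{baseline condition (default: the first sample's).}
#'   \item{thresholds}{\code{alpha} (0.05), \code{fpkm_min} (1),
#'     \code{roar_boundary} (1), \code{fdr_max} (0.01), \code{bc_min} (5).}
#'   \item{stranded, boundary}{counting options (defaults \code{none},
#'     \code{post}).}
#'   \item{clip_sites, qpcr_table}{optional input paths.}
#'   \item{seed}{integer recorded in the run log (default 1).}
#'   \item{outdir}{output directory (required).}
#' }
#' Unknown keys, missing required keys, duplicate sample ids and non-numeric
#' thresholds raise a config error naming the offending key.
#'
#' Relative paths in a config file are resolved against the directory of the
#' config file itself (or against \code{baseDir}), so a run directory can be
#' relocated without breaking.
#'
#' @param x YAML path or list.
#' @param baseDir directory against which relative paths are resolved
#'   (default: the config file's directory, or the working directory for
#'   list input).
#' @return A validated config (class \code{ApaPipelineConfig}).
#' @export
validateApaConfig <- function(x, baseDir = NULL) {
    if (is.character(x)) {
        checkFileExists(x, "config")
        if (is.null(baseDir)) baseDir <- dirname(normalizePath(x))
        x <- yaml::read_yaml(x)
    }
    if (is.null(baseDir)) baseDir <- "."
    if (!is.list(x)) apaConfigError("config must be a mapping")
    known <- c("annotation", "polya_sites", "samples", "baseline",
               "thresholds", "stranded", "boundary", "clip_sites",
               "qpcr_table", "seed", "outdir", "base_dir")
    bad <- setdiff(names(x), known)
    if (length(bad))
        apaConfigError(paste("unknown config key(s):",
                             paste(bad, collapse = ", ")))
    for (k in c("annotation", "polya_sites", "samples", "outdir"))
        if (is.null(x[[k]]))
            apaConfigError(paste("missing required config key:", k))
    if (!is.list(x$samples) || !length(x$samples))
        apaConfigError("samples must be a non-empty list")
    for (s in x$samples) {
        if (is.null(s$id) || is.null(s$condition))
            apaConfigError("every sample needs id and condition")
        if (sum(!is.null(s$counts), !is.null(s$alignments)) != 1L)
            apaConfigError(paste0("sample ", s$id,
                " needs exactly one of counts/alignments"))
    }
    ids <- vapply(x$samples, function(s) as.character(s$id), "")
    if (anyDuplicated(ids))
        apaConfigError(paste("duplicate sample id:", ids[duplicated(ids)][1]))

    thr <- defaultThresholds()
    if (!is.null(x$thresholds)) {
        badT <- setdiff(names(x$thresholds), names(thr))
        if (length(badT))
            apaConfigError(paste("unknown threshold key(s):",
                                 paste(badT, collapse = ", ")))
        for (k in names(x$thresholds)) {
            v <- x$thresholds[[k]]
            if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
                apaConfigError(paste("threshold", k,
                                     "must be a positive number"))
            thr[[k]] <- v
        }
    }
    x$thresholds <- thr
    if (is.null(x$baseline))
        x$baseline <- as.character(x$samples[[1]]$condition)
    x$stranded <- if (is.null(x$stranded)) "none" else x$stranded
    x$boundary <- if (is.null(x$boundary)) "post" else x$boundary
    if (!x$stranded %in% c("none", "forward", "reverse"))
        apaConfigError("stranded must be none/forward/reverse")
    if (!x$boundary %in% c("post", "both"))
        apaConfigError("boundary must be post/both")
    if (is.null(x$seed)) x$seed <- 1L
    if (!is.numeric(x$seed) || length(x$seed) != 1L)
        apaConfigError("seed must be a number")
    conds <- unique(vapply(x$samples, function(s) as.character(s$condition), ""))
    if (!x$baseline %in% conds)
        apaConfigError("baseline is not a condition of any sample")
    if (length(conds) < 2L)
        apaConfigError("need at least two conditions")
    if (is.null(x$base_dir)) x$base_dir <- baseDir
    structure(x, class = "ApaPipelineConfig")
}

resolvePath <- function(p, config) {
    if (startsWith(p, "/") || is.null(config$base_dir)) p
    else file.path(config$base_dir, p)
}

#' Run the APA analysis pipeline
#'
#' Executes annotation segmentation, PRE/POST quantification, per-comparison
#' statistics (baseline vs every other condition, in sample order),
#' classification, consensus across comparisons, optional CLIP enrichment of
#' the always-shortened/always-lengthened sets, optional qPCR ratios, and a
#' run log. All outputs are deterministic functions of the config and seed.
#'
#' @param config A config path, list, or validated \code{ApaPipelineConfig}.
#' @return Invisibly, a list with the segmentation, counts, per-comparison
#'   stats and calls, and the consensus.
#' @export
runApaPipeline <- function(config) {
    if (!inherits(config, "ApaPipelineConfig"))
        config <- validateApaConfig(config)
    out <- resolvePath(config$outdir, config)
    dir.create(out, showWarnings = FALSE, recursive = TRUE)

    models <- readTranscriptModels(resolvePath(config$annotation, config))
    sites <- readPolyASites(resolvePath(config$polya_sites, config))
    seg <- buildAllSegmentations(models, sites)
    writeSegmentationBed(seg, file.path(out, "segmentation.bed"))
    writeExclusionsTable(seg, file.path(out, "exclusions.tsv"))

    countsList <- lapply(config$samples, function(s) {
        if (!is.null(s$counts)) readCountsTable(resolvePath(s$counts, config))
        else countReads(resolvePath(s$alignments, config), seg, s$id,
                        s$condition,
                        stranded = config$stranded,
                        boundary = config$boundary)
    })
    g <- rownames(countsList[[1]])
    counts <- do.call(SummarizedExperiment::cbind,
                      lapply(countsList, function(x) x[g, ]))

    conds <- unique(sampleConditions(counts))
    contrasts <- setdiff(conds, config$baseline)
    thr <- config$thresholds
    statsList <- list(); callsList <- list()
    for (ct in contrasts) {
        cmp <- paste0(config$baseline, "vs", ct)
        st <- apaStats(counts, seg, config$baseline, ct)
        writeStatsTable(st, file.path(out, paste0("stats_", cmp, ".tsv")))
        statsList[[cmp]] <- st
        callsList[[cmp]] <- classifyApa(st, cmp,
            roarBoundary = thr$roar_boundary, alpha = thr$alpha,
            fpkmMin = thr$fpkm_min)
    }
    consensus <- apaConsensus(callsList)
    writeApaReport(consensus, callsList, out)

    if (!is.null(config$clip_sites)) {
        csites <- filterRobustSites(
            readBindingSites(resolvePath(config$clip_sites, config)),
                                    fdrMax = thr$fdr_max, bcMin = thr$bc_min)
        spans <- geneSpans(seg)
        universe <- rownames(statsList[[1]])
        ov <- geneOverlaps(spans[universe], csites)
        enr <- lapply(list(LENGTHENED = alwaysLengthened(consensus),
                           SHORTENED = alwaysShortened(consensus)),
            function(target) {
                if (!length(target)) return(list(note = "empty target set"))
                r <- enrichmentTest(target, universe, ov)
                list(table = as.vector(r$table), odds_ratio = r$odds_ratio,
                     p_value = r$p_value, alternative = r$alternative)
            })
        jsonlite::write_json(enr, file.path(out, "enrichment.json"),
                             auto_unbox = TRUE, pretty = TRUE, digits = NA)
    }
    if (!is.null(config$qpcr_table)) {
        ct <- readCtTable(resolvePath(config$qpcr_table, config))
        qconds <- unique(ct$condition)
        qb <- if (config$baseline %in% qconds) config$baseline else qconds[1]
        qc <- setdiff(qconds, qb)[1]
        writeTsv(qpcrConditionRatios(ct, qb, qc),
                 file.path(out, "qpcr_ratios.tsv"))
    }

    log <- c(
        paste0("apaShift version: ",
               as.character(utils::packageVersion("apaShift"))),
        paste0("seed: ", config$seed),
        paste0("baseline: ", config$baseline),
        paste0("comparisons: ", paste(names(callsList), collapse = ", ")),
        paste0("thresholds: ", paste(names(thr), unlist(thr), sep = "=",
                                     collapse = " ")),
        paste0("stranded: ", config$stranded, " boundary: ", config$boundary),
        paste0("annotation: ", config$annotation),
        paste0("polya_sites: ", config$polya_sites),
        paste0("genes segmented: ", length(seg)),
        paste0("genes excluded: ", nrow(exclusions(seg))),
        paste0("samples: ", paste(colnames(counts), collapse = ", ")))
    writeLines(log, file.path(out, "run_log.txt"))

    invisible(list(segmentation = seg, counts = counts, stats = statsList,
                   calls = callsList, consensus = consensus))
}

#' One-shot synthetic demo of the full pipeline
#'
#' Simulates a genome (four-time-point preset, 3/3/3/2 replicates), writes its
#' GTF/BED/truth/counts/CLIP/qPCR inputs plus a \code{config.yaml} under
#' \code{dir/input}, then runs \code{\link{runApaPipeline}} into
#' \code{dir/output}. Rerunning with the same seed reproduces every artifact
#' byte for byte.
#'
#' @param dir target directory.
#' @param seed RNG seed (default 1).
#' @param nGenes genes to simulate (default 200).
#' @param meanDepth,dispersion count-simulation parameters (defaults 150, 0.1).
#' @return Invisibly, the \code{\link{runApaPipeline}} result.
#' @export
runApaDemo <- function(dir, seed = 1, nGenes = 200, meanDepth = 150,
                       dispersion = 0.1) {
    input <- file.path(dir, "input")
    dir.create(input, showWarnings = FALSE, recursive = TRUE)
    genome <- simulateApaGenome(nGenes, seed = seed)
    exportGenomeFiles(genome, input)
    counts <- simulateApaCounts(genome, meanDepth = meanDepth,
                                dispersion = dispersion, seed = seed + 1)
    sampleRecs <- lapply(colnames(counts), function(s) {
        rel <- paste0("counts_", s, ".tsv")
        writeCountsTable(counts, s, file.path(input, rel))
        list(id = s,
             condition = unname(sampleConditions(counts)[s]), counts = rel)
    })

    # synthetic CLIP sites: enriched in the spans of lengthened genes
    tr <- truthTable(genome)
    seg0 <- buildAllSegmentations(genome@models, genome@sites)
    spans <- geneSpans(seg0)
    clipPath <- file.path(input, "clip_sites.tsv")
    withSeed(seed + 2, {
        pHit <- ifelse(tr[names(spans), "true_class"] == "LENGTHENED", 0.8, 0.15)
        hit <- stats::runif(length(spans)) < pHit
        sp <- spans[hit]
        st <- pmin(GenomicRanges::start(sp) +
                       floor(stats::runif(sum(hit)) * GenomicRanges::width(sp)),
                   GenomicRanges::end(sp)) - 1L  # 0-based
        df <- data.frame(chrom = as.character(GenomicRanges::seqnames(sp)),
                         start = st, end = st + 40L,
                         strand = as.character(GenomicRanges::strand(sp)),
                         fdr = round(stats::runif(sum(hit), 0, 0.02), 5),
                         bc = sample(0:8, sum(hit), replace = TRUE))
        writeTsv(df, clipPath)
    })

    # synthetic qPCR Ct table for five genes, derived from the truth
    qpcrPath <- file.path(input, "qpcr.tsv")
    qg <- head(tr$gene_id, 5)
    qrows <- do.call(rbind, lapply(qg, function(g) {
        do.call(rbind, lapply(c("T0", "T3"), function(cond) {
            lf <- tr[g, paste0("lf_", cond)]
            ctc <- 22 - log2(tr[g, "expression_level"])
            data.frame(gene_id = g, condition = cond, replicate = 1:3,
                       ct_long = round(ctc - log2(lf), 3),
                       ct_common = round(ctc, 3), ct_reference = 15)
        }))
    }))
    writeTsv(qrows, qpcrPath)

    # paths relative to the config file so the run directory is relocatable
    # and reruns are byte-identical wherever they land
    cfg <- list(annotation = "genes.gtf", polya_sites = "sites.bed",
                samples = sampleRecs, baseline = "T0",
                clip_sites = "clip_sites.tsv", qpcr_table = "qpcr.tsv",
                seed = as.integer(seed), outdir = file.path("..", "output"))
    yaml::write_yaml(cfg, file.path(input, "config.yaml"))
    runApaPipeline(file.path(input, "config.yaml"))
}
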