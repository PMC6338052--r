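#' Classify genes as shortened/lengthened for one comparison
#'
#' Applies the three call criteria to each gene's statistics:
#' \enumerate{
#'   \item roar value > \code{roarBoundary} (shortening) or <
#'     \code{roarBoundary} (lengthening), strictly;
#'   \item every replicate pairing yields a nominal p-value < \code{alpha},
#'     strictly (no multiple-testing correction);
#'   \item PRE (common region) FPKM > \code{fpkmMin} in both conditions.
#' }
#' A gene failing criterion 3, or carrying a validity flag, is
#' \code{NOT_TESTABLE}; a testable gene failing criterion 1 or 2 is
#' \code{UNCHANGED}; otherwise it is \code{SHORTENED} or \code{LENGTHENED}
#' according to the roar direction. Failed criteria are recorded in
#' \code{reasons} (comma-separated tags: \code{fpkm}, \code{flag_<flag>},
#' \code{pairwise_p}, \code{roar_boundary}).
#'
#' @param stats Result of \code{\link{apaStats}}.
#' @param comparison Label for this comparison (e.g. \code{"T0vsT1"}).
#' @param roarBoundary,alpha,fpkmMin thresholds (defaults 1, 0.05, 1).
#' @return \code{DataFrame} with \code{gene_id}, \code{comparison},
#'   \code{call}, \code{reasons}.
#' @export
classifyApa <- function(stats, comparison = "baseline_vs_contrast",
                        roarBoundary = 1, alpha = 0.05, fpkmMin = 1) {
    stopifnot(roarBoundary > 0, alpha > 0, fpkmMin >= 0)
    n <- nrow(stats)
    pv <- unclass(stats$pvalues)
    allP <- apply(pv, 1L, function(p) all(!is.na(p)) && all(p < alpha))
    fpkmOk <- stats$fpkm_baseline > fpkmMin & stats$fpkm_contrast > fpkmMin
    flagOk <- stats$flag == "ok"

    call <- rep("UNCHANGED", n)
    reasons <- vector("list", n)
    testable <- fpkmOk & flagOk
    call[!testable] <- "NOT_TESTABLE"
    for (i in which(!testable)) {
        r <- character()
        if (!fpkmOk[i]) r <- c(r, "fpkm")
        if (!flagOk[i]) r <- c(r, paste0("flag_", stats$flag[i]))
        reasons[[i]] <- r
    }
    up <- testable & allP & stats$roar > roarBoundary
    dn <- testable & allP & stats$roar < roarBoundary
    call[up] <- "SHORTENED"
    call[dn] <- "LENGTHENED"
    for (i in which(testable & call == "UNCHANGED")) {
        r <- character()
        if (!allP[i]) r <- c(r, "pairwise_p")
        if (stats$roar[i] == roarBoundary) r <- c(r, "roar_boundary")
        reasons[[i]] <- r
    }
    S4Vectors::DataFrame(
        gene_id = stats$gene_id, comparison = comparison, call = call,
        reasons = vapply(reasons, function(r)
            paste(r, collapse = ","), ""),
        row.names = stats$gene_id)
}

callSet <- function(calls, what) calls$gene_id[calls$call == what]

#' Intersect APA calls across comparisons
#'
#' Computes the "always shortened" and "always lengthened" gene sets (the
#' intersection of the per-comparison call sets) and exact Venn region counts:
#' for each combination of comparisons, the number of genes called in exactly
#' those comparisons. All comparisons must cover the same gene universe.
#'
#' @param callsList Named list of \code{\link{classifyApa}} results, one per
#'   comparison; names are the comparison labels.
#' @return An \linkS4class{ApaConsensus} object.
#' @export
apaConsensus <- function(callsList) {
    stopifnot(is.list(callsList), length(callsList) >= 1L,
              !is.null(names(callsList)))
    comparisons <- names(callsList)
    universe <- radixSort(callsList[[1]]$gene_id)
    for (cl in callsList[-1]) {
        if (!identical(radixSort(cl$gene_id), universe))
            stop("comparisons cover different gene universes")
    }
    callMat <- S4Vectors::DataFrame(row.names = universe)
    for (cmp in comparisons)
        callMat[[cmp]] <- callsList[[cmp]][universe, "call"]

    vennOf <- function(direction) {
        member <- vapply(comparisons, function(cmp)
            callMat[[cmp]] == direction, logical(length(universe)))
        member <- matrix(member, nrow = length(universe))
        inAny <- rowSums(member) > 0
        if (!any(inAny)) return(integer())
        pat <- apply(member[inAny, , drop = FALSE], 1L, function(m)
            paste(comparisons[m], collapse = "&"))
        tab <- table(pat)
        out <- as.integer(tab)
        names(out) <- names(tab)
        out[radixSort(names(out))]
    }
    interOf <- function(direction)
        Reduce(intersect, lapply(callsList, callSet, direction))

    new("ApaConsensus", comparisons = comparisons, calls = callMat,
        alwaysShortened = radixSort(interOf("SHORTENED")),
        alwaysLengthened = radixSort(interOf("LENGTHENED")),
        vennShortened = vennOf("SHORTENED"),
        vennLengthened = vennOf("LENGTHENED"))
}

#' Write APA call and consensus reports
#'
#' Writes, into \code{dir}: \code{calls.tsv} (long-format per-comparison
#' calls), \code{consensus.tsv} (genes always shortened/lengthened),
#' \code{venn.json} (exact Venn region counts) and \code{summary.txt}.
#' Output is sorted and byte-deterministic.
#'
#' @param consensus An \linkS4class{ApaConsensus}.
#' @param callsList The list of per-comparison calls used to build it.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
writeApaReport <- function(consensus, callsList, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    long <- do.call(rbind, lapply(callsList, as.data.frame))
    long <- long[order(long$comparison, long$gene_id, method = "radix"), ]
    rownames(long) <- NULL
    writeTsv(long, file.path(dir, "calls.tsv"))

    cons <- data.frame(
        gene_id = c(alwaysShortened(consensus), alwaysLengthened(consensus)),
        direction = rep(c("SHORTENED", "LENGTHENED"),
                        c(length(alwaysShortened(consensus)),
                          length(alwaysLengthened(consensus)))))
    writeTsv(cons, file.path(dir, "consensus.tsv"))

    jsonlite::write_json(
        list(comparisons = consensus@comparisons,
             venn = vennCounts(consensus),
             always = list(SHORTENED = alwaysShortened(consensus),
                           LENGTHENED = alwaysLengthened(consensus))),
        file.path(dir, "venn.json"), auto_unbox = TRUE, pretty = TRUE)

    lines <- c(sprintf("comparisons: %s",
                       paste(consensus@comparisons, collapse = ", ")))
    for (cmp in consensus@comparisons) {
        tab <- table(factor(consensus@calls[[cmp]],
            levels = c("SHORTENED", "LENGTHENED", "UNCHANGED", "NOT_TESTABLE")))
        lines <- c(lines, sprintf("%s: %s", cmp,
            paste(names(tab), tab, sep = "=", collapse = " ")))
    }
    lines <- c(lines,
        sprintf("always shortened: %d", length(alwaysShortened(consensus))),
        sprintf("always lengthened: %d", length(alwaysLengthened(consensus))))
    writeLines(lines, file.path(dir, "summary.txt"))
    invisible(dir)
}
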