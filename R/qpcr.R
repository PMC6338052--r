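#' Read a qPCR Ct table
#'
#' TSV with header and columns \code{gene_id}, \code{condition},
#' \code{replicate}, \code{ct_long}, \code{ct_common}, \code{ct_reference}.
#' \code{ct_long} amplifies the long 3'UTR form only, \code{ct_common} both
#' forms, \code{ct_reference} the normalizer gene (e.g. GAPDH).
#'
#' @param path Input TSV path.
#' @return data.frame.
#' @export
readCtTable <- function(path) {
    checkFileExists(path, "Ct table")
    df <- utils::read.delim(path, header = TRUE)
    need <- c("gene_id", "condition", "replicate",
              "ct_long", "ct_common", "ct_reference")
    if (!all(need %in% colnames(df)))
        apaInputError(paste("Ct table needs columns:",
                            paste(need, collapse = ", ")))
    df
}

checkCt <- function(m) {
    ct <- c(m$ct_long, m$ct_common, m$ct_reference)
    if (!nrow(m)) stop("no replicates supplied")
    if (anyNA(ct) || any(!is.finite(ct)) || any(ct <= 0))
        stop("all Ct values must be present, finite and > 0")
    invisible(m)
}

#' Relative abundance index of the long 3'UTR form (delta-delta-Ct)
#'
#' Within one condition, each replicate yields
#' \code{efficiency^-((ct_long - ct_reference) - (ct_common - ct_reference))
#' = efficiency^-(ct_long - ct_common)}; the reference Ct cancels but is
#' required so that incomplete measurements are caught. Replicates are combined
#' by geometric mean (equivalent to arithmetic averaging on the Ct scale).
#'
#' @param m data.frame of one gene and condition with columns \code{ct_long},
#'   \code{ct_common}, \code{ct_reference} (one row per replicate).
#' @param efficiency amplification efficiency per cycle (default 2, ideal PCR).
#' @return The long-form abundance index (1 = long and common amplicons
#'   equally abundant).
#' @export
longFractionIndex <- function(m, efficiency = 2) {
    stopifnot(efficiency > 1)
    need <- c("ct_long", "ct_common", "ct_reference")
    if (!all(need %in% colnames(m)))
        stop("missing Ct column(s): ",
             paste(setdiff(need, colnames(m)), collapse = ", "))
    checkCt(m)
    idx <- efficiency^(-(m$ct_long - m$ct_common))
    exp(mean(log(idx)))
}

#' Between-condition ratio of the long-form index
#'
#' \code{ratio = longFractionIndex(contrast) / longFractionIndex(baseline)};
#' a ratio > 1 indicates relative 3'UTR lengthening in the contrast condition.
#'
#' @param baseline,contrast data.frames of measurements for the same gene
#'   (columns as in \code{\link{longFractionIndex}}, plus \code{gene_id}).
#' @param efficiency amplification efficiency (default 2).
#' @return The ratio.
#' @export
conditionRatio <- function(baseline, contrast, efficiency = 2) {
    gb <- unique(baseline$gene_id); gc <- unique(contrast$gene_id)
    if (length(gb) != 1L || length(gc) != 1L || gb != gc)
        stop("baseline and contrast must measure the same single gene")
    ib <- longFractionIndex(baseline, efficiency)
    ic <- longFractionIndex(contrast, efficiency)
    if (ib == 0) stop("zero baseline index")
    ic / ib
}

#' Long-form condition ratios for every gene in a Ct table
#'
#' @param ct data.frame from \code{\link{readCtTable}}.
#' @param baseline,contrast condition labels.
#' @param efficiency amplification efficiency (default 2).
#' @return data.frame with \code{gene_id}, \code{index_baseline},
#'   \code{index_contrast}, \code{ratio}, sorted by gene id.
#' @export
qpcrConditionRatios <- function(ct, baseline, contrast, efficiency = 2) {
    genes <- radixSort(unique(ct$gene_id))
    rows <- lapply(genes, function(g) {
        b <- ct[ct$gene_id == g & ct$condition == baseline, , drop = FALSE]
        cc <- ct[ct$gene_id == g & ct$condition == contrast, , drop = FALSE]
        data.frame(gene_id = g,
                   index_baseline = longFractionIndex(b, efficiency),
                   index_contrast = longFractionIndex(cc, efficiency),
                   ratio = conditionRatio(b, cc, efficiency))
    })
    do.call(rbind, rows)
}
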