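test_that("canonical transcript is the longest, ties break lexicographically", {
    m <- mkModels(
        exons = list(NM_1 = mkExons("chr1", c(101, 1001), c(600, 1700), "+"),
                     NM_2 = mkExons("chr1", 101, 1000, "+")),
        txGene = c(NM_1 = "gA", NM_2 = "gA"))
    expect_equal(selectCanonicalTranscript(m, "gA"), "NM_1")  # 1200 vs 900

    single <- mkModels(exons = list(NM_9 = mkExons("chr1", 1, 500, "+")),
                       txGene = c(NM_9 = "gB"))
    expect_equal(selectCanonicalTranscript(single, "gB"), "NM_9")

    tie <- mkModels(
        exons = list(NM_2 = mkExons("chr1", 1, 1000, "+"),
                     NM_1 = mkExons("chr1", 2001, 3000, "+")),
        txGene = c(NM_2 = "gC", NM_1 = "gC"))
    expect_equal(selectCanonicalTranscript(tie, "gC"), "NM_1")

    expect_error(selectCanonicalTranscript(m, "nope"), "no transcripts")
})

test_that("proximal site choice is most 5' in the 3'UTR, strand aware", {
    # + strand: 0-based utr3 [1800,2000), sites at 1850 and 1900
    m <- mkGeneModels(list(g = list(
        exons = mkExons("chr1", 1001, 2000, "+"),
        utr3 = mkExons("chr1", 1801, 2000, "+"))))
    s <- mkSites("chr1", c(1851, 1901), "+")
    hit <- chooseProximalSite(m, "g.t1", s)
    expect_equal(start(hit), 1851)

    # - strand: 0-based utr3 [100,300), sites at 150 and 250 -> 250
    m2 <- mkGeneModels(list(g = list(
        exons = mkExons("chr1", 1, 500, "-"),
        utr3 = mkExons("chr1", 101, 300, "-"))))
    s2 <- mkSites("chr1", c(151, 251), "-")
    expect_equal(start(chooseProximalSite(m2, "g.t1", s2)), 251)

    # fallback: no site in utr3, one upstream site inside the span
    s3 <- mkSites("chr1", 1301, "+")
    expect_equal(start(chooseProximalSite(m, "g.t1", s3)), 1301)

    # wrong strand/chrom sites are excluded, not errors
    expect_null(chooseProximalSite(m, "g.t1", mkSites("chr1", 1851, "-")))
    expect_null(chooseProximalSite(m, "g.t1", mkSites("chr2", 1851, "+")))
    # position tie breaks to the smallest site id
    tiedS <- mkSites("chr1", c(1851, 1851), "+", c("z", "a"))
    expect_equal(chooseProximalSite(m, "g.t1", tiedS)$site_id, "a")
})

test_that("segmentation splits exonic bases at the site coordinate", {
    # + strand single exon, 0-based [1000,2000), proximal at 0-based 1850
    ex <- mkExons("chr1", 1001, 2000, "+")
    parts <- buildSegmentation(ex, mkSites("chr1", 1851, "+"))
    expect_equal(sum(width(parts$pre)), 850)
    expect_equal(sum(width(parts$post)), 150)
    expect_equal(start(parts$post), 1851)

    # - strand single exon, proximal at 0-based 1200
    exm <- mkExons("chr1", 1001, 2000, "-")
    pm <- buildSegmentation(exm, mkSites("chr1", 1201, "-"))
    expect_equal(sum(width(pm$pre)), 800)
    expect_equal(sum(width(pm$post)), 200)
    expect_equal(start(pm$pre), 1201)
    expect_equal(end(pm$post), 1200)

    # multi-exon + strand, 0-based exons [0,100)+[200,300), site at 0-based 250;
    # oracle: per-base enumeration of exonic bases against the split point
    ex2 <- mkExons("chr1", c(1, 201), c(100, 300), "+")
    p2 <- buildSegmentation(ex2, mkSites("chr1", 251, "+"))
    bases <- c(1:100, 201:300)
    expect_equal(sort(unlist(mapply(seq, start(p2$pre), end(p2$pre)))),
                 bases[bases < 251])
    expect_equal(sort(unlist(mapply(seq, start(p2$post), end(p2$post)))),
                 bases[bases >= 251])
    expect_equal(sum(width(p2$pre)), 150)
    expect_equal(sum(width(p2$post)), 50)

    expect_error(buildSegmentation(ex, mkSites("chr1", 2001, "+")),
                 "degenerate POST")
    expect_error(buildSegmentation(ex, mkSites("chr1", 1001, "+")),
                 "degenerate PRE")
})

test_that("buildAllSegmentations excludes with machine-readable reasons", {
    m <- mkGeneModels(list(
        g1 = list(exons = mkExons("chr1", 1001, 3000, "+"),
                  utr3 = mkExons("chr1", 2501, 3000, "+")),
        g2 = list(exons = mkExons("chr1", 5001, 7000, "-"),
                  utr3 = mkExons("chr1", 5001, 5500, "-")),
        g3 = list(exons = mkExons("chr1", 9001, 11000, "+"),
                  utr3 = mkExons("chr1", 10501, 11000, "+"))))
    sites <- mkSites("chr1", c(2701, 5301), c("+", "-"))
    seg <- buildAllSegmentations(m, sites)
    expect_equal(length(seg), 2L)
    expect_setequal(names(seg), c("g1", "g2"))
    expect_equal(as.data.frame(exclusions(seg)),
                 data.frame(gene_id = "g3", reason = "no_apa_site"))

    # a site whose base is the canonical 3'-end base (- strand: the genomic
    # start) leaves POST empty
    gMinus <- mkGeneModels(list(g4 = list(
        exons = mkExons("chr1", 9001, 11000, "-"),
        utr3 = mkExons("chr1", 9001, 9500, "-"))))
    seg3 <- buildAllSegmentations(gMinus, mkSites("chr1", 9001, "-"))
    expect_equal(exclusions(seg3)$reason, "degenerate_post")
    # a site at the transcript 5' end leaves PRE empty
    gPlus <- mkGeneModels(list(g5 = list(
        exons = mkExons("chr1", 9001, 11000, "+"),
        utr3 = mkExons("chr1", 10501, 11000, "+"))))
    seg4 <- buildAllSegmentations(gPlus, mkSites("chr1", 9001, "+"))
    expect_equal(exclusions(seg4)$reason, "degenerate_pre")
})

test_that("partition invariant holds for every synthetic gene", {
    g <- simulateApaGenome(80, seed = 11)
    seg <- buildAllSegmentations(transcriptModels(g), polyASites(g))
    expect_equal(length(seg), 80L)
    gi <- geneInfo(seg)
    canonical <- gi$transcript_id
    exLen <- sum(width(transcriptModels(g)@exons[canonical]))
    expect_equal(gi$pre_length + gi$post_length, unname(exLen))
    # and the segmentation equals the generator's ground truth
    tr <- truthTable(g)[gi$gene_id, ]
    expect_equal(gi$pre_length, tr$pre_length)
    expect_equal(gi$post_length, tr$post_length)
    expect_equal(gi$proximal_pos, tr$proximal_pos)
})

test_that("mirroring coordinates and flipping strand mirrors the segmentation", {
    g <- simulateApaGenome(30, seed = 13)
    m <- transcriptModels(g)
    sites <- polyASites(g)
    C <- 10000000L
    flip <- function(s) c("+" = "-", "-" = "+")[s]
    mirrorGR <- function(gr) {
        out <- GRanges(seqnames(gr),
                       IRanges::IRanges(C - end(gr) + 1L, C - start(gr) + 1L),
                       strand = flip(as.character(strand(gr))))
        mcols(out) <- mcols(gr)
        sort(out)
    }
    mExons <- GRangesList(lapply(m@exons, mirrorGR))
    mU3 <- GRangesList(lapply(m@utr3, mirrorGR))
    mm <- new("TranscriptModels", exons = mExons, utr3 = mU3, txGene = m@txGene)
    # the split point (0-based boundary) mirrors as P -> C - P + 2 in 1-based
    mSites <- GRanges(seqnames(sites),
                      IRanges::IRanges(C - start(sites) + 2L, width = 1L),
                      strand = flip(as.character(strand(sites))))
    mSites$site_id <- sites$site_id

    seg <- buildAllSegmentations(m, sites)
    mseg <- buildAllSegmentations(mm, mSites)
    expect_identical(names(seg), names(mseg))
    gi <- geneInfo(seg); mgi <- geneInfo(mseg)
    expect_equal(mgi$pre_length, gi$pre_length)
    expect_equal(mgi$post_length, gi$post_length)
    for (gene in names(seg)) {
        expect_identical(ranges(mirrorGR(seg@pre[[gene]])),
                         ranges(mseg@pre[[gene]]))
        expect_identical(ranges(mirrorGR(seg@post[[gene]])),
                         ranges(mseg@post[[gene]]))
    }
})

test_that("segmentation BED output is byte-deterministic", {
    seg <- tinySeg()
    f1 <- tempfile(); f2 <- tempfile()
    writeSegmentationBed(seg, f1)
    writeSegmentationBed(seg, f2)
    expect_identical(readLines(f1), readLines(f2))
    bed <- read.delim(f1, header = FALSE)
    expect_equal(bed$V4, c("gA|PRE", "gA|POST", "gB|PRE", "gB|POST"))
    # BED is 0-based half-open: PRE of gA is 1-based [1001, 2700]
    expect_equal(bed$V2[1], 1000)
    expect_equal(bed$V3[1], 2700)
})

test_that("GTF round trip and CDS-based 3'UTR inference work", {
    g <- simulateApaGenome(20, seed = 17)
    d <- tempfile(); paths <- exportGenomeFiles(g, d)
    m2 <- readTranscriptModels(paths["gtf"])
    m1 <- transcriptModels(g)
    expect_identical(names(m1@exons), names(m2@exons))
    expect_identical(ranges(m1@exons), ranges(m2@exons))
    expect_identical(ranges(m1@utr3), ranges(m2@utr3))

    # CDS + stop_codon inference: 3'UTR = exonic bases 3' of the stop
    gtf <- tempfile(fileext = ".gtf")
    attrs <- "gene_id \"gX\"; transcript_id \"gX.t1\";"
    writeLines(c(
        paste("chr9", "test", "exon", "101", "400", ".", "+", ".", attrs,
              sep = "\t"),
        paste("chr9", "test", "exon", "501", "900", ".", "+", ".", attrs,
              sep = "\t"),
        paste("chr9", "test", "CDS", "151", "400", ".", "+", "0", attrs,
              sep = "\t"),
        paste("chr9", "test", "CDS", "501", "597", ".", "+", "0", attrs,
              sep = "\t"),
        paste("chr9", "test", "stop_codon", "598", "600", ".", "+", "0", attrs,
              sep = "\t")), gtf)
    m3 <- readTranscriptModels(gtf)
    expect_equal(start(m3@utr3[["gX.t1"]]), 601)
    expect_equal(end(m3@utr3[["gX.t1"]]), 900)
})
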