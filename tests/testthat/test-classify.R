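test_that("the three call criteria are applied with strict inequalities", {
    # all criteria pass -> SHORTENED
    st <- mkStats(roar = 1.8, p = c(0.01, 0.02, 0.03, 0.04, 0.01, 0.02,
                                    0.03, 0.04, 0.02), fpkmB = 5, fpkmC = 7)
    expect_equal(classifyApa(st)$call, "SHORTENED")

    # one pairing at 0.06 -> UNCHANGED with reason pairwise_p
    st2 <- mkStats(mMb = 2, mMc = 0.8, roar = 0.4,
                   p = c(rep(0.01, 8), 0.06))
    cl2 <- classifyApa(st2)
    expect_equal(cl2$call, "UNCHANGED")
    expect_match(cl2$reasons, "pairwise_p")

    # FPKM below the cutoff in one condition -> NOT_TESTABLE
    st3 <- mkStats(roar = 1.8, fpkmB = 0.5)
    cl3 <- classifyApa(st3)
    expect_equal(cl3$call, "NOT_TESTABLE")
    expect_match(cl3$reasons, "fpkm")
    # the limit applies to both conditions; FPKM exactly 1 fails the > rule
    expect_equal(classifyApa(mkStats(roar = 1.8, fpkmC = 1))$call,
                 "NOT_TESTABLE")

    # roar < 1 with all p significant -> LENGTHENED
    expect_equal(classifyApa(mkStats(mMb = 2, mMc = 0.5, roar = 0.25))$call,
                 "LENGTHENED")
    # roar exactly at the boundary -> UNCHANGED
    cl4 <- classifyApa(mkStats(roar = 1))
    expect_equal(cl4$call, "UNCHANGED")
    expect_match(cl4$reasons, "roar_boundary")
    # p exactly alpha fails criterion 2
    expect_equal(classifyApa(mkStats(roar = 1.8,
                                     p = c(rep(0.01, 8), 0.05)))$call,
                 "UNCHANGED")
    # a validity flag makes the gene NOT_TESTABLE
    cl5 <- classifyApa(mkStats(roar = NA, flag = "negative_mM"))
    expect_equal(cl5$call, "NOT_TESTABLE")
    expect_match(cl5$reasons, "flag_negative_mM")
})

test_that("every gene gets exactly one call and alpha acts monotonically", {
    set.seed(61)
    n <- 200
    stats <- do.call(rbindStats, lapply(seq_len(n), function(i) {
        mMb <- runif(1, 0.1, 3); mMc <- runif(1, 0.1, 3)
        mkStats(gene = sprintf("g%03d", i), mMb = mMb, mMc = mMc,
                p = rbeta(9, 0.5, 2), fpkmB = runif(1, 0, 10),
                fpkmC = runif(1, 0, 10))
    }))
    cl <- classifyApa(stats, "c")
    expect_equal(nrow(cl), n)
    expect_true(all(cl$call %in% c("SHORTENED", "LENGTHENED", "UNCHANGED",
                                   "NOT_TESTABLE")))

    called <- function(calls) calls$gene_id[calls$call %in%
                                            c("SHORTENED", "LENGTHENED")]
    loose <- classifyApa(stats, "c", alpha = 0.2)
    strict <- classifyApa(stats, "c", alpha = 0.01)
    expect_true(all(called(strict) %in% called(cl)))
    expect_true(all(called(cl) %in% called(loose)))

    testableSet <- function(calls) calls$gene_id[calls$call != "NOT_TESTABLE"]
    hiF <- classifyApa(stats, "c", fpkmMin = 5)
    expect_true(all(testableSet(hiF) %in% testableSet(cl)))
})

test_that("consensus is the intersection of per-comparison call sets", {
    mkCalls <- function(cmp, lengthened, shortened = character()) {
        genes <- LETTERS[1:6]
        call <- ifelse(genes %in% lengthened, "LENGTHENED",
                ifelse(genes %in% shortened, "SHORTENED", "UNCHANGED"))
        S4Vectors::DataFrame(gene_id = genes, comparison = cmp, call = call,
                             reasons = "", row.names = genes)
    }
    cons <- apaConsensus(list(
        c1 = mkCalls("c1", c("A", "B", "C")),
        c2 = mkCalls("c2", c("B", "C")),
        c3 = mkCalls("c3", c("B", "C", "D"))))
    expect_equal(alwaysLengthened(cons), c("B", "C"))
    expect_equal(alwaysShortened(cons), character(0))
    v <- vennCounts(cons)$LENGTHENED
    expect_equal(unname(v[c("c1", "c1&c2&c3", "c3")]), c(1L, 2L, 1L))
    expect_equal(sum(v), 4L)  # union {A,B,C,D}

    # opposite directions in different comparisons -> in neither intersection
    cons2 <- apaConsensus(list(
        c1 = mkCalls("c1", lengthened = "A"),
        c2 = mkCalls("c2", lengthened = character(), shortened = "A")))
    expect_equal(alwaysLengthened(cons2), character(0))
    expect_equal(alwaysShortened(cons2), character(0))

    bad <- mkCalls("c2", "B")[1:5, ]
    expect_error(apaConsensus(list(c1 = mkCalls("c1", "B"), c2 = bad)),
                 "universe")
})

test_that("venn region counts are exact for all membership patterns", {
    # genes covering every non-empty subset of three comparisons
    pats <- expand.grid(c1 = c(FALSE, TRUE), c2 = c(FALSE, TRUE),
                        c3 = c(FALSE, TRUE))
    genes <- sprintf("g%d", seq_len(nrow(pats)))
    mk <- function(cmp) {
        call <- ifelse(pats[[cmp]], "LENGTHENED", "UNCHANGED")
        S4Vectors::DataFrame(gene_id = genes, comparison = cmp, call = call,
                             reasons = "", row.names = genes)
    }
    cons <- apaConsensus(list(c1 = mk("c1"), c2 = mk("c2"), c3 = mk("c3")))
    v <- vennCounts(cons)$LENGTHENED
    # each of the 7 non-empty regions holds exactly one gene
    expect_equal(length(v), 7L)
    expect_true(all(v == 1L))
    expect_setequal(names(v), c("c1", "c2", "c3", "c1&c2", "c1&c3", "c2&c3",
                                "c1&c2&c3"))
    expect_equal(alwaysLengthened(cons), genes[pats$c1 & pats$c2 & pats$c3])
})

test_that("reports are sorted, complete and byte-deterministic", {
    g <- simulateApaGenome(40, seed = 71)
    seg <- buildAllSegmentations(transcriptModels(g), polyASites(g))
    cnt <- simulateApaCounts(g, meanDepth = 150, seed = 72)
    callsList <- list()
    for (ct in c("T1", "T2", "T3"))
        callsList[[paste0("T0vs", ct)]] <-
            classifyApa(apaStats(cnt, seg, "T0", ct), paste0("T0vs", ct))
    cons <- apaConsensus(callsList)
    d1 <- tempfile(); d2 <- tempfile()
    writeApaReport(cons, callsList, d1)
    writeApaReport(cons, callsList, d2)
    for (f in c("calls.tsv", "consensus.tsv", "venn.json", "summary.txt"))
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)))
    calls <- read.delim(file.path(d1, "calls.tsv"))
    expect_equal(nrow(calls), 3 * 40)

    # an empty consensus still yields a header-only consensus table
    empty <- lapply(callsList, function(x) {
        x$call <- "UNCHANGED"; x
    })
    dE <- tempfile()
    writeApaReport(apaConsensus(empty), empty, dE)
    expect_equal(readLines(file.path(dE, "consensus.tsv")),
                 "gene_id\tdirection")
})
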