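test_that("fisherPrePost matches closed forms and fisher.test", {
    expect_equal(fisherPrePost(10, 10, 10, 10), 1.0)
    # [[5,0],[0,5]]: 2/choose(10,5) by exhaustive enumeration
    expect_equal(fisherPrePost(5, 0, 0, 5), 2 / 252, tolerance = 1e-12)
    expect_true(is.na(fisherPrePost(0, 0, 0, 0)))
    expect_true(is.na(fisherPrePost(3, 4, 0, 0)))  # all-zero row
    expect_true(is.na(fisherPrePost(3, 0, 4, 0)))  # all-zero column
    expect_error(fisherPrePost(-1, 2, 3, 4), "non-negative")
    expect_error(fisherPrePost(1.5, 2, 3, 4), "non-negative")

    set.seed(5)
    for (i in 1:100) {
        t <- rpois(4, 8)
        if (sum(t[1:2]) == 0 || sum(t[3:4]) == 0 ||
            t[1] + t[3] == 0 || t[2] + t[4] == 0) next
        expect_equal(
            fisherPrePost(t[1], t[2], t[3], t[4]),
            stats::fisher.test(matrix(t, 2, byrow = TRUE))$p.value,
            tolerance = 1e-9)
    }
})

test_that("fisherPrePost equals hypergeometric enumeration for small tables", {
    tabs <- expand.grid(a = 0:8, b = 0:8, c = 0:8, d = 0:8)
    p <- fisherPrePost(tabs$a, tabs$b, tabs$c, tabs$d)
    po <- fisherOracle(tabs$a, tabs$b, tabs$c, tabs$d)
    expect_equal(is.na(p), is.na(po))
    expect_lt(max(abs(p - po), na.rm = TRUE), 1e-12)
})

test_that("m/M follows the PRE/POST coverage-rate formula", {
    expect_equal(mOverM(100, 50, 1000, 500), 0)
    expect_equal(mOverM(300, 50, 1000, 500), 2)
    expect_equal(mOverM(50, 100, 1000, 500), -0.75)
    expect_true(is.na(mOverM(100, 0, 1000, 500)))
    expect_error(mOverM(1, 1, 0, 500), "lengths")
    expect_error(mOverM(-1, 1, 10, 500), "counts")
})

test_that("m/M estimate is recovered from a simulated molar mixture", {
    # 2:1 short:long mixture (m/M = 2): PRE covered by 3 molar units,
    # POST by 1; 1e5 reads split by per-base rate x length
    set.seed(31)
    preL <- 1000; postL <- 500
    pPre <- (3 * preL) / (3 * preL + 1 * postL)
    pre <- rbinom(1, 1e5, pPre); post <- 1e5 - pre
    expect_lt(abs(mOverM(pre, post, preL, postL) - 2) / 2, 0.05)
})

test_that("roar value is the contrast/baseline ratio of m/M", {
    expect_equal(roarValue(1, 1), 1)
    expect_equal(roarValue(0.5, 2), 4)
    expect_true(is.na(roarValue(0, 2)))
    expect_true(is.na(roarValue(NA, 2)))
    expect_true(is.na(roarValue(-0.2, 2)))
})

test_that("all pairings produce one Fisher p per replicate pair", {
    g <- simulateApaGenome(5, conditions = c("T0", "T1"), seed = 41)
    cnt <- simulateApaCounts(g, nReplicates = 3, meanDepth = 100,
                             dispersion = 0, seed = 42)
    gene <- rownames(cnt)[1]
    pv <- allPairingsPvalues(cnt, gene, "T0", "T1")
    expect_length(pv, 9L)
    expect_true(all(pv >= 0 & pv <= 1, na.rm = TRUE))
    # ordering: (baseline index, contrast index); check one entry by hand
    expect_equal(pv[2], fisherPrePost(
        preCounts(cnt)[gene, "T0_r1"], postCounts(cnt)[gene, "T0_r1"],
        preCounts(cnt)[gene, "T1_r2"], postCounts(cnt)[gene, "T1_r2"]))
    expect_error(allPairingsPvalues(cnt, "nope", "T0", "T1"),
                 "gene/sample mismatch")

    # 1x1 replicates reduce to a single fisherPrePost
    one <- cnt[, c("T0_r1", "T1_r1")]
    pv1 <- allPairingsPvalues(one, gene, "T0", "T1")
    expect_equal(pv1, fisherPrePost(
        preCounts(cnt)[gene, "T0_r1"], postCounts(cnt)[gene, "T0_r1"],
        preCounts(cnt)[gene, "T1_r1"], postCounts(cnt)[gene, "T1_r1"]))
})

test_that("identical counts in all replicates give roar 1 and p 1", {
    seg <- tinySeg()  # both genes: pre_length 1700, post_length 300
    pre <- matrix(170L, 2, 6, dimnames = list(c("gA", "gB"), paste0("s", 1:6)))
    post <- matrix(15L, 2, 6, dimnames = dimnames(pre))
    cnt <- ApaCounts(pre, post, paste0("s", 1:6),
                     rep(c("T0", "T1"), each = 3), rep(420, 6))
    st <- apaStats(cnt, seg, "T0", "T1")
    expect_equal(unname(st$roar), c(1, 1))
    expect_true(all(unclass(st$pvalues) == 1))
    expect_equal(st$flag, c("ok", "ok"))
    expect_equal(ncol(unclass(st$pvalues)), 9L)
})

test_that("pooled stats flag genes that defeat the two-isoform model", {
    seg <- tinySeg()
    mk <- function(preA, postA, preB, postB) {
        dn <- list(c("gA", "gB"), c("s1", "s2"))
        pre <- matrix(c(preA, 500L, preB, 500L), 2, 2, dimnames = dn)
        post <- matrix(c(postA, 20L, postB, 20L), 2, 2, dimnames = dn)
        ApaCounts(pre, post, c("s1", "s2"), c("T0", "T1"), c(1e5, 1e5))
    }
    stZeroPost <- apaStats(mk(100L, 0L, 100L, 30L), seg, "T0", "T1")
    expect_equal(stZeroPost["gA", "flag"], "zero_post")
    expect_true(is.na(stZeroPost["gA", "roar"]))
    stZeroPre <- apaStats(mk(0L, 30L, 100L, 30L), seg, "T0", "T1")
    expect_equal(stZeroPre["gA", "flag"], "zero_pre")
    # PRE per-base rate below POST: impossible under the generative model
    stNeg <- apaStats(mk(10L, 300L, 100L, 30L), seg, "T0", "T1")
    expect_equal(stNeg["gA", "flag"], "negative_mM")
})

test_that("roar is invariant to scaling one condition's counts and library", {
    seg <- tinySeg()
    dn <- list(c("gA", "gB"), c("s1", "s2"))
    pre <- matrix(c(600L, 800L, 900L, 700L), 2, 2, dimnames = dn)
    post <- matrix(c(30L, 25L, 40L, 22L), 2, 2, dimnames = dn)
    cnt <- ApaCounts(pre, post, c("s1", "s2"), c("T0", "T1"), c(1e5, 1e5))
    pre2 <- pre; post2 <- post
    pre2[, 2] <- pre2[, 2] * 7L; post2[, 2] <- post2[, 2] * 7L
    cnt2 <- ApaCounts(pre2, post2, c("s1", "s2"), c("T0", "T1"),
                      c(1e5, 7e5))
    st <- apaStats(cnt, seg, "T0", "T1")
    st2 <- apaStats(cnt2, seg, "T0", "T1")
    expect_equal(st2$roar, st$roar)
    expect_equal(st2$fpkm_contrast, st$fpkm_contrast)
})

test_that("per-pairing Fisher p-values are super-uniform under the null", {
    g <- simulateApaGenome(2000, conditions = c("T0", "T1"),
                           trueClass = rep("UNCHANGED", 2000), seed = 101)
    seg <- buildAllSegmentations(transcriptModels(g), polyASites(g))
    cnt <- simulateApaCounts(g, nReplicates = 3, meanDepth = 200,
                             dispersion = 0.1, seed = 102)
    st <- apaStats(cnt, seg, "T0", "T1")
    p1 <- unclass(st$pvalues)[, 1]
    expect_lte(mean(p1 < 0.05, na.rm = TRUE), 0.07)
})

test_that("m/M estimator is consistent across true ratios", {
    # true m/M in {0.25, 1, 4} <=> long fraction {0.8, 0.5, 0.2}
    lf <- matrix(c(0.8, 0.5, 0.2), ncol = 1)
    g <- simulateApaGenome(3, conditions = "T0", longFractions = lf,
                           trueClass = rep("UNCHANGED", 3), seed = 51)
    cnt <- simulateApaCounts(g, nReplicates = 1, meanDepth = 1e5,
                             dispersion = 0, seed = 52)
    tr <- truthTable(g)
    est <- mOverM(preCounts(cnt)[, 1], postCounts(cnt)[, 1],
                  tr$pre_length, tr$post_length)
    truth <- (1 - lf[, 1]) / lf[, 1]
    expect_true(all(abs(est - truth) / truth < 0.10))
})
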