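cfg <- quantConfig()

makeCt <- function(ct, condition, replicate = NULL, refs = character()) {
    CtExperiment(ct, condition, replicate, referenceAssays = refs)
}

test_that("reference normalization subtracts the reference mean per condition", {
    # single replicate: 25 - 20 = 5
    ct <- matrix(c(25, 26, 20, 20), nrow = 2, byrow = TRUE,
                 dimnames = list(c("m1", "ref"), c("c1", "t1")))
    x <- makeCt(ct, c("control", "treated"), refs = "ref")
    dct <- normalizeCt(x, quantConfig(normalization = "reference"))
    expect_equal(dct$dct_control[dct$mirna_id == "m1"], 5)
    expect_equal(dct$dct_treated[dct$mirna_id == "m1"], 6)

    # assay equal to reference everywhere -> delta-Ct 0 in both conditions
    ct2 <- matrix(22, nrow = 2, ncol = 4,
                  dimnames = list(c("m1", "ref"), c("c1", "c2", "t1", "t2")))
    x2 <- makeCt(ct2, c("control", "control", "treated", "treated"),
                 refs = "ref")
    dct2 <- normalizeCt(x2, quantConfig(normalization = "reference"))
    expect_equal(dct2$dct_control[1], 0)
    expect_equal(dct2$dct_treated[1], 0)

    # replicates averaged on the CT scale: mean(24, 26) - mean(20, 20) = 5
    ct3 <- matrix(c(24, 26, 24, 26, 20, 20, 20, 20), nrow = 2, byrow = TRUE,
                  dimnames = list(c("m1", "ref"), c("c1", "c2", "t1", "t2")))
    x3 <- makeCt(ct3, c("control", "control", "treated", "treated"),
                 refs = "ref")
    dct3 <- normalizeCt(x3, quantConfig(normalization = "reference"))
    expect_equal(dct3$dct_control[1], 5)
})

test_that("normalization degenerate inputs behave as specified", {
    ct <- matrix(c(25, NA, NA, NA, 20, 20, 20, 20), nrow = 2, byrow = TRUE,
                 dimnames = list(c("m1", "ref"), c("c1", "c2", "t1", "t2")))
    x <- makeCt(ct, c("control", "control", "treated", "treated"),
                refs = "ref")
    dct <- normalizeCt(x, quantConfig(normalization = "reference"))
    # all-missing assay in a condition: delta-Ct is NA, never zero
    expect_true(is.na(dct$dct_treated[dct$mirna_id == "m1"]))
    expect_equal(dct$dct_control[dct$mirna_id == "m1"], 5)

    # missing reference CT in one sample is a configuration error naming it
    ct2 <- ct; ct2["ref", "t1"] <- NA; ct2["m1", ] <- 25
    x2 <- makeCt(ct2, c("control", "control", "treated", "treated"),
                 refs = "ref")
    expect_error(normalizeCt(x2, quantConfig(normalization = "reference")),
                 "t1")
})

test_that("adding a constant to one sample leaves reference delta-Ct unchanged", {
    set.seed(42)
    ct <- matrix(runif(5 * 4, 22, 30), nrow = 5,
                 dimnames = list(c(sprintf("m%d", 1:4), "ref"),
                                 c("c1", "c2", "t1", "t2")))
    x <- makeCt(ct, c("control", "control", "treated", "treated"),
                refs = "ref")
    refCfg <- quantConfig(normalization = "reference")
    base <- normalizeCt(x, refCfg)
    ct2 <- ct; ct2[, "c2"] <- ct2[, "c2"] + 3.7
    x2 <- makeCt(ct2, c("control", "control", "treated", "treated"),
                 refs = "ref")
    expect_equal(normalizeCt(x2, refCfg), base)
})

test_that("detection classes follow the inclusive 16-37 CT bounds", {
    ct <- matrix(c(20, 20,   # common
                   20, 40,   # control_only
                   40, 20,   # treated_only
                   15, 15,   # below lower bound -> undetected
                   16, 37),  # boundary inclusive -> common
                 ncol = 2, byrow = TRUE,
                 dimnames = list(sprintf("m%d", 1:5), c("c1", "t1")))
    x <- makeCt(ct, c("control", "treated"))
    calls <- callDetection(x, cfg)
    expect_equal(calls$status,
                 c("common", "control_only", "treated_only", "undetected",
                   "common"))
})

test_that("detection rule over replicates treats missing CT as out-of-bounds", {
    ct <- matrix(c(20, NA, 20, 20,
                   20, 25, 20, 20), nrow = 2, byrow = TRUE,
                 dimnames = list(c("m1", "m2"), c("c1", "c2", "t1", "t2")))
    x <- makeCt(ct, c("control", "control", "treated", "treated"))
    all_ <- callDetection(x, quantConfig(detectionRule = "all_replicates"))
    expect_equal(all_$status, c("treated_only", "common"))
    maj <- callDetection(x, quantConfig(detectionRule = "majority"))
    expect_equal(maj$status, c("treated_only", "common"))
})

test_that("ddCt arithmetic and inclusive direction thresholds are exact", {
    dct <- data.frame(mirna_id = c("a", "b", "c", "d", "e"),
                      dct_control = c(5, 5, 5, 5, 5),
                      dct_treated = c(5, 2, 6, 4, 6))
    calls <- data.frame(mirna_id = dct$mirna_id, status = "common")
    de <- differentialExpression(dct, calls, cfg)
    de <- de[match(dct$mirna_id, de$mirna_id), ]
    # ddct {0, -3, +1, -1, +1}: RQ {1, 8, 0.5, 2, 0.5}
    expect_equal(de$rel_quantity, c(1, 8, 0.5, 2, 0.5))
    expect_equal(de$direction, c("unchanged", "up", "down", "up", "down"))
    # RQ equals 2^-ddct to machine precision
    expect_identical(de$rel_quantity, 2^(-de$ddct))
})

test_that("DE output is sorted by |log2 RQ| with lexicographic tie-break", {
    dct <- data.frame(mirna_id = c("b", "a", "c"),
                      dct_control = c(0, 0, 0), dct_treated = c(1, -2, -1))
    calls <- data.frame(mirna_id = c("a", "b", "c", "zz"),
                        status = c("common", "common", "common", "common"))
    expect_warning(de <- differentialExpression(dct, calls, cfg), "zz")
    expect_equal(de$mirna_id, c("a", "b", "c"))  # |2| then |1| ties a< b< c
})

test_that("RQ reciprocity and condition-swap symmetry hold", {
    for (ddct in c(-3.2, -1, 0, 0.4, 2.5))
        expect_equal(2^(-ddct) * 2^(ddct), 1)
    set.seed(11)
    inst <- randomCtInstance(25)
    swapped <- CtExperiment(ctValues(inst$ct),
                            ifelse(sampleConditions(inst$ct) == "control",
                                   "treated", "control"))
    c1 <- callDetection(inst$ct, cfg)
    c2 <- callDetection(swapped, cfg)
    map <- c(common = "common", control_only = "treated_only",
             treated_only = "control_only", undetected = "undetected")
    expect_equal(unname(map[c1$status]), c2$status)
    d1 <- differentialExpression(normalizeCt(inst$ct, cfg), c1, cfg)
    d2 <- differentialExpression(normalizeCt(swapped, cfg), c2, cfg)
    d2 <- d2[match(d1$mirna_id, d2$mirna_id), ]
    dirmap <- c(up = "down", down = "up", unchanged = "unchanged")
    expect_equal(unname(dirmap[d1$direction]), d2$direction)
    expect_equal(d1$ddct, -d2$ddct)
})

test_that("the four detection classes always partition the assay list", {
    set.seed(99)
    for (i in 1:100) {
        inst <- randomCtInstance(sample(5:40, 1))
        calls <- callDetection(inst$ct, cfg)
        venn <- vennDecompose(calls)
        expect_equal(sum(venn) + sum(calls$status == "undetected"),
                     nrow(calls))
    }
})

test_that("vennDecompose counts classes and rejects duplicate assays", {
    calls <- data.frame(mirna_id = c("a", "b", "c"),
                        status = c("common", "control_only", "undetected"))
    expect_equal(unname(vennDecompose(calls)), c(1L, 1L, 0L))
    empty <- data.frame(mirna_id = character(), status = character())
    expect_equal(unname(vennDecompose(empty)), c(0L, 0L, 0L))
    dup <- data.frame(mirna_id = c("a", "a"), status = c("common", "common"))
    expect_error(vennDecompose(dup), "duplicate")
})

test_that("planted DE directions are recovered under realistic CT noise", {
    # |ddCt| >= 1.5 effects, sigma = 0.2: >= 95% of planted calls correct
    set.seed(2024)
    hits <- 0; total <- 0
    for (s in 1:5) {
        ids <- sprintf("sim-miR-%03d", 1:60)
        eff <- c(setNames(-runif(15, 1.5, 3), ids[1:15]),
                 setNames(runif(15, 1.5, 3), ids[16:30]))
        sim <- simulateCtMatrix(nMirnas = 60, ctNoiseSd = 0.2,
                                plantedDe = eff, seed = s)
        de <- differentialExpression(normalizeCt(sim$ct, cfg),
                                     callDetection(sim$ct, cfg), cfg)
        got <- setNames(de$direction, de$mirna_id)
        want <- ifelse(eff < 0, "up", "down")
        hits <- hits + sum(got[names(eff)] == want, na.rm = TRUE)
        total <- total + length(eff)
    }
    expect_gte(hits / total, 0.95)
})
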