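test_that("generators are fully deterministic under a seed", {
    a <- simulateCtMatrix(nMirnas = 25, seed = 5)
    b <- simulateCtMatrix(nMirnas = 25, seed = 5)
    expect_identical(ctValues(a$ct), ctValues(b$ct))
    c_ <- simulateCtMatrix(nMirnas = 25, seed = 6)
    expect_false(identical(ctValues(a$ct), ctValues(c_$ct)))
    s1 <- simulateStudy(seed = 2, nMirnas = 40, nGenes = 100, nUp = 5,
                        nDown = 5, nControlOnly = 2, nTreatedOnly = 1)
    s2 <- simulateStudy(seed = 2, nMirnas = 40, nGenes = 100, nUp = 5,
                        nDown = 5, nControlOnly = 2, nTreatedOnly = 1)
    expect_identical(s1$predictions, s2$predictions)
    expect_identical(s1$geneDe, s2$geneDe)
})

test_that("planted ids outside the assay space are rejected", {
    expect_error(simulateCtMatrix(nMirnas = 5,
                                  plantedDe = c("sim-miR-099" = -2)),
                 "outside")
})

test_that("noiseless CT simulation recovers planted classes and directions", {
    ids <- sprintf("sim-miR-%03d", 1:49)
    eff <- c(setNames(rep(-2, 10), ids[1:10]),
             setNames(rep(2, 10), ids[11:20]))
    sim <- simulateCtMatrix(nMirnas = 49, ctNoiseSd = 0, plantedDe = eff,
                            plantedControlOnly = ids[41:46],
                            plantedTreatedOnly = ids[47:49], seed = 8)
    cfg <- quantConfig()
    calls <- callDetection(sim$ct, cfg)
    venn <- vennDecompose(calls)
    expect_equal(unname(venn["n_control_only"]), 6L)
    expect_equal(unname(venn["n_treated_only"]), 3L)
    de <- differentialExpression(normalizeCt(sim$ct, cfg), calls, cfg)
    got <- setNames(de$direction, de$mirna_id)[names(eff)]
    expect_equal(unname(got), unname(ifelse(eff < 0, "up", "down")))
})

test_that("recovered ddCt is unbiased within the sampling-error bound", {
    # planted ddCt -2, sigma = 0.1, 3 replicates; mean over 50 seeds
    cfg <- quantConfig()
    rec <- vapply(1:50, function(s) {
        sim <- simulateCtMatrix(nMirnas = 20, ctNoiseSd = 0.1,
                                plantedDe = c("sim-miR-001" = -2),
                                seed = s)
        de <- differentialExpression(normalizeCt(sim$ct, cfg),
                                     callDetection(sim$ct, cfg), cfg)
        de$ddct[de$mirna_id == "sim-miR-001"]
    }, numeric(1))
    expect_lt(abs(mean(rec) - (-2)), 0.2)
})

test_that("prediction simulation hits its sensitivity/FPR extremes", {
    map <- list(m1 = c("g1", "g2"), m2 = c("g3"))
    universe <- sprintf("g%d", 1:30)
    perfect <- simulatePredictions(map, universe, nTools = 5,
                                   toolSensitivity = 1, toolFpr = 0,
                                   nValidated = 0, seed = 1)
    hits <- aggregateHits(perfect$predictions)
    expect_true(all(hits$hit == 5L))
    expect_equal(nrow(hits), 3L)
    blind <- simulatePredictions(map, universe, nTools = 5,
                                 toolSensitivity = 0, toolFpr = 0,
                                 nValidated = 0, seed = 1)
    expect_true(is.null(blind$predictions) || nrow(blind$predictions) == 0)
})

test_that("perfect anti-correlation recovers the planted target set exactly", {
    map <- list(m1 = c("g1", "g2", "g3"))
    universe <- sprintf("g%d", 1:10)
    gde <- simulateGeneDe(map, c(m1 = "up"), universe,
                          anticorrelationStrength = 1, seed = 2)
    preds <- simulatePredictions(map, universe, nTools = 5,
                                 toolSensitivity = 1, toolFpr = 0,
                                 nValidated = 0, seed = 2)
    cons <- consensusTargets(preds$predictions, NULL,
                             consensusConfig(universeSize = 10))
    conf <- matchAnticorrelated(gde$geneDe, cons,
                                data.frame(mirna_id = "m1",
                                           direction = "up"))
    expect_equal(conf$down$gene_id, c("g1", "g2", "g3"))
})

test_that("inconsistent interactome plans are rejected, empty plans legal", {
    bad <- data.frame(bait = "ERalpha", gene_id = c("g1", "g1"),
                      representation = c("under", "over"))
    expect_error(simulateInteractome(bad), "inconsistent")
    plan <- data.frame(bait = character(), gene_id = character(),
                       representation = character())
    conf <- list(down = data.frame(gene_id = "g", log2fc = -1,
                                   mirnas = "m"),
                 up = data.frame(gene_id = character(), log2fc = numeric(),
                                 mirnas = character()))
    expect_error(overlayInteractome(conf, simulateInteractome(plan)),
                 "empty")
})

test_that("planted cohort structure is recovered exactly at zero noise", {
    co <- simulateCohort(noiseSdLog = 0, seed = 4)
    tv <- tumorVsNormal(co$measurements)
    expect_equal(sum(tv$call == "down"), 15L)
    expect_equal(sum(tv$call == "up"), 3L)
    expect_equal(sort(tv$patient_id[tv$call == "up"]),
                 sort(co$truth$upPatients))
    f <- treatmentResponse(co$measurements)
    expect_equal(
        groupResponseContrast(f, co$groups, "tumor")$percent_difference, 73)
    expect_equal(
        groupResponseContrast(f, co$groups, "normal")$percent_difference,
        38)
})

test_that("emitted tables round-trip through the package readers", {
    dir <- withr::local_tempdir()
    sim <- simulateCtMatrix(nMirnas = 10, seed = 9)
    ct <- ctValues(sim$ct)
    writeTsvTable(data.frame(mirna_id = rownames(ct), ct,
                             check.names = FALSE),
                  file.path(dir, "ct.tsv"))
    writeTsvTable(data.frame(sample_id = colnames(ct),
                             condition = sampleConditions(sim$ct),
                             replicate = rep(1:3, 2)),
                  file.path(dir, "samples.tsv"))
    back <- suppressMessages(
        readCtMatrix(file.path(dir, "ct.tsv"), file.path(dir, "samples.tsv"),
                     referenceAssays = referenceAssays(sim$ct)))
    expect_equal(ctValues(back), ct)
    expect_equal(sampleConditions(back), sampleConditions(sim$ct))
    expect_equal(referenceAssays(back), referenceAssays(sim$ct))

    co <- simulateCohort(seed = 2)
    writeTsvTable(co$measurements, file.path(dir, "cohort.tsv"))
    expect_equal(suppressMessages(
        readCohortTable(file.path(dir, "cohort.tsv")))$value,
        co$measurements$value)

    inter <- simulateInteractome(data.frame(
        bait = "LSD1", gene_id = c("g1", "g2"),
        representation = c("under", "over")), seed = 1)
    writeTsvTable(inter, file.path(dir, "interactome.tsv"))
    expect_equal(suppressMessages(
        readInteractomeTable(file.path(dir, "interactome.tsv"))),
        inter)
})
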