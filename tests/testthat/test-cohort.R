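test_that("IHC receptor rules apply the 1%/20% and HER2 3+ cut-offs", {
    p <- data.frame(patient_id = sprintf("p%d", 1:5),
                    er_pct = c(0, 0.9, 1, 50, 0),
                    pr_pct = c(70, 0, 19, 20, 0.8),
                    ki67_pct = c(10, 20, 25, 5, NA),
                    her2_score = c(3, 2, 1, 0, 3))
    s <- classifyReceptors(p)
    expect_equal(s$er_pos, c(FALSE, FALSE, TRUE, TRUE, FALSE))
    expect_equal(s$pr_pos, c(TRUE, FALSE, TRUE, TRUE, FALSE))
    expect_equal(s$pr_high, c(TRUE, FALSE, FALSE, TRUE, FALSE))
    expect_equal(s$ki67_high, c(FALSE, TRUE, TRUE, FALSE, NA))
    expect_equal(s$her2_pos, c(TRUE, FALSE, FALSE, FALSE, TRUE))
    # pr_high implies pr_pos
    expect_true(all(!s$pr_high | s$pr_pos))
    # ER drives grouping; HER2 3+ without ER stays ER_negative
    expect_equal(s$group, c("ER_negative", "ER_negative", "ER_positive",
                            "ER_positive", "ER_negative"))
    expect_error(classifyReceptors(transform(p, er_pct = 120)), "er_pct")
    expect_error(classifyReceptors(transform(p, her2_score = 4)),
                 "her2_score")
})

test_that("the packaged cohort table reproduces the published ER partition", {
    tab <- bcPatientTable()
    expect_equal(nrow(tab), 18L)
    s <- classifyReceptors(tab)
    expect_equal(sort(s$patient_id[s$group == "ER_negative"]),
                 sort(sprintf("PT%d", c(4, 7, 8, 13, 14))))
    # HER2 positivity on all 18 rows: only scores of 3 are positive
    expect_equal(s$patient_id[s$her2_pos],
                 tab$patient_id[tab$her2_score == 3])
    expect_equal(sum(s$her2_pos), 3L)  # PT1, PT4, PT8
    # verbatim staging detail survives transcription
    expect_equal(tab$staging[tab$patient_id == "PT18"], "pT2N1M1 (bone)")
    # grouping matches the er_group annotation column throughout
    expect_equal(s$group == "ER_positive", tab$er_group == "positive")
})

test_that("paired tumor/normal ratios use the inclusive 2-fold rule", {
    m <- data.frame(patient_id = rep(c("p1", "p2", "p3"), each = 2),
                    tissue = rep(c("tumor", "normal"), 3),
                    treatment = "ctrl",
                    value = c(0.25, 1, 2, 1, 1.5, 1))
    tv <- tumorVsNormal(m)
    expect_equal(tv$ratio, c(0.25, 2, 1.5))
    expect_equal(tv$call, c("down", "up", "unchanged"))
    # incomplete pair skipped with warning
    expect_warning(tv2 <- tumorVsNormal(rbind(m, data.frame(
        patient_id = "p4", tissue = "tumor", treatment = "ctrl",
        value = 1))), "p4")
    expect_equal(nrow(tv2), 3L)
    expect_error(tumorVsNormal(transform(m, value = -value)), "positive")
})

test_that("treatment-response folds classify like the miRNome module", {
    m <- data.frame(patient_id = "p1",
                    tissue = rep(c("tumor", "normal"), each = 2),
                    treatment = rep(c("ctrl", "MC3324"), 2),
                    value = c(1, 2, 1, 1))
    f <- treatmentResponse(m)
    expect_equal(f$fold, c(2, 1))
    expect_equal(f$call, c("up", "unchanged"))
    expect_warning(treatmentResponse(rbind(m, data.frame(
        patient_id = "p2", tissue = "tumor", treatment = "ctrl",
        value = 1))), "p2")
})

test_that("group contrast follows the declared ratio-of-means formula", {
    folds <- data.frame(patient_id = sprintf("p%d", 1:4),
                        tissue = "tumor", ctrl = 1,
                        treated = c(1.73, 1.73, 1, 1),
                        fold = c(1.73, 1.73, 1, 1), call = "unchanged")
    groups <- data.frame(patient_id = sprintf("p%d", 1:4),
                         group = c("ER_positive", "ER_positive",
                                   "ER_negative", "ER_negative"))
    d <- groupResponseContrast(folds, groups, "tumor")
    expect_equal(d$percent_difference, 73)
    expect_equal(d$n_pos, 2L)
    # identical means -> 0
    folds0 <- transform(folds, fold = 1.2)
    expect_equal(groupResponseContrast(folds0, groups,
                                       "tumor")$percent_difference, 0)
    # empty group errors by name
    g2 <- transform(groups, group = "ER_positive")
    expect_error(groupResponseContrast(folds, g2, "tumor"), "ER_negative")
})

test_that("group swap follows the antisymmetry identity and scaling cancels", {
    set.seed(21)
    folds <- data.frame(patient_id = sprintf("p%d", 1:10),
                        tissue = "tumor", ctrl = 1, treated = 1,
                        fold = exp(rnorm(10, 0.2, 0.3)), call = "unchanged")
    groups <- data.frame(patient_id = sprintf("p%d", 1:10),
                         group = rep(c("ER_positive", "ER_negative"), 5))
    D <- groupResponseContrast(folds, groups, "tumor")$percent_difference
    gswap <- transform(groups, group = ifelse(group == "ER_positive",
                                              "ER_negative", "ER_positive"))
    Dswap <- groupResponseContrast(folds, gswap,
                                   "tumor")$percent_difference
    expect_equal(Dswap, -D / (1 + D / 100))
    # multiplying every measurement by a constant leaves ratios and D alone
    m <- simulateCohort(seed = 3)$measurements
    g <- simulateCohort(seed = 3)$groups
    m2 <- transform(m, value = value * 7.5)
    f1 <- treatmentResponse(m); f2 <- treatmentResponse(m2)
    expect_equal(f1$fold, f2$fold)
    expect_equal(tumorVsNormal(m)$ratio, tumorVsNormal(m2)$ratio)
    expect_equal(groupResponseContrast(f1, g, "normal"),
                 groupResponseContrast(f2, g, "normal"))
})
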