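test_that("cohort generation matches configured counts and is seeded", {
    cfg <- cohortConfig(seed = 101)
    cohort <- generateCohort(cfg)
    expect_equal(nrow(cohort), 61)
    expect_equal(sum(cohort$group == "PD"), 22)
    expect_equal(sum(!is.na(cohort$putaminalDaT)), 22)   # DaT in PD only
    expect_true(all(is.na(cohort$putaminalDaT[cohort$group == "HC"])))
    expect_equal(sum(cohort$sex[cohort$group == "PD"] == "m"), 15)
    expect_equal(unname(table(cohort$sequence[cohort$group == "PD"])),
                 c(4, 17, 1), ignore_attr = TRUE)
    expect_equal(cohort$nVolumes,
                 c(740L, 500L, 740L)[cohort$sequence])
    expect_identical(cohort, generateCohort(cfg))  # same seed, same table
    expect_false(identical(cohort,
                           generateCohort(cohortConfig(seed = 102))))
})

test_that("degenerate zero-variance config collapses to the means", {
    cfg <- cohortConfig(agePD = c(62.1, 0), eduPD = c(15.8, 0),
                        dat = c(-3.6, 0), paLog = c(log(50), 0),
                        noiseSd = 0, seed = 1)
    cohort <- generateCohort(cfg)
    pd <- cohort[cohort$group == "PD", ]
    expect_true(all(pd$age == 62.1))
    expect_true(all(pd$education == 15.8))
    expect_true(all(pd$putaminalDaT == -3.6))
    expect_true(all(abs(pd$pa - 50) < 1e-9))
})

test_that("invalid configurations are rejected", {
    expect_error(cohortConfig(nPD = 0), "positive")
    expect_error(cohortConfig(seqProbs = c(0.5, 0.5, 0.5)), "summing")
    expect_error(cohortConfig(agePD = c(60, -1)), "sd >= 0")
    expect_error(cohortConfig(noiseSd = -0.1), "noiseSd")
})

test_that("series length follows the fMRI sequence", {
    cfg <- cohortConfig(seed = 1)
    atlas <- smallAtlas()
    set.seed(1)
    expect_equal(ncol(generateTimeseries(pdProfile(sequence = 2),
                                         atlas, cfg)), 500)
    expect_equal(ncol(generateTimeseries(pdProfile(sequence = 1),
                                         atlas, cfg)), 740)
    ts <- generateTimeseries(pdProfile(), atlas, cfg)
    expect_equal(rownames(ts), roiIds(atlas))
})

test_that("within-subnetwork coupling exceeds between in expectation", {
    cfg <- cohortConfig(seed = 1)
    atlas <- smallAtlas()
    set.seed(21)
    ts <- generateTimeseries(pdProfile(), atlas, cfg, nVolumes = 2000)
    r <- cor(t(ts))
    lab <- networkLabels(atlas)
    within <- mean(r[upper.tri(r)][outer(lab, lab, "==")[upper.tri(r)] &
                                   outer(lab != "none", lab != "none",
                                         "&")[upper.tri(r)]])
    between <- mean(r[upper.tri(r)][outer(lab, lab, "!=")[upper.tri(r)]])
    expect_gt(within, between + 0.1)
})

test_that("SMN coupling rises with DaT integrity", {
    cfg <- cohortConfig(seed = 1)
    atlas <- smallAtlas()
    set.seed(22)
    lo <- replicate(5, meanWithinCor(
        generateTimeseries(pdProfile(dat = -5), atlas, cfg,
                           nVolumes = 1500), atlas, "SMN"))
    hi <- replicate(5, meanWithinCor(
        generateTimeseries(pdProfile(dat = -2), atlas, cfg,
                           nVolumes = 1500), atlas, "SMN"))
    expect_gt(mean(hi), mean(lo))
})

test_that("the homogeneous coupling slope is recovered and nulls out", {
    atlas <- smallAtlas()
    # topology effect off isolates the homogeneous base + effect model
    cfg <- cohortConfig(datToSMNCoupling = 0.06, datTopoEffect = 0,
                        coreSize = 0, seed = 1)
    set.seed(23)
    dat <- runif(120, -5, -2)
    coup <- vapply(dat, function(dz) meanWithinCor(
        generateTimeseries(pdProfile(dat = dz), atlas, cfg,
                           nVolumes = 600), atlas, "SMN"), numeric(1))
    slope <- coef(lm(coup ~ dat))[2]
    expect_gt(slope, 0)
    expect_lt(abs(slope - 0.06), 0.015)

    # null coupling: no association left
    cfg0 <- cohortConfig(datToSMNCoupling = 0, datTopoEffect = 0,
                         coreSize = 0, seed = 1)
    set.seed(24)
    coup0 <- vapply(dat[1:60], function(dz) meanWithinCor(
        generateTimeseries(pdProfile(dat = dz), atlas, cfg0,
                           nVolumes = 600), atlas, "SMN"), numeric(1))
    expect_lt(abs(cor(dat[1:60], coup0)), 0.3)
})

test_that("ATN coupling rises with education", {
    atlas <- smallAtlas()
    cfg <- cohortConfig(seed = 1)
    set.seed(25)
    lo <- replicate(5, meanWithinCor(
        generateTimeseries(pdProfile(education = 10), atlas, cfg,
                           nVolumes = 1500), atlas, "ATN"))
    hi <- replicate(5, meanWithinCor(
        generateTimeseries(pdProfile(education = 20), atlas, cfg,
                           nVolumes = 1500), atlas, "ATN"))
    expect_gt(mean(hi), mean(lo))
})

test_that("noise-free behavior is monotone in NAT and frozen at the knot", {
    cfg <- cohortConfig(noiseSd = 0, seed = 1)
    dirs <- testDirections()
    p <- pdProfile(pa = 20)  # below the knot of 45
    set.seed(26)
    b_lo <- generateBehavior(p, 0.3, cfg)
    b_hi <- generateBehavior(p, 0.6, cfg)
    for (j in seq_len(nrow(dirs))) {
        if (dirs$domain[j] != "motor") next
        if (dirs$direction[j] == "higher_better")
            expect_gt(b_hi[[dirs$test[j]]], b_lo[[dirs$test[j]]])
        else
            expect_lt(b_hi[[dirs$test[j]]], b_lo[[dirs$test[j]]])
    }
    # moderation increment freezes at the knot: pa = knot and pa > knot
    # give identical scores, pa just below differs
    at <- generateBehavior(pdProfile(pa = 45), 0.5, cfg)
    above <- generateBehavior(pdProfile(pa = 80), 0.5, cfg)
    below <- generateBehavior(pdProfile(pa = 35), 0.5, cfg)
    expect_equal(at[, -1], above[, -1])
    expect_false(isTRUE(all.equal(at$gripStrength, below$gripStrength)))
    # direct evaluation of the planted latent formula at the knot
    latent <- function(pa) cfg@gmpIntercept + cfg@natToGMPSlope * 0.5 +
        cfg@paModerationSlope * 0.5 * min(pa, cfg@paModerationKnot)
    expect_equal(at$gripStrength - below$gripStrength,
                 8 * (latent(45) - latent(35)))
})

test_that("behavior rejects out-of-range NAT for PD participants", {
    cfg <- cohortConfig(seed = 1)
    expect_error(generateBehavior(pdProfile(), 1.2, cfg), "strictly")
    expect_error(generateBehavior(pdProfile(), 0, cfg), "strictly")
    hc <- pdProfile(); hc$group <- "HC"; hc$putaminalDaT <- NA
    expect_silent({set.seed(1); generateBehavior(hc, NA, cfg)})
})

test_that("cognitive scores are independent of NAT", {
    cfg <- cohortConfig(seed = 1)
    profiles <- do.call(rbind, lapply(1:500, function(i)
        pdProfile(id = sprintf("P%03d", i), idx = i)))
    set.seed(27)
    nat <- runif(500, 0.2, 0.8)
    b <- generateBehavior(profiles, nat, cfg)
    fit <- summary(lm(b$screening ~ nat))
    expect_gt(fit$coefficients["nat", "Pr(>|t|)"], 0.001)
    # while motor scores do depend on NAT
    fit2 <- summary(lm(b$gripStrength ~ nat))
    expect_lt(fit2$coefficients["nat", "Pr(>|t|)"], 1e-6)
})

test_that("diaries reproduce the drawn lifetime PA exactly", {
    cfg <- cohortConfig(seed = 5)
    cohort <- generateCohort(cfg)
    set.seed(28)
    diaries <- generateDiaries(cohort, cfg)
    pa <- diaryPA(diaries)
    expect_equal(pa$pa[match(cohort$id, pa$participant)], cohort$pa,
                 tolerance = 1e-12)
    # all four periods present, only two enter the PA definition
    expect_setequal(unique(diaries$period),
                    c("12-19", "19-35", "35-50", "50+"))
})
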