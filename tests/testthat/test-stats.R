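test_that("the NAT beta GLMM consumes 198 rows and carries 8 slopes", {
    cohort <- generateCohort(cohortConfig(seed = 41))
    set.seed(41)
    records <- simulateBetaNAT(cohort, bDat = 0.1)
    fit <- fitNATModel(records, cohort, network = "SMN")
    expect_equal(fit@nObs, 198L)
    expect_equal(nrow(fit@coefficients), 9)  # intercept + 8 slopes
    expect_setequal(
        fit@coefficients$term,
        c("(Intercept)", "putaminalDaT", "pa", "education", "age",
          "sexm", "density", "sequence2", "sequence3"))
    expect_true(fit@converged)
    expect_true(fit@pseudoR2 >= 0 && fit@pseudoR2 <= 1)
    # CI brackets the estimate
    expect_true(all(fit@coefficients$ciLow <= fit@coefficients$estimate &
                    fit@coefficients$estimate <= fit@coefficients$ciHigh))
})

test_that("planted logit-scale coefficients are recovered", {
    cohort <- generateCohort(cohortConfig(seed = 42))
    set.seed(42)
    records <- simulateBetaNAT(cohort, bDensity = 0.6, bDat = 0.1)
    fit <- fitNATModel(records, cohort, network = "SMN")
    cf <- fit@coefficients
    d <- cf[cf$term == "density", ]
    expect_true(d$ciLow <= 0.6 && 0.6 <= d$ciHigh)
    expect_lt(abs(d$estimate - 0.6), 0.4)
    a <- cf[cf$term == "putaminalDaT", ]
    expect_gt(a$estimate, 0)
})

test_that("an intercept-only generating model yields flat slopes", {
    cohort <- generateCohort(cohortConfig(seed = 43))
    set.seed(43)
    records <- simulateBetaNAT(cohort, b0 = -0.5, bDensity = 0,
                               bDat = 0, tau = 0.2)
    fit <- fitNATModel(records, cohort, network = "SMN")
    cf <- fit@coefficients
    slopes <- cf[cf$term %in% c("putaminalDaT", "education", "density"), ]
    expect_true(all(slopes$p > 0.01))
})

test_that("boundary NAT responses are nudged with a warning", {
    cohort <- generateCohort(cohortConfig(seed = 44))
    set.seed(44)
    records <- simulateBetaNAT(cohort)
    records$nat[1] <- 0
    records$nat[2] <- 1
    expect_warning(fit <- fitNATModel(records, cohort, "SMN"), "nudged")
    expect_true(fit@converged)
})

test_that("estimates are invariant to row order of the long table", {
    cohort <- generateCohort(cohortConfig(seed = 45))
    set.seed(45)
    records <- simulateBetaNAT(cohort)
    f1 <- fitNATModel(records, cohort, "SMN")
    set.seed(46)
    perm <- sample(nrow(records))
    f2 <- fitNATModel(records[perm, ], cohort, "SMN")
    expect_equal(f1@coefficients$estimate, f2@coefficients$estimate,
                 tolerance = 1e-5)
})

test_that("logit-transformed linear mixed model agrees in slope signs", {
    skip_if_not_installed("lme4")
    cohort <- generateCohort(cohortConfig(seed = 47))
    set.seed(47)
    records <- simulateBetaNAT(cohort, bDensity = 1.2, bDat = 0.25,
                               phi = 200, tau = 0.1)
    fit <- fitNATModel(records, cohort, "SMN")
    d <- merge(records, cohort, by.x = "participant", by.y = "id")
    d$y <- qlogis(d$nat)
    lf <- lme4::lmer(y ~ putaminalDaT + pa + education + age + sex +
                         density + factor(sequence) + (1 | participant),
                     data = d)
    lcf <- lme4::fixef(lf)
    bcf <- setNames(fit@coefficients$estimate, fit@coefficients$term)
    expect_gt(bcf[["density"]] * lcf[["density"]], 0)
    expect_gt(bcf[["putaminalDaT"]] * lcf[["putaminalDaT"]], 0)
})

test_that("the moderation model recovers a planted interaction", {
    set.seed(48)
    d <- makeModData(200, bInt = 0.5)
    fit <- fitModeration(d, "gmp", moderator = "pa")
    tab <- moderationTable(fit)
    i <- tab[tab$term == "natMean:pa", ]
    expect_lt(abs(i$estimate - 0.5), 2 * i$se)
    expect_lt(fit@fp, 1e-6)
    expect_equal(fit@nObs, 200L)
})

test_that("a constant moderator is rejected as rank deficient", {
    set.seed(49)
    d <- makeModData(50)
    d$pa <- 40
    expect_error(fitModeration(d, "gmp", moderator = "pa"),
                 "natMean:pa")
})

test_that("incomplete cases are dropped (one missing GCP gives n-1)", {
    set.seed(50)
    d <- makeModData(22)
    d$gcp[5] <- NA
    fit <- fitModeration(d, "gcp", moderator = "education")
    expect_equal(fit@nObs, 21L)
})

test_that("Johnson-Neyman boundaries match a dense grid-search oracle", {
    set.seed(51)
    # negative interaction against a positive main effect creates an
    # interior boundary within the moderator range
    d <- makeModData(120, bNat = 8, bPA = 0.02, bInt = -0.12,
                     noise = 1.5)
    fit <- fitModeration(d, "gmp", moderator = "pa")
    jn <- johnsonNeyman(fit, alpha = 0.05)
    oracle <- oracleJNBoundaries(fit, alpha = 0.05)
    expect_gt(length(jn@boundaries), 0)
    expect_equal(sort(jn@boundaries), sort(oracle), tolerance = 1e-4)
    # at each boundary the recomputed two-sided p equals alpha
    g <- jn@grid
    for (w in jn@boundaries) {
        cf <- coef(fit@model); V <- vcov(fit@model)
        eff <- cf[["natMean"]] + cf[["natMean:pa"]] * w
        se <- sqrt(V["natMean", "natMean"] + w^2 *
                       V["natMean:pa", "natMean:pa"] +
                       2 * w * V["natMean", "natMean:pa"])
        p <- 2 * pt(abs(eff / se), fit@model$df.residual,
                    lower.tail = FALSE)
        expect_equal(p, 0.05, tolerance = 1e-8)
    }
    # significant regions lie inside the observed moderator range
    expect_true(all(jn@regions$lower >= jn@range[1] - 1e-9))
    expect_true(all(jn@regions$upper <= jn@range[2] + 1e-9))
})

test_that("flat interactions give all-or-nothing JN regions", {
    set.seed(52)
    strong <- makeModData(150, bNat = 10, bInt = 0.001, noise = 0.5)
    f1 <- fitModeration(strong, "gmp", moderator = "pa")
    jn1 <- johnsonNeyman(f1)
    expect_true(jn1@status %in% c("everywhere", "boundary"))
    expect_gt(sum(jn1@regions$upper - jn1@regions$lower),
              0.9 * diff(jn1@range))

    none <- makeModData(60, bNat = 0, bPA = 0, bInt = 0, noise = 20)
    f2 <- fitModeration(none, "gmp", moderator = "pa")
    jn2 <- johnsonNeyman(f2)
    covered <- if (nrow(jn2@regions))
        sum(jn2@regions$upper - jn2@regions$lower) else 0
    expect_lt(covered, 0.5 * diff(jn2@range))
})

test_that("below-knot moderation is detected as a lower PA interval", {
    cfg <- cohortConfig(noiseSd = 0.25, paModerationSlope = -0.02,
                        natToGMPSlope = 1.0, seed = 53)
    n <- 150
    profiles <- do.call(rbind, lapply(seq_len(n), function(i)
        pdProfile(id = sprintf("P%03d", i), idx = i)))
    set.seed(53)
    profiles$sex <- sample(c("f", "m"), n, TRUE)
    profiles$sequence <- sample(1:3, n, TRUE)
    profiles$pa <- rlnorm(n, log(40), 0.8)
    profiles$putaminalDaT <- rnorm(n, -3.6, 0.7)
    profiles$age <- rnorm(n, 62, 8)
    profiles$education <- rnorm(n, 16, 2.7)
    nat <- runif(n, 0.2, 0.8)
    hcp <- do.call(rbind, lapply(1:80, function(i) {
        h <- pdProfile(id = sprintf("H%03d", i), idx = n + i)
        h$group <- "HC"; h$putaminalDaT <- NA; h
    }))
    cs <- compositeScores(generateBehavior(profiles, nat, cfg),
                          generateBehavior(hcp, NA, cfg))
    d <- cbind(profiles, natMean = nat,
               gmp = cs$gmp[match(profiles$id, cs$participant)],
               gcp = 0)
    fit <- fitModeration(d, "gmp", moderator = "pa")
    jn <- johnsonNeyman(fit)
    # the NAT effect weakens with PA below the knot: the significant
    # positive-effect region must be a lower interval of the PA range
    pos <- jn@regions[jn@regions$direction == "positive", , drop = FALSE]
    expect_gt(nrow(pos), 0)
    expect_lt(pos$lower[1] - jn@range[1], 1e-9)
    expect_lt(pos$upper[1], jn@range[2])
})
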