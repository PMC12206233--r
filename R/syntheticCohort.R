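#' Configuration of the synthetic study cohort
#'
#' Bundles every distribution parameter and planted effect size the
#' synthetic-cohort generator uses. The defaults emulate the study
#' conditions of an early Parkinson's disease (PD) cohort with healthy
#' controls (HC): 22 PD / 39 HC; age 62.1 (8.0) vs 63.5 (6.5) years;
#' 15/7 vs 26/13 male/female; education 15.8 (2.7) vs 16.7 (2.8) years;
#' putaminal dopamine-transporter (DaT) z-scores -3.6 (0.7) in PD only;
#' lifetime physical activity (PA, weekly energy expenditure units)
#' log-normal with median 58.3; fMRI sequences allocated 4/17/1 with
#' 740/500/740 volumes.
#'
#' Planted effects: within-SMN coupling rises with DaT integrity
#' (`datToSMNCoupling` per z unit) and within-ATN coupling with
#' education (`eduToATNCoupling` per year); a small core of hub ROIs
#' concentrates connectivity as the covariate falls (`datTopoEffect`,
#' `eduTopoEffect`), which lowers the thresholded network's attack
#' tolerance; latent motor ability follows
#' `gmpIntercept + natToGMPSlope * NAT +
#'  paModerationSlope * NAT * min(PA, paModerationKnot) + noise`,
#' while cognitive ability is independent of NAT.
#'
#' @slot nPD,nHC group sizes.
#' @slot agePD,ageHC,eduPD,eduHC,dat,paLog length-2 numeric vectors
#'   `(mean, sd)`; `paLog` is location/scale on the log scale; `dat`
#'   applies to PD only.
#' @slot maleFracPD,maleFracHC fraction of males per group.
#' @slot seqProbs probabilities of the three fMRI sequences.
#' @slot baseWithin,baseBetween baseline within- and between-subnetwork
#'   correlation of the block factor model.
#' @slot subjectSd standard deviation of the per-participant jitter on
#'   the baseline within-network coupling (individual differences in
#'   overall connectivity; this is what the mixed model's random
#'   intercepts absorb).
#' @slot datToSMNCoupling,eduToATNCoupling homogeneous coupling slopes.
#' @slot coreSize,coreBase,datTopoEffect,eduTopoEffect hub-core
#'   concentration: number of core ROIs, baseline loading inflation, and
#'   its decrease per covariate unit.
#' @slot gmpIntercept,natToGMPSlope,paModerationKnot,paModerationSlope
#'   planted behavior model (see above).
#' @slot noiseSd residual noise scale of the behavioral model (0 gives
#'   deterministic scores).
#' @slot seed integer RNG seed honored by [generateCohort()].
#' @seealso [cohortConfig()], [generateCohort()], [generateTimeseries()],
#'   [generateBehavior()], [generateDiaries()]
#' @export
setClass("CohortConfig",
    representation(
        nPD = "integer", nHC = "integer",
        agePD = "numeric", ageHC = "numeric",
        maleFracPD = "numeric", maleFracHC = "numeric",
        eduPD = "numeric", eduHC = "numeric",
        dat = "numeric", paLog = "numeric", seqProbs = "numeric",
        baseWithin = "numeric", baseBetween = "numeric",
        subjectSd = "numeric",
        datToSMNCoupling = "numeric", eduToATNCoupling = "numeric",
        coreSize = "integer", coreBase = "numeric",
        datTopoEffect = "numeric", eduTopoEffect = "numeric",
        gmpIntercept = "numeric", natToGMPSlope = "numeric",
        paModerationKnot = "numeric", paModerationSlope = "numeric",
        noiseSd = "numeric", seed = "integer"),
    validity = function(object) {
        msg <- character()
        if (object@nPD <= 0 || object@nHC <= 0)
            msg <- c(msg, "group sizes must be positive")
        for (s in c("agePD", "ageHC", "eduPD", "eduHC", "dat", "paLog")) {
            v <- slot(object, s)
            if (length(v) != 2 || v[2] < 0)
                msg <- c(msg, paste0(s, " must be c(mean, sd) with sd >= 0"))
        }
        if (abs(sum(object@seqProbs) - 1) > 1e-8 ||
            length(object@seqProbs) != 3 || any(object@seqProbs < 0))
            msg <- c(msg, "seqProbs must be 3 nonnegative values summing to 1")
        if (object@maleFracPD < 0 || object@maleFracPD > 1 ||
            object@maleFracHC < 0 || object@maleFracHC > 1)
            msg <- c(msg, "male fractions must lie in [0, 1]")
        if (object@baseBetween < 0 || object@baseWithin <= object@baseBetween)
            msg <- c(msg, "need 0 <= baseBetween < baseWithin")
        if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
        if (object@subjectSd < 0) msg <- c(msg, "subjectSd must be >= 0")
        if (object@coreSize < 0) msg <- c(msg, "coreSize must be >= 0")
        if (length(msg)) msg else TRUE
    })

.SEQ_VOLUMES <- c(740L, 500L, 740L)

#' Create a cohort configuration
#'
#' All arguments default to the emulated study conditions; see
#' [CohortConfig-class] for their meaning.
#'
#' @param nPD,nHC group sizes.
#' @param agePD,ageHC,eduPD,eduHC,dat,paLog `(mean, sd)` pairs.
#' @param maleFracPD,maleFracHC fraction male per group.
#' @param seqProbs sequence allocation probabilities.
#' @param baseWithin,baseBetween baseline block correlations.
#' @param subjectSd per-participant jitter of the baseline coupling.
#' @param datToSMNCoupling,eduToATNCoupling coupling slopes.
#' @param coreSize,coreBase,datTopoEffect,eduTopoEffect hub-core
#'   concentration parameters.
#' @param gmpIntercept,natToGMPSlope,paModerationKnot,paModerationSlope
#'   planted behavior model.
#' @param noiseSd behavioral noise scale.
#' @param seed integer RNG seed.
#' @return A validated [CohortConfig-class].
#' @examples
#' cfg <- cohortConfig(seed = 7)
#' cohort <- generateCohort(cfg)
#' table(cohort$group)
#' @export
cohortConfig <- function(nPD = 22, nHC = 39,
                         agePD = c(62.1, 8.0), ageHC = c(63.5, 6.5),
                         maleFracPD = 15 / 22, maleFracHC = 26 / 39,
                         eduPD = c(15.8, 2.7), eduHC = c(16.7, 2.8),
                         dat = c(-3.6, 0.7),
                         paLog = c(log(58.3), 0.9),
                         seqProbs = c(4, 17, 1) / 22,
                         baseWithin = 0.45, baseBetween = 0.10,
                         subjectSd = 0.05,
                         datToSMNCoupling = 0.06,
                         eduToATNCoupling = 0.02,
                         coreSize = 8, coreBase = 0.15,
                         datTopoEffect = 0.15, eduTopoEffect = 0.05,
                         gmpIntercept = -12, natToGMPSlope = 40,
                         paModerationKnot = 45,
                         paModerationSlope = -0.35,
                         noiseSd = 0.5, seed = 1) {
    new("CohortConfig",
        nPD = as.integer(nPD), nHC = as.integer(nHC),
        agePD = agePD, ageHC = ageHC,
        maleFracPD = maleFracPD, maleFracHC = maleFracHC,
        eduPD = eduPD, eduHC = eduHC, dat = dat, paLog = paLog,
        seqProbs = seqProbs,
        baseWithin = baseWithin, baseBetween = baseBetween,
        subjectSd = subjectSd,
        datToSMNCoupling = datToSMNCoupling,
        eduToATNCoupling = eduToATNCoupling,
        coreSize = as.integer(coreSize), coreBase = coreBase,
        datTopoEffect = datTopoEffect, eduTopoEffect = eduTopoEffect,
        gmpIntercept = gmpIntercept, natToGMPSlope = natToGMPSlope,
        paModerationKnot = paModerationKnot,
        paModerationSlope = paModerationSlope,
        noiseSd = noiseSd, seed = as.integer(seed))
}

setMethod("show", "CohortConfig", function(object) {
    cat(sprintf("CohortConfig: %d PD + %d HC (seed %d)\n",
                object@nPD, object@nHC, object@seed))
    cat(sprintf("  coupling: within %.2f, between %.2f; DaT->SMN %.3f, edu->ATN %.3f\n",
                object@baseWithin, object@baseBetween,
                object@datToSMNCoupling, object@eduToATNCoupling))
    cat(sprintf("  behavior: NAT->GMP %.2f, PA knot %.1f, slope %.4f, noise %.2f\n",
                object@natToGMPSlope, object@paModerationKnot,
                object@paModerationSlope, object@noiseSd))
})

# deterministic largest-remainder allocation of n items to probs
.apportion <- function(n, probs) {
    raw <- probs * n
    counts <- floor(raw)
    left <- n - sum(counts)
    if (left > 0) {
        extra <- order(raw - counts, decreasing = TRUE)[seq_len(left)]
        counts[extra] <- counts[extra] + 1L
    }
    as.integer(counts)
}

#' Generate participant profiles
#'
#' Draws a cohort table from the configured distributions. Sex and fMRI
#' sequence are allocated by deterministic largest-remainder counts in
#' random order (matching the study's fixed design: all sequence levels
#' are present whenever their probability allows); continuous covariates
#' are drawn from the configured normal / log-normal distributions. PD
#' participants carry a putaminal DaT z-score, HC participants do not.
#' The RNG is seeded from `config@seed`, so identical configurations
#' yield identical tables.
#'
#' @param config a [CohortConfig-class].
#' @return `data.frame` with columns `id`, `idx`, `group`, `age`, `sex`,
#'   `education`, `putaminalDaT`, `pa`, `sequence`, `nVolumes`.
#' @export
generateCohort <- function(config) {
    stopifnot(is(config, "CohortConfig"))
    validObject(config)
    set.seed(config@seed)
    make_group <- function(n, group, age, maleFrac, edu) {
        nm <- round(maleFrac * n)
        data.frame(
            id = sprintf("%s%02d", group, seq_len(n)),
            group = group,
            age = rnorm(n, age[1], age[2]),
            sex = sample(rep(c("m", "f"), c(nm, n - nm))),
            education = rnorm(n, edu[1], edu[2]),
            sequence = sample(rep(1:3, .apportion(n, config@seqProbs))),
            stringsAsFactors = FALSE)
    }
    pd <- make_group(config@nPD, "PD", config@agePD, config@maleFracPD,
                     config@eduPD)
    hc <- make_group(config@nHC, "HC", config@ageHC, config@maleFracHC,
                     config@eduHC)
    cohort <- rbind(pd, hc)
    cohort$idx <- seq_len(nrow(cohort))
    cohort$putaminalDaT <- ifelse(cohort$group == "PD",
                                  rnorm(nrow(cohort), config@dat[1],
                                        config@dat[2]), NA_real_)
    cohort$pa <- rlnorm(nrow(cohort), config@paLog[1], config@paLog[2])
    cohort$nVolumes <- .SEQ_VOLUMES[cohort$sequence]
    cohort[, c("id", "idx", "group", "age", "sex", "education",
               "putaminalDaT", "pa", "sequence", "nVolumes")]
}

# Per-ROI factor loadings for one participant. The connectome is a
# factor model: a global factor (between-network coupling), one factor
# per subnetwork (within-network coupling = base + covariate effects,
# clipped), and an inflated loading for a small hub core of the SMN
# (driven by DaT) and ATN (driven by education). Uniquenesses absorb the
# rest of the unit variance; total loading^2 is capped at 0.95.
.connectome_loadings <- function(profile, atlas, config) {
    net <- atlas@network
    n <- length(net)
    clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
    base <- config@baseWithin + rnorm(1, 0, config@subjectSd)
    r_within <- setNames(rep(base, 4), .NETWORKS)
    if (!is.na(profile$putaminalDaT))
        r_within["SMN"] <- r_within["SMN"] + config@datToSMNCoupling *
            (profile$putaminalDaT - config@dat[1])
    r_within["ATN"] <- r_within["ATN"] + config@eduToATNCoupling *
        (profile$education - config@eduPD[1])
    r_within <- clip(r_within, config@baseBetween + 0.01, 0.90)

    lam_g <- sqrt(config@baseBetween)
    lam_b <- rep(0, n)
    for (b in .NETWORKS)
        lam_b[net == b] <- sqrt(r_within[b] - config@baseBetween)

    infl <- rep(1, n)
    core_infl <- function(members, delta) {
        core <- members[seq_len(min(config@coreSize, length(members)))]
        infl[core] <<- 1 + clip(delta, 0, 0.5)
    }
    if (config@coreSize > 0) {
        if (!is.na(profile$putaminalDaT))
            core_infl(which(net == "SMN"),
                      config@coreBase - config@datTopoEffect *
                          (profile$putaminalDaT - config@dat[1]))
        core_infl(which(net == "ATN"),
                  config@coreBase - config@eduTopoEffect *
                      (profile$education - config@eduPD[1]))
    }
    lam_b <- lam_b * infl
    tot <- lam_g^2 + lam_b^2
    over <- tot > 0.95
    lam_b[over] <- sqrt(0.95 - lam_g^2)
    list(global = lam_g, block = lam_b,
         unique = sqrt(1 - pmin(tot, 0.95)), net = net)
}

#' Generate a synthetic ROI time-series matrix
#'
#' Simulates a resting-state scan for one participant as a multivariate
#' normal factor model: a global factor gives the baseline
#' between-network coupling, per-subnetwork factors give the
#' within-network coupling (base plus the planted DaT and education
#' effects), and a small hub core concentrates SMN/ATN connectivity as
#' the covariate falls. Series length equals the participant's
#' `nVolumes` (740/500/740 for sequences 1/2/3) and a constant offset of
#' 100 puts the temporal SNR on a realistic scale.
#'
#' @param profile one row of a [generateCohort()] table.
#' @param atlas an [ROIAtlas-class].
#' @param config the [CohortConfig-class] used for the cohort.
#' @param nVolumes optional override of the series length.
#' @return Numeric matrix (ROIs x time) with ROI ids as row names.
#' @export
generateTimeseries <- function(profile, atlas, config,
                               nVolumes = profile$nVolumes) {
    stopifnot(is(atlas, "ROIAtlas"), is(config, "CohortConfig"))
    validObject(atlas)
    L <- .connectome_loadings(profile, atlas, config)
    n <- length(L$net)
    Tn <- as.integer(nVolumes)
    fac_g <- rnorm(Tn)
    fac_b <- matrix(rnorm(Tn * 4), Tn, 4,
                    dimnames = list(NULL, .NETWORKS))
    x <- fac_g %o% rep(L$global, n)
    for (b in .NETWORKS) {
        m <- L$net == b
        if (any(m)) x[, m] <- x[, m] + fac_b[, b] %o% L$block[m]
    }
    x <- x + matrix(rnorm(Tn * n), Tn, n) * rep(L$unique, each = Tn)
    ts <- t(x) + 100
    rownames(ts) <- atlas@roi
    ts
}

#' Test battery layout and direction flags
#'
#' The synthetic battery mirrors a motor assessment (grip strength,
#' finger tapping, pegboard, a hand-function duration task and a
#' timed-up-and-go duration task) and a cognitive assessment (a
#' screening score, a DemTect-like score and two trail-making
#' durations). Duration tests are flagged `lower_better` and are
#' inverted before composite scoring.
#'
#' @return `data.frame` with columns `test`, `domain`, `direction`.
#' @export
testDirections <- function() {
    data.frame(
        test = c("gripStrength", "fingerTapping", "pegboard",
                 "handFunction", "timedUpAndGo",
                 "screening", "demtect", "trailMakingA", "trailMakingB"),
        domain = c(rep("motor", 5), rep("cognitive", 4)),
        direction = c("higher_better", "higher_better", "higher_better",
                      "lower_better", "lower_better",
                      "higher_better", "higher_better",
                      "lower_better", "lower_better"),
        stringsAsFactors = FALSE)
}

.TEST_SCALE <- data.frame(
    test = c("gripStrength", "fingerTapping", "pegboard",
             "handFunction", "timedUpAndGo",
             "screening", "demtect", "trailMakingA", "trailMakingB"),
    mu = c(35, 50, 13, 35, 9, 55, 15, 40, 90),
    sigma = c(8, 8, 2, 8, 2, 5, 2.5, 12, 30),
    stringsAsFactors = FALSE)

#' Generate synthetic motor and cognitive test scores
#'
#' Latent motor ability follows the planted model
#' `gmpIntercept + natToGMPSlope * nat +
#'  paModerationSlope * nat * min(pa, paModerationKnot) + noise`
#' for PD participants (the NAT-behavior coupling and the PA moderation
#' apply only below the knot); HC ability is pure noise around zero, and
#' latent cognitive ability is independent of NAT in both groups
#' (matching a null cognitive finding). Each test maps ability linearly
#' onto its own scale; duration tests decrease as ability increases.
#'
#' @param profiles cohort table rows ([generateCohort()]).
#' @param natGlobal numeric vector of global NAT values aligned with
#'   `profiles`; must lie strictly in (0, 1) for PD rows (`NA` allowed
#'   for HC, whose scores do not depend on NAT).
#' @param config the [CohortConfig-class].
#' @return `data.frame` with one row per participant: `participant`
#'   plus one column per test of [testDirections()].
#' @export
generateBehavior <- function(profiles, natGlobal, config) {
    stopifnot(is(config, "CohortConfig"))
    n <- nrow(profiles)
    natGlobal <- rep_len(natGlobal, n)
    pd <- profiles$group == "PD"
    bad <- pd & (!is.finite(natGlobal) | natGlobal <= 0 | natGlobal >= 1)
    if (any(bad))
        stop("natGlobal must lie strictly in (0, 1) for PD participants: ",
             paste(profiles$id[bad], collapse = ", "))
    motor <- rnorm(n, 0, config@noiseSd)
    motor[pd] <- motor[pd] + config@gmpIntercept +
        config@natToGMPSlope * natGlobal[pd] +
        config@paModerationSlope * natGlobal[pd] *
            pmin(profiles$pa[pd], config@paModerationKnot)
    cognitive <- rnorm(n, ifelse(pd, -0.1, 0), config@noiseSd)

    dirs <- testDirections()
    out <- data.frame(participant = profiles$id,
                      stringsAsFactors = FALSE)
    for (j in seq_len(nrow(dirs))) {
        sc <- .TEST_SCALE[.TEST_SCALE$test == dirs$test[j], ]
        ability <- if (dirs$domain[j] == "motor") motor else cognitive
        sign <- if (dirs$direction[j] == "lower_better") -1 else 1
        out[[dirs$test[j]]] <- sc$mu + sign * sc$sigma * ability +
            rnorm(n, 0, sc$sigma * config@noiseSd)
    }
    out
}

.PERIODS <- data.frame(
    period = c("12-19", "19-35", "35-50", "50+"),
    span = c(7, 16, 15, 20),
    stringsAsFactors = FALSE)

#' Generate activity diaries consistent with the drawn PA
#'
#' Writes one long-format diary per participant. The two periods that
#' enter lifetime PA (19-35 and 35-50 years) each carry one activity
#' spanning the whole period all year round, with weekly hours chosen so
#' that the period's weekly energy expenditure equals the participant's
#' drawn `pa` exactly; the 12-19 and 50+ periods carry filler activities
#' that the lifetime-PA definition excludes.
#'
#' @param profiles cohort table ([generateCohort()]).
#' @param config the [CohortConfig-class].
#' @return Long `data.frame`: `participant`, `period`, `activity`,
#'   `met`, `years`, `monthsPerYear`, `hoursPerWeek`.
#' @export
generateDiaries <- function(profiles, config) {
    stopifnot(is(config, "CohortConfig"))
    mets <- c(cycling = 6, swimming = 8, jogging = 7, hiking = 4.5)
    rows <- lapply(seq_len(nrow(profiles)), function(i) {
        p <- profiles[i, ]
        act <- sample(names(mets), 2, replace = TRUE)
        data.frame(
            participant = p$id,
            period = c("12-19", "19-35", "35-50", "50+"),
            activity = c("school sports", act, "walking"),
            met = c(5, mets[act], 3.3),
            years = c(5, 16, 15, 4),
            monthsPerYear = c(9, 12, 12, 6),
            hoursPerWeek = c(2, p$pa / mets[act[1]],
                             p$pa / mets[act[2]], 1.5),
            stringsAsFactors = FALSE, row.names = NULL)
    })
    do.call(rbind, rows)
}
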