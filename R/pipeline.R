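#' Pipeline run configuration
#'
#' Collects everything an end-to-end run needs: the synthetic-cohort
#' configuration (or the promise of user-supplied matrices), the atlas,
#' the density grid, the networks to analyze, attack and composite
#' modes, the significance level and the master seed. The seed
#' overrides the cohort configuration's own seed so one integer
#' reproduces the whole run.
#'
#' @param cohort a [CohortConfig-class].
#' @param atlas an [ROIAtlas-class].
#' @param densities density grid, each in (0, 1].
#' @param networks subset of `c("global", "SMN", "DMN", "FPN", "ATN")`.
#'   Behavior generation is driven by global mean NAT when `"global"`
#'   is analyzed, otherwise by the first listed network.
#' @param attackMode `"adaptive"` or `"static"` degree ranking.
#' @param rank `"signed"` or `"absolute"` edge ranking.
#' @param compositeMode `"sum"` or `"mean"` composite scoring.
#' @param alpha significance level for the Johnson-Neyman regions.
#' @param seed master integer seed.
#' @return A classed list (`"RunConfig"`).
#' @export
runConfig <- function(cohort = cohortConfig(),
                      atlas = syntheticAtlas(),
                      densities = natDensities(),
                      networks = c("global", "SMN", "DMN", "FPN", "ATN"),
                      attackMode = c("adaptive", "static"),
                      rank = c("signed", "absolute"),
                      compositeMode = c("sum", "mean"),
                      alpha = 0.05, seed = 1) {
    stopifnot(is(cohort, "CohortConfig"), is(atlas, "ROIAtlas"),
              all(densities > 0 & densities <= 1),
              all(networks %in% .NETWORK_CHOICES),
              length(networks) > 0,
              alpha > 0, alpha < 1)
    cohort@seed <- as.integer(seed)
    structure(list(cohort = cohort, atlas = atlas,
                   densities = densities, networks = networks,
                   attackMode = match.arg(attackMode),
                   rank = match.arg(rank),
                   compositeMode = match.arg(compositeMode),
                   alpha = alpha, seed = as.integer(seed)),
              class = "RunConfig")
}

.hash_config <- function(config) {
    f <- tempfile()
    on.exit(unlink(f))
    writeLines(deparse(config[setdiff(names(config), "atlas")]), f)
    unname(tools::md5sum(f))
}

#' Run the full NAT analysis pipeline
#'
#' Orchestrates synthesize -> connectomes -> NAT -> scores ->
#' statistics. Stages are independently seeded from the master seed, so
#' a run is reproducible end to end and feeding back the matrices of a
#' previous run (skipping synthesis) yields identical downstream
#' results.
#'
#' Stages: (1) draw the cohort and activity diaries, recomputing
#' lifetime PA from the diaries; (2) simulate each participant's ROI
#' time series, record the scan's temporal SNR and build the Fisher-z
#' connectivity matrix; (3) threshold each PD participant's networks
#' across the density sweep, attack, and score NAT; (4) generate test
#' batteries (PD motor scores driven by realized global mean NAT) and
#' compute HC-referenced composites; (5) fit the per-network beta
#' GLMMs, the GMP/GCP moderation models and the Johnson-Neyman regions.
#'
#' @param config a [runConfig()] object.
#' @param matrices optional named list of [ConnectivityMatrix-class]
#'   per participant; skips time-series synthesis (requires `cohort`).
#' @param cohort optional precomputed cohort table.
#' @param diaries optional precomputed diary table.
#' @return A classed list (`"ResultsBundle"`) with elements `cohort`,
#'   `diaries`, `tsnr`, `matrices`, `natTable`, `natMeans`, `battery`,
#'   `composites`, `glmmFits`, `moderationGMP`, `moderationGCP`,
#'   `jnRegions`, `provenance`.
#' @export
runPipeline <- function(config = runConfig(), matrices = NULL,
                        cohort = NULL, diaries = NULL) {
    stopifnot(inherits(config, "RunConfig"))
    ccfg <- config$cohort
    t0 <- Sys.time()

    if (is.null(cohort)) cohort <- generateCohort(ccfg)
    if (is.null(diaries)) {
        set.seed(config$seed + 1L)
        diaries <- generateDiaries(cohort, ccfg)
    }
    pa <- diaryPA(diaries)
    cohort$pa <- pa$pa[match(cohort$id, pa$participant)]
    message(sprintf("[cohort] %d participants (%d PD), %d diary rows",
                    nrow(cohort), sum(cohort$group == "PD"),
                    nrow(diaries)))

    tsnr <- data.frame(participant = cohort$id,
                       sequence = cohort$sequence, tsnr = NA_real_)
    if (is.null(matrices)) {
        set.seed(config$seed + 2L)
        matrices <- vector("list", nrow(cohort))
        names(matrices) <- cohort$id
        for (i in seq_len(nrow(cohort))) {
            ts <- generateTimeseries(cohort[i, ], config$atlas, ccfg)
            tsnr$tsnr[i] <- scanTSNR(ts)
            matrices[[i]] <- fisherConnectivity(ts, config$atlas)
        }
        message(sprintf("[connectome] %d matrices of %d ROIs; mean tSNR %.1f",
                        length(matrices), length(config$atlas@roi),
                        mean(tsnr$tsnr)))
    }

    pdIds <- cohort$id[cohort$group == "PD"]
    natTab <- natTable(matrices[pdIds], networks = config$networks,
                       densities = config$densities,
                       mode = config$attackMode, rank = config$rank)
    natMeans <- meanNAT(natTab, densities = config$densities)
    message(sprintf("[attack] %d NAT records (%d participants x %d networks x %d densities)",
                    nrow(natTab), length(pdIds),
                    length(config$networks), length(config$densities)))

    set.seed(config$seed + 3L)
    driver <- if ("global" %in% config$networks) "global"
              else config$networks[1]
    gl <- natMeans[natMeans$network == driver, ]
    natGlobal <- gl$natMean[match(cohort$id, gl$participant)]
    battery <- generateBehavior(cohort, natGlobal, ccfg)
    composites <- compositeScores(
        battery[cohort$group == "PD", , drop = FALSE],
        battery[cohort$group == "HC", , drop = FALSE],
        mode = config$compositeMode)

    modData <- merge(merge(natMeans, composites, by = "participant"),
                     cohort, by.x = "participant", by.y = "id")
    glmmFits <- list()
    moderationGMP <- list()
    moderationGCP <- list()
    jnRegions <- list()
    for (net in config$networks) {
        glmmFits[[net]] <- fitNATModel(natTab, cohort, network = net)
        dnet <- modData[modData$network == net, , drop = FALSE]
        moderationGMP[[net]] <- fitModeration(dnet, "gmp",
                                              network = net)
        moderationGCP[[net]] <- fitModeration(dnet, "gcp",
                                              network = net)
        jnRegions[[net]] <- johnsonNeyman(moderationGMP[[net]],
                                          alpha = config$alpha)
    }
    message(sprintf("[stats] %d networks fitted in %.1f s",
                    length(config$networks),
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))

    structure(list(
        config = config, cohort = cohort, diaries = diaries,
        tsnr = tsnr, matrices = matrices, natTable = natTab,
        natMeans = natMeans, battery = battery, composites = composites,
        glmmFits = glmmFits, moderationGMP = moderationGMP,
        moderationGCP = moderationGCP, jnRegions = jnRegions,
        provenance = list(seed = config$seed,
                          configHash = .hash_config(config),
                          packageVersion =
                              as.character(utils::packageVersion("brainNAT")),
                          timestamp = format(t0, tz = "UTC"))),
        class = "ResultsBundle")
}

#' Sequence-restricted sensitivity analysis
#'
#' Refits every statistical model of a results bundle on the subgroup
#' of PD participants scanned with one fMRI sequence, dropping the
#' sequence contrasts from the designs (they are constant within the
#' subgroup).
#'
#' @param bundle a [runPipeline()] results bundle.
#' @param sequence the fMRI sequence id defining the subgroup.
#' @return A list with the subgroup `natTable`, `glmmFits`,
#'   `moderationGMP`, `moderationGCP` and `jnRegions`.
#' @export
sensitivitySubgroup <- function(bundle, sequence = 2) {
    stopifnot(inherits(bundle, "ResultsBundle"))
    cohort <- bundle$cohort
    ids <- cohort$id[cohort$group == "PD" & cohort$sequence == sequence]
    if (!length(ids))
        stop("no PD participants scanned with sequence ", sequence)
    natTab <- bundle$natTable[bundle$natTable$participant %in% ids, ]
    nCoef <- 8  # intercept + nat + moderator + interaction + 4 controls
    if (length(ids) <= nCoef)
        stop("subgroup of ", length(ids),
             " participants is too small for the moderation design (",
             nCoef, " coefficients)")
    modData <- merge(merge(bundle$natMeans, bundle$composites,
                           by = "participant"),
                     cohort, by.x = "participant", by.y = "id")
    modData <- modData[modData$participant %in% ids, , drop = FALSE]
    out <- list(sequence = sequence, participants = ids,
                natTable = natTab, glmmFits = list(),
                moderationGMP = list(), moderationGCP = list(),
                jnRegions = list())
    for (net in bundle$config$networks) {
        out$glmmFits[[net]] <- fitNATModel(natTab, cohort,
                                           network = net,
                                           sequenceTerm = FALSE)
        dnet <- modData[modData$network == net, , drop = FALSE]
        out$moderationGMP[[net]] <- fitModeration(dnet, "gmp",
                                                  network = net,
                                                  sequenceTerm = FALSE)
        out$moderationGCP[[net]] <- fitModeration(dnet, "gcp",
                                                  network = net,
                                                  sequenceTerm = FALSE)
        out$jnRegions[[net]] <- johnsonNeyman(out$moderationGMP[[net]],
                                              alpha = bundle$config$alpha)
    }
    out
}

#' Write a results bundle as tab-separated tables
#'
#' Writes the long tables (cohort, diaries, tSNR, NAT records, NAT
#' means, battery, composites), the per-network GLMM and moderation
#' coefficient tables, the Johnson-Neyman regions and a provenance
#' block to plain TSV files under `dir`.
#'
#' @param bundle a [runPipeline()] results bundle.
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
writeBundle <- function(bundle, dir) {
    stopifnot(inherits(bundle, "ResultsBundle"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    tsv <- function(d, name) {
        p <- file.path(dir, name)
        write.table(d, p, sep = "\t", quote = FALSE, row.names = FALSE)
        p
    }
    paths <- c(
        tsv(bundle$cohort, "cohort.tsv"),
        tsv(bundle$diaries, "diaries.tsv"),
        tsv(bundle$tsnr, "tsnr.tsv"),
        tsv(bundle$natTable, "nat_records.tsv"),
        tsv(bundle$natMeans, "nat_means.tsv"),
        tsv(bundle$battery, "battery.tsv"),
        tsv(bundle$composites, "composites.tsv"))
    stack <- function(fits, fun)
        do.call(rbind, lapply(names(fits), function(net)
            cbind(network = net, fun(fits[[net]]))))
    paths <- c(paths,
        tsv(stack(bundle$glmmFits, function(f) f@coefficients),
            "glmm_coefficients.tsv"),
        tsv(stack(bundle$moderationGMP, moderationTable),
            "moderation_gmp.tsv"),
        tsv(stack(bundle$moderationGCP, moderationTable),
            "moderation_gcp.tsv"))
    jn <- do.call(rbind, lapply(names(bundle$jnRegions), function(net) {
        r <- bundle$jnRegions[[net]]
        if (nrow(r@regions))
            cbind(network = net, r@regions, status = r@status)
        else data.frame(network = net, lower = NA, upper = NA,
                        direction = NA, status = r@status)
    }))
    paths <- c(paths, tsv(jn, "jn_regions.tsv"))
    prov <- data.frame(key = names(bundle$provenance),
                       value = unlist(bundle$provenance))
    paths <- c(paths, tsv(prov, "provenance.tsv"))
    invisible(paths)
}
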