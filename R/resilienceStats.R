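#' Beta mixed-model fit for NAT
#'
#' @slot coefficients coefficient table (`term`, `estimate`, `se`,
#'   `ciLow`, `ciHigh`, `p`).
#' @slot pseudoR2 squared correlation between observed and fitted NAT.
#' @slot converged logical convergence flag.
#' @slot nObs number of observations consumed.
#' @slot network network the model was fit for.
#' @slot model the underlying `glmmTMB` fit.
#' @export
setClass("NATModelFit",
    representation(coefficients = "data.frame", pseudoR2 = "numeric",
                   converged = "logical", nObs = "integer",
                   network = "character", model = "ANY"))

#' Linear moderation-model fit
#'
#' @slot model the underlying `lm` fit.
#' @slot outcome outcome label (`"gmp"` or `"gcp"`).
#' @slot network network whose mean NAT entered the model.
#' @slot natTerm,modTerm,intTerm names of the NAT, moderator and
#'   interaction coefficients in the design.
#' @slot fstat overall model F statistic `(value, df1, df2)`.
#' @slot fp overall model p-value.
#' @slot nObs complete cases used.
#' @export
setClass("ModerationFit",
    representation(model = "ANY", outcome = "character",
                   network = "character", natTerm = "character",
                   modTerm = "character", intTerm = "character",
                   fstat = "numeric", fp = "numeric", nObs = "integer"))

#' Johnson-Neyman significance region
#'
#' @slot boundaries moderator values where the conditional-effect t
#'   statistic equals the critical value (possibly empty).
#' @slot regions `data.frame` of significant moderator intervals
#'   (`lower`, `upper`, `direction`), clipped to the observed range.
#' @slot status `"boundary"`, `"everywhere"` or `"nowhere"`.
#' @slot alpha significance level.
#' @slot tCrit critical t value at `df` residual degrees of freedom.
#' @slot df residual degrees of freedom.
#' @slot range observed moderator range used for clipping.
#' @slot grid conditional NAT effect, its SE and t over a moderator
#'   grid (for plotting).
#' @export
setClass("JNRegion",
    representation(boundaries = "numeric", regions = "data.frame",
                   status = "character", alpha = "numeric",
                   tCrit = "numeric", df = "numeric", range = "numeric",
                   grid = "data.frame"))

setMethod("show", "NATModelFit", function(object) {
    cat(sprintf("NATModelFit [%s]: beta GLMM (logit link), %d obs, pseudo-R2 %.2f%s\n",
                object@network, object@nObs, object@pseudoR2,
                if (object@converged) "" else " [NOT CONVERGED]"))
    print(object@coefficients, digits = 3, row.names = FALSE)
})

setMethod("show", "ModerationFit", function(object) {
    cat(sprintf("ModerationFit [%s -> %s]: n=%d, F(%g,%g)=%.2f, p=%.4g\n",
                object@network, toupper(object@outcome), object@nObs,
                object@fstat[2], object@fstat[3], object@fstat[1],
                object@fp))
})

setMethod("show", "JNRegion", function(object) {
    cat(sprintf("JNRegion (alpha=%.2f, df=%g): %s\n", object@alpha,
                object@df, object@status))
    if (nrow(object@regions)) print(object@regions, row.names = FALSE)
})

#' Fit the beta mixed model for NAT
#'
#' Fits a generalized linear mixed model with a beta response
#' distribution and logit link to the NAT long table of one network:
#' fixed effects for putaminal DaT, physical activity, education, age,
#' sex (female reference), network density (continuous) and fMRI
#' sequence (level 1 reference, two contrasts) — eight slopes — plus a
#' random intercept per participant. Responses touching 0 or 1 are
#' nudged into the open interval with a warning.
#'
#' @param records NAT long table ([natTable()]).
#' @param cohort cohort covariate table ([generateCohort()] layout).
#' @param network which network's records to model.
#' @param sequenceTerm include the two sequence contrasts (drop for a
#'   single-sequence subgroup).
#' @param eps nudge margin for boundary responses.
#' @return A [NATModelFit-class].
#' @export
fitNATModel <- function(records, cohort, network = "SMN",
                        sequenceTerm = TRUE, eps = 1e-6) {
    network <- match.arg(network, .NETWORK_CHOICES)
    d <- records[records$network == network, , drop = FALSE]
    if (!nrow(d)) stop("no records for network ", network)
    d <- merge(d, cohort, by.x = "participant", by.y = "id")
    if (min(table(d$participant)) < 2)
        stop("need at least 2 observations per participant")
    if (any(d$nat <= 0 | d$nat >= 1)) {
        warning("NAT values touching 0/1 nudged into (",
                eps, ", ", 1 - eps, ")")
        d$nat <- pmin(pmax(d$nat, eps), 1 - eps)
    }
    d$sex <- factor(d$sex, levels = c("f", "m"))
    d$sequence <- factor(d$sequence)
    d$participant <- factor(d$participant)
    rhs <- "putaminalDaT + pa + education + age + sex + density"
    if (sequenceTerm) rhs <- paste(rhs, "+ sequence")
    form <- as.formula(paste("nat ~", rhs, "+ (1 | participant)"))
    fit <- glmmTMB::glmmTMB(form, data = d,
                            family = glmmTMB::beta_family())
    sm <- summary(fit)$coefficients$cond
    ci <- confint(fit, parm = "beta_", estimate = FALSE)
    tab <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                      se = sm[, "Std. Error"], ciLow = ci[, 1],
                      ciHigh = ci[, 2], p = sm[, "Pr(>|z|)"],
                      row.names = NULL, stringsAsFactors = FALSE)
    converged <- isTRUE(fit$fit$convergence == 0) &&
        isTRUE(fit$sdr$pdHess)
    if (!converged)
        warning("beta GLMM did not converge for network ", network)
    new("NATModelFit", coefficients = tab,
        pseudoR2 = cor(d$nat, fitted(fit))^2,
        converged = converged, nObs = nrow(d), network = network,
        model = fit)
}

#' Fit a linear moderation model for behavior
#'
#' Ordinary least squares predicting a composite performance score from
#' a network's mean NAT, a moderator, their interaction, and controls
#' (the other reserve proxy, putaminal DaT, age, sex and the fMRI
#' sequence contrasts). The motor model (GMP) uses physical activity as
#' moderator and education as control; the cognitive model (GCP) uses
#' education as moderator and physical activity as control. Only
#' complete cases enter. A rank-deficient design (e.g. a constant
#' moderator) is an error naming the collinear columns.
#'
#' @param data one row per participant with columns `natMean`, the
#'   outcome, `pa`, `education`, `putaminalDaT`, `age`, `sex`,
#'   `sequence`.
#' @param outcome `"gmp"` or `"gcp"`.
#' @param moderator moderating variable; defaults to `"pa"` for GMP and
#'   `"education"` for GCP.
#' @param network label carried through to the fit object.
#' @param sequenceTerm include the sequence contrasts.
#' @return A [ModerationFit-class].
#' @export
fitModeration <- function(data, outcome = c("gmp", "gcp"),
                          moderator = NULL, network = "global",
                          sequenceTerm = TRUE) {
    outcome <- match.arg(outcome)
    if (is.null(moderator))
        moderator <- if (outcome == "gmp") "pa" else "education"
    control <- setdiff(c("pa", "education"), moderator)
    vars <- c(outcome, "natMean", moderator, control, "putaminalDaT",
              "age", "sex", if (sequenceTerm) "sequence")
    stopifnot(all(vars %in% names(data)))
    d <- data[complete.cases(data[, vars]), vars, drop = FALSE]
    d$sex <- factor(d$sex, levels = c("f", "m"))
    if (sequenceTerm) d$sequence <- factor(d$sequence)
    rhs <- paste(c(paste0("natMean * ", moderator), control,
                   "putaminalDaT", "age", "sex",
                   if (sequenceTerm) "sequence"), collapse = " + ")
    form <- as.formula(paste(outcome, "~", rhs))
    mm <- model.matrix(form, d)
    qrd <- qr(mm)
    if (qrd$rank < ncol(mm)) {
        dropped <- colnames(mm)[qrd$pivot[(qrd$rank + 1):ncol(mm)]]
        stop("rank-deficient moderation design; collinear column(s): ",
             paste(dropped, collapse = ", "))
    }
    fit <- lm(form, data = d)
    fs <- summary(fit)$fstatistic
    new("ModerationFit", model = fit, outcome = outcome,
        network = network, natTerm = "natMean", modTerm = moderator,
        intTerm = paste0("natMean:", moderator),
        fstat = unname(fs),
        fp = unname(pf(fs[1], fs[2], fs[3], lower.tail = FALSE)),
        nObs = nrow(d))
}

#' Coefficient table of a moderation fit
#'
#' @param fit a [ModerationFit-class].
#' @return `data.frame` with `term`, `estimate`, `ciLow`, `ciHigh`, `p`.
#' @export
moderationTable <- function(fit) {
    stopifnot(is(fit, "ModerationFit"))
    sm <- summary(fit@model)$coefficients
    ci <- confint(fit@model)
    data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
               se = sm[, "Std. Error"], ciLow = ci[, 1],
               ciHigh = ci[, 2], p = sm[, "Pr(>|t|)"],
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Johnson-Neyman regions of moderator significance
#'
#' For a fitted moderation model the conditional effect of NAT at
#' moderator value `w` is `b1 + b3 w` with standard error
#' `sqrt(V11 + w^2 V33 + 2 w V13)`. Boundaries solve
#' `|effect / SE| = t(1 - alpha/2, df)` analytically (a quadratic in
#' `w`); the returned significance regions are clipped to the observed
#' moderator range. If no boundary falls in range the region is
#' `"everywhere"` or `"nowhere"`.
#'
#' @param fit a [ModerationFit-class].
#' @param alpha significance level (default 0.05).
#' @param range moderator interval to report over; defaults to the
#'   observed range in the fitting data.
#' @param gridLength number of grid points stored for plotting.
#' @return A [JNRegion-class].
#' @export
johnsonNeyman <- function(fit, alpha = 0.05, range = NULL,
                          gridLength = 101) {
    stopifnot(is(fit, "ModerationFit"))
    cf <- coef(fit@model)
    V <- vcov(fit@model)
    ints <- intersect(c(fit@intTerm,
                        paste0(fit@modTerm, ":", fit@natTerm)),
                      names(cf))
    if (!length(ints)) stop("fit carries no NAT x moderator interaction")
    b1 <- cf[[fit@natTerm]]
    b3 <- cf[[ints[1]]]
    v11 <- V[fit@natTerm, fit@natTerm]
    v33 <- V[ints[1], ints[1]]
    v13 <- V[fit@natTerm, ints[1]]
    df <- fit@model$df.residual
    tc <- qt(1 - alpha / 2, df)
    if (is.null(range))
        range <- base::range(fit@model$model[[fit@modTerm]])

    eff <- function(w) b1 + b3 * w
    se <- function(w) sqrt(v11 + w^2 * v33 + 2 * w * v13)
    tval <- function(w) eff(w) / se(w)

    A <- b3^2 - tc^2 * v33
    B <- 2 * (b1 * b3 - tc^2 * v13)
    C <- b1^2 - tc^2 * v11
    roots <- numeric(0)
    if (abs(A) > 1e-300) {
        disc <- B^2 - 4 * A * C
        if (disc >= 0)
            roots <- sort((-B + c(-1, 1) * sqrt(disc)) / (2 * A))
    } else if (abs(B) > 1e-300) {
        roots <- -C / B
    }
    inRange <- roots[roots > range[1] & roots < range[2]]

    edges <- sort(unique(c(range, inRange)))
    mids <- (head(edges, -1) + edges[-1]) / 2
    sig <- abs(tval(mids)) > tc
    regions <- data.frame(lower = head(edges, -1), upper = edges[-1],
                          direction = ifelse(eff(mids) > 0,
                                             "positive", "negative"),
                          stringsAsFactors = FALSE)[sig, , drop = FALSE]
    rownames(regions) <- NULL
    status <- if (length(inRange)) "boundary"
              else if (all(sig)) "everywhere" else "nowhere"

    w <- seq(range[1], range[2], length.out = gridLength)
    grid <- data.frame(moderator = w, effect = eff(w), se = se(w),
                       t = tval(w),
                       p = 2 * pt(abs(tval(w)), df, lower.tail = FALSE))
    new("JNRegion", boundaries = inRange, regions = regions,
        status = status, alpha = alpha, tCrit = tc, df = df,
        range = range, grid = grid)
}
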