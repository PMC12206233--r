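#' Weekly energy expenditure of one life period
#'
#' Evaluates, for all activities of one period,
#' `WEE = sum_i years_i * months_i * weeklyHours_i / (12 * yearsPeriod)
#'        * MET_i`
#' — MET-weighted average weekly activity hours over the period. An
#' empty activity list yields 0.
#'
#' @param entries `data.frame` with columns `met`, `years`,
#'   `monthsPerYear`, `hoursPerWeek` (one row per activity).
#' @param yearsPeriod span of the period in years (> 0).
#' @return Weekly energy expenditure (MET-hours/week).
#' @examples
#' periodWEE(data.frame(met = 8, years = 16, monthsPerYear = 12,
#'                      hoursPerWeek = 2), yearsPeriod = 16)  # 16
#' @export
periodWEE <- function(entries, yearsPeriod) {
    if (!is.numeric(yearsPeriod) || yearsPeriod <= 0)
        stop("yearsPeriod must be > 0")
    if (is.null(entries) || nrow(entries) == 0) return(0)
    need <- c("met", "years", "monthsPerYear", "hoursPerWeek")
    stopifnot(all(need %in% names(entries)))
    if (any(entries[need] < 0))
        stop("activity quantities must be nonnegative")
    if (any(entries$monthsPerYear > 12))
        stop("monthsPerYear cannot exceed 12")
    if (any(entries$years > yearsPeriod))
        stop("years active cannot exceed the period span")
    sum(entries$years * entries$monthsPerYear * entries$hoursPerWeek /
            (12 * yearsPeriod) * entries$met)
}

#' Lifetime physical activity
#'
#' Lifetime PA is the mean of the weekly energy expenditure of the
#' 19-35 and 35-50 year periods; the 12-19 and 50+ periods never enter.
#'
#' @param wee1935 WEE of the 19-35 year period.
#' @param wee3550 WEE of the 35-50 year period.
#' @return Lifetime PA in WEE units.
#' @seealso [diaryPA()] to evaluate a long-format diary table.
#' @export
lifetimePA <- function(wee1935, wee3550) {
    if (missing(wee1935) || missing(wee3550) ||
        is.na(wee1935) || is.na(wee3550))
        stop("both the 19-35 and 35-50 period WEE values are required")
    (wee1935 + wee3550) / 2
}

#' Per-participant WEE and lifetime PA from an activity diary
#'
#' `diaryWEE` evaluates the period formula for every participant and
#' period present in a long diary table; `diaryPA` reduces that to the
#' lifetime PA (mean of the 19-35 and 35-50 periods, which must both be
#' present).
#'
#' @param diary long `data.frame` with columns `participant`, `period`
#'   (one of `"12-19"`, `"19-35"`, `"35-50"`, `"50+"`), `met`, `years`,
#'   `monthsPerYear`, `hoursPerWeek`.
#' @return `diaryWEE`: `data.frame` with `participant`, `period`,
#'   `wee`; `diaryPA`: `data.frame` with `participant`, `pa`.
#' @export
diaryWEE <- function(diary) {
    stopifnot(all(c("participant", "period") %in% names(diary)))
    bad <- setdiff(unique(diary$period), .PERIODS$period)
    if (length(bad))
        stop("unknown period(s): ", paste(bad, collapse = ", "))
    cells <- unique(diary[, c("participant", "period")])
    cells$wee <- mapply(function(p, per) {
        periodWEE(diary[diary$participant == p & diary$period == per, ],
                  .PERIODS$span[.PERIODS$period == per])
    }, cells$participant, cells$period)
    rownames(cells) <- NULL
    cells
}

#' @rdname diaryWEE
#' @export
diaryPA <- function(diary) {
    wee <- diaryWEE(diary)
    ids <- sort(unique(wee$participant))
    pa <- vapply(ids, function(p) {
        w1 <- wee$wee[wee$participant == p & wee$period == "19-35"]
        w2 <- wee$wee[wee$participant == p & wee$period == "35-50"]
        if (!length(w1) || !length(w2))
            stop("participant ", p,
                 " is missing a 19-35 or 35-50 period diary")
        lifetimePA(w1, w2)
    }, numeric(1))
    data.frame(participant = ids, pa = unname(pa),
               stringsAsFactors = FALSE)
}

#' Composite motor and cognitive performance scores
#'
#' z-standardizes every PD participant's test scores against the
#' healthy-control reference (unbiased HC standard deviation), after
#' negating the raw scores of `lower_better` (duration) tests so that
#' larger always means better. Per-domain z-scores are combined into the
#' general motor performance (GMP) and general cognitive performance
#' (GCP) composites — by summation by default, or averaging with
#' `mode = "mean"`. Tests with zero HC variance are excluded with a
#' warning.
#'
#' @param pdBattery,hcBattery wide test tables ([generateBehavior()]
#'   layout): column `participant` plus one column per test.
#' @param directions direction-flag table, see [testDirections()].
#' @param mode combine z-scores by `"sum"` (default) or `"mean"`.
#' @return `data.frame`: `participant`, `gmp`, `gcp`, and one `z.<test>`
#'   column per retained test.
#' @export
compositeScores <- function(pdBattery, hcBattery,
                            directions = testDirections(),
                            mode = c("sum", "mean")) {
    mode <- match.arg(mode)
    stopifnot(nrow(hcBattery) > 0)
    tests <- directions$test[directions$test %in% names(pdBattery)]
    if (!length(tests)) stop("no known test columns found")
    z <- matrix(NA_real_, nrow(pdBattery), length(tests),
                dimnames = list(NULL, tests))
    keep <- logical(length(tests))
    for (j in seq_along(tests)) {
        tst <- tests[j]
        sgn <- if (directions$direction[directions$test == tst] ==
                   "lower_better") -1 else 1
        ref <- sgn * hcBattery[[tst]]
        m <- mean(ref, na.rm = TRUE)
        s <- sd(ref, na.rm = TRUE)
        if (!is.finite(s) || s == 0) {
            warning("test '", tst,
                    "' has zero HC variance; excluded from composites")
            next
        }
        keep[j] <- TRUE
        z[, j] <- (sgn * pdBattery[[tst]] - m) / s
    }
    z <- z[, keep, drop = FALSE]
    combine <- function(domain) {
        cols <- intersect(colnames(z),
                          directions$test[directions$domain == domain])
        if (!length(cols)) return(rep(NA_real_, nrow(z)))
        v <- rowSums(z[, cols, drop = FALSE])
        if (mode == "mean") v <- v / length(cols)
        v
    }
    out <- data.frame(participant = pdBattery$participant,
                      gmp = combine("motor"), gcp = combine("cognitive"),
                      stringsAsFactors = FALSE)
    zd <- as.data.frame(z)
    names(zd) <- paste0("z.", names(zd))
    cbind(out, zd)
}
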