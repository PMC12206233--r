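.check_binary_adjacency <- function(a) {
    if (!is.matrix(a) || nrow(a) != ncol(a))
        stop("adjacency must be a square matrix")
    if (!all(a %in% c(0, 1)))
        stop("graph must be binary (0/1 adjacency); weighted input rejected")
    if (any(a != t(a)))
        stop("graph must be undirected (symmetric adjacency)")
    if (any(diag(a) != 0))
        stop("self-loops are not allowed")
    storage.mode(a) <- "integer"
    a
}

#' @rdname globalEfficiency
setMethod("globalEfficiency", "ThresholdedGraph",
    function(x) .global_efficiency_engine(x@adjacency))

#' @rdname globalEfficiency
setMethod("globalEfficiency", "matrix",
    function(x) .global_efficiency_engine(.check_binary_adjacency(x)))

.targeted_attack <- function(a, mode, network, density) {
    n <- nrow(a)
    if (n == 0)
        return(new("AttackCurve", ge = numeric(0), order = character(0),
                   network = network, density = density))
    res <- .attack_curve_engine(a, mode == "adaptive")
    labels <- rownames(a)
    if (is.null(labels)) labels <- as.character(seq_len(n))
    new("AttackCurve", ge = pmin(pmax(res$ge, 0), 1),
        order = labels[res$order], network = network, density = density)
}

#' @rdname targetedAttack
setMethod("targetedAttack", "ThresholdedGraph",
    function(x, mode = c("adaptive", "static")) {
        mode <- match.arg(mode)
        .targeted_attack(x@adjacency, mode, x@network, x@density)
    })

#' @rdname targetedAttack
setMethod("targetedAttack", "matrix",
    function(x, mode = c("adaptive", "static")) {
        mode <- match.arg(mode)
        .targeted_attack(.check_binary_adjacency(x), mode, "graph",
                         NA_real_)
    })

#' @rdname natScore
setMethod("natScore", "AttackCurve", function(x) {
    if (!length(x@ge)) stop("empty attack curve")
    mean(x@ge)
})

#' @rdname natScore
setMethod("natScore", "numeric", function(x) {
    if (!length(x)) stop("empty attack curve")
    mean(x)
})

#' NAT long table over participants, networks and densities
#'
#' For every participant's connectivity matrix, extracts each requested
#' network's own submatrix, thresholds it across the density sweep,
#' attacks each binarized graph and scores the curve. One row per
#' participant x network x density: 22 participants and one network at
#' the nine-density sweep give 198 rows.
#'
#' @param matrices named list of [ConnectivityMatrix-class], one per
#'   participant (names are participant ids). `NULL` entries are skipped
#'   with a warning.
#' @param networks networks to analyze (default all five).
#' @param densities density grid (default the nine-density sweep).
#' @param mode attack mode, see [targetedAttack()].
#' @param rank edge ranking rule, see [proportionalThreshold()].
#' @return `data.frame` with columns `participant`, `network`,
#'   `density`, `nat`.
#' @export
natTable <- function(matrices, networks = .NETWORK_CHOICES,
                     densities = natDensities(),
                     mode = c("adaptive", "static"),
                     rank = c("signed", "absolute")) {
    mode <- match.arg(mode)
    rank <- match.arg(rank)
    networks <- match.arg(networks, .NETWORK_CHOICES, several.ok = TRUE)
    ids <- names(matrices)
    if (is.null(ids)) ids <- as.character(seq_along(matrices))
    missing <- vapply(matrices, is.null, logical(1))
    if (any(missing)) {
        warning("missing connectivity matrix for participant(s): ",
                paste(ids[missing], collapse = ", "), "; skipped")
        matrices <- matrices[!missing]
        ids <- ids[!missing]
    }
    rows <- vector("list", length(matrices))
    for (p in seq_along(matrices)) {
        cm <- matrices[[p]]
        nat <- unlist(lapply(networks, function(net) {
            sub <- extractSubnetwork(cm, net)
            vapply(densitySweep(sub, densities, rank = rank),
                   function(g) natScore(targetedAttack(g, mode = mode)),
                   numeric(1))
        }))
        rows[[p]] <- data.frame(
            participant = ids[p],
            network = rep(networks, each = length(densities)),
            density = rep(densities, times = length(networks)),
            nat = nat, stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Mean NAT across the density sweep
#'
#' Collapses the NAT long table to one value per participant and
#' network — the arithmetic mean across all densities — the input
#' variable of the moderation models. Each participant x network cell
#' must carry exactly one record per density of the sweep.
#'
#' @param records NAT long table as produced by [natTable()].
#' @param densities the density grid the records must cover.
#' @return `data.frame` with columns `participant`, `network`,
#'   `natMean`.
#' @export
meanNAT <- function(records, densities = natDensities()) {
    stopifnot(all(c("participant", "network", "density", "nat") %in%
                  names(records)))
    counts <- aggregate(nat ~ participant + network, records, length)
    if (any(counts$nat != length(densities)))
        stop("each participant x network must have exactly ",
             length(densities), " density records")
    out <- aggregate(nat ~ participant + network, records, mean)
    names(out)[names(out) == "nat"] <- "natMean"
    out[order(out$participant, out$network), , drop = FALSE]
}
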