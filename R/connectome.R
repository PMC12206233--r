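#' The nine-density NAT sweep grid
#'
#' Proportional thresholds from 10% to 50% of the strongest edges in 5%
#' increments — nine network densities per network.
#'
#' @return Numeric vector `c(0.10, 0.15, ..., 0.50)`.
#' @export
natDensities <- function() seq(0.10, 0.50, by = 0.05)

#' Synthetic 300-ROI reference atlas
#'
#' Builds an atlas with the reference subnetwork sizes used throughout
#' the package: 51 somatomotor (SMN), 65 default-mode (DMN), 36
#' frontoparietal (FPN) and 27 attention (ATN) ROIs, the remaining ROIs
#' unlabelled. Coordinates are a deterministic synthetic lattice (the
#' pipeline never uses them spatially); `sizes` can be overridden for
#' small test atlases.
#'
#' @param sizes named integer vector of subnetwork sizes; must contain
#'   `SMN`, `DMN`, `FPN`, `ATN`, `none`.
#' @return An [ROIAtlas-class].
#' @examples
#' atlas <- syntheticAtlas()
#' table(networkLabels(atlas))
#' @export
syntheticAtlas <- function(sizes = c(SMN = 51, DMN = 65, FPN = 36,
                                     ATN = 27, none = 121)) {
    stopifnot(all(c("SMN", "DMN", "FPN", "ATN", "none") %in% names(sizes)),
              all(sizes >= 0))
    sizes <- sizes[c("SMN", "DMN", "FPN", "ATN", "none")]
    n <- sum(sizes)
    network <- rep(names(sizes), times = sizes)
    roi <- sprintf("%s_%03d", network, unlist(lapply(sizes, seq_len)))
    # deterministic lattice stand-in for MNI coordinates
    g <- ceiling(n^(1 / 3))
    idx <- seq_len(n) - 1L
    coords <- cbind(x = (idx %% g) * 12 - 66,
                    y = ((idx %/% g) %% g) * 12 - 90,
                    z = (idx %/% (g * g)) * 12 - 60)
    ROIAtlas(roi, network, coords = coords)
}

#' Read / write an ROI atlas as tab-separated text
#'
#' The interchange format is a TSV with columns `roi_id`, `x`, `y`, `z`,
#' `network`.
#'
#' @param file path to a TSV file.
#' @return `readAtlas` returns an [ROIAtlas-class]; `writeAtlas` is
#'   called for its side effect.
#' @examples
#' f <- system.file("extdata", "example_atlas_synthetic.tsv",
#'                  package = "brainNAT")
#' readAtlas(f)
#' @export
readAtlas <- function(file) {
    d <- read.delim(file, stringsAsFactors = FALSE)
    ROIAtlas(d$roi_id, d$network,
             coords = as.matrix(d[, c("x", "y", "z")]))
}

#' @rdname readAtlas
#' @param atlas an [ROIAtlas-class].
#' @export
writeAtlas <- function(atlas, file) {
    co <- if (nrow(atlas@coords)) atlas@coords else
        matrix(NA_real_, length(atlas@roi), 3)
    write.table(data.frame(roi_id = atlas@roi, x = co[, 1], y = co[, 2],
                           z = co[, 3], network = atlas@network),
                file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(file)
}

#' Fisher-z connectivity from ROI time series
#'
#' Computes the bivariate Pearson correlation between every pair of ROI
#' time series and applies the Fisher (arctanh) transform. Correlations
#' are clamped to +/-(1 - 1e-7) beforehand so duplicated series stay
#' finite; the diagonal is forced to zero.
#'
#' @param timeseries numeric matrix, ROIs in rows, time points in
#'   columns (>= 3), row names giving ROI ids.
#' @param atlas optional [ROIAtlas-class] to bind; defaults to a
#'   label-only atlas built from the row names.
#' @return A [ConnectivityMatrix-class].
#' @examples
#' ts <- matrix(rnorm(5 * 100), 5, dimnames = list(paste0("R", 1:5), NULL))
#' fisherConnectivity(ts)
#' @export
fisherConnectivity <- function(timeseries, atlas = NULL) {
    if (ncol(timeseries) < 3)
        stop("need at least 3 time points")
    sds <- apply(timeseries, 1, sd)
    if (any(sds == 0)) {
        ids <- rownames(timeseries)
        if (is.null(ids)) ids <- as.character(which(sds == 0))
        else ids <- ids[sds == 0]
        stop("zero-variance time series for ROI(s): ",
             paste(ids, collapse = ", "))
    }
    r <- cor(t(timeseries))
    clamp <- 1 - 1e-7
    r[r > clamp] <- clamp
    r[r < -clamp] <- -clamp
    z <- atanh(r)
    z <- (z + t(z)) / 2
    diag(z) <- 0
    connectivityMatrix(z, atlas = atlas, network = "global")
}

setMethod("extractSubnetwork", "ConnectivityMatrix",
    function(x, network) {
        network <- match.arg(network, .NETWORK_CHOICES)
        if (network == "global") return(x)
        keep <- which(x@atlas@network == network)
        if (!length(keep))
            stop("network '", network, "' has no member ROIs in the atlas")
        sub <- x@values[keep, keep, drop = FALSE]
        atlas <- ROIAtlas(x@atlas@roi[keep], x@atlas@network[keep],
                          coords = if (nrow(x@atlas@coords))
                              x@atlas@coords[keep, , drop = FALSE] else NULL)
        connectivityMatrix(sub, atlas = atlas, network = network)
    })

.proportional_threshold <- function(values, density, rank, network) {
    if (!is.numeric(density) || length(density) != 1 ||
        is.na(density) || density <= 0 || density > 1)
        stop("density must be a single value in (0, 1]")
    n <- nrow(values)
    ut <- which(upper.tri(values), arr.ind = TRUE)
    w <- values[upper.tri(values)]
    if (rank == "absolute") w <- abs(w)
    k <- floor(density * n * (n - 1) / 2 + 0.5)
    # strongest first; ties at the cut resolved by ascending (row, col)
    keep <- order(-w, ut[, 1], ut[, 2])[seq_len(k)]
    a <- matrix(0L, n, n, dimnames = dimnames(values))
    a[ut[keep, , drop = FALSE]] <- 1L
    a <- a + t(a)
    thresholdedGraph(a, density = density, network = network)
}

#' @rdname proportionalThreshold
setMethod("proportionalThreshold", "ConnectivityMatrix",
    function(x, density, rank = c("signed", "absolute")) {
        rank <- match.arg(rank)
        .proportional_threshold(x@values, density, rank, x@network)
    })

#' @rdname proportionalThreshold
setMethod("proportionalThreshold", "matrix",
    function(x, density, rank = c("signed", "absolute")) {
        rank <- match.arg(rank)
        .proportional_threshold(x, density, rank, "graph")
    })

#' @rdname densitySweep
setMethod("densitySweep", "ConnectivityMatrix",
    function(x, densities = natDensities(),
             rank = c("signed", "absolute")) {
        rank <- match.arg(rank)
        lapply(densities, function(d)
            proportionalThreshold(x, d, rank = rank))
    })

#' @rdname densitySweep
setMethod("densitySweep", "matrix",
    function(x, densities = natDensities(),
             rank = c("signed", "absolute")) {
        rank <- match.arg(rank)
        lapply(densities, function(d)
            proportionalThreshold(x, d, rank = rank))
    })

#' Temporal signal-to-noise ratio
#'
#' Per ROI, the temporal mean divided by the temporal standard
#' deviation. Constant series have undefined tSNR: they are returned as
#' `Inf` with a warning and excluded from the scan summary.
#'
#' @param timeseries numeric matrix, ROIs in rows, >= 2 time points.
#' @return Named numeric vector of per-ROI tSNR values.
#' @seealso [scanTSNR()] for the per-scan summary (mean over ROIs).
#' @export
temporalSNR <- function(timeseries) {
    if (ncol(timeseries) < 2)
        stop("need at least 2 time points")
    m <- rowMeans(timeseries)
    s <- apply(timeseries, 1, sd)
    out <- ifelse(s == 0, Inf, m / s)
    names(out) <- rownames(timeseries)
    if (any(s == 0))
        warning("undefined tSNR (zero temporal sd) for ",
                sum(s == 0), " ROI(s); excluded from scan summary")
    out
}

#' @rdname temporalSNR
#' @export
scanTSNR <- function(timeseries) {
    v <- suppressWarnings(temporalSNR(timeseries))
    mean(v[is.finite(v)])
}
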