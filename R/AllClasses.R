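#' @import methods
#' @importFrom stats cor sd rnorm rbeta rbinom rlnorm runif plogis qlogis
#'   lm vcov coef confint as.formula model.matrix complete.cases pf pt qt
#'   setNames aggregate quantile logLik fitted resid anova var
#' @importFrom utils write.table read.delim head
#' @importFrom tools md5sum
#' @useDynLib brainNAT, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.NETWORKS <- c("SMN", "DMN", "FPN", "ATN")
.NETWORK_CHOICES <- c("global", .NETWORKS)

#' ROI atlas with subnetwork labels
#'
#' An `ROIAtlas` binds region-of-interest identifiers to (optional) MNI
#' coordinates and a resting-state subnetwork label. Labels partition the
#' ROIs: each ROI belongs to exactly one of `SMN`, `DMN`, `FPN`, `ATN`, or
#' `none` (not part of any analyzed subnetwork), so subnetworks never
#' overlap.
#'
#' @slot roi character vector of unique ROI identifiers.
#' @slot coords numeric matrix (n x 3) of MNI coordinates in mm; may have
#'   zero rows when coordinates are unknown.
#' @slot network character vector of subnetwork labels, one per ROI.
#'
#' @seealso [syntheticAtlas()] for the 300-ROI reference fixture,
#'   [readAtlas()] / [writeAtlas()] for the TSV interchange format.
#' @export
setClass("ROIAtlas",
    representation(roi = "character", coords = "matrix",
                   network = "character"),
    validity = function(object) {
        msg <- character()
        n <- length(object@roi)
        if (anyDuplicated(object@roi))
            msg <- c(msg, "ROI identifiers must be unique")
        if (length(object@network) != n)
            msg <- c(msg, "one network label per ROI required")
        bad <- setdiff(unique(object@network), c(.NETWORKS, "none"))
        if (length(bad))
            msg <- c(msg, paste0("unknown network label(s): ",
                                 paste(bad, collapse = ", ")))
        if (nrow(object@coords) > 0 &&
            (nrow(object@coords) != n || ncol(object@coords) != 3))
            msg <- c(msg, "coords must be an n x 3 matrix (or 0-row)")
        if (length(msg)) msg else TRUE
    })

#' Construct an ROI atlas
#'
#' @param roi character vector of unique ROI identifiers.
#' @param network character vector of subnetwork labels
#'   (`"SMN"`, `"DMN"`, `"FPN"`, `"ATN"`, or `"none"`), one per ROI.
#' @param coords optional numeric matrix (n x 3) of MNI coordinates.
#' @return An [ROIAtlas-class] object.
#' @export
ROIAtlas <- function(roi, network, coords = NULL) {
    if (is.null(coords))
        coords <- matrix(numeric(0), nrow = 0, ncol = 3)
    new("ROIAtlas", roi = as.character(roi), coords = coords,
        network = as.character(network))
}

#' Symmetric Fisher-z connectivity matrix
#'
#' Holds an ROI-by-ROI matrix of Fisher-transformed bivariate correlation
#' coefficients, bound to an [ROIAtlas-class] that fixes ROI order and
#' subnetwork membership. The matrix is symmetric with a zero diagonal and
#' finite entries (correlations are clamped before the arctanh transform).
#'
#' @slot values symmetric numeric matrix, zero diagonal, finite.
#' @slot atlas the bound [ROIAtlas-class].
#' @slot network label of the (sub)network the matrix covers; `"global"`
#'   for the full atlas.
#' @export
setClass("ConnectivityMatrix",
    representation(values = "matrix", atlas = "ROIAtlas",
                   network = "character"),
    validity = function(object) {
        v <- object@values
        msg <- character()
        if (nrow(v) != ncol(v)) msg <- c(msg, "matrix must be square")
        if (nrow(v) != length(object@atlas@roi))
            msg <- c(msg, "matrix dimension must match atlas size")
        if (any(!is.finite(v))) msg <- c(msg, "entries must be finite")
        else {
            if (max(abs(v - t(v))) > 1e-8)
                msg <- c(msg, "matrix must be symmetric")
            if (any(abs(diag(v)) > 1e-12))
                msg <- c(msg, "diagonal must be zero")
        }
        if (!object@network %in% c(.NETWORK_CHOICES))
            msg <- c(msg, "network must be one of global/SMN/DMN/FPN/ATN")
        if (length(msg)) msg else TRUE
    })

#' Construct a connectivity matrix object
#'
#' @param values symmetric numeric matrix of Fisher-z values with zero
#'   diagonal.
#' @param atlas [ROIAtlas-class] matching the matrix rows; if `NULL` a
#'   label-only atlas with network `"none"` is derived from the row names.
#' @param network network label covered by the matrix.
#' @return A [ConnectivityMatrix-class].
#' @export
connectivityMatrix <- function(values, atlas = NULL, network = "global") {
    if (is.null(atlas)) {
        ids <- rownames(values)
        if (is.null(ids)) ids <- sprintf("ROI%03d", seq_len(nrow(values)))
        atlas <- ROIAtlas(ids, rep("none", nrow(values)))
    }
    dimnames(values) <- list(atlas@roi, atlas@roi)
    new("ConnectivityMatrix", values = values, atlas = atlas,
        network = network)
}

#' Binarized proportionally thresholded graph
#'
#' The result of retaining the strongest `density` fraction of edges of a
#' weighted connectivity matrix and binarizing: an undirected, unweighted
#' simple graph. When `density` is not `NA`, the edge count equals
#' `round(density * n(n-1)/2)` (round half up).
#'
#' @slot adjacency symmetric 0/1 integer matrix with zero diagonal.
#' @slot density retained edge fraction in (0, 1], or `NA` for ad-hoc
#'   graphs built directly from an adjacency matrix.
#' @slot network label of the parent network.
#' @export
setClass("ThresholdedGraph",
    representation(adjacency = "matrix", density = "numeric",
                   network = "character"),
    validity = function(object) {
        a <- object@adjacency
        msg <- character()
        if (nrow(a) != ncol(a)) msg <- c(msg, "adjacency must be square")
        if (!all(a %in% c(0L, 1L))) msg <- c(msg, "adjacency must be 0/1")
        else {
            if (any(a != t(a))) msg <- c(msg, "graph must be undirected")
            if (any(diag(a) != 0)) msg <- c(msg, "no self-loops allowed")
            d <- object@density
            if (!is.na(d)) {
                if (d <= 0 || d > 1)
                    msg <- c(msg, "density must be in (0, 1]")
                else {
                    n <- nrow(a)
                    k <- floor(d * n * (n - 1) / 2 + 0.5)
                    if (sum(a) / 2 != k)
                        msg <- c(msg, sprintf(
                            "edge count %d does not match density %.2f (expected %d)",
                            sum(a) %/% 2, d, k))
                }
            }
        }
        if (length(msg)) msg else TRUE
    })

#' Construct a thresholded graph from an adjacency matrix
#'
#' @param adjacency symmetric 0/1 matrix, zero diagonal.
#' @param density retained edge fraction, or `NA` for ad-hoc graphs.
#' @param network parent network label.
#' @return A [ThresholdedGraph-class].
#' @export
thresholdedGraph <- function(adjacency, density = NA_real_,
                             network = "graph") {
    storage.mode(adjacency) <- "integer"
    new("ThresholdedGraph", adjacency = adjacency,
        density = as.numeric(density), network = network)
}

#' Attack curve: global efficiency under targeted node removal
#'
#' `ge[k + 1]` is the global efficiency of the graph after `k` node
#' removals, for `k = 0, ..., N - 1`; the curve therefore has one value
#' per surviving state, starting from the intact graph. `order` lists the
#' `N - 1` removed node labels in attack order.
#'
#' @slot ge numeric vector of global-efficiency values in \[0, 1\].
#' @slot order character vector of removed node labels (length `N - 1`).
#' @slot network parent network label.
#' @slot density density of the attacked graph (may be `NA`).
#' @export
setClass("AttackCurve",
    representation(ge = "numeric", order = "character",
                   network = "character", density = "numeric"),
    validity = function(object) {
        msg <- character()
        n <- length(object@ge)
        if (n > 0 && length(object@order) != n - 1)
            msg <- c(msg, "need one removal per post-attack state")
        if (any(object@ge < -1e-12 | object@ge > 1 + 1e-12))
            msg <- c(msg, "global efficiency must lie in [0, 1]")
        if (length(msg)) msg else TRUE
    })

setMethod("show", "ROIAtlas", function(object) {
    tab <- table(factor(object@network, levels = c(.NETWORKS, "none")))
    cat("ROIAtlas with", length(object@roi), "ROIs\n")
    cat("  membership:",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "ConnectivityMatrix", function(object) {
    cat(sprintf("ConnectivityMatrix [%s]: %d x %d Fisher-z\n",
                object@network, nrow(object@values), ncol(object@values)))
    off <- object@values[upper.tri(object@values)]
    if (length(off))
        cat(sprintf("  edge weights: min %.3f, median %.3f, max %.3f\n",
                    min(off), stats::median(off), max(off)))
})

setMethod("show", "ThresholdedGraph", function(object) {
    n <- nrow(object@adjacency)
    cat(sprintf("ThresholdedGraph [%s]: %d nodes, %d edges, density %s\n",
                object@network, n, sum(object@adjacency) %/% 2,
                ifelse(is.na(object@density), "NA",
                       sprintf("%.2f", object@density))))
})

setMethod("show", "AttackCurve", function(object) {
    cat(sprintf("AttackCurve [%s]: %d states, GE %.4f -> %.4f, NAT %.4f\n",
                object@network, length(object@ge),
                object@ge[1], object@ge[length(object@ge)],
                mean(object@ge)))
})
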