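#' @rdname ROIAtlas-class
#' @param x an object.
#' @export
setGeneric("roiIds", function(x) standardGeneric("roiIds"))

#' @rdname ROIAtlas-class
#' @export
setGeneric("networkLabels", function(x) standardGeneric("networkLabels"))

#' Member ROIs of a subnetwork
#'
#' @param x an [ROIAtlas-class].
#' @param network one of `"global"`, `"SMN"`, `"DMN"`, `"FPN"`, `"ATN"`.
#' @return Character vector of member ROI ids (`"global"` returns all).
#' @export
setGeneric("networkMembers",
           function(x, network) standardGeneric("networkMembers"))

#' @rdname ConnectivityMatrix-class
#' @param x an object.
#' @export
setGeneric("connValues", function(x) standardGeneric("connValues"))

#' @rdname ThresholdedGraph-class
#' @param x an object.
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' @rdname ThresholdedGraph-class
#' @export
setGeneric("graphDensity", function(x) standardGeneric("graphDensity"))

#' @rdname AttackCurve-class
#' @param x an object.
#' @export
setGeneric("geValues", function(x) standardGeneric("geValues"))

#' @rdname AttackCurve-class
#' @export
setGeneric("removalOrder", function(x) standardGeneric("removalOrder"))

setMethod("roiIds", "ROIAtlas", function(x) x@roi)
setMethod("networkLabels", "ROIAtlas", function(x) x@network)
setMethod("networkMembers", "ROIAtlas", function(x, network) {
    network <- match.arg(network, .NETWORK_CHOICES)
    if (network == "global") return(x@roi)
    x@roi[x@network == network]
})
setMethod("connValues", "ConnectivityMatrix", function(x) x@values)
setMethod("adjacency", "ThresholdedGraph", function(x) x@adjacency)
setMethod("graphDensity", "ThresholdedGraph", function(x) x@density)
setMethod("geValues", "AttackCurve", function(x) x@ge)
setMethod("removalOrder", "AttackCurve", function(x) x@order)

#' Extract the submatrix of one subnetwork
#'
#' Restricts a global connectivity matrix to the member ROIs of one
#' subnetwork, preserving ROI order. `"global"` returns the input
#' unchanged.
#'
#' @param x a [ConnectivityMatrix-class].
#' @param network subnetwork label or `"global"`.
#' @return A [ConnectivityMatrix-class] over the member ROIs.
#' @export
setGeneric("extractSubnetwork",
           function(x, network) standardGeneric("extractSubnetwork"))

#' Proportional thresholding and binarization
#'
#' Retains exactly `round(density * n(n-1)/2)` edges — the strongest by
#' signed weight (or by absolute weight with `rank = "absolute"`) — and
#' binarizes. Ties at the cut are broken by ascending (row, column)
#' index, making the selection deterministic.
#'
#' @param x a [ConnectivityMatrix-class] or plain symmetric matrix.
#' @param density fraction of possible edges to keep, in (0, 1].
#' @param rank rank edges by `"signed"` weight (default, the toolbox
#'   convention for unsigned-intent connectomes) or `"absolute"` value.
#' @return A [ThresholdedGraph-class].
#' @export
setGeneric("proportionalThreshold",
           function(x, density, rank = c("signed", "absolute"))
               standardGeneric("proportionalThreshold"))

#' Density sweep
#'
#' Thresholds one weighted matrix at each density of the sweep grid
#' (default 10% to 50% in 5% steps, nine graphs).
#'
#' @param x a [ConnectivityMatrix-class] or plain symmetric matrix.
#' @param densities density grid, each in (0, 1].
#' @param rank edge ranking rule, see [proportionalThreshold()].
#' @return A list of [ThresholdedGraph-class], one per density.
#' @export
setGeneric("densitySweep",
           function(x, densities = natDensities(),
                    rank = c("signed", "absolute"))
               standardGeneric("densitySweep"))

#' Global efficiency of a binary undirected graph
#'
#' Average inverse shortest-path length over all ordered node pairs;
#' disconnected pairs contribute zero and graphs with at most one node
#' have efficiency 0 by convention.
#'
#' @param x a [ThresholdedGraph-class] or binary symmetric matrix.
#' @return Global efficiency in \[0, 1\].
#' @export
setGeneric("globalEfficiency",
           function(x) standardGeneric("globalEfficiency"))

#' Degree-targeted node attack
#'
#' Iteratively removes the node with the highest degree (recomputed on
#' the surviving subgraph in `"adaptive"` mode, or ranked once on the
#' intact graph in `"static"` mode; ties broken by ascending node
#' index), recording global efficiency after each removal.
#'
#' @param x a [ThresholdedGraph-class] or binary symmetric matrix.
#' @param mode `"adaptive"` (default) or `"static"` degree ranking.
#' @return An [AttackCurve-class].
#' @export
setGeneric("targetedAttack",
           function(x, mode = c("adaptive", "static"))
               standardGeneric("targetedAttack"))

#' Network attack tolerance of an attack curve
#'
#' The area under the efficiency-versus-removals curve normalized by the
#' number of nodes: the mean retained global efficiency, a fraction of
#' the maximum possible (a graph at efficiency 1 throughout scores 1).
#'
#' @param x an [AttackCurve-class] or numeric vector of GE values.
#' @return NAT score in \[0, 1\].
#' @export
setGeneric("natScore", function(x) standardGeneric("natScore"))
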