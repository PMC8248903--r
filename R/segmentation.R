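# Step B: connected-component labelling, speck discarding, and fusion of
# components into ordered ECG row waveforms via a truncated Hausdorff
# distance over endpoint pixel subsets.

#' Merge parameters for row assembly
#'
#' The three tunables controlling component fusion: the merge distance
#' threshold, the endpoint pixel count of the truncated Hausdorff distance,
#' and the minimum component area, plus the pixel connectivity.
#'
#' @param distanceThreshold merge distance in pixels; components whose
#'   truncated Hausdorff distance is strictly below it are fused.  The
#'   default \code{NULL} means "twice the grid pitch in pixels", resolved
#'   when the template is known, so the setting transfers across DPI.
#' @param endpointPixels pixels retained per side (leftmost and rightmost)
#'   for the truncated distance.  Default 75, the midpoint of the 50-100
#'   range explored in the source method's tradeoff analysis.
#' @param minComponentArea components with fewer pixels are discarded
#'   (strictly fewer: a component exactly at the threshold is kept).
#' @param connectivity 4 or 8; 8 suits thin diagonal trace strokes.
#' @return a validated list of class \code{MergeParams}.
#' @export
mergeParams <- function(distanceThreshold = NULL, endpointPixels = 75L,
                        minComponentArea = 100L, connectivity = 8L) {
    stopIfNot(is.null(distanceThreshold) || distanceThreshold > 0,
        "distanceThreshold must be positive")
    stopIfNot(endpointPixels >= 1, "endpointPixels must be >= 1")
    stopIfNot(minComponentArea >= 0, "minComponentArea must be >= 0")
    stopIfNot(connectivity %in% c(4L, 8L), "connectivity must be 4 or 8")
    structure(list(distanceThreshold = distanceThreshold,
        endpointPixels = as.integer(endpointPixels),
        minComponentArea = as.integer(minComponentArea),
        connectivity = as.integer(connectivity)), class = "MergeParams")
}

#' Label connected components of a binary mask
#'
#' Builds the pixel-adjacency graph under the chosen connectivity and labels
#' its connected components.  Labels are renumbered in column-major order of
#' each component's first pixel, so the labelling is deterministic and
#' independent of internal graph ordering.
#'
#' @param mask a \linkS4class{BinaryMask}.
#' @param connectivity 4 (edge-adjacent) or 8 (edge- or corner-adjacent).
#' @return a \linkS4class{ComponentSet} (empty mask gives an empty set).
#' @examples
#' m <- matrix(FALSE, 4, 4); m[1, 1] <- TRUE; m[2, 2] <- TRUE
#' nComponents(labelComponents(BinaryMask(m), connectivity = 8))
#' nComponents(labelComponents(BinaryMask(m), connectivity = 4))
#' @export
labelComponents <- function(mask, connectivity = 8L) {
    stopIfNot(connectivity %in% c(4L, 8L), "connectivity must be 4 or 8")
    m <- maskData(mask)
    idx <- which(m)  # column-major linear indices
    n <- length(idx)
    if (n == 0L)
        return(new("ComponentSet",
            coords = matrix(integer(0), 0, 2,
                dimnames = list(NULL, c("row", "col"))),
            label = integer(0), dim = dim(m),
            connectivity = as.integer(connectivity)))
    nr <- nrow(m); nc <- ncol(m)
    pos <- integer(nr * nc)
    pos[idx] <- seq_len(n)
    rr <- ((idx - 1L) %% nr) + 1L
    offs <- list(c(1L, 0L), c(0L, 1L))
    if (connectivity == 8L) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
    edges <- list()
    for (o in offs) {
        dr <- o[1]; dc <- o[2]
        nb <- idx + dr + dc * nr
        ok <- rr + dr >= 1L & rr + dr <= nr & nb >= 1L & nb <= nr * nc
        ok[ok] <- m[nb[ok]]
        if (any(ok))
            edges[[length(edges) + 1L]] <- cbind(pos[idx[ok]], pos[nb[ok]])
    }
    memb <- if (length(edges)) {
        g <- igraph::graph_from_edgelist(do.call(rbind, edges),
            directed = FALSE)
        g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
        igraph::components(g)$membership
    } else seq_len(n)
    # renumber by first occurrence in column-major pixel order
    lab <- as.integer(match(memb, unique(memb)))
    cc <- ((idx - 1L) %/% nr) + 1L
    new("ComponentSet",
        coords = cbind(row = rr, col = cc),
        label = lab, dim = dim(m), connectivity = as.integer(connectivity))
}

#' Discard components below a minimum area
#'
#' Components whose pixel count is strictly less than \code{minArea} are
#' dropped (around 100 pixels is a typical setting); a component exactly at
#' the threshold is retained.  Remaining labels are renumbered contiguously.
#'
#' @param components a \linkS4class{ComponentSet}.
#' @param minArea minimum pixel count, >= 0.
#' @return the filtered \linkS4class{ComponentSet}.
#' @export
discardSmall <- function(components, minArea = 100L) {
    stopIfNot(minArea >= 0, "minArea must be >= 0")
    areas <- componentAreas(components)
    keep <- which(areas >= minArea)
    sel <- components@label %in% keep
    lab <- components@label[sel]
    new("ComponentSet",
        coords = components@coords[sel, , drop = FALSE],
        label = as.integer(match(lab, unique(lab))),
        dim = components@dim, connectivity = components@connectivity)
}

#' Closest approach between two pixel sets
#'
#' The minimum Euclidean distance over all pixel pairs; the fusion metric of
#' \code{\link{assembleRows}} (0 when the sets share a pixel).
#'
#' @param a,b integer matrices of (row, col) pixel coordinates.
#' @return distance in pixels.
#' @export
closestApproach <- function(a, b) {
    A <- .asCoords(a); B <- .asCoords(b)
    stopIfNot(nrow(A) > 0 && nrow(B) > 0,
        "input error: components must be non-empty")
    best <- Inf
    step <- max(1L, floor(2e6 / nrow(B)))
    for (s in seq(1L, nrow(A), by = step)) {
        e <- min(s + step - 1L, nrow(A))
        d2 <- outer(A[s:e, 1], B[, 1], "-")^2 + outer(A[s:e, 2], B[, 2], "-")^2
        best <- min(best, min(d2))
    }
    sqrt(best)
}

# max over rows of A of the min distance to B, chunked to bound memory
.directedHausdorff <- function(A, B) {
    worst <- 0
    step <- max(1L, floor(2e6 / nrow(B)))
    for (s in seq(1L, nrow(A), by = step)) {
        e <- min(s + step - 1L, nrow(A))
        d2 <- outer(A[s:e, 1], B[, 1], "-")^2 + outer(A[s:e, 2], B[, 2], "-")^2
        worst <- max(worst, max(apply(d2, 1, min)))
    }
    sqrt(worst)
}

.asCoords <- function(x) {
    if (is(x, "ComponentSet")) {
        stopIfNot(nComponents(x) == 1L,
            "pass a single component's pixel matrix")
        return(x@coords)
    }
    x
}

#' Symmetric Hausdorff distance between two pixel sets
#'
#' The classical form over all pixel pairs (Euclidean ground metric):
#' \eqn{\max(\sup_a \inf_b d(a,b), \sup_b \inf_a d(a,b))}.  Quadratic in the
#' pixel counts; it serves as the exact reference for
#' \code{\link{hausdorffTruncated}}.
#'
#' @param a,b integer matrices of (row, col) pixel coordinates (or
#'   single-component \linkS4class{ComponentSet}s).
#' @return distance in pixels.
#' @examples
#' hausdorffFull(cbind(0, 0), cbind(3, 4))  # 5
#' @export
hausdorffFull <- function(a, b) {
    A <- .asCoords(a); B <- .asCoords(b)
    stopIfNot(nrow(A) > 0 && nrow(B) > 0,
        "input error: components must be non-empty")
    max(.directedHausdorff(A, B), .directedHausdorff(B, A))
}

# the endpointPixels leftmost plus endpointPixels rightmost pixels of a
# component, by column order (ties broken by row for determinism)
.endpointSubset <- function(A, endpointPixels, axis = c("col", "row")) {
    axis <- match.arg(axis)
    k <- if (axis == "col") order(A[, 2], A[, 1]) else order(A[, 1], A[, 2])
    n <- nrow(A)
    if (2L * endpointPixels >= n) return(A)
    sel <- unique(c(head(k, endpointPixels), tail(k, endpointPixels)))
    A[sel, , drop = FALSE]
}

#' Truncated Hausdorff distance over endpoint pixel subsets
#'
#' The Hausdorff distance computed only over each component's
#' \code{endpointPixels} leftmost and \code{endpointPixels} rightmost pixels
#' (column order, matching the left-to-right time axis).  When the subset
#' saturates the component this equals \code{\link{hausdorffFull}} exactly;
#' with small subsets it is the fast approximation used for row merging.
#'
#' @param a,b integer matrices of (row, col) pixel coordinates.
#' @param endpointPixels pixels retained per side, >= 1.
#' @param axis \code{"col"} (default) selects column-extremal pixels;
#'   \code{"row"} selects row-extremal ones.
#' @return distance in pixels.
#' @export
hausdorffTruncated <- function(a, b, endpointPixels = 75L, axis = "col") {
    A <- .asCoords(a); B <- .asCoords(b)
    stopIfNot(nrow(A) > 0 && nrow(B) > 0,
        "input error: components must be non-empty")
    stopIfNot(endpointPixels >= 1, "endpointPixels must be >= 1")
    hausdorffFull(.endpointSubset(A, endpointPixels, axis),
                  .endpointSubset(B, endpointPixels, axis))
}

#' Fuse connected components into ordered row waveforms
#'
#' Components closer than the merge threshold are linked; the transitive
#' closure of that relation (single-linkage) partitions the components into
#' groups.  The pairwise distance is the closest approach (minimum Euclidean
#' distance) between the two components' endpoint-pixel subsets -- the same
#' truncated subsets as \code{\link{hausdorffTruncated}} -- which is what a
#' merge threshold sitting "above the largest within-row gap and below the
#' inter-row spacing" bounds; \code{metric = "full"} computes the closest
#' approach over all pixels instead.  Groups are ordered top to bottom by
#' mean row coordinate.  Groups narrower than \code{minWidth} columns are
#' set aside as rejects (stray specks and non-overlapping lead characters);
#' when more viable groups are found than \code{expectedRows} the result is
#' flagged, never silently truncated.
#'
#' @param components a \linkS4class{ComponentSet} (typically after
#'   \code{\link{discardSmall}}).
#' @param params a \code{\link{mergeParams}} object with a resolved (non-NULL)
#'   \code{distanceThreshold}.
#' @param expectedRows the template's row count, or NA to accept any.
#' @param minWidth minimum column span of a viable row group; default half
#'   the widest group's span.
#' @param metric \code{"truncated"} (endpoint subsets, default) or
#'   \code{"full"} (all pixels).
#' @return a \linkS4class{RowWaveforms}.
#' @export
assembleRows <- function(components, params, expectedRows = NA,
                         minWidth = NULL, metric = c("truncated", "full")) {
    metric <- match.arg(metric)
    stopIfNot(nComponents(components) > 0,
        "no waveform found: no components to assemble")
    stopIfNot(!is.null(params$distanceThreshold),
        "distanceThreshold must be resolved before assembly")
    n <- nComponents(components)
    pix <- lapply(seq_len(n), function(l) componentPixels(components, l))
    sub <- if (metric == "truncated")
        lapply(pix, .endpointSubset, endpointPixels = params$endpointPixels)
    else pix
    bb <- componentBoundingBoxes(components)
    edges <- list()
    if (n > 1) {
        for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
            # the bounding-box gap lower-bounds the Hausdorff distance, so
            # pairs further apart than the threshold can be skipped outright
            gapR <- max(0, max(bb$top[i], bb$top[j]) -
                           min(bb$bottom[i], bb$bottom[j]))
            gapC <- max(0, max(bb$left[i], bb$left[j]) -
                           min(bb$right[i], bb$right[j]))
            if (sqrt(gapR^2 + gapC^2) >= params$distanceThreshold)
                next
            d <- closestApproach(sub[[i]], sub[[j]])
            if (d < params$distanceThreshold)
                edges[[length(edges) + 1L]] <- c(i, j)
        }
    }
    memb <- if (length(edges)) {
        g <- igraph::graph_from_edgelist(do.call(rbind, edges),
            directed = FALSE)
        g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
        igraph::components(g)$membership
    } else seq_len(n)
    groups <- split(seq_len(n), memb)
    meanRow <- vapply(groups, function(ls)
        mean(unlist(lapply(ls, function(l) pix[[l]][, 1]))), 0)
    width <- vapply(groups, function(ls) {
        cols <- unlist(lapply(ls, function(l) pix[[l]][, 2]))
        diff(range(cols)) + 1L
    }, 0)
    if (is.null(minWidth)) minWidth <- max(width) / 2
    viable <- width >= minWidth
    ord <- order(meanRow[viable])
    kept <- unname(groups[viable][ord])
    rejects <- as.integer(unlist(groups[!viable]))
    flagged <- !is.na(expectedRows) && length(kept) > expectedRows
    if (flagged)
        warning(sprintf("found %d row groups but template expects %d",
            length(kept), expectedRows))
    new("RowWaveforms", components = components,
        groups = lapply(kept, as.integer),
        rejects = rejects, flagged = flagged)
}
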