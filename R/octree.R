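#' Octree spatial index over vacant dendritic elements
#'
#' Builds the Barnes-Hut acceleration structure used for approximate
#' distance-weighted partner selection. Each node stores its bounding cube,
#' the total vacancy of the neurons below it, and their vacancy-weighted
#' centroid; leaves hold single neurons. The tree must be rebuilt (or the
#' caller must supply updated vacancies) whenever vacancies change.
#'
#' @param pos n x 3 position matrix indexed by neuron id.
#' @param vacant per-neuron vacancy counts for one dendritic element kind;
#'   neurons with zero vacancy are not entered into the tree.
#' @param ids neuron ids corresponding to the rows used (defaults to all
#'   rows with `vacant > 0`).
#' @return A nested-list tree of class `"spatial_index"`, or `NULL` when no
#'   neuron has a vacancy.
#' @export
build_spatial_index <- function(pos, vacant, ids = NULL) {
    if (is.null(ids)) ids <- which(vacant > 0) else ids <- ids[vacant[ids] > 0]
    if (!length(ids)) return(NULL)
    v <- vacant[ids]
    p <- pos[ids, , drop = FALSE]
    lo <- apply(p, 2, min)
    width <- max(apply(p, 2, max) - lo, 1e-9)
    node <- octree_build(p, v, ids, lo, width)
    class(node) <- "spatial_index"
    node
}

octree_build <- function(p, v, ids, lo, width) {
    total <- sum(v)
    centroid <- colSums(p * v) / total
    if (length(ids) == 1L)
        return(list(leaf = TRUE, id = ids, pos = p[1, ], vacant = v,
                    total = total, centroid = centroid, width = width))
    mid <- lo + width / 2
    oct <- 1L + (p[, 1] >= mid[1]) + 2L * (p[, 2] >= mid[2]) +
           4L * (p[, 3] >= mid[3])
    children <- vector("list", 0L)
    for (o in unique(oct)) {
        sel <- oct == o
        off <- c((o - 1L) %% 2L, ((o - 1L) %/% 2L) %% 2L, (o - 1L) %/% 4L)
        children[[length(children) + 1L]] <-
            octree_build(p[sel, , drop = FALSE], v[sel], ids[sel],
                         lo + off * width / 2, width / 2)
    }
    list(leaf = FALSE, children = children, total = total,
         centroid = centroid, width = width)
}

# Flatten a node's subtree into selection units, as seen from `src_pos`.
# The acceptance test is applied to each *child* during expansion: a child
# with width/distance <= theta becomes an aggregate (weighted by its total
# vacancy times the kernel at its vacancy centroid), any other internal
# child is expanded recursively, and leaves are always exact. The node
# itself is never re-tested, so recursing into a chosen aggregate always
# descends a level.
octree_units <- function(node, src_pos, sigma, theta, exclude) {
    leaf_unit <- function(nd) {
        wt <- if (!is.na(exclude) && nd$id == exclude) 0
              else nd$total * kernel_weight(src_pos, nd$pos, sigma)
        list(node = nd, weight = wt, aggregate = FALSE)
    }
    if (node$leaf) return(list(leaf_unit(node)))
    out <- list()
    for (ch in node$children) {
        if (ch$leaf) {
            out[[length(out) + 1L]] <- leaf_unit(ch)
        } else {
            dist <- sqrt(sum((ch$centroid - src_pos)^2))
            if (dist > 0 && ch$width / dist <= theta) {
                out[[length(out) + 1L]] <- list(
                    node = ch,
                    weight = ch$total *
                        kernel_weight(src_pos, ch$centroid, sigma),
                    aggregate = TRUE)
            } else {
                out <- c(out, octree_units(ch, src_pos, sigma, theta,
                                           exclude))
            }
        }
    }
    out
}

#' Barnes-Hut approximate partner selection
#'
#' Draws one partner neuron by probabilistic top-down descent through the
#' octree: the tree is flattened (from the source's viewpoint) into units
#' that either satisfy the acceptance criterion `width/distance <= theta`
#' or are leaves, one unit is drawn with probability proportional to its
#' vacancy-times-kernel weight, and a drawn aggregate is recursed into with
#' the same rule until a leaf is reached. Each call consumes a single
#' uniform variate, mapped through nested cumulative-weight intervals.
#'
#' With `theta = 0` no node is ever aggregated, so the induced distribution
#' is exactly that of [select_partner_exact()]; with moderate `theta`
#' (e.g. 0.3) it approximates it while evaluating far fewer kernels.
#'
#' @param index a `"spatial_index"` from [build_spatial_index()].
#' @param src_pos length-3 position of the selecting neuron.
#' @param sigma_gauss kernel scale.
#' @param theta Barnes-Hut acceptance criterion, >= 0.
#' @param exclude neuron id excluded from selection (the source itself; no
#'   autapses). Default none.
#' @return Chosen neuron id, or `NA_integer_` if the tree is empty or all
#'   weights vanish.
#' @export
select_partner_octree <- function(index, src_pos, sigma_gauss, theta,
                                  exclude = NA_integer_) {
    if (is.null(index)) return(NA_integer_)
    u <- stats::runif(1)
    node <- index
    repeat {
        units <- octree_units(node, src_pos, sigma_gauss, theta, exclude)
        w <- vapply(units, `[[`, numeric(1), "weight")
        total <- sum(w)
        if (total <= 0) return(NA_integer_)
        cw <- cumsum(w)
        k <- sum(cw < u * total) + 1L
        # rescale u to be uniform within the chosen interval
        left <- if (k > 1L) cw[k - 1L] else 0
        u <- (u * total - left) / w[k]
        u <- min(max(u, 0), 1 - 1e-12)
        unit <- units[[k]]
        if (!unit$aggregate) {
            if (unit$node$leaf) return(unit$node$id)
            node <- unit$node
        } else {
            node <- unit$node
        }
        if (node$leaf) return(node$id)
    }
}

#' Induced selection probabilities of the octree sampler
#'
#' Computes, exactly and without sampling, the probability with which
#' [select_partner_octree()] returns each neuron, by recursing through the
#' same unit decomposition and multiplying branch probabilities. Used to
#' verify that `theta = 0` reproduces the exact sampler and to measure the
#' approximation error at `theta > 0`.
#'
#' @inheritParams select_partner_octree
#' @return Named numeric vector (names are neuron ids) summing to 1.
#' @export
octree_probabilities <- function(index, src_pos, sigma_gauss, theta,
                                 exclude = NA_integer_) {
    acc <- new.env(parent = emptyenv())
    recurse <- function(node, mass) {
        units <- octree_units(node, src_pos, sigma_gauss, theta, exclude)
        w <- vapply(units, `[[`, numeric(1), "weight")
        total <- sum(w)
        if (total <= 0) return(invisible())
        for (k in seq_along(units)) {
            if (w[k] <= 0) next
            p <- mass * w[k] / total
            nd <- units[[k]]$node
            if (nd$leaf) {
                key <- as.character(nd$id)
                acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + p
            } else {
                recurse(nd, p)
            }
        }
    }
    if (!is.null(index)) recurse(index, 1)
    out <- unlist(as.list(acc))
    if (is.null(out)) return(numeric(0))
    out[order(as.integer(names(out)))]
}
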