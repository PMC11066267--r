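#' Apply a focal lesion
#'
#' In every box, draws a lesion centre uniformly at random, selects the
#' given fraction of in-scope neurons closest to it (Euclidean distance,
#' ties broken by neuron id), and removes all synapses from and to the
#' selected neurons, including static readout synapses touching them. In
#' `"connections"` mode the neurons keep their positions and elements and
#' later regrow synapses; in `"remove"` mode they are additionally
#' removed from the network and from all future partner pools.
#'
#' @param net an `"engram_network"`.
#' @param fraction fraction of in-scope neurons to lesion, in `[0, 1]`.
#' @param scope `"ensemble"` (one named ensemble per box) or `"box"`
#'   (all plastic neurons of the box).
#' @param ensemble ensemble name for `scope = "ensemble"`.
#' @param mode `"connections"` or `"remove"`.
#' @param seed optional integer seed for the centre draws.
#' @return The lesioned network; the selected ids are attached as
#'   attribute `"lesioned"` (list per box).
#' @export
apply_lesion <- function(net, fraction, scope = c("ensemble", "box"),
                         ensemble = "C1", mode = c("connections", "remove"),
                         seed = NULL) {
    scope <- match.arg(scope)
    mode <- match.arg(mode)
    stopifnot(fraction >= 0, fraction <= 1)
    if (!is.null(seed)) set.seed(seed)
    if (fraction == 0) {
        attr(net, "lesioned") <- list()
        return(net)
    }
    pop <- net$pop
    boxes <- sort(unique(pop$box_id))
    g <- net$params$box_grid
    edge <- net$params$box_edge
    sel_all <- integer(0)
    lesioned <- list()
    for (b in boxes) {
        in_scope <- pop$alive & pop$plastic & pop$box_id == b
        if (scope == "ensemble") in_scope <- in_scope & pop$ensemble == ensemble
        ids <- pop$id[in_scope]
        if (!length(ids)) next
        org <- box_origin(b, g, edge)
        centre <- org + stats::runif(3, 0, edge)
        d <- sqrt((pop$x[ids] - centre[1])^2 + (pop$y[ids] - centre[2])^2 +
                  (pop$z[ids] - centre[3])^2)
        k <- round(fraction * length(ids))
        sel <- ids[order(d, ids)][seq_len(k)]
        lesioned[[as.character(b)]] <- sel
        sel_all <- c(sel_all, sel)
    }
    if (length(sel_all)) {
        hit <- net$syn$src %in% sel_all | net$syn$tgt %in% sel_all
        rem <- which(hit & !net$syn$static)
        bound <- net$elem$bound
        if (length(rem)) {
            dec_ax <- tabulate(net$syn$src[rem], nrow(pop))
            dec_de <- tabulate(net$syn$tgt[rem][net$syn$w[rem] > 0], nrow(pop))
            dec_di <- tabulate(net$syn$tgt[rem][net$syn$w[rem] < 0], nrow(pop))
            bound[, 1] <- bound[, 1] - dec_ax
            bound[, 2] <- bound[, 2] - dec_de
            bound[, 3] <- bound[, 3] - dec_di
        }
        keep <- !hit
        net$syn <- list(src = net$syn$src[keep], tgt = net$syn$tgt[keep],
                        w = net$syn$w[keep], static = net$syn$static[keep])
        net$elem$bound <- bound
        net$syn_dirty <- TRUE
        if (mode == "remove") {
            net$pop$alive[sel_all] <- FALSE
            net$pop$plastic[sel_all] <- FALSE
            net$elem$z[sel_all, ] <- 0
            net$state$fired[sel_all] <- FALSE
        }
    }
    attr(net, "lesioned") <- lesioned
    net
}
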