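#' Create a network in the fully disconnected state
#'
#' Builds the population, attaches the static readout synapses, and
#' initialises the electrical state (membrane potential at the reset value
#' `c_izh`, recovery `u = b_izh * c_izh`, calcium 0) and the element state
#' (no grown elements, no plastic synapses). Connectivity then has to be
#' grown by the homeostatic mechanism, see [grow_network()].
#'
#' @param params a [simulation_params()] list.
#' @param seed integer seed for the population draw.
#' @return An object of class `"engram_network"`.
#' @export
new_network <- function(params, seed) {
    pop <- build_population(params, seed)
    n <- nrow(pop)
    ro <- attach_readout_synapses(pop)
    z <- matrix(0, n, 3, dimnames = list(NULL, c("axon", "den_ex", "den_inh")))
    bound <- matrix(0L, n, 3, dimnames = dimnames(z))
    net <- list(
        params = params,
        pop = pop,
        pos = cbind(pop$x, pop$y, pop$z),
        state = list(v = rep(params$c_izh, n),
                     u = rep(params$b_izh * params$c_izh, n),
                     ca = rep(0, n),
                     fired = rep(FALSE, n)),
        elem = list(z = z, bound = bound),
        syn = list(src = as.integer(ro$src), tgt = as.integer(ro$tgt),
                   w = as.integer(ro$w), static = ro$static),
        step = 0L,
        plasticity_on = TRUE,
        syn_dirty = TRUE)
    class(net) <- "engram_network"
    net
}

#' @export
print.engram_network <- function(x, ...) {
    n <- nrow(x$pop)
    cat("<engram_network> ", n, " neurons (",
        sum(x$pop$kind == "readout"), " readouts), ",
        sum(!x$syn$static), " plastic + ", sum(x$syn$static),
        " static synapses, step ", x$step, "\n", sep = "")
    invisible(x)
}

#' Synapse table of a network
#'
#' @param net an `"engram_network"`.
#' @param static include static readout synapses (default yes).
#' @return data.frame with `src`, `tgt`, `w`, `static`.
#' @export
synapse_table <- function(net, static = TRUE) {
    d <- data.frame(src = net$syn$src, tgt = net$syn$tgt, w = net$syn$w,
                    static = net$syn$static)
    if (!static) d <- d[!d$static, , drop = FALSE]
    d
}

#' Mean number of plastic synapses per neuron
#'
#' Total non-static synapses divided by the number of live plastic
#' neurons; readouts and removed neurons are excluded from the
#' denominator.
#'
#' @param net an `"engram_network"`.
#' @return A single number.
#' @export
synapses_per_neuron <- function(net) {
    sum(!net$syn$static) / sum(net$pop$plastic & net$pop$alive)
}

#' Check the structural invariants of a network
#'
#' Asserts conservation (total bound axonal elements = total bound
#' dendritic elements = plastic synapse count), the absence of autapses,
#' weight signs matching source kinds, bound counts consistent with the
#' synapse table, `floor(z) >= bound`, and box ids re-derivable from
#' positions. Errors on the first violation.
#'
#' @param net an `"engram_network"`.
#' @return `TRUE`, invisibly.
#' @export
verify_network <- function(net) {
    syn <- net$syn
    ns <- !syn$static
    n <- nrow(net$pop)
    if (any(syn$src == syn$tgt)) stop("autapse present")
    src_kind <- net$pop$kind[syn$src]
    if (any(syn$w[ns] == 1L & src_kind[ns] != "exc") ||
        any(syn$w[ns] == -1L & src_kind[ns] != "inh"))
        stop("weight sign does not match source kind")
    b_ax <- tabulate(syn$src[ns], n)
    b_de <- tabulate(syn$tgt[ns & syn$w > 0], n)
    b_di <- tabulate(syn$tgt[ns & syn$w < 0], n)
    if (!identical(b_ax, as.integer(net$elem$bound[, 1])) ||
        !identical(b_de, as.integer(net$elem$bound[, 2])) ||
        !identical(b_di, as.integer(net$elem$bound[, 3])))
        stop("bound counts inconsistent with synapse table")
    if (sum(b_ax) != sum(ns) || sum(b_de) + sum(b_di) != sum(ns))
        stop("element conservation violated")
    if (any(floor(net$elem$z) < net$elem$bound - 1e-9))
        stop("floor(z) < bound after update")
    bid <- box_of_position(net$pop$x, net$pop$y, net$pop$z, net$params)
    if (!identical(bid, as.integer(net$pop$box_id)))
        stop("box ids not re-derivable from positions")
    dead <- which(!net$pop$alive)
    if (length(dead) && (any(syn$src %in% dead) || any(syn$tgt %in% dead)))
        stop("synapse references a removed neuron")
    invisible(TRUE)
}

# compressed sparse row view of the synapse table, grouped by source
build_csr <- function(net) {
    n <- nrow(net$pop)
    o <- order(net$syn$src)
    list(ptr = c(0L, cumsum(tabulate(net$syn$src, n))),
         tgt = net$syn$tgt[o] - 1L,
         w = as.numeric(net$syn$w[o]))
}

# ids of neurons in a named ensemble of one box ("*" = all boxes)
ensemble_ids <- function(pop, ensemble, box = "*") {
    sel <- pop$ensemble == ensemble
    if (!identical(box, "*")) sel <- sel & pop$box_id == as.integer(box)
    pop$id[sel]
}
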