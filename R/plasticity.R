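#' Calcium-dependent element growth rate
#'
#' Gaussian-shaped homeostatic growth rule for synaptic elements. The rate
#' is zero at the minimum calcium `eta` and at the set-point `epsilon`,
#' maximal (`+nu`) at their midpoint `xi = (eta + epsilon)/2`, and negative
#' (element retraction) below `eta` and above `epsilon`:
#'
#' `dz/dt = nu * (2 * exp(-((Ca - xi)/zeta)^2) - 1)`,
#' `zeta = (eta - epsilon) / (2 * sqrt(-log(0.5)))`.
#'
#' @param ca calcium concentration (vectorised).
#' @param eta minimum calcium for growth of this element kind.
#' @param epsilon target calcium (set-point).
#' @param nu maximal growth rate, elements/step.
#' @return Growth rate in elements/step, same length as `ca`.
#' @export
#' @examples
#' growth_rate(0.55, eta = 0.4, epsilon = 0.7, nu = 3e-4)  # maximum: +nu
#' growth_rate(c(0.4, 0.7), 0.4, 0.7, 3e-4)                # zeros
growth_rate <- function(ca, eta, epsilon, nu) {
    stopifnot(epsilon != eta)
    xi <- (eta + epsilon) / 2
    zeta <- (eta - epsilon) / (2 * sqrt(-log(0.5)))
    nu * (2 * exp(-((ca - xi) / zeta)^2) - 1)
}

# growth rates for the three element kinds as an n x 3 matrix
# (columns: axon, den_ex, den_inh)
growth_rate_matrix <- function(ca, params) {
    cbind(growth_rate(ca, params$eta_axon, params$epsilon, params$nu_axon),
          growth_rate(ca, params$eta_den_ex, params$epsilon, params$nu_den_ex),
          growth_rate(ca, params$eta_den_inh, params$epsilon, params$nu_den_inh))
}

#' Integrate synaptic element counts over one plasticity interval
#'
#' Applies the growth rule and the decay of vacant (grown but unconnected)
#' elements by explicit Euler over `interval` steps:
#' `z <- z + growth_rate(Ca) * interval - (vacant / tau_vac) * interval`,
#' clamped at zero. `vacant = max(0, floor(z) - bound)` is the number of
#' offered-but-unbound elements; bound elements are not subject to decay.
#'
#' @param z numeric n x 3 matrix of continuous element counts
#'   (axon, den_ex, den_inh).
#' @param bound integer n x 3 matrix of elements bound in synapses.
#' @param ca per-neuron calcium vector.
#' @param params a [simulation_params()] list.
#' @param interval steps since the last update.
#' @param active logical vector; rows with `FALSE` (readouts, removed
#'   neurons) are left untouched.
#' @return Updated `z` matrix.
#' @export
update_elements <- function(z, bound, ca, params, interval,
                            active = rep(TRUE, nrow(z))) {
    vac <- pmax(floor(z) - bound, 0)
    zn <- z + (growth_rate_matrix(ca, params) - vac / params$tau_vac) * interval
    zn[zn < 0] <- 0
    if (!all(active)) zn[!active, ] <- z[!active, ]
    zn
}

#' Prune synapses in excess of grown elements
#'
#' For every neuron and element kind with `floor(z) < bound`, removes the
#' excess synapses, chosen uniformly at random among that neuron's
#' non-static synapses of that kind. A removal frees the element on both
#' sides: the partner's bound count decreases (and its vacancy increases)
#' regardless of the partner's own element count. Neurons are visited in
#' random order, re-checking the (possibly already reduced) deficit at each
#' visit.
#'
#' @param syn synapse table (list or data.frame with `src`, `tgt`, `w`,
#'   `static`).
#' @param z,bound element-state matrices as in [update_elements()].
#' @return `list(syn, bound, n_removed)`.
#' @export
prune_excess <- function(syn, z, bound) {
    deficit <- bound - floor(z)
    pairs <- which(deficit > 0, arr.ind = TRUE)
    if (nrow(pairs) == 0)
        return(list(syn = syn, bound = bound, n_removed = 0L))
    m <- length(syn$src)
    keep <- rep(TRUE, m)
    nonstatic <- !syn$static
    ord <- if (nrow(pairs) > 1) sample.int(nrow(pairs)) else 1L
    for (r in ord) {
        i <- pairs[r, 1]
        kd <- pairs[r, 2]
        need <- bound[i, kd] - floor(z[i, kd])
        if (need <= 0) next
        cand <- switch(kd,
            which(keep & nonstatic & syn$src == i),
            which(keep & nonstatic & syn$tgt == i & syn$w > 0),
            which(keep & nonstatic & syn$tgt == i & syn$w < 0))
        if (!length(cand)) next
        rem <- if (length(cand) <= need) cand
               else cand[sample.int(length(cand), need)]
        keep[rem] <- FALSE
        for (e in rem) {
            bound[syn$src[e], 1L] <- bound[syn$src[e], 1L] - 1L
            kc <- if (syn$w[e] > 0) 2L else 3L
            bound[syn$tgt[e], kc] <- bound[syn$tgt[e], kc] - 1L
        }
    }
    list(syn = list(src = syn$src[keep], tgt = syn$tgt[keep],
                    w = syn$w[keep], static = syn$static[keep]),
         bound = bound, n_removed = sum(!keep))
}

#' Gaussian distance kernel
#'
#' Probability weight for forming a synapse between positions `xi` and
#' `xj`: `exp(-||xj - xi||^2 / (2 sigma^2))`, in (0, 1].
#'
#' @param xi length-3 position of the axon's neuron.
#' @param xj length-3 position, or an n x 3 matrix of candidate positions.
#' @param sigma_gauss kernel scale, > 0.
#' @return Kernel weight(s).
#' @export
#' @examples
#' kernel_weight(c(0, 0, 0), c(12, 0, 0), 12)  # exp(-0.5)
kernel_weight <- function(xi, xj, sigma_gauss) {
    stopifnot(sigma_gauss > 0)
    if (is.matrix(xj)) {
        d2 <- (xj[, 1] - xi[1])^2 + (xj[, 2] - xi[2])^2 + (xj[, 3] - xi[3])^2
    } else {
        d2 <- sum((xj - xi)^2)
    }
    exp(-d2 / (2 * sigma_gauss^2))
}

#' Exact distance-weighted partner selection
#'
#' Chooses one candidate neuron with probability proportional to
#' `vacant_j * kernel_weight(i, j)`. This is the reference sampler: the
#' Barnes-Hut octree sampler ([select_partner_octree()]) is specified by
#' equivalence to it. The draw consumes a single uniform variate.
#'
#' @param source id of the neuron offering the vacant axonal element
#'   (excluded from the candidates; no autapses).
#' @param candidates integer ids of neurons with at least one vacant
#'   dendritic element of the matching polarity.
#' @param vacant vacancy counts aligned with `candidates`.
#' @param pos n x 3 position matrix indexed by neuron id.
#' @param sigma_gauss kernel scale.
#' @return The chosen neuron id, or `NA_integer_` if no candidate has
#'   positive weight (the axonal element stays vacant).
#' @export
select_partner_exact <- function(source, candidates, vacant, pos,
                                 sigma_gauss) {
    keep <- candidates != source & vacant > 0
    candidates <- candidates[keep]
    vacant <- vacant[keep]
    if (!length(candidates)) return(NA_integer_)
    w <- vacant * kernel_weight(pos[source, ], pos[candidates, , drop = FALSE],
                                sigma_gauss)
    total <- sum(w)
    if (total <= 0) return(NA_integer_)
    u <- stats::runif(1)
    cw <- cumsum(w)
    candidates[sum(cw < u * total) + 1L]
}

#' Form synapses between vacant elements
#'
#' One matching pass of the plasticity cycle, run after
#' [update_elements()] and [prune_excess()]: every vacant axonal element,
#' in uniformly random order, attempts to find a partner among the neurons
#' holding vacant dendritic elements of the matching polarity (excitatory
#' axons bind excitatory-dendritic elements, inhibitory axons
#' inhibitory-dendritic ones). A successful match commits a synapse whose
#' weight is +1 for excitatory and -1 for inhibitory sources and
#' decrements both vacancies immediately, so later draws in the same pass
#' see the updated pools (sequential commitment). Autapses are forbidden;
#' multi-edges between the same ordered pair are allowed. An element whose
#' draw finds no candidates stays vacant (one attempt per update).
#'
#' @param net an `"engram_network"`.
#' @return The network with updated synapse table and bound counts.
#' @export
connectivity_update <- function(net) {
    z <- net$elem$z
    bound <- net$elem$bound
    eligible <- net$pop$plastic & net$pop$alive
    vac <- pmax(floor(z) - bound, 0)
    vac[!eligible, ] <- 0
    ax_own <- which(vac[, 1] > 0)
    if (!length(ax_own)) return(net)
    ax <- rep.int(ax_own, vac[ax_own, 1])
    if (length(ax) > 1) ax <- ax[sample.int(length(ax))]
    vd_ex <- vac[, 2]
    vd_inh <- vac[, 3]
    exc <- net$pop$kind == "exc"
    pos <- net$pos
    sg2 <- 2 * net$params$sigma_gauss^2
    n <- nrow(pos)

    ns <- length(ax)
    new_src <- integer(ns); new_tgt <- integer(ns); new_w <- integer(ns)
    cnt <- 0L
    for (i in ax) {
        pool <- if (exc[i]) vd_ex else vd_inh
        d2 <- (pos[, 1] - pos[i, 1])^2 + (pos[, 2] - pos[i, 2])^2 +
              (pos[, 3] - pos[i, 3])^2
        w <- pool * exp(-d2 / sg2)
        w[i] <- 0
        total <- sum(w)
        if (total <= 0) next
        u <- stats::runif(1)
        j <- sum(cumsum(w) < u * total) + 1L
        cnt <- cnt + 1L
        new_src[cnt] <- i
        new_tgt[cnt] <- j
        if (exc[i]) {
            new_w[cnt] <- 1L
            vd_ex[j] <- vd_ex[j] - 1
            bound[j, 2L] <- bound[j, 2L] + 1L
        } else {
            new_w[cnt] <- -1L
            vd_inh[j] <- vd_inh[j] - 1
            bound[j, 3L] <- bound[j, 3L] + 1L
        }
        bound[i, 1L] <- bound[i, 1L] + 1L
    }
    if (cnt > 0) {
        idx <- seq_len(cnt)
        net$syn <- list(src = c(net$syn$src, new_src[idx]),
                        tgt = c(net$syn$tgt, new_tgt[idx]),
                        w = c(net$syn$w, new_w[idx]),
                        static = c(net$syn$static, rep(FALSE, cnt)))
        net$elem$bound <- bound
        net$syn_dirty <- TRUE
    }
    net
}

# One full structural update: element integration, pruning of excess
# synapses, then matching of vacant elements.
structural_tick <- function(net) {
    active <- net$pop$plastic & net$pop$alive
    net$elem$z <- update_elements(net$elem$z, net$elem$bound,
                                  net$state$ca, net$params,
                                  net$params$plasticity_interval, active)
    pr <- prune_excess(net$syn, net$elem$z, net$elem$bound)
    if (pr$n_removed > 0) net$syn_dirty <- TRUE
    net$syn <- pr$syn
    net$elem$bound <- pr$bound
    connectivity_update(net)
}
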