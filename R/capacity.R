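#' Parameters of the analytic memory-capacity model
#'
#' The capacity model abstracts engram storage as rewiring: storing a
#' memory recruits `n_engram` of the `n_total` neurons and replaces
#' `s_engram` of each recruited neuron's `s_neuron` equilibrium synapses.
#' Each later memory overwrites a stored memory's synapses independently
#' with probability `q`, so its signal decays geometrically.
#'
#' @param n_total neurons in the network.
#' @param n_engram neurons recruited per memory, `0 < n_engram <= n_total`.
#' @param s_neuron synapses per neuron at equilibrium.
#' @param s_engram synapses retracted and regrown per recruited neuron,
#'   `0 < s_engram <= s_neuron`.
#' @return list of class `"capacity_params"`.
#' @export
capacity_params <- function(n_total, n_engram, s_neuron, s_engram) {
    stopifnot(n_total > 0, n_engram > 0, n_engram <= n_total,
              s_neuron > 0, s_engram > 0, s_engram <= s_neuron)
    structure(list(n_total = n_total, n_engram = n_engram,
                   s_neuron = s_neuron, s_engram = s_engram),
              class = "capacity_params")
}

#' Per-synapse overwrite probability
#'
#' Probability that one synapse of a stored memory is removed when a new
#' memory is stored:
#' `q = (n_engram / n_total) * (s_engram / s_neuron)` — the first factor
#' is the chance that a synapse's neuron belongs to the newly stimulated
#' set, the second that the synapse is among those the neuron rewires.
#'
#' @param params a [capacity_params()] list.
#' @return `q` in (0, 1].
#' @export
#' @examples
#' overwrite_probability(capacity_params(12500, 333, 9, 4))  # ~0.01184
overwrite_probability <- function(params) {
    with(params, (n_engram / n_total) * (s_engram / s_neuron))
}

#' Signal-to-noise trajectory of a stored memory
#'
#' `snr(t) = snr_init * (1 - q)^t` after `t` later memories, with
#' `snr_init = (n_engram * s_engram) / (n_total * s_neuron)` (the
#' proportionality constant is fixed to 1, so `snr_init` is the stored
#' fraction of all synapses and lies in (0, 1]).
#'
#' @param params a [capacity_params()] list.
#' @param t_max largest number of later memories, >= 0.
#' @return data.frame of class `"snr_curve"` with columns `t`, `snr`.
#' @export
snr_curve <- function(params, t_max) {
    stopifnot(t_max >= 0)
    q <- overwrite_probability(params)
    snr_init <- with(params, (n_engram * s_engram) / (n_total * s_neuron))
    t <- 0:t_max
    structure(data.frame(t = t, snr = snr_init * (1 - q)^t),
              class = c("snr_curve", "data.frame"))
}

#' Number of memories until a stored memory is forgotten
#'
#' Smallest integer `t` with `snr(t) < snr_threshold`; a memory is
#' considered forgotten once its SNR falls below the threshold. Closed
#' form `ceiling(log(threshold / snr_init) / log(1 - q))`, with the
#' boundary adjusted so the strict inequality holds exactly. Returns 0
#' when even the initial SNR is below threshold, and `Inf` when `q = 0`
#' (the signal never decays).
#'
#' @param params a [capacity_params()] list, or any list providing `q`
#'   and `snr_init` directly (e.g. a normalised curve with
#'   `snr_init = 1`).
#' @param snr_threshold forgetting threshold, > 0.
#' @return Integer count of later memories (possibly 0 or `Inf`).
#' @export
#' @examples
#' memories_until(list(q = 0.011840, snr_init = 1), 0.1)  # 194
memories_until <- function(params, snr_threshold) {
    stopifnot(snr_threshold > 0)
    if (inherits(params, "capacity_params")) {
        q <- overwrite_probability(params)
        snr_init <- with(params, (n_engram * s_engram) / (n_total * s_neuron))
    } else {
        q <- params$q
        snr_init <- params$snr_init
    }
    if (snr_init < snr_threshold) return(0L)
    if (q <= 0) return(Inf)
    t <- max(0, ceiling(log(snr_threshold / snr_init) / log(1 - q)))
    while (snr_init * (1 - q)^t >= snr_threshold) t <- t + 1
    while (t > 0 && snr_init * (1 - q)^(t - 1) < snr_threshold) t <- t - 1
    as.integer(t)
}
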