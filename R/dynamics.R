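#' Per-neuron synaptic input from the previous step's spikes
#'
#' Reference (pure R) implementation of the input rule: every synapse
#' whose source fired in the previous step contributes its conductance-
#' weighted weight, `I_syn(j) = sum k * w` over incoming synapses with
#' fired sources (`w = +1` excitatory, `-1` inhibitory source). The
#' compiled stepper computes the same quantity; this function is its
#' testable oracle and is used for single-step experiments.
#'
#' @param syn synapse table (`src`, `tgt`, `w`).
#' @param fired_prev integer ids of the neurons that fired last step.
#' @param k synapse conductance.
#' @param n number of neurons.
#' @return Numeric vector of per-neuron input currents.
#' @export
synaptic_input <- function(syn, fired_prev, k, n) {
    out <- numeric(n)
    sel <- syn$src %in% fired_prev
    if (any(sel)) {
        contrib <- k * syn$w[sel]
        agg <- rowsum(contrib, syn$tgt[sel])
        out[as.integer(rownames(agg))] <- agg[, 1]
    }
    out
}

#' Normally distributed background drive
#'
#' One i.i.d. `N(mu, sigma^2)` draw per neuron, reproducible from the
#' current RNG state.
#'
#' @param n number of neurons.
#' @param mu mean (mV).
#' @param sigma standard deviation (mV), >= 0.
#' @return Numeric vector of length `n`.
#' @export
background_input <- function(n, mu, sigma) {
    stopifnot(sigma >= 0)
    stats::rnorm(n, mu, sigma)
}

#' Right-hand side of the membrane equation
#'
#' `dv/dt = k2 v^2 + k1 v + k0 - u + I` in mV/ms.
#'
#' @param v membrane potential (mV).
#' @param u recovery variable.
#' @param I total input current.
#' @param params a [simulation_params()] list.
#' @return Instantaneous derivative, vectorised.
#' @export
izhikevich_deriv <- function(v, u, I, params) {
    params$k2 * v^2 + params$k1 * v + params$k0 - u + I
}

#' One 1 ms Izhikevich step with spike-and-reset
#'
#' Advances the membrane potential with two 0.5 ms half-steps and the
#' recovery variable with one full step, then applies the threshold rule:
#' a neuron spikes when `v >= 30` mV, upon which `v` is reset to `c_izh`
#' exactly and `u` is incremented by `d_izh`. Vectorised reference
#' implementation; the compiled stepper applies the identical scheme.
#'
#' @param v,u state vectors (mV, mV-scale).
#' @param I total input per neuron for this step.
#' @param params a [simulation_params()] list.
#' @return list(v, u, fired).
#' @export
izhikevich_step <- function(v, u, I, params) {
    if (any(!is.finite(v)) || any(!is.finite(u)))
        stop("non-finite neuron state")
    # a state at or above threshold spikes immediately (the reset rule is
    # applied wherever v >= 30; in normal stepping it triggers right after
    # the integration below, so v never persists above threshold)
    pre <- v >= 30
    integ <- !pre
    vi <- v[integ]; ui <- u[integ]; Ii <- if (length(I) > 1) I[integ] else I
    vi <- vi + 0.5 * izhikevich_deriv(vi, ui, Ii, params)
    vi <- vi + 0.5 * izhikevich_deriv(vi, ui, Ii, params)
    ui <- ui + params$a_izh * (params$b_izh * vi - ui)
    v[integ] <- vi; u[integ] <- ui
    fired <- v >= 30
    v[fired] <- params$c_izh
    u[fired] <- u[fired] + params$d_izh
    list(v = v, u = u, fired = fired)
}

#' Calcium update for one step
#'
#' Explicit Euler step of the leaky spike integrator that proxies the
#' firing rate: `Ca <- Ca - Ca/tau * dt + beta * fired`. For a constant
#' firing probability `p` per step the fixed point is `beta * tau * p`
#' (0.7 at 70 Hz under the defaults).
#'
#' @param ca calcium vector, >= 0.
#' @param fired logical vector.
#' @param tau_ca decay constant (steps).
#' @param beta_ca intake per spike.
#' @return Updated calcium vector.
#' @export
#' @examples
#' update_calcium(0.7, TRUE, 10000, 0.001)  # 0.70093
update_calcium <- function(ca, fired, tau_ca, beta_ca) {
    ca - ca / tau_ca + beta_ca * fired
}
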