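#' Simulation parameters
#'
#' Builds the full parameter set for a structural-plasticity simulation.
#' Defaults are the reference parameterisation used throughout the package:
#' a calcium set-point of 0.7 reached at 70 Hz (`beta_ca * tau_ca * rate`),
#' Gaussian distance kernel with scale 12, synapse conductance 3, and the
#' three synaptic element kinds (axonal, excitatory-dendritic,
#' inhibitory-dendritic) with their minimum-calcium thresholds and growth
#' rates.
#'
#' The Izhikevich polynomial constants `k0`, `k1`, `k2` follow the canonical
#' quadratic form `dv/dt = k2 v^2 + k1 v + k0 - u + I`. `k0` is set to 144.5
#' so that the model's stated operating points are self-consistent: an
#' isolated neuron under the `N(5, 2)` background fires ~62 Hz (calcium 0.62,
#' inside the axonal growth window so a disconnected network can bootstrap),
#' and a neuron receiving background plus the input of ~9 synapses whose
#' partners fire at 70 Hz itself fires at 70 Hz, which is the homeostatic
#' equilibrium the network settles into. See the methods vignette.
#'
#' @param mu_background,sigma_background mean and s.d. (mV) of the
#'   per-step normal background drive.
#' @param theta Barnes-Hut acceptance criterion (node width / distance).
#' @param tau_vac decay time constant (steps) of vacant synaptic elements.
#' @param epsilon target calcium concentration (set-point).
#' @param eta_axon,eta_den_ex,eta_den_inh minimum calcium to grow each
#'   element kind.
#' @param sigma_gauss Gaussian distance-kernel scale (distance units).
#' @param k_conductance synapse conductance multiplying each +-1 weight.
#' @param tau_ca calcium decay constant (steps).
#' @param beta_ca calcium intake per spike.
#' @param nu_axon,nu_den_ex,nu_den_inh maximal element growth rates
#'   (elements/step).
#' @param a_izh,b_izh,c_izh,d_izh Izhikevich recovery/reset constants.
#' @param k0,k1,k2 Izhikevich polynomial constants.
#' @param dt integration step, ms (one simulation step).
#' @param plasticity_interval steps between structural updates.
#' @param box_grid integer vector of 3 box counts per axis.
#' @param neurons_per_box plastic neurons per box.
#' @param ensemble_size neurons per stimulus ensemble (US/C1/C2).
#' @param frac_inhibitory fraction of inhibitory neurons.
#' @param box_edge side length of one box (distance units).
#' @param stim_amplitude stimulation current (mV).
#' @param stim_duration stimulation length (steps, before protocol scaling).
#' @param ... unused; present so partial lists can be spliced with do.call.
#'
#' @return A validated list of class `"simulation_params"`.
#' @export
#' @examples
#' p <- simulation_params(box_grid = c(1, 1, 1), neurons_per_box = 100,
#'                        ensemble_size = 10)
#' p$epsilon
simulation_params <- function(mu_background = 5, sigma_background = 2,
                              theta = 0.3, tau_vac = 100,
                              epsilon = 0.7,
                              eta_axon = 0.4, eta_den_ex = 0.1,
                              eta_den_inh = 0,
                              sigma_gauss = 12, k_conductance = 3,
                              tau_ca = 10000, beta_ca = 0.001,
                              nu_axon = 3e-4, nu_den_ex = 6e-4,
                              nu_den_inh = 6e-4,
                              a_izh = 0.1, b_izh = 0.2, c_izh = -65,
                              d_izh = 2,
                              k0 = 144.5, k1 = 5, k2 = 0.04,
                              dt = 1, plasticity_interval = 100,
                              box_grid = c(3, 3, 3),
                              neurons_per_box = 12500,
                              ensemble_size = 333,
                              frac_inhibitory = 0.2,
                              box_edge = 50,
                              stim_amplitude = 20, stim_duration = 2000,
                              ...) {
    extra <- list(...)
    if (length(extra))
        stop("unknown parameter(s): ", paste(names(extra), collapse = ", "))
    p <- list(mu_background = mu_background,
              sigma_background = sigma_background,
              theta = theta, tau_vac = tau_vac, epsilon = epsilon,
              eta_axon = eta_axon, eta_den_ex = eta_den_ex,
              eta_den_inh = eta_den_inh, sigma_gauss = sigma_gauss,
              k_conductance = k_conductance, tau_ca = tau_ca,
              beta_ca = beta_ca, nu_axon = nu_axon,
              nu_den_ex = nu_den_ex, nu_den_inh = nu_den_inh,
              a_izh = a_izh, b_izh = b_izh, c_izh = c_izh, d_izh = d_izh,
              k0 = k0, k1 = k1, k2 = k2, dt = dt,
              plasticity_interval = plasticity_interval,
              box_grid = as.integer(box_grid),
              neurons_per_box = as.integer(neurons_per_box),
              ensemble_size = as.integer(ensemble_size),
              frac_inhibitory = frac_inhibitory, box_edge = box_edge,
              stim_amplitude = stim_amplitude,
              stim_duration = as.integer(stim_duration))
    class(p) <- "simulation_params"
    validate_params(p)
    p
}

#' Validate a parameter set
#'
#' Checks the structural invariants of a [simulation_params()] list:
#' calcium thresholds ordered `epsilon > eta_axon > eta_den_ex >=
#' eta_den_inh >= 0`, strictly positive rates and time constants, an
#' inhibitory fraction in `[0, 1)`, and ensembles that fit in a box's
#' excitatory pool.
#'
#' @param p a `"simulation_params"` list.
#' @return `p`, invisibly; errors with a descriptive message otherwise.
#' @export
validate_params <- function(p) {
    stopifnot(inherits(p, "simulation_params"))
    if (!(p$epsilon > p$eta_axon && p$eta_axon > p$eta_den_ex &&
          p$eta_den_ex >= p$eta_den_inh && p$eta_den_inh >= 0))
        stop("calcium thresholds must satisfy epsilon > eta_axon > ",
             "eta_den_ex >= eta_den_inh >= 0")
    pos <- c("nu_axon", "nu_den_ex", "nu_den_inh", "tau_vac", "tau_ca",
             "sigma_gauss", "beta_ca", "dt", "plasticity_interval",
             "box_edge")
    for (nm in pos)
        if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || p[[nm]] <= 0)
            stop("parameter '", nm, "' must be a single positive number")
    if (p$frac_inhibitory < 0 || p$frac_inhibitory >= 1)
        stop("frac_inhibitory must lie in [0, 1)")
    if (length(p$box_grid) != 3 || any(p$box_grid < 1))
        stop("box_grid must be 3 positive integers")
    if (p$sigma_background < 0)
        stop("sigma_background must be >= 0")
    if (p$theta < 0) stop("theta must be >= 0")
    n_exc_box <- (1 - p$frac_inhibitory) * p$neurons_per_box
    if (p$ensemble_size > 0 && 3 * p$ensemble_size > n_exc_box)
        stop("3 * ensemble_size (", 3 * p$ensemble_size,
             ") exceeds a box's excitatory pool (", n_exc_box, ")")
    invisible(p)
}

#' Load a run configuration from a YAML file
#'
#' Reads a YAML configuration whose keys are [simulation_params()] argument
#' names; omitted keys take the package defaults. Unknown keys and
#' invariant violations are rejected with a descriptive error, so a config
#' file cannot silently misspell a parameter.
#'
#' An empty file (or one containing only comments) yields the pure default
#' parameter set.
#'
#' @param path path to a YAML file.
#' @return A `"simulation_params"` list.
#' @export
load_config <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- yaml::read_yaml(path)
    if (is.null(cfg)) cfg <- list()
    if (!is.list(cfg)) stop("config must be a YAML mapping")
    known <- names(formals(simulation_params))
    known <- setdiff(known, "...")
    bad <- setdiff(names(cfg), known)
    if (length(bad))
        stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
    do.call(simulation_params, cfg)
}

#' Compress the slow dynamics for a desk-scale run
#'
#' Protocol scaling follows dynamical similarity: a run at scale `s`
#' multiplies every schedule step number and stimulus duration by `s`
#' (see [conditioning_schedule()]) and must compress the slow structural
#' timescales by the same factor, or the calcium excursions that drive
#' pruning and regrowth would shrink with the stimulus and the engram
#' physics would be lost. This helper rescales `tau_ca` and `tau_vac` by
#' `s`, divides `beta_ca` and the three growth rates by `s` (so the
#' calcium set-point rate `epsilon/(beta_ca * tau_ca)` and the per-step-
#' span element turnover are unchanged), and shortens
#' `plasticity_interval` proportionally (floor 1). The millisecond
#' electrical dynamics (Izhikevich constants, background, conductance)
#' are left untouched.
#'
#' @param params a [simulation_params()] list at reference scale.
#' @param scale compression factor in (0, 1].
#' @return A rescaled `"simulation_params"` list.
#' @export
scale_dynamics <- function(params, scale) {
    stopifnot(inherits(params, "simulation_params"),
              scale > 0, scale <= 1)
    params$tau_ca <- params$tau_ca * scale
    params$beta_ca <- params$beta_ca / scale
    params$tau_vac <- params$tau_vac * scale
    params$nu_axon <- params$nu_axon / scale
    params$nu_den_ex <- params$nu_den_ex / scale
    params$nu_den_inh <- params$nu_den_inh / scale
    params$plasticity_interval <-
        max(1L, as.integer(round(params$plasticity_interval * scale)))
    validate_params(params)
    params
}

#' Change the Gaussian scaling parameter of a network or parameter set
#'
#' Replaces `sigma_gauss` used by all subsequent partner selection, leaving
#' existing synapses untouched. Used by the long-distance association
#' protocol, where a larger kernel scale lets engrams in far-apart boxes
#' wire together.
#'
#' @param x a `"simulation_params"` list or an `"engram_network"`.
#' @param sigma_distant new kernel scale, > 0.
#' @return `x` with the kernel scale replaced.
#' @export
set_sigma <- function(x, sigma_distant) {
    stopifnot(is.numeric(sigma_distant), length(sigma_distant) == 1,
              sigma_distant > 0)
    if (inherits(x, "engram_network")) {
        x$params$sigma_gauss <- sigma_distant
        return(x)
    }
    stopifnot(inherits(x, "simulation_params"))
    x$sigma_gauss <- sigma_distant
    validate_params(x)
    x
}
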