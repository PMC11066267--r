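#' Save a network snapshot
#'
#' Writes the complete simulation state as a directory of plain-text
#' tables readable without the simulator: `population.tsv`, `state.tsv`
#' (membrane, recovery, calcium, last-step spikes), `elements.tsv`,
#' `synapses.tsv`, and `meta.json` (step counter, plasticity flag,
#' parameters, RNG state). Doubles are written with 17 significant
#' digits, so [load_snapshot()] reproduces the state bitwise and a
#' resumed run is identical to an uninterrupted one.
#'
#' @param net an `"engram_network"`.
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
save_snapshot <- function(net, path) {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    num <- function(x) sprintf("%.17g", x)
    w <- function(d, f) utils::write.table(d, file.path(path, f),
        sep = "\t", quote = FALSE, row.names = FALSE)
    pop <- net$pop
    pop$x <- num(pop$x); pop$y <- num(pop$y); pop$z <- num(pop$z)
    w(pop, "population.tsv")
    w(data.frame(id = seq_along(net$state$v), v = num(net$state$v),
                 u = num(net$state$u), ca = num(net$state$ca),
                 fired = net$state$fired), "state.tsv")
    w(data.frame(id = seq_len(nrow(net$elem$z)),
                 z_axon = num(net$elem$z[, 1]),
                 z_den_ex = num(net$elem$z[, 2]),
                 z_den_inh = num(net$elem$z[, 3]),
                 bound_axon = net$elem$bound[, 1],
                 bound_den_ex = net$elem$bound[, 2],
                 bound_den_inh = net$elem$bound[, 3]), "elements.tsv")
    w(data.frame(src = net$syn$src, tgt = net$syn$tgt, w = net$syn$w,
                 static = net$syn$static), "synapses.tsv")
    rng <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
    meta <- list(step = net$step, plasticity_on = net$plasticity_on,
                 params = unclass(net$params), rng_state = rng)
    jsonlite::write_json(meta, file.path(path, "meta.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    invisible(path)
}

#' Load a network snapshot
#'
#' Inverse of [save_snapshot()].
#'
#' @param path snapshot directory.
#' @param restore_rng restore the saved RNG state into the session, so a
#'   subsequent [run_simulation()] continues the interrupted random
#'   stream?
#' @return An `"engram_network"`.
#' @export
load_snapshot <- function(path, restore_rng = FALSE) {
    rd <- function(f, ...) utils::read.delim(file.path(path, f),
        stringsAsFactors = FALSE, ...)
    meta <- jsonlite::read_json(file.path(path, "meta.json"),
                                simplifyVector = TRUE)
    pars <- meta$params
    pars <- pars[names(pars) %in% setdiff(names(formals(simulation_params)), "...")]
    params <- do.call(simulation_params, pars)
    pop <- rd("population.tsv")
    st <- rd("state.tsv")
    el <- rd("elements.tsv")
    sy <- rd("synapses.tsv")
    if (nrow(sy)) {
        if (any(sy$src < 1 | sy$src > nrow(pop)) ||
            any(sy$tgt < 1 | sy$tgt > nrow(pop)))
            stop("snapshot corrupted: synapse references unknown neuron")
    }
    z <- cbind(el$z_axon, el$z_den_ex, el$z_den_inh)
    colnames(z) <- c("axon", "den_ex", "den_inh")
    bound <- cbind(el$bound_axon, el$bound_den_ex, el$bound_den_inh)
    colnames(bound) <- colnames(z)
    storage.mode(bound) <- "integer"
    net <- list(params = params, pop = pop,
                pos = cbind(pop$x, pop$y, pop$z),
                state = list(v = st$v, u = st$u, ca = st$ca,
                             fired = st$fired),
                elem = list(z = z, bound = bound),
                syn = list(src = as.integer(sy$src),
                           tgt = as.integer(sy$tgt),
                           w = as.integer(sy$w), static = sy$static),
                step = as.integer(meta$step),
                plasticity_on = isTRUE(meta$plasticity_on),
                syn_dirty = TRUE)
    class(net) <- "engram_network"
    if (restore_rng && !is.null(meta$rng_state))
        assign(".Random.seed", as.integer(meta$rng_state),
               envir = globalenv())
    net
}

#' Write a spike raster as TSV
#'
#' Two columns (`step`, `neuron_id`), optionally restricted to readouts.
#'
#' @param run an `"engram_run"`.
#' @param path output file.
#' @param readouts_only keep only readout neurons?
#' @return `path`, invisibly.
#' @export
write_raster <- function(run, path, readouts_only = FALSE) {
    sp <- run$spikes
    if (readouts_only) {
        ro <- run$net$pop$id[run$net$pop$kind == "readout"]
        sp <- sp[sp$id %in% ro, , drop = FALSE]
    }
    names(sp) <- c("step", "neuron_id")
    utils::write.table(sp, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Deterministic desk-scale test networks
#'
#' Two reference configurations used across the test-suite and example
#' protocols: `"onebox-small"` is a single box of 1,000 neurons (800
#' excitatory / 200 inhibitory) with three 50-neuron ensembles;
#' `"twobox-mini"` is two adjacent boxes of 800 neurons each with
#' 100-neuron ensembles (large enough that the readout operates in its
#' driven, low-variability regime, small enough that a stimulated
#' ensemble stays a minority of its box). Both run at a protocol
#' time-compression factor of 0.2, with the slow structural dynamics
#' compressed to match (see [scale_dynamics()] and the methods vignette
#' for why 0.2 is the strongest compression whose spike-quantisation
#' noise in the calcium integrator stays acceptable); all other
#' parameters are the package defaults.
#'
#' @param name `"onebox-small"` or `"twobox-mini"`.
#' @param seed integer seed; the same seed reproduces the fixture
#'   exactly.
#' @param scaled compress the slow dynamics by the fixture scale
#'   (default)? `FALSE` keeps the reference-scale parameters.
#' @return list with `params`, `net` (disconnected starting network),
#'   `scale`, `name`.
#' @export
make_fixture <- function(name = c("onebox-small", "twobox-mini"), seed = 1,
                         scaled = TRUE) {
    name <- match.arg(name)
    scale <- 0.2
    params <- switch(name,
        "onebox-small" = simulation_params(box_grid = c(1, 1, 1),
                                           neurons_per_box = 1000,
                                           ensemble_size = 50),
        "twobox-mini" = simulation_params(box_grid = c(2, 1, 1),
                                          neurons_per_box = 800,
                                          ensemble_size = 100))
    if (scaled) params <- scale_dynamics(params, scale)
    list(params = params, net = new_network(params, seed),
         scale = scale, name = name)
}
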