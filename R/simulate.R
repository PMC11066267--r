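#' Run a simulation
#'
#' Steps the network forward, executing an optional stimulation schedule.
#' Electrical dynamics advance every step (synaptic input from the
#' previous step's spikes, normal background drive, stimulation current,
#' Izhikevich integration with two 0.5 ms half-steps for `v` and one full
#' step for `u`, calcium update); structural plasticity runs every
#' `plasticity_interval` steps while enabled (element growth and vacancy
#' decay, pruning of excess synapses, distance-weighted matching of vacant
#' elements). Plasticity on/off events in the schedule gate all structural
#' updates; once plasticity is off the synapse table is frozen.
#'
#' All step numbers in the schedule and in the outputs are relative to the
#' start of this run (spike steps are 1-based). The run is fully
#' deterministic given `seed` and the network state.
#'
#' @param net an `"engram_network"`.
#' @param schedule a `"stim_schedule"`, or `NULL` for spontaneous
#'   dynamics.
#' @param n_steps number of steps; defaults to the schedule's end.
#' @param record which neurons enter the spike raster: `"readouts"`
#'   (default), `"all"`, `"none"`, or an integer id vector.
#' @param bin_steps bin width for the per-neuron spike-count matrix.
#' @param seed optional integer; if given, `set.seed(seed)` is called
#'   first.
#' @param trace record per-tick totals (step, synapse count, mean
#'   calcium)?
#' @param capture_at integer steps at which to capture a copy of the
#'   synapse table and calcium vector mid-run (e.g. phase boundaries).
#' @return A list of class `"engram_run"`: `net` (final state), `spikes`
#'   (data.frame `step`, `id`), `bins` (neuron x bin spike counts),
#'   `bin_steps`, `n_steps`, `trace`, `schedule`, `captures` (named by
#'   step).
#' @export
run_simulation <- function(net, schedule = NULL, n_steps = NULL,
                           record = "readouts", bin_steps = 1000,
                           seed = NULL, trace = TRUE,
                           capture_at = integer(0)) {
    stopifnot(inherits(net, "engram_network"))
    if (!is.null(seed)) set.seed(seed)
    N <- if (!is.null(n_steps)) as.integer(n_steps)
         else if (!is.null(schedule)) schedule$end
         else stop("either schedule or n_steps is required")
    if (N < 1) stop("n_steps must be >= 1")
    p <- net$params
    n <- nrow(net$pop)

    stims <- if (!is.null(schedule)) schedule$stims else
        data.frame(start = integer(0), duration = integer(0),
                   amplitude = numeric(0), target = character(0))
    plast_ev <- if (!is.null(schedule)) schedule$plasticity else
        data.frame(step = integer(0), on = logical(0))
    stim_ids <- lapply(seq_len(nrow(stims)), function(i)
        resolve_target(net$pop, stims$target[i],
                       if (!is.null(stims$ids)) stims$ids[[i]] else NULL))
    stim_end <- stims$start + stims$duration

    capture_at <- as.integer(capture_at)
    breaks <- sort(unique(c(0L, pmin(pmax(c(stims$start, stim_end,
                                            plast_ev$step, capture_at),
                                          0L), N), N)))
    captures <- list()
    record_mask <- switch(as.character(record[1]),
        readouts = net$pop$kind == "readout",
        all = rep(TRUE, n),
        none = rep(FALSE, n),
        seq_len(n) %in% as.integer(record))

    v <- net$state$v + 0
    u <- net$state$u + 0
    ca <- net$state$ca + 0
    fired <- net$state$fired & TRUE
    alive <- net$pop$alive
    bins <- matrix(0L, n, ceiling(N / bin_steps))
    csr <- build_csr(net)
    net$syn_dirty <- FALSE
    interval <- p$plasticity_interval
    trace_rows <- list()
    spk <- list()
    plastic_alive <- net$pop$plastic & alive

    do_tick <- function() {
        net$state$ca <<- ca
        net <<- structural_tick(net)
        if (isTRUE(net$syn_dirty)) {
            csr <<- build_csr(net)
            net$syn_dirty <<- FALSE
        }
        if (trace)
            trace_rows[[length(trace_rows) + 1L]] <<- c(
                step = s, n_syn = sum(!net$syn$static),
                mean_ca = mean(ca[plastic_alive]))
    }

    s <- 0L
    for (bi in seq_len(length(breaks) - 1L)) {
        b1 <- breaks[bi]; b2 <- breaks[bi + 1L]
        if (b2 <= b1) next
        if (b1 %in% capture_at)
            captures[[as.character(b1)]] <- list(syn = net$syn, ca = ca + 0)
        for (e in which(plast_ev$step == b1)) net$plasticity_on <- plast_ev$on[e]
        stim <- numeric(n)
        act <- which(stims$start <= b1 & stim_end >= b2)
        for (e in act) stim[stim_ids[[e]]] <- stim[stim_ids[[e]]] +
            stims$amplitude[e]
        while (s < b2) {
            nxt <- if (net$plasticity_on)
                min(b2, (s %/% interval + 1L) * interval) else b2
            chunk <- step_chunk_cpp(v, u, ca, fired, csr$ptr, csr$tgt,
                csr$w, stim, alive, bins, s, nxt - s, bin_steps,
                record_mask, p$a_izh, p$b_izh, p$c_izh, p$d_izh,
                p$k0, p$k1, p$k2, p$mu_background, p$sigma_background,
                p$k_conductance, p$tau_ca, p$beta_ca)
            if (length(chunk$step))
                spk[[length(spk) + 1L]] <- chunk
            s <- nxt
            if (net$plasticity_on && s %% interval == 0L && s < N) do_tick()
        }
        if (any(!is.finite(v)))
            stop("non-finite membrane potential at step ", s)
    }

    net$state <- list(v = v, u = u, ca = ca, fired = fired)
    net$step <- net$step + N
    spikes <- if (length(spk))
        data.frame(step = unlist(lapply(spk, `[[`, "step")),
                   id = unlist(lapply(spk, `[[`, "id")))
    else data.frame(step = integer(0), id = integer(0))
    tr <- if (length(trace_rows))
        as.data.frame(do.call(rbind, trace_rows))
    else data.frame(step = numeric(0), n_syn = numeric(0),
                    mean_ca = numeric(0))
    if (N %in% capture_at)
        captures[[as.character(N)]] <- list(syn = net$syn, ca = ca + 0)
    structure(list(net = net, spikes = spikes, bins = bins,
                   bin_steps = bin_steps, n_steps = N, trace = tr,
                   schedule = schedule, captures = captures),
              class = "engram_run")
}

#' @export
print.engram_run <- function(x, ...) {
    cat("<engram_run> ", x$n_steps, " steps, ", nrow(x$spikes),
        " recorded spikes, ", sum(!x$net$syn$static),
        " plastic synapses at end\n", sep = "")
    invisible(x)
}

#' Grow a network to homeostatic equilibrium
#'
#' Runs spontaneous dynamics (background drive only) with plasticity
#' enabled until the population's mean calcium is within `ca_tol` of the
#' set-point and the synapse count is stationary (relative change below
#' `syn_tol` between successive check windows), or `max_steps` is reached.
#' Starting from the fully disconnected state, neurons grow elements,
#' synapses form through distance-weighted matching, firing rates rise
#' toward the set-point rate `epsilon / (beta_ca * tau_ca)` (70 Hz under
#' the default parameters), and growth tapers off as calcium approaches
#' `epsilon`.
#'
#' @param net an `"engram_network"`.
#' @param seed optional integer seed.
#' @param max_steps hard cap on the number of steps.
#' @param check_every window (steps) between convergence checks; should be
#'   a multiple of `plasticity_interval`.
#' @param ca_tol relative calcium tolerance (default 5%).
#' @param syn_tol relative synapse-count stationarity tolerance.
#' @param verbose print progress lines?
#' @return The grown network; the per-window history is attached as
#'   attribute `"growth_history"` (data.frame `step`, `n_syn`, `mean_ca`,
#'   `rate_hz`).
#' @export
grow_network <- function(net, seed = NULL, max_steps = 400000L,
                         check_every = 25000L, ca_tol = 0.05,
                         syn_tol = 0.01, verbose = FALSE) {
    if (!is.null(seed)) set.seed(seed)
    eps <- net$params$epsilon
    hist <- list()
    prev_syn <- sum(!net$syn$static)
    done <- 0L
    while (done < max_steps) {
        run <- run_simulation(net, n_steps = check_every, record = "none",
                              bin_steps = check_every, trace = FALSE)
        net <- run$net
        done <- done + check_every
        pa <- net$pop$plastic & net$pop$alive
        mca <- mean(net$state$ca[pa])
        nsyn <- sum(!net$syn$static)
        rate <- sum(run$bins[pa, ]) / sum(pa) / check_every * 1000
        hist[[length(hist) + 1L]] <- c(step = done, n_syn = nsyn,
                                       mean_ca = mca, rate_hz = rate)
        if (verbose)
            message(sprintf("step %d: %.1f Hz, Ca %.3f, %.2f syn/neuron",
                            done, rate, mca, synapses_per_neuron(net)))
        ca_ok <- abs(mca - eps) / eps <= ca_tol
        syn_ok <- abs(nsyn - prev_syn) / max(prev_syn, 1) <= syn_tol
        prev_syn <- nsyn
        if (ca_ok && syn_ok) break
    }
    attr(net, "growth_history") <- as.data.frame(do.call(rbind, hist))
    net
}
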