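# Expensive shared objects (grown / conditioned networks) are built once
# per test session and reused across files.

.engram_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
    if (!exists(name, envir = .engram_cache))
        assign(name, force(expr), envir = .engram_cache)
    get(name, envir = .engram_cache)
}

# single box, 1,000 neurons + readout, grown to homeostatic equilibrium
grown_onebox <- function() cached("grown_onebox", {
    fx <- make_fixture("onebox-small", seed = 1)
    grow_network(fx$net, seed = 2, max_steps = 80000, check_every = 10000)
})

# two boxes of 800 neurons, grown, then run through the full three-phase
# conditioning protocol at the fixture scale; captures hold the synapse
# table at the end of the baseline and encoding phases
conditioned_twobox <- function(seed) cached(paste0("cond_twobox_", seed), {
    fx <- make_fixture("twobox-mini", seed = seed)
    net <- grow_network(fx$net, seed = seed + 1000, max_steps = 80000,
                        check_every = 10000)
    sch <- conditioning_schedule(2, net$params, scale = fx$scale)
    s45 <- as.integer(round(450000 * fx$scale))
    s65 <- as.integer(round(650000 * fx$scale))
    run <- run_simulation(net, sch, seed = seed + 2000,
                          capture_at = c(s45, s65))
    list(grown = net, run = run, sch = sch, scale = fx$scale,
         post_baseline = run$captures[[as.character(s45)]],
         post_encoding = run$captures[[as.character(s65)]])
})

# normalised within-ensemble diagonal and mean cross-ensemble entry
within_cross <- function(syn, pop) {
    M <- ensemble_connectivity(syn, pop)$normalized
    ens <- grep("^(US|C1|C2)@", rownames(M), value = TRUE)
    within <- diag(M[ens, ens, drop = FALSE])
    cross <- M[ens, ens, drop = FALSE]
    diag(cross) <- NA
    list(within = within, cross_mean = mean(cross, na.rm = TRUE))
}

# symmetrised normalised connectivity between two ensembles of one box
pair_connectivity <- function(M, a, b, box) {
    M[paste0(a, "@", box), paste0(b, "@", box)] +
        M[paste0(b, "@", box), paste0(a, "@", box)]
}
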