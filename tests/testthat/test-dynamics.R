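p0 <- simulation_params(box_grid = c(1, 1, 1), neurons_per_box = 10,
                        ensemble_size = 0)

test_that("synaptic input sums conductance-weighted spikes of the last step", {
    syn <- list(src = c(1L, 2L, 3L, 4L), tgt = c(5L, 5L, 5L, 5L),
                w = c(1L, 1L, 1L, -1L), static = rep(FALSE, 4))
    # three fired excitatory inputs at k = 3
    expect_equal(synaptic_input(syn, fired_prev = 1:3, k = 3, n = 5)[5], 9)
    # one excitatory and one inhibitory cancel
    expect_equal(synaptic_input(syn, fired_prev = c(3, 4), k = 3, n = 5)[5], 0)
    # no presynaptic spikes
    expect_equal(synaptic_input(syn, integer(0), 3, 5), rep(0, 5))
})

test_that("background drive is N(mu, sigma^2), degenerate at sigma = 0", {
    set.seed(1)
    x <- background_input(1e6, 5, 2)
    expect_lt(abs(mean(x) - 5), 3 * 2 / sqrt(1e6))
    expect_lt(abs(stats::sd(x) - 2), 0.01)
    expect_equal(background_input(10, 5, 0), rep(5, 10))
    set.seed(9); a <- background_input(100, 5, 2)
    set.seed(9); b <- background_input(100, 5, 2)
    expect_identical(a, b)
})

test_that("membrane equation and reset follow the quadratic model", {
    # canonical polynomial at rest: 0.04*65^2 - 325 + 140 + 13 = -3
    pc <- simulation_params(box_grid = c(1, 1, 1), neurons_per_box = 10,
                            ensemble_size = 0, k0 = 140)
    expect_equal(izhikevich_deriv(-65, 0.2 * -65, 0, pc), -3)
    # threshold crossing: fired, v reset to c exactly, u += d
    st <- izhikevich_step(35, 0, 0, p0)
    expect_true(st$fired)
    expect_identical(st$v, p0$c_izh)
    expect_equal(st$u, 0 + p0$d_izh)   # u increased by exactly d
    expect_error(izhikevich_step(NaN, 0, 0, p0), "non-finite")
})

test_that("sustained depolarising input elicits spiking from rest", {
    v <- -65; u <- p0$b_izh * v; fired_any <- FALSE
    for (i in 1:100) {
        st <- izhikevich_step(v, u, 20, p0)
        v <- st$v; u <- st$u
        if (st$fired) { fired_any <- TRUE; break }
    }
    expect_true(fired_any)
    # reset exactness right after any spike
    expect_identical(v, p0$c_izh)
})

test_that("calcium is a leaky spike integrator with fixed point beta*tau*p", {
    expect_equal(update_calcium(0.7, TRUE, 10000, 0.001), 0.70093)
    expect_equal(update_calcium(0, FALSE, 10000, 0.001), 0)
    # long-run mean under Bernoulli firing matches the closed form
    set.seed(4)
    for (p_fire in c(0, 0.07, 0.1)) {
        x <- stats::rbinom(2e5, 1, p_fire) * 0.001
        ca <- stats::filter(x, 1 - 1e-4, method = "recursive")
        m <- mean(ca[1e5:2e5])
        expect_lt(abs(m - 0.001 * 10000 * p_fire),
                  0.02 * max(0.001 * 10000 * p_fire, 0.05))
    }
})

test_that("compiled stepper matches the R reference step for step", {
    p <- simulation_params(box_grid = c(1, 1, 1), neurons_per_box = 40,
                           ensemble_size = 4)
    net <- new_network(p, seed = 2)
    # hand-wire some synapses so the synaptic term is exercised
    set.seed(5)
    src <- sample(which(net$pop$plastic), 60, replace = TRUE)
    tgt <- sample(which(net$pop$plastic), 60, replace = TRUE)
    keep <- src != tgt
    src <- src[keep]; tgt <- tgt[keep]
    w <- ifelse(net$pop$kind[src] == "exc", 1L, -1L)
    net$syn <- list(src = c(net$syn$src, src), tgt = c(net$syn$tgt, tgt),
                    w = c(net$syn$w, w),
                    static = c(net$syn$static, rep(FALSE, length(src))))
    n <- nrow(net$pop)
    n_steps <- 50

    set.seed(77)
    run <- run_simulation(net, n_steps = n_steps, record = "all",
                          bin_steps = n_steps, trace = FALSE)

    # R reference trajectory with the identical RNG stream
    set.seed(77)
    v <- net$state$v; u <- net$state$u; ca <- net$state$ca
    fired <- net$state$fired
    spikes <- list()
    for (s in seq_len(n_steps)) {
        isyn <- synaptic_input(net$syn, which(fired), p$k_conductance, n)
        bg <- background_input(n, p$mu_background, p$sigma_background)
        st <- izhikevich_step(v, u, isyn + bg, p)
        v <- st$v; u <- st$u; fired <- st$fired
        ca <- update_calcium(ca, fired, p$tau_ca, p$beta_ca)
        if (any(fired)) spikes[[length(spikes) + 1]] <-
            data.frame(step = s, id = which(fired))
    }
    ref <- do.call(rbind, spikes)
    expect_equal(run$spikes$step, ref$step)
    expect_equal(run$spikes$id, ref$id)
    expect_equal(run$net$state$v, v)
    expect_equal(run$net$state$ca, ca)
})
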