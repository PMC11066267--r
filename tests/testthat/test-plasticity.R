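p_tab <- simulation_params()   # reference parameter set

test_that("growth curve vanishes at eta and epsilon and peaks at their midpoint", {
    kinds <- list(c(p_tab$eta_axon, p_tab$nu_axon),
                  c(p_tab$eta_den_ex, p_tab$nu_den_ex),
                  c(p_tab$eta_den_inh, p_tab$nu_den_inh))
    for (k in kinds) {
        eta <- k[1]; nu <- k[2]
        expect_equal(growth_rate(eta, eta, 0.7, nu), 0)
        expect_equal(growth_rate(0.7, eta, 0.7, nu), 0)
        xi <- (eta + 0.7) / 2
        expect_equal(growth_rate(xi, eta, 0.7, nu), nu)
        # negative outside [eta, epsilon], positive inside
        expect_lt(growth_rate(eta - 0.05, eta + 0.001, 0.7, nu), 0)
        expect_lt(growth_rate(0.9, eta, 0.7, nu), 0)
        expect_gt(growth_rate(xi + 0.05, eta, 0.7, nu), 0)
    }
    # direct evaluation far below eta approaches -nu
    expect_equal(growth_rate(0, 0.4, 0.7, 3e-4), -2.9995e-4,
                 tolerance = 1e-4)
})

test_that("element integration applies growth and vacancy decay per interval", {
    z <- matrix(c(2, 0, 0), 1, 3)
    bound <- matrix(0L, 1, 3)
    # vacant = 2, tau_vac = 100, growth 0 (Ca at epsilon), interval 1
    zn <- update_elements(z, bound, ca = 0.7, p_tab, interval = 1)
    expect_equal(zn[1, 1], 2 - 0.02)
    # no vacancy, Ca at set-point: unchanged
    z2 <- matrix(c(3, 3, 3), 1, 3)
    b2 <- matrix(3L, 1, 3)
    expect_equal(update_elements(z2, b2, 0.7, p_tab, 1), z2,
                 ignore_attr = TRUE)
    # fractional surplus below the next integer is not yet vacant
    z3 <- matrix(c(3.4, 0, 0), 1, 3)
    b3 <- matrix(c(3L, 0L, 0L), 1, 3)
    zn3 <- update_elements(z3, b3, 0.7, p_tab, 1)
    expect_equal(zn3[1, 1], 3.4)
    # inactive rows are frozen
    zn4 <- update_elements(z, bound, 0.7, p_tab, 1, active = FALSE)
    expect_equal(zn4, z, ignore_attr = TRUE)
})

test_that("excess synapses are pruned exactly and uniformly at random", {
    # one neuron with 5 outgoing synapses but only floor(z) = 3 axons
    mk <- function() {
        syn <- list(src = rep(1L, 5), tgt = 2:6, w = rep(1L, 5),
                    static = rep(FALSE, 5))
        z <- matrix(0, 6, 3); z[1, 1] <- 3.9; z[2:6, 2] <- 1
        bound <- matrix(0L, 6, 3); bound[1, 1] <- 5L; bound[2:6, 2] <- 1L
        list(syn = syn, z = z, bound = bound)
    }
    s <- mk()
    out <- prune_excess(s$syn, s$z, s$bound)
    expect_equal(out$n_removed, 2L)
    expect_equal(length(out$syn$src), 3L)
    expect_equal(out$bound[1, 1], 3L)
    # partner elements freed regardless of the partner's own z
    expect_equal(sum(out$bound[2:6, 2]), 3L)
    # no deficit anywhere: table unchanged
    ok <- prune_excess(out$syn, s$z, out$bound)
    expect_equal(ok$n_removed, 0L)
    expect_identical(ok$syn$tgt, out$syn$tgt)
    # uniformity over many repetitions (chi-square)
    set.seed(31)
    kept <- integer(5)
    for (r in 1:10000) {
        s <- mk()
        s$z[1, 1] <- 4.2   # remove exactly one of five
        res <- prune_excess(s$syn, s$z, s$bound)
        gone <- setdiff(2:6, res$syn$tgt)
        kept[gone - 1L] <- kept[gone - 1L] + 1L
    }
    expect_gt(stats::chisq.test(kept)$p.value, 0.01)
})

test_that("kernel weight is the Gaussian of distance", {
    expect_equal(kernel_weight(c(0, 0, 0), c(0, 0, 0), 12), 1)
    expect_equal(kernel_weight(c(0, 0, 0), c(12, 0, 0), 12), exp(-0.5))
    # long-distance mode: sigma >> distance makes weights approach 1
    expect_gt(kernel_weight(c(0, 0, 0), c(50, 50, 50), 1e4), 0.999)
    # vectorised over a candidate matrix
    m <- rbind(c(12, 0, 0), c(0, 0, 0))
    expect_equal(kernel_weight(c(0, 0, 0), m, 12), c(exp(-0.5), 1))
})

test_that("exact partner selection weights candidates by vacancy and distance", {
    pos <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(50, 50, 50))
    # single candidate: always chosen
    set.seed(1)
    expect_equal(select_partner_exact(1L, 2L, 1, pos, 12), 2L)
    # empty candidate set: no-match signal
    expect_identical(select_partner_exact(1L, integer(0), numeric(0), pos, 12),
                     NA_integer_)
    # source excluded even if listed
    expect_equal(select_partner_exact(1L, c(1L, 2L), c(5, 1), pos, 12), 2L)
    # two equidistant candidates, equal vacancies: 50/50 within binomial CI
    set.seed(2)
    draws <- replicate(1e4, select_partner_exact(1L, c(2L, 3L), c(1, 1),
                                                 pos, 12))
    p2 <- mean(draws == 2L)
    expect_lt(abs(p2 - 0.5), 2.58 * sqrt(0.25 / 1e4))
    # vacancies 2 vs 1: first chosen ~2/3 of the time
    set.seed(3)
    draws <- replicate(1e4, select_partner_exact(1L, c(2L, 3L), c(2, 1),
                                                 pos, 12))
    p2 <- mean(draws == 2L)
    expect_lt(abs(p2 - 2 / 3), 2.58 * sqrt(2 / 9 / 1e4))
})

test_that("matching commits the only legal synapses and conserves elements", {
    p <- simulation_params(box_grid = c(1, 1, 1), neurons_per_box = 2,
                           ensemble_size = 0, frac_inhibitory = 0)
    net <- new_network(p, seed = 1)
    # two excitatory neurons, each one vacant axon and one vacant
    # excitatory dendrite: exactly two synapses form, one each way
    net$elem$z[1:2, 1] <- 1
    net$elem$z[1:2, 2] <- 1
    set.seed(5)
    net2 <- connectivity_update(net)
    syn <- synapse_table(net2, static = FALSE)
    expect_equal(nrow(syn), 2)
    expect_setequal(paste(syn$src, syn$tgt), c("1 2", "2 1"))
    expect_true(all(syn$src != syn$tgt))
    verify_network(net2)
    # no vacant dendrites anywhere: nothing forms
    net$elem$z[, 2:3] <- 0
    net3 <- connectivity_update(net)
    expect_equal(nrow(synapse_table(net3, static = FALSE)), 0)
})

test_that("structural conservation holds through growth from empty", {
    p <- scale_dynamics(
        simulation_params(box_grid = c(1, 1, 1), neurons_per_box = 150,
                          ensemble_size = 10), 0.1)
    net <- new_network(p, seed = 4)
    run <- run_simulation(net, n_steps = 6000, record = "none", seed = 6,
                          trace = FALSE)
    net <- run$net
    expect_gt(sum(!net$syn$static), 0)
    verify_network(net)
    b <- net$elem$bound
    expect_equal(sum(b[, 1]), sum(!net$syn$static))
    expect_equal(sum(b[, 2]) + sum(b[, 3]), sum(!net$syn$static))
})
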