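test_that("binned rates convert counts at 1 ms steps", {
    sp <- data.frame(step = c(rep(1:600, 1), 1500), id = c(rep(7L, 600), 7L))
    tr <- bin_firing_rates(sp, bin_steps = 1000, n_steps = 2000, ids = 7L)
    expect_equal(tr$rate[1, 1], 600)   # 600 spikes in a 1,000-step bin
    expect_equal(tr$rate[2, 1], 1)
    # one spike every step saturates at 1000 Hz
    sp2 <- data.frame(step = 1:3000, id = 1L)
    tr2 <- bin_firing_rates(sp2, 1000, 3000, ids = 1L)
    expect_equal(as.vector(tr2$rate), rep(1000, 3))
    # empty raster: all-zero trace
    tr3 <- bin_firing_rates(data.frame(step = integer(0), id = integer(0)),
                            1000, 3000, ids = 1L)
    expect_equal(as.vector(tr3$rate), rep(0, 3))
})

test_that("sliding rates agree with direct window counts", {
    set.seed(12)
    steps <- sort(sample(1:5000, 400))
    sp <- data.frame(step = steps, id = 3L)
    tr <- sliding_rates(sp, window = 500, slide = 100, n_steps = 5000,
                        ids = 3L)
    for (k in c(1, 10, 37, length(tr$start))) {
        lo <- tr$start[k]
        direct <- sum(steps > lo & steps <= lo + 500)
        expect_equal(tr$rate[k, 1], direct * 2)
    }
})

test_that("KS check accepts normal rates and rejects bimodal ones", {
    set.seed(30)
    ok <- 0
    for (r in 1:100) {
        p <- ks_normality(stats::rnorm(1000, 600, 30))
        if (p > 0.05) ok <- ok + 1
    }
    expect_gte(ok, 90)
    bimodal <- c(stats::rnorm(500, 300, 10), stats::rnorm(500, 900, 10))
    expect_lt(ks_normality(bimodal), 0.01)
    expect_error(ks_normality(rep(5, 100)), "zero-variance")
    expect_error(ks_normality(stats::rnorm(10)), "at least 20")
})

test_that("3-sigma classification respects the band and the persistence rule", {
    mk_trace <- function(rates, window = 100, slide = 100)
        structure(list(rate = matrix(rates, ncol = 1),
                       start = (seq_along(rates) - 1L) * slide,
                       window = window, slide = slide, ids = 1L),
                  class = "rate_trace")
    bl <- list(mu = 600, sigma = 30)   # band [510, 690]
    # 700 Hz sustained over 600 steps: one increased interval
    tr <- mk_trace(c(rep(600, 10), rep(700, 6), rep(600, 10)))
    cl <- classify_rate(tr, bl, min_duration = 500)
    expect_equal(cl$label, c("normal", "increased", "normal"))
    expect_equal(cl$start[2], 1000)
    # the same excursion lasting only 300 steps folds into normal
    tr2 <- mk_trace(c(rep(600, 10), rep(700, 3), rep(600, 10)))
    cl2 <- classify_rate(tr2, bl, min_duration = 500)
    expect_equal(cl2$label, "normal")
    expect_equal(nrow(cl2), 1)
    # constant at the mean: single normal interval covering the span
    cl3 <- classify_rate(mk_trace(rep(600, 20)), bl, 500)
    expect_equal(cl3$label, "normal")
    # below the band: decreased
    tr4 <- mk_trace(c(rep(600, 5), rep(400, 7), rep(600, 5)))
    expect_true("decreased" %in% classify_rate(tr4, bl, 500)$label)
    # intervals partition the span
    expect_equal(cl$start[-1], cl$end[-nrow(cl)])
    # min_duration = 0 yields a superset of abnormal intervals
    cl5 <- classify_rate(tr2, bl, min_duration = 0)
    expect_true("increased" %in% cl5$label)
})

test_that("for near-normal noise the band catches ~0.3% of windows before filtering", {
    set.seed(44)
    rates <- stats::rnorm(20000, 600, 30)
    bl <- list(mu = mean(rates), sigma = stats::sd(rates))
    frac <- mean(rates > bl$mu + 3 * bl$sigma | rates < bl$mu - 3 * bl$sigma)
    expect_lt(frac, 0.006)
    expect_gt(frac, 0.0005)
})

test_that("validity check matches increased intervals to expected windows", {
    exp_w <- data.frame(start = c(1000, 5000), end = c(1500, 5500))
    good <- data.frame(start = c(0, 1010, 1510, 4990, 5490),
                       end = c(1010, 1510, 4990, 5490, 9000),
                       label = c("normal", "increased", "normal",
                                 "increased", "normal"))
    expect_true(validity_check(good, exp_w, tolerance = 100)$pass)
    # an extra increased interval elsewhere fails
    bad <- rbind(good, data.frame(start = 7000, end = 7600,
                                  label = "increased"))
    vc <- validity_check(bad, exp_w, tolerance = 100)
    expect_false(vc$pass)
    expect_equal(nrow(vc$unexpected), 1)
    # a missing response fails
    vc2 <- validity_check(good[1:3, ], exp_w, tolerance = 100)
    expect_false(vc2$pass)
    expect_equal(nrow(vc2$missing), 1)
    # vacuous pass: nothing expected, nothing abnormal
    none <- data.frame(start = 0, end = 9000, label = "normal")
    empty <- data.frame(start = numeric(0), end = numeric(0))
    expect_true(validity_check(none, empty, 100)$pass)
})

test_that("ensemble connectivity normalises by group sizes and is invertible", {
    p <- simulation_params(box_grid = c(1, 1, 1), neurons_per_box = 40,
                           ensemble_size = 3)
    pop <- build_population(p, seed = 6)
    us <- pop$id[pop$ensemble == "US"][1:3]
    c1 <- pop$id[pop$ensemble == "C1"][1:2]
    # empty table: zero matrix
    e0 <- ensemble_connectivity(list(src = integer(0), tgt = integer(0),
                                     w = integer(0), static = logical(0)),
                                pop)
    expect_true(all(e0$normalized == 0))
    # 2 synapses from a 3-neuron US into a 2-neuron C1 subgroup
    syn <- list(src = us[1:2], tgt = c1[1:2], w = c(1L, 1L),
                static = c(FALSE, FALSE))
    ec <- ensemble_connectivity(syn, pop)
    expect_equal(ec$counts["US@0", "C1@0"], 2)
    expect_equal(ec$normalized["US@0", "C1@0"], 2 / (3 * 3))
    # multiplying back by |A||B| and summing recovers the synapse count
    sz <- ec$sizes
    expect_equal(sum(ec$normalized * outer(sz, sz)), 2)
    # static synapses excluded
    syn$static <- c(TRUE, TRUE)
    expect_true(all(ensemble_connectivity(syn, pop)$counts == 0))
})
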