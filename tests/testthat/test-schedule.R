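p27 <- simulation_params()   # 27-box reference layout

test_that("conditioning schedule reproduces the reference timeline", {
    sch <- conditioning_schedule(27, p27, scale = 1)
    st <- sch$stims
    # phases stimulate US, C1, C2 at the documented steps
    expect_equal(st$start[st$phase == "baseline"],
                 c(150000, 250000, 350000))
    expect_equal(sort(unique(st$start[st$phase == "encoding"])),
                 c(450000, 550000))
    # retrieval: 27 single-C1 events plus one all-C2 event
    ret <- st[st$phase == "retrieval", ]
    expect_equal(nrow(ret), 28)
    expect_equal(ret$start[ret$target == "C2@*"], 1190000)
    expect_equal(max(ret$start[ret$target != "C2@*"]), 1170000)
    expect_true(all(st$duration == 2000))
    expect_true(all(st$amplitude == 20))
    # plasticity switched off at the start of retrieval
    expect_equal(sch$plasticity$step, 650000)
    expect_false(sch$plasticity$on)
})

test_that("scale multiplies step numbers and durations alike", {
    s1 <- conditioning_schedule(2, p27, scale = 1)
    s01 <- conditioning_schedule(2, p27, scale = 0.1)
    expect_equal(s01$stims$start, as.integer(round(s1$stims$start * 0.1)))
    expect_equal(s01$stims$duration, rep(200L, nrow(s01$stims)))
    expect_equal(s01$plasticity$step, 65000L)
    expect_error(conditioning_schedule(2, p27, scale = 1e-5),
                 "too small")
})

test_that("pattern-completion subsets are nested cumulative ceilings", {
    p <- simulation_params(box_grid = c(1, 1, 1), neurons_per_box = 1250,
                           ensemble_size = 333)
    pop <- build_population(p, seed = 2)
    sch <- pattern_completion_schedule(pop, box = 0, p, scale = 1, seed = 9)
    expect_equal(nrow(sch$stims), 20)
    expect_equal(sch$stims$fraction, seq(0.05, 1, by = 0.05))
    sizes <- lengths(sch$stims$ids)
    expect_equal(sizes, ceiling(seq(0.05, 1, 0.05) * 333))
    expect_equal(sizes[9], 150)   # 45% of 333 stimulated neurons
    # nested: earlier subsets always contained in later ones
    for (k in 2:20)
        expect_true(all(sch$stims$ids[[k - 1]] %in% sch$stims$ids[[k]]))
    # at 100% the stimulated set is the whole ensemble
    expect_setequal(sch$stims$ids[[20]],
                    pop$id[pop$ensemble == "C1" & pop$box_id == 0])
})

test_that("expected readout windows are the three own-box events", {
    sch <- conditioning_schedule(3, p27, scale = 1)
    w <- expected_readout_windows(sch, box = 1)
    expect_equal(nrow(w), 3)
    expect_equal(w$start, c(150000, 450000, 650000 + 20000))
    expect_equal(w$phase, c("baseline", "encoding", "retrieval"))
})

test_that("long-distance association stimulates the two chosen boxes jointly", {
    sch <- long_distance_schedule(c(0, 25), p27, scale = 1)
    st <- sch$stims
    joint <- st[st$start == 150000, ]
    expect_setequal(joint$target, c("US@0", "C1@0", "US@25", "C1@25"))
    expect_equal(st$start[st$target == "C2@*"], 520000)
    expect_equal(sch$plasticity$step, 250000)
    # enlarging the kernel scale leaves existing synapses untouched
    p <- simulation_params(box_grid = c(2, 1, 1), neurons_per_box = 100,
                           ensemble_size = 10)
    net <- new_network(p, seed = 1)
    net$elem$z[1:200, 1:2] <- 1
    set.seed(2)
    net <- connectivity_update(net)
    wide <- set_sigma(net, 10 * p$sigma_gauss)
    expect_identical(wide$syn, net$syn)
    expect_equal(wide$params$sigma_gauss, 120)
})

test_that("lesions select the nearest fraction and keep referential integrity", {
    p <- simulation_params(box_grid = c(1, 1, 1), neurons_per_box = 200,
                           ensemble_size = 20)
    net <- new_network(p, seed = 3)
    net$elem$z[1:200, ] <- 2
    set.seed(4)
    net <- connectivity_update(net)
    n0 <- sum(!net$syn$static)
    expect_gt(n0, 0)
    # fraction 0: unchanged
    un <- apply_lesion(net, 0, scope = "box", mode = "connections", seed = 1)
    expect_identical(un$syn, net$syn)
    # connections-only: neurons keep position and plastic flag
    le <- apply_lesion(net, 0.5, scope = "ensemble", ensemble = "C1",
                       mode = "connections", seed = 2)
    sel <- attr(le, "lesioned")[["0"]]
    expect_equal(length(sel), 10)
    expect_true(all(le$pop$plastic[sel]))
    expect_equal(sum(le$syn$src %in% sel | le$syn$tgt %in% sel), 0)
    verify_network(le)
    # full removal of a box empties it and leaves no dangling synapse
    rm_all <- apply_lesion(net, 1, scope = "box", mode = "remove", seed = 3)
    expect_equal(sum(rm_all$pop$alive & rm_all$pop$plastic), 0)
    expect_equal(sum(!rm_all$syn$static), 0)
    verify_network(rm_all)
})
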