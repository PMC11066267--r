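#' Binned firing rates from a spike raster
#'
#' Splits the run into consecutive bins of `bin_steps` steps and converts
#' per-bin spike counts to rates in Hz (`count * 1000 / bin_steps` at 1 ms
#' steps, so one spike per step is 1000 Hz).
#'
#' @param spikes data.frame with `step` (1-based), `id`.
#' @param bin_steps bin width in steps, >= 1.
#' @param n_steps run length (defines the number of bins).
#' @param ids neurons to tabulate (default: all ids present).
#' @return A `"rate_trace"`: list with `rate` (bins x ids matrix), `start`
#'   (bin start steps, 0-based), `window`, `slide`, `ids`.
#' @export
bin_firing_rates <- function(spikes, bin_steps, n_steps, ids = NULL) {
    stopifnot(bin_steps >= 1)
    if (is.null(ids)) ids <- sort(unique(spikes$id))
    nb <- n_steps %/% bin_steps
    rate <- matrix(0, nb, length(ids))
    if (nrow(spikes) && nb > 0) {
        sel <- spikes$id %in% ids & spikes$step <= nb * bin_steps
        b <- (spikes$step[sel] - 1L) %/% bin_steps + 1L
        j <- match(spikes$id[sel], ids)
        for (k in seq_along(b)) rate[b[k], j[k]] <- rate[b[k], j[k]] + 1
        rate <- rate * (1000 / bin_steps)
    }
    structure(list(rate = rate, start = (seq_len(nb) - 1L) * bin_steps,
                   window = bin_steps, slide = bin_steps, ids = ids),
              class = "rate_trace")
}

#' Sliding-window firing rates
#'
#' Rates over overlapping windows of `window` steps advanced by `slide`
#' steps, used for the 3-sigma classification where a persistence rule
#' cannot be evaluated on coarse disjoint bins.
#'
#' @inheritParams bin_firing_rates
#' @param window window width (steps).
#' @param slide stride between window starts (steps).
#' @return A `"rate_trace"` (see [bin_firing_rates()]).
#' @export
sliding_rates <- function(spikes, window, slide, n_steps, ids = NULL) {
    stopifnot(window >= 1, slide >= 1)
    if (is.null(ids)) ids <- sort(unique(spikes$id))
    starts <- seq(0L, max(n_steps - window, 0L), by = slide)
    rate <- matrix(0, length(starts), length(ids))
    for (j in seq_along(ids)) {
        st <- spikes$step[spikes$id == ids[j]]
        if (!length(st)) next
        cum <- cumsum(tabulate(st, n_steps))
        hi <- pmin(starts + window, n_steps)
        cl <- numeric(length(starts))
        pos <- starts > 0
        cl[pos] <- cum[starts[pos]]
        rate[, j] <- (cum[hi] - cl) * (1000 / window)
    }
    structure(list(rate = rate, start = starts, window = window,
                   slide = slide, ids = ids), class = "rate_trace")
}

#' Baseline firing statistics over an unstimulated span
#'
#' Mean and standard deviation of a neuron's rate over the windows fully
#' contained in `interval`, used as the reference for the 3-sigma rule.
#'
#' @param trace a `"rate_trace"`.
#' @param interval length-2 step interval `[lo, hi)`.
#' @param id neuron id (must be in `trace$ids`).
#' @return list(mu, sigma) in Hz.
#' @export
rate_baseline <- function(trace, interval, id) {
    j <- match(id, trace$ids)
    if (is.na(j)) stop("id ", id, " not in trace")
    sel <- trace$start >= interval[1] & (trace$start + trace$window) <= interval[2]
    if (sum(sel) < 2) stop("baseline interval holds fewer than 2 windows")
    r <- trace$rate[sel, j]
    list(mu = mean(r), sigma = stats::sd(r))
}

#' Kolmogorov-Smirnov normality check of firing rates
#'
#' One-sample KS test of the rates against a normal distribution with
#' their own sample mean and standard deviation, as used to justify the
#' 3-sigma rule on readout rates.
#'
#' @param rates numeric vector of at least 20 binned rates.
#' @return The KS p-value.
#' @export
ks_normality <- function(rates) {
    if (length(rates) < 20) stop("need at least 20 rate bins")
    s <- stats::sd(rates)
    if (!is.finite(s) || s <= 0) stop("zero-variance rates: KS test undefined")
    suppressWarnings(
        stats::ks.test(rates, "pnorm", mean(rates), s)$p.value)
}

#' 3-sigma classification of a rate trace
#'
#' Labels every window of the trace as `increased` (rate above
#' `mu + 3 sigma`), `decreased` (below `mu - 3 sigma`) or `normal`, merges
#' consecutive equal labels into maximal intervals, and folds abnormal
#' intervals shorter than `min_duration` steps back into the surrounding
#' normal state. The returned intervals partition the analysed span.
#'
#' @param trace a `"rate_trace"`.
#' @param baseline list(mu, sigma) from [rate_baseline()].
#' @param min_duration minimum persistence (steps) of an abnormal
#'   excursion.
#' @param id neuron id.
#' @return data.frame `start`, `end`, `label`.
#' @export
classify_rate <- function(trace, baseline, min_duration = 500, id = trace$ids[1]) {
    j <- match(id, trace$ids)
    if (is.na(j)) stop("id ", id, " not in trace")
    r <- trace$rate[, j]
    lab <- rep("normal", length(r))
    lab[r > baseline$mu + 3 * baseline$sigma] <- "increased"
    lab[r < baseline$mu - 3 * baseline$sigma] <- "decreased"
    merge_labels(trace$start, trace$window, trace$slide, lab, min_duration)
}

merge_labels <- function(starts, window, slide, lab, min_duration) {
    if (!length(lab))
        return(data.frame(start = numeric(0), end = numeric(0),
                          label = character(0)))
    runs <- rle(lab)
    hi <- cumsum(runs$lengths)
    lo <- hi - runs$lengths + 1L
    iv <- data.frame(start = starts[lo], end = starts[hi] + window,
                     label = runs$values, stringsAsFactors = FALSE)
    # overlapping windows smear a brief excursion over a full window
    # width; the run of abnormal window *starts* estimates its true
    # duration, and the persistence rule filters on that
    excursion <- starts[hi] - starts[lo] + slide
    short <- iv$label != "normal" & excursion < min_duration
    iv$label[short] <- "normal"
    runs2 <- rle(iv$label)
    hi2 <- cumsum(runs2$lengths)
    lo2 <- hi2 - runs2$lengths + 1L
    out <- data.frame(start = iv$start[lo2], end = iv$end[hi2],
                      label = runs2$values, stringsAsFactors = FALSE)
    # overlapping windows can make adjacent intervals overlap; clip
    if (nrow(out) > 1)
        out$end[-nrow(out)] <- pmin(out$end[-nrow(out)], out$start[-1])
    out
}

#' Expected readout-response windows of a conditioning run
#'
#' A box's readout neuron is expected to fire at a significantly
#' increased rate exactly when its own US ensemble is stimulated during
#' the baseline phase, when its US (together with C1) is stimulated
#' during encoding, and when its own C1 is stimulated during retrieval.
#'
#' @param schedule a conditioning `"stim_schedule"`.
#' @param box box id of the readout.
#' @return data.frame `start`, `end`, `phase`.
#' @export
expected_readout_windows <- function(schedule, box) {
    st <- schedule$stims
    sel <- (st$phase %in% c("baseline", "encoding") & st$target == "US@*") |
           (st$phase == "retrieval" & st$target == paste0("C1@", box))
    data.frame(start = st$start[sel], end = st$start[sel] + st$duration[sel],
               phase = st$phase[sel], stringsAsFactors = FALSE)
}

#' Validity check of classified readout activity
#'
#' Passes a readout if and only if each expected window is matched by one
#' significantly-increased interval whose start and end both align within
#' `tolerance` steps, and no unexpected increased interval occurs. With no
#' expected windows and no increased intervals the check passes vacuously.
#'
#' @param classified data.frame from [classify_rate()].
#' @param expected data.frame of expected windows
#'   ([expected_readout_windows()]).
#' @param tolerance alignment tolerance in steps. Rate estimates smear a
#'   response by up to one window width, so protocol-level wrappers pass
#'   the scaled 100-step allowance plus the estimation window.
#' @return list(pass, matched, unexpected, missing).
#' @export
validity_check <- function(classified, expected, tolerance = 100) {
    inc <- classified[classified$label == "increased", , drop = FALSE]
    matched <- logical(nrow(expected))
    used <- logical(nrow(inc))
    for (k in seq_len(nrow(expected))) {
        ok <- which(!used &
                    abs(inc$start - expected$start[k]) <= tolerance &
                    abs(inc$end - expected$end[k]) <= tolerance)
        if (length(ok)) {
            matched[k] <- TRUE
            used[ok[1]] <- TRUE
        }
    }
    list(pass = all(matched) && all(used),
         matched = matched,
         unexpected = inc[!used, , drop = FALSE],
         missing = expected[!matched, , drop = FALSE])
}

#' Classify and validity-check every readout of a protocol run
#'
#' Convenience wrapper: estimates each readout's sliding-window rates,
#' takes the baseline statistics from the schedule's unstimulated window,
#' classifies with the 3-sigma rule, and checks the increased intervals
#' against the expected windows. Window, stride, persistence and
#' tolerance default to the reference values (500 / 100 / 500 / 100
#' steps) multiplied by the schedule's scale, with floors of 100 / 5
#' steps so that scaled-down runs retain enough spikes per window for a
#' stable rate estimate.
#'
#' @param run an `"engram_run"` whose raster includes the readouts.
#' @param schedule the schedule the run executed (defaults to the run's).
#' @param window,slide,min_duration,tolerance analysis parameters
#'   (steps); `NULL` for the scaled defaults.
#' @return data.frame, one row per readout: `id`, `box`, `mu`, `sigma`,
#'   `pass`, `n_increased`; the per-readout interval tables are attached
#'   as attribute `"intervals"`.
#' @export
classify_readouts <- function(run, schedule = run$schedule,
                              window = NULL, slide = NULL,
                              min_duration = NULL, tolerance = NULL) {
    if (is.null(schedule)) stop("run has no schedule")
    s <- schedule$scale
    if (is.null(window)) window <- max(100L, as.integer(round(500 * s)))
    if (is.null(slide)) slide <- max(5L, as.integer(round(100 * s)))
    if (is.null(min_duration)) min_duration <- as.integer(round(500 * s))
    if (is.null(tolerance))
        tolerance <- as.integer(round(100 * s)) + window
    pop <- run$net$pop
    ro <- pop[pop$kind == "readout", ]
    trace <- sliding_rates(run$spikes, window, slide, run$n_steps,
                           ids = ro$id)
    res <- data.frame(id = ro$id, box = ro$box_id, mu = NA_real_,
                      sigma = NA_real_, pass = NA, n_increased = NA_integer_)
    ivs <- list()
    for (k in seq_len(nrow(ro))) {
        bl <- rate_baseline(trace, schedule$baseline_window, ro$id[k])
        cl <- classify_rate(trace, bl, min_duration, id = ro$id[k])
        exp_w <- expected_readout_windows(schedule, ro$box_id[k])
        vc <- validity_check(cl, exp_w, tolerance)
        res$mu[k] <- bl$mu
        res$sigma[k] <- bl$sigma
        res$pass[k] <- vc$pass
        res$n_increased[k] <- sum(cl$label == "increased")
        ivs[[as.character(ro$id[k])]] <- cl
    }
    attr(res, "intervals") <- ivs
    res
}

#' Ensemble-to-ensemble connectivity matrix
#'
#' Counts plastic synapses between neuron groups and normalises each
#' entry by the product of the two group sizes. Groups are the labelled
#' ensembles per box (`US@b`, `C1@b`, `C2@b`) and the remaining plastic
#' neurons of each box (`O@b`). Static readout synapses are excluded.
#'
#' @param syn a synapse table (data.frame or list with `src`, `tgt`,
#'   `static`).
#' @param pop a population table.
#' @param boxes restrict to these box ids (default: all).
#' @return list of class `"ensemble_connectivity"`: `normalized` and
#'   `counts` matrices plus the group `sizes`.
#' @export
ensemble_connectivity <- function(syn, pop, boxes = NULL) {
    grp <- ifelse(pop$ensemble == "none", "O", pop$ensemble)
    grp <- paste0(grp, "@", pop$box_id)
    grp[pop$kind == "readout" | !pop$alive] <- NA
    if (!is.null(boxes)) grp[!(pop$box_id %in% boxes)] <- NA
    keep_boxes <- if (is.null(boxes)) sort(unique(pop$box_id)) else sort(boxes)
    levels <- as.vector(t(outer(keep_boxes, c("US", "C1", "C2", "O"),
                                function(b, e) paste0(e, "@", b))))
    levels <- levels[levels %in% grp[!is.na(grp)]]
    sizes <- table(factor(grp, levels = levels))
    cnt <- matrix(0, length(levels), length(levels),
                  dimnames = list(levels, levels))
    ns <- !syn$static
    ga <- factor(grp[syn$src[ns]], levels = levels)
    gb <- factor(grp[syn$tgt[ns]], levels = levels)
    ok <- !is.na(ga) & !is.na(gb)
    if (any(ok)) cnt <- unclass(table(ga[ok], gb[ok]))
    norm <- cnt / outer(as.numeric(sizes), as.numeric(sizes))
    structure(list(normalized = norm, counts = cnt,
                   sizes = as.numeric(sizes)),
              class = "ensemble_connectivity")
}
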