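#' Stimulation schedules
#'
#' A schedule holds timed current injections onto named neuron sets plus
#' plasticity on/off control events. Times are steps relative to the start
#' of the run that executes the schedule. Targets are strings
#' `"<ensemble>@<box>"` (`box = "*"` for all boxes) resolved against the
#' population at run time, or `"ids"` with explicit neuron ids in the
#' `ids` list-column.
#'
#' @param stims data.frame with `start`, `duration`, `amplitude`,
#'   `target`, `phase` (and optionally a list-column `ids`).
#' @param plasticity data.frame with `step`, `on` (logical) control
#'   events.
#' @param end last step of the run.
#' @param scale protocol time-compression factor the times were built
#'   with (metadata).
#' @param baseline_window length-2 step interval used to estimate the
#'   unstimulated readout baseline, or `NULL`.
#' @return An object of class `"stim_schedule"`.
#' @export
stim_schedule <- function(stims = NULL, plasticity = NULL, end,
                          scale = 1, baseline_window = NULL) {
    if (is.null(stims))
        stims <- data.frame(start = integer(0), duration = integer(0),
                            amplitude = numeric(0), target = character(0),
                            phase = character(0), stringsAsFactors = FALSE)
    if (is.null(plasticity))
        plasticity <- data.frame(step = integer(0), on = logical(0))
    stopifnot(all(stims$duration > 0), end >= 0)
    sch <- list(stims = stims, plasticity = plasticity,
                end = as.integer(end), scale = scale,
                baseline_window = baseline_window)
    class(sch) <- "stim_schedule"
    sch
}

#' @export
print.stim_schedule <- function(x, ...) {
    cat("<stim_schedule> ", nrow(x$stims), " stimulation events, ",
        nrow(x$plasticity), " plasticity events, end step ", x$end,
        " (scale ", x$scale, ")\n", sep = "")
    invisible(x)
}

# resolve one target specification to neuron ids
resolve_target <- function(pop, target, ids = NULL) {
    if (identical(target, "ids")) return(ids)
    parts <- strsplit(target, "@", fixed = TRUE)[[1]]
    if (length(parts) != 2)
        stop("malformed target '", target, "' (want 'ENSEMBLE@box')")
    ensemble_ids(pop, parts[1], parts[2])
}

#' Three-phase conditioned-learning schedule
#'
#' Builds the full baseline / encoding / retrieval protocol. At scale 1
#' the run assumes a network already grown to equilibrium and stabilises
#' until step 150,000; the baseline phase stimulates all US ensembles at
#' 150,000, all C1 at 250,000 and all C2 at 350,000; the encoding phase
#' stimulates US and C1 together at 450,000 and C2 alone (control) at
#' 550,000; plasticity is switched off at 650,000, after which each box's
#' C1 is stimulated alone (2,000-step stimulations, 18,000-step pauses,
#' starting at 650,000) and finally all C2 together at 1,190,000 when 27
#' boxes are present. Every stimulation lasts `stim_duration` steps at
#' `stim_amplitude` mV. `scale` multiplies every step number and duration
#' for desk-scale runs.
#'
#' @param n_boxes number of boxes.
#' @param params a [simulation_params()] list (amplitude and duration).
#' @param scale positive time-compression factor.
#' @return A `"stim_schedule"`.
#' @export
conditioning_schedule <- function(n_boxes, params, scale = 1) {
    stopifnot(scale > 0)
    s <- function(x) as.integer(round(x * scale))
    dur <- max(s(params$stim_duration), 1L)
    if (dur >= s(20000))
        stop("scale ", scale, " is too small: stimulation windows overlap ",
             "the retrieval pitch")
    amp <- params$stim_amplitude
    ev <- function(start, target, phase)
        data.frame(start = s(start), duration = dur, amplitude = amp,
                   target = target, phase = phase, stringsAsFactors = FALSE)
    stims <- rbind(
        ev(150000, "US@*", "baseline"),
        ev(250000, "C1@*", "baseline"),
        ev(350000, "C2@*", "baseline"),
        ev(450000, "US@*", "encoding"),
        ev(450000, "C1@*", "encoding"),
        ev(550000, "C2@*", "encoding"))
    for (b in seq_len(n_boxes) - 1L)
        stims <- rbind(stims, ev(650000 + 20000 * b, paste0("C1@", b),
                                 "retrieval"))
    stims <- rbind(stims, ev(650000 + 20000 * n_boxes, "C2@*", "retrieval"))
    plast <- data.frame(step = s(650000), on = FALSE)
    end <- s(650000 + 20000 * n_boxes) + dur + s(18000)
    stim_schedule(stims, plast, end = end, scale = scale,
                  baseline_window = c(s(50000), s(150000)))
}

#' Cumulative pattern-completion schedule
#'
#' After a stabilisation period, switches plasticity off and stimulates
#' nested, cumulatively growing random subsets of one box's C1 ensemble:
#' 5%, 10%, ..., 100% (subset sizes are ceilings, and earlier neurons are
#' always included in later subsets). Each subset is stimulated for
#' `stim_duration * scale` steps with pauses of `98000 * scale` steps.
#'
#' @param pop population table of the network that will be run.
#' @param box box id whose C1 ensemble is probed.
#' @param params a [simulation_params()] list.
#' @param scale positive time-compression factor.
#' @param seed seed for the random subset order.
#' @return A `"stim_schedule"` whose events carry explicit `ids`; the
#'   stimulated fraction is in the `fraction` column.
#' @export
pattern_completion_schedule <- function(pop, box, params, scale = 1,
                                        seed = 1) {
    c1 <- ensemble_ids(pop, "C1", box)
    if (!length(c1)) stop("box ", box, " has no C1 ensemble")
    ord <- with_seed(seed, sample(c1))
    s <- function(x) as.integer(round(x * scale))
    dur <- max(s(params$stim_duration), 1L)
    fracs <- seq(0.05, 1, by = 0.05)
    starts <- s(60000) + (seq_along(fracs) - 1L) * s(100000)
    stims <- data.frame(start = starts, duration = dur,
                        amplitude = params$stim_amplitude,
                        target = "ids", phase = "completion",
                        fraction = fracs, stringsAsFactors = FALSE)
    stims$ids <- lapply(fracs, function(f) ord[seq_len(ceiling(f * length(ord)))])
    # plasticity runs during the stabilisation wait, then freezes
    plast <- data.frame(step = c(0L, s(60000)), on = c(TRUE, FALSE))
    end <- starts[length(starts)] + dur + s(8000)
    stim_schedule(stims, plast, end = end, scale = scale,
                  baseline_window = c(s(10000), s(55000)))
}

#' Post-lesion recovery and retrieval schedule
#'
#' Run from the moment a lesion is applied (see [apply_lesion()]): the
#' network remodels with plasticity enabled for `200000 * scale` steps so
#' every neuron returns to its calcium set-point, then plasticity is
#' switched off and each box's C1 ensemble is stimulated alone
#' (retrieval pitch of `20000 * scale` steps), followed by all C2
#' ensembles as a control.
#'
#' @param n_boxes number of boxes.
#' @param params a [simulation_params()] list.
#' @param scale positive time-compression factor.
#' @return A `"stim_schedule"`.
#' @export
lesion_recovery_schedule <- function(n_boxes, params, scale = 1) {
    s <- function(x) as.integer(round(x * scale))
    dur <- max(s(params$stim_duration), 1L)
    ev <- function(start, target)
        data.frame(start = s(start), duration = dur,
                   amplitude = params$stim_amplitude, target = target,
                   phase = "retrieval", stringsAsFactors = FALSE)
    stims <- do.call(rbind, lapply(seq_len(n_boxes) - 1L, function(b)
        ev(200000 + 20000 * b, paste0("C1@", b))))
    stims <- rbind(stims, ev(200000 + 20000 * n_boxes, "C2@*"))
    plast <- data.frame(step = c(0L, s(200000)), on = c(TRUE, FALSE))
    stim_schedule(stims, plast,
                  end = s(200000 + 20000 * n_boxes) + dur + s(8000),
                  scale = scale,
                  baseline_window = c(s(100000), s(195000)))
}

#' Long-distance association schedule
#'
#' Implements the large-sigma experiment: after a stabilisation period the
#' US and C1 ensembles of two (typically far-apart) boxes are stimulated
#' together once; plasticity is then switched off and each box's C1 is
#' stimulated alone, followed by all C2 ensembles as a control. The caller
#' is responsible for enlarging the kernel scale beforehand with
#' [set_sigma()].
#'
#' @param boxes integer vector of two box ids.
#' @param params a [simulation_params()] list.
#' @param scale positive time-compression factor.
#' @return A `"stim_schedule"`.
#' @export
long_distance_schedule <- function(boxes, params, scale = 1) {
    stopifnot(length(boxes) == 2)
    s <- function(x) as.integer(round(x * scale))
    dur <- max(s(params$stim_duration), 1L)
    amp <- params$stim_amplitude
    ev <- function(start, target, phase)
        data.frame(start = s(start), duration = dur, amplitude = amp,
                   target = target, phase = phase, stringsAsFactors = FALSE)
    stims <- rbind(
        ev(150000, paste0("US@", boxes[1]), "encoding"),
        ev(150000, paste0("C1@", boxes[1]), "encoding"),
        ev(150000, paste0("US@", boxes[2]), "encoding"),
        ev(150000, paste0("C1@", boxes[2]), "encoding"),
        ev(250000, paste0("C1@", boxes[1]), "retrieval"),
        ev(250000 + 10000, paste0("C1@", boxes[2]), "retrieval"),
        ev(520000, "C2@*", "retrieval"))
    plast <- data.frame(step = s(250000), on = FALSE)
    stim_schedule(stims, plast, end = s(520000) + dur + s(8000),
                  scale = scale,
                  baseline_window = c(s(50000), s(145000)))
}
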