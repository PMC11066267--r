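#' Build the spatial neuron population
#'
#' Distributes `prod(box_grid) * neurons_per_box` neurons uniformly at
#' random inside a 3-D volume of `box_grid * box_edge` boxes, assigns each
#' box `round(frac_inhibitory * neurons_per_box)` inhibitory neurons, draws
#' three disjoint excitatory ensembles (US, C1, C2) of `ensemble_size`
#' neurons per box, and appends one non-plastic readout neuron at every box
#' centre.
#'
#' The readout neuron monitors its box's unconditioned-stimulus ensemble
#' (see [attach_readout_synapses()]); it never grows synaptic elements and
#' has no outgoing synapses.
#'
#' @param params a [simulation_params()] list.
#' @param seed integer seed; the same seed reproduces the population
#'   bitwise.
#' @return A data.frame with one row per neuron: `id`, `x`, `y`, `z`,
#'   `kind` (`"exc"`, `"inh"`, `"readout"`), `box_id` (0-based), `ensemble`
#'   (`"US"`, `"C1"`, `"C2"`, `"none"`), `plastic`, `alive`.
#' @export
#' @examples
#' p <- simulation_params(box_grid = c(1, 1, 1), neurons_per_box = 100,
#'                        ensemble_size = 10)
#' pop <- build_population(p, seed = 1)
#' table(pop$kind)
build_population <- function(params, seed) {
    validate_params(params)
    with_seed(seed, {
        g <- params$box_grid
        nb <- prod(g)
        npb <- params$neurons_per_box
        n <- nb * npb
        edge <- params$box_edge

        box_id <- rep(seq_len(nb) - 1L, each = npb)
        origin <- box_origin(box_id, g, edge)
        pos <- origin + matrix(stats::runif(3L * n, 0, edge), n, 3L)

        kind <- character(n)
        ens <- rep("none", n)
        n_inh <- as.integer(round(params$frac_inhibitory * npb))
        for (b in seq_len(nb) - 1L) {
            idx <- which(box_id == b)
            k <- rep("exc", npb)
            if (n_inh > 0) k[sample.int(npb, n_inh)] <- "inh"
            kind[idx] <- k
            if (params$ensemble_size > 0) {
                exc <- idx[k == "exc"]
                if (3L * params$ensemble_size > length(exc))
                    stop("ensemble_size too large for box ", b)
                pick <- sample(exc, 3L * params$ensemble_size)
                ens[pick[seq_len(params$ensemble_size)]] <- "US"
                ens[pick[params$ensemble_size + seq_len(params$ensemble_size)]] <- "C1"
                ens[pick[2L * params$ensemble_size + seq_len(params$ensemble_size)]] <- "C2"
            }
        }

        ro_box <- seq_len(nb) - 1L
        ro_pos <- box_origin(ro_box, g, edge) + edge / 2

        pop <- data.frame(
            id = seq_len(n + nb),
            x = c(pos[, 1], ro_pos[, 1]),
            y = c(pos[, 2], ro_pos[, 2]),
            z = c(pos[, 3], ro_pos[, 3]),
            kind = c(kind, rep("readout", nb)),
            box_id = c(box_id, ro_box),
            ensemble = c(ens, rep("none", nb)),
            plastic = c(rep(TRUE, n), rep(FALSE, nb)),
            alive = TRUE,
            stringsAsFactors = FALSE)
        pop
    })
}

# lower corner of each box, rows aligned with box_id (0-based)
box_origin <- function(box_id, grid, edge) {
    ix <- box_id %% grid[1]
    iy <- (box_id %/% grid[1]) %% grid[2]
    iz <- box_id %/% (grid[1] * grid[2])
    cbind(ix, iy, iz) * edge
}

#' Box index of a position
#'
#' Pure function of position and box geometry; re-deriving `box_id` from
#' the stored coordinates reproduces the ids assigned at build time.
#'
#' @param x,y,z coordinates (vectors of equal length).
#' @param params a [simulation_params()] list (uses `box_grid`,
#'   `box_edge`).
#' @return Integer 0-based box ids.
#' @export
box_of_position <- function(x, y, z, params) {
    g <- params$box_grid
    e <- params$box_edge
    clamp <- function(i, m) pmin(pmax(i, 0L), m - 1L)
    ix <- clamp(as.integer(floor(x / e)), g[1])
    iy <- clamp(as.integer(floor(y / e)), g[2])
    iz <- clamp(as.integer(floor(z / e)), g[3])
    ix + g[1] * (iy + g[2] * iz)
}

#' Static readout synapses
#'
#' For each box, connects every neuron of the US ensemble to the box's
#' readout neuron with one static synapse of weight +1. Static synapses
#' carry no synaptic-element bookkeeping and are never touched by the
#' homeostatic plasticity; they only transmit spikes.
#'
#' @param pop a population from [build_population()].
#' @return A synapse table data.frame (`src`, `tgt`, `w`, `static`); zero
#'   rows for boxes without a US ensemble.
#' @export
attach_readout_synapses <- function(pop) {
    ro <- pop[pop$kind == "readout", c("id", "box_id")]
    us <- pop[pop$ensemble == "US", c("id", "box_id")]
    if (nrow(us) == 0 || nrow(ro) == 0)
        return(data.frame(src = integer(0), tgt = integer(0),
                          w = integer(0), static = logical(0)))
    tgt <- ro$id[match(us$box_id, ro$box_id)]
    keep <- !is.na(tgt)
    data.frame(src = us$id[keep], tgt = tgt[keep], w = 1L,
               static = TRUE)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
with_seed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}
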