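#' Small-world connectivity configuration
#'
#' Initial wiring rule for the 3D reservoir: a directed edge i -> j is
#' created with probability `base_prob * exp(-d(i,j)^2 / radius_mm^2)` for
#' distances up to `radius_mm` and never beyond, so connection probability
#' decreases with distance and has compact support. Initial weights are
#' uniform on `(0, init_weight_scale]`; a random fraction of presynaptic
#' neurons is inhibitory (all their outgoing weights negated).
#'
#' @param radius_mm Hard distance cutoff (mm). `NULL` resolves at build time
#'   to 2.5 times the median nearest-neighbour spacing of the grid, i.e.
#'   2.5 grid units.
#' @param base_prob Connection probability at zero distance, in `(0, 1]`.
#' @param inhibitory_fraction Fraction of neurons whose outgoing connections
#'   are inhibitory (default 0.2).
#' @param init_weight_scale Upper bound of the initial uniform weights.
#' @param seed Integer seed for wiring and weights.
#' @return A list of class `swc_config`.
#' @export
swc_config <- function(radius_mm = NULL, base_prob = 0.15,
                       inhibitory_fraction = 0.2, init_weight_scale = 1,
                       seed = 1) {
  if (!is.null(radius_mm) && (!is_num1(radius_mm) || radius_mm < 0)) {
    stop_snnerp("radius_mm must be nonnegative", "snnerp_config_error")
  }
  if (base_prob <= 0 || base_prob > 1 || inhibitory_fraction < 0 ||
      inhibitory_fraction > 1 || init_weight_scale <= 0) {
    stop_snnerp("invalid swc_config parameters", "snnerp_config_error")
  }
  structure(list(radius_mm = radius_mm, base_prob = base_prob,
                 inhibitory_fraction = inhibitory_fraction,
                 init_weight_scale = init_weight_scale,
                 seed = as.integer(seed)),
            class = "swc_config")
}

#' Leaky integrate-and-fire configuration
#'
#' @param fire_threshold Membrane potential above which a neuron fires.
#'   Input events have unit magnitude and initial weights average half of
#'   `init_weight_scale`; the default 1.2 makes internal neurons coincidence
#'   detectors (several near-simultaneous afferent events are needed), so
#'   reservoir activity stays input-driven rather than self-sustaining.
#' @param leak Multiplicative decay of the membrane potential per step,
#'   in `[0, 1)`.
#' @param refractory_steps Steps during which a neuron that fired ignores
#'   input.
#' @return A list of class `lif_config`.
#' @export
lif_config <- function(fire_threshold = 1.2, leak = 0.9,
                       refractory_steps = 5) {
  if (fire_threshold <= 0 || leak < 0 || leak >= 1 || refractory_steps < 0) {
    stop_snnerp("invalid lif_config parameters", "snnerp_config_error")
  }
  structure(list(fire_threshold = fire_threshold, leak = leak,
                 refractory_steps = as.integer(refractory_steps)),
            class = "lif_config")
}

#' Spike-timing-dependent plasticity configuration
#'
#' Nearest-spike pairing with additive updates: when a neuron fires at time
#' t, each incoming connection whose presynaptic neuron last fired dt steps
#' earlier is potentiated by `a_plus * exp(-dt / tau_ms)`, and each outgoing
#' connection whose postsynaptic neuron last fired dt steps earlier is
#' depressed by `a_minus * exp(-dt / tau_ms)`. Excitatory weights are
#' clipped to `[0, w_max]`; inhibitory weights mirror the rule on their
#' magnitude.
#'
#' @param a_plus,a_minus Potentiation / depression amplitudes (nonnegative;
#'   0/0 disables plasticity). The 2:1 default makes plasticity
#'   potentiation-dominant, so connection weights grow with the amount of
#'   causal spike transmission a connection carries.
#' @param tau_ms Exponential decay constant of the pairing window (ms).
#' @param w_max Weight magnitude cap.
#' @return A list of class `stdp_config`.
#' @export
stdp_config <- function(a_plus = 0.02, a_minus = 0.01, tau_ms = 10,
                        w_max = 2) {
  if (a_plus < 0 || a_minus < 0 || tau_ms <= 0 || w_max <= 0) {
    stop_snnerp("invalid stdp_config parameters", "snnerp_config_error")
  }
  structure(list(a_plus = a_plus, a_minus = a_minus, tau_ms = tau_ms,
                 w_max = w_max),
            class = "stdp_config")
}

#' Build a 3D spatially mapped spiking reservoir
#'
#' Neurons sit at the grid coordinates; each montage channel is mapped to
#' its nearest free grid neuron (montage order breaks ties; an already
#' claimed neuron falls through to the next nearest), so the scalp topology
#' is preserved inside the model. Wiring follows the small-world rule of
#' [swc_config()].
#'
#' @param grid Neuron coordinates: numeric matrix with columns x, y, z (mm),
#'   e.g. `load_fixture("grid1471")` or [subsample_grid()].
#' @param montage Data frame with `channel`, `x`, `y`, `z` in the same frame
#'   (default the packaged 62-channel montage).
#' @param swc An [swc_config()].
#' @return An object of class `snn_reservoir`: `coords`, `channels`,
#'   `input_map` (named neuron indices), `edges` (data.frame `pre`, `post`,
#'   `weight`), `inhib` (per-edge flag), `swc`.
#' @examples
#' res <- build_reservoir(subsample_grid(200))
#' nrow(res$coords); length(res$input_map)
#' @export
build_reservoir <- function(grid = load_fixture("grid1471"),
                            montage = load_fixture("montage62"),
                            swc = swc_config()) {
  grid <- as.matrix(grid)
  if (nrow(grid) < nrow(montage)) {
    stop_snnerp("grid has fewer neurons than montage channels",
                "snnerp_config_error")
  }
  mxyz <- as.matrix(montage[, c("x", "y", "z")])

  # nearest free grid neuron per channel, montage order
  input_map <- integer(nrow(montage))
  taken <- logical(nrow(grid))
  for (i in seq_len(nrow(montage))) {
    d2 <- colSums((t(grid) - mxyz[i, ])^2)
    ord <- order(d2)
    input_map[i] <- ord[which(!taken[ord])[1]]
    taken[input_map[i]] <- TRUE
  }
  names(input_map) <- montage$channel

  radius <- swc$radius_mm
  if (is.null(radius)) {
    nn <- vapply(seq_len(nrow(grid)), function(i) {
      d2 <- colSums((t(grid) - grid[i, ])^2)
      sqrt(min(d2[-i]))
    }, 0)
    radius <- 2.5 * stats::median(nn)
  }

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(swc$seed)

  edges <- data.frame(pre = integer(0), post = integer(0), weight = numeric(0))
  inhib_edge <- logical(0)
  if (radius > 0) {
    d2 <- as.matrix(stats::dist(grid))^2
    cand <- which(d2 <= radius^2 & d2 > 0, arr.ind = TRUE)  # ordered pairs
    p <- swc$base_prob * exp(-d2[cand] / radius^2)
    keep <- stats::runif(nrow(cand)) < p
    pre <- cand[keep, 1]
    post <- cand[keep, 2]
    w <- stats::runif(length(pre), 0, swc$init_weight_scale)
    w[w == 0] <- swc$init_weight_scale  # open at 0
    inhib_neuron <- logical(nrow(grid))
    n_inhib <- round(swc$inhibitory_fraction * nrow(grid))
    inhib_neuron[sample(nrow(grid), n_inhib)] <- TRUE
    inhib_edge <- inhib_neuron[pre]
    w[inhib_edge] <- -w[inhib_edge]
    edges <- data.frame(pre = pre, post = post, weight = w)
    rownames(edges) <- NULL
  }
  structure(list(coords = grid, channels = montage$channel,
                 input_map = input_map, edges = edges, inhib = inhib_edge,
                 radius_mm = radius, swc = swc),
            class = "snn_reservoir")
}

#' Deterministically thin the packaged grid to n neurons
#'
#' Greedy farthest-point thinning (started from the site nearest the grid
#' centroid), giving a spatially uniform reduced reservoir for simulation
#' studies. Fully deterministic.
#'
#' @param n Number of neurons to keep.
#' @param grid Source grid (default the packaged 1471-site grid).
#' @return A numeric coordinate matrix with `n` rows.
#' @export
subsample_grid <- function(n, grid = load_fixture("grid1471")) {
  grid <- as.matrix(grid)
  stopifnot(n >= 1, n <= nrow(grid))
  ctr <- colMeans(grid)
  sel <- integer(n)
  sel[1] <- which.min(colSums((t(grid) - ctr)^2))
  mind <- colSums((t(grid) - grid[sel[1], ])^2)
  for (i in seq_len(n - 1)) {
    sel[i + 1] <- which.max(mind)
    mind <- pmin(mind, colSums((t(grid) - grid[sel[i + 1], ])^2))
  }
  grid[sort(sel), , drop = FALSE]
}

#' Run reservoir dynamics with STDP learning over one spike-encoded sample
#'
#' Input neurons transfer their channel's encoded spike train directly into
#' the model, emitting one event per spike with its polarity; a negative
#' event delivers `-w` along each outgoing edge (inhibitory input
#' contribution). All other neurons are leaky integrate-and-fire. Events
#' propagate along the directed edges with a one-step delay, and connection
#' weights adapt by nearest-spike STDP (see [stdp_config()]). Membrane
#' state is reset at the start of every pass; weights persist.
#'
#' @param reservoir An `snn_reservoir`.
#' @param spikes A `spike_trains` object whose channels all exist in the
#'   reservoir's input map.
#' @param lif An [lif_config()].
#' @param stdp An [stdp_config()]; use `a_plus = a_minus = 0` to propagate
#'   without plasticity.
#' @param passes Number of presentations of the sample (default 1).
#' @return List with `reservoir` (updated weights) and `firing_log`
#'   (data.frame `neuron`, `t` (0-based sample index = ms at 1 kHz),
#'   `polarity` of the membrane drive at firing).
#' @export
run_stdp <- function(reservoir, spikes, lif = lif_config(),
                     stdp = stdp_config(), passes = 1) {
  stopifnot(inherits(reservoir, "snn_reservoir"),
            inherits(spikes, "spike_trains"))
  chans <- rownames(spikes$spikes)
  if (!all(chans %in% names(reservoir$input_map))) {
    stop_snnerp(paste("unmapped channel(s):",
                      paste(setdiff(chans, names(reservoir$input_map)),
                            collapse = ", ")),
                "snnerp_input_error")
  }
  res <- stdp_run_cpp(
    pre = as.integer(reservoir$edges$pre) - 1L,
    post = as.integer(reservoir$edges$post) - 1L,
    w0 = as.numeric(reservoir$edges$weight),
    inhib = if (length(reservoir$inhib)) reservoir$inhib
            else logical(nrow(reservoir$edges)),
    spikes = matrix(as.integer(spikes$spikes), nrow(spikes$spikes)),
    inputNeurons = as.integer(reservoir$input_map[chans]) - 1L,
    nNeurons = nrow(reservoir$coords),
    leak = lif$leak, fireThreshold = lif$fire_threshold,
    refractorySteps = lif$refractory_steps,
    aPlus = stdp$a_plus, aMinus = stdp$a_minus,
    tauMs = stdp$tau_ms, wMax = stdp$w_max,
    passes = as.integer(passes))
  reservoir$edges$weight <- res$w
  list(reservoir = reservoir,
       firing_log = data.frame(neuron = res$neuron, t = res$t,
                               polarity = res$polarity))
}

#' Train a reservoir on a sequence of samples (unsupervised STDP)
#'
#' Presents each spike-encoded sample in turn; membrane state resets between
#' samples, weights accumulate.
#'
#' @param reservoir An `snn_reservoir`.
#' @param spike_sets List of `spike_trains`.
#' @inheritParams run_stdp
#' @return The trained `snn_reservoir`.
#' @export
train_reservoir <- function(reservoir, spike_sets, lif = lif_config(),
                            stdp = stdp_config(), passes = 1) {
  for (st in spike_sets) {
    reservoir <- run_stdp(reservoir, st, lif, stdp, passes)$reservoir
  }
  reservoir
}

#' Count firings per neuron in a time window around a latency
#'
#' @param firing_log A firing log from [run_stdp()].
#' @param t_ms Window centre (0-based ms).
#' @param window_ms Window width; the window is
#'   `[t_ms - window_ms/2, t_ms + window_ms/2]`, inclusive.
#' @param n_neurons Reservoir size.
#' @param epoch_len Epoch length in samples; the window must lie inside
#'   `[0, epoch_len - 1]`.
#' @return Integer matrix `n_neurons` x 2 with columns `positive`,
#'   `negative`: firing counts split by membrane-drive polarity.
#' @export
snapshot_activity <- function(firing_log, t_ms, window_ms, n_neurons,
                              epoch_len) {
  lo <- t_ms - window_ms / 2
  hi <- t_ms + window_ms / 2
  if (lo < 0 || hi > epoch_len - 1) {
    stop_snnerp("window extends outside the epoch", "snnerp_range_error")
  }
  out <- matrix(0L, n_neurons, 2, dimnames = list(NULL, c("positive", "negative")))
  sel <- firing_log$t >= lo & firing_log$t <= hi
  if (any(sel)) {
    pos <- table(factor(firing_log$neuron[sel & firing_log$polarity > 0],
                        levels = seq_len(n_neurons)))
    neg <- table(factor(firing_log$neuron[sel & firing_log$polarity < 0],
                        levels = seq_len(n_neurons)))
    out[, 1] <- as.integer(pos)
    out[, 2] <- as.integer(neg)
  }
  out
}

#' Serialise a reservoir to a JSON + edge-list bundle
#'
#' Writes `reservoir.json` (sizes, radius, input map) and `edges.tsv`
#' (`pre`, `post`, `weight`) into `dir`.
#'
#' @param reservoir An `snn_reservoir`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_reservoir <- function(reservoir, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(n_neurons = nrow(reservoir$coords),
                            radius_mm = reservoir$radius_mm,
                            input_map = as.list(reservoir$input_map)),
                       file.path(dir, "reservoir.json"), auto_unbox = TRUE)
  utils::write.table(reservoir$edges, file.path(dir, "edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
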