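# Independent straight-line re-simulation of the reservoir dynamics, used as
# the oracle for the compiled implementation on tiny networks. Written
# directly from the dynamics definition:
#  - input neurons emit their channel's encoded spikes (signed events);
#  - other neurons: u <- u*leak + sum(incoming w * sign of last-step events),
#    fire (+1 event) when u > threshold, reset, refractory;
#  - one-step delivery delay;
#  - nearest-spike STDP, each spike paired at most once per role per edge:
#    a counterpart spike only pairs if newer than the emitter's own previous
#    spike; potentiation a_plus*exp(-dt/tau) for pre-before-post, depression
#    a_minus*exp(-dt/tau) for post-before-pre; excitatory weights clipped to
#    [0, w_max], inhibitory mirrored to [-w_max, 0].
ref_sim <- function(edges, inhib, spikes, input_map, n_neurons,
                    lif, stdp, passes = 1) {
  w <- edges$weight
  ch_of <- rep(NA_integer_, n_neurons)
  ch_of[input_map] <- seq_along(input_map)
  log <- data.frame(neuron = integer(0), t = integer(0), polarity = integer(0))
  nT <- ncol(spikes)
  for (pass in seq_len(passes)) {
    u <- numeric(n_neurons)
    refr <- integer(n_neurons)
    last <- rep(-1L, n_neurons)
    prev <- integer(0)
    prev_sign <- integer(0)
    for (t in 0:(nT - 1)) {
      drive <- numeric(n_neurons)
      for (k in seq_along(prev)) {
        sel <- which(edges$pre == prev[k])
        for (e in sel) drive[edges$post[e]] <- drive[edges$post[e]] +
            prev_sign[k] * w[e]
      }
      emit <- integer(0)
      esign <- integer(0)
      for (i in seq_len(n_neurons)) {
        if (!is.na(ch_of[i])) {
          s <- spikes[ch_of[i], t + 1]
          if (s != 0) {
            emit <- c(emit, i); esign <- c(esign, s)
            log <- rbind(log, data.frame(neuron = i, t = t, polarity = s))
          }
          next
        }
        if (refr[i] > 0) {
          refr[i] <- refr[i] - 1
          u[i] <- 0
          next
        }
        u[i] <- u[i] * lif$leak + drive[i]
        if (u[i] > lif$fire_threshold) {
          emit <- c(emit, i); esign <- c(esign, 1L)
          log <- rbind(log, data.frame(neuron = i, t = t,
                                       polarity = if (drive[i] >= 0) 1L else -1L))
        }
      }
      if (stdp$a_plus != 0 || stdp$a_minus != 0) {
        for (i in emit) {
          own <- last[i]
          for (e in which(edges$post == i)) {   # LTP on incoming
            lf <- last[edges$pre[e]]
            if (lf >= 0 && t - lf >= 1 && lf > own) {
              dw <- stdp$a_plus * exp(-(t - lf) / stdp$tau_ms)
              if (inhib[e]) w[e] <- max(w[e] - dw, -stdp$w_max)
              else w[e] <- min(w[e] + dw, stdp$w_max)
            }
          }
          for (e in which(edges$pre == i)) {    # LTD on outgoing
            lf <- last[edges$post[e]]
            if (lf >= 0 && t - lf >= 1 && lf > own) {
              dw <- stdp$a_minus * exp(-(t - lf) / stdp$tau_ms)
              if (inhib[e]) w[e] <- min(w[e] + dw, 0)
              else w[e] <- max(w[e] - dw, 0)
            }
          }
        }
      }
      for (i in emit) {
        if (is.na(ch_of[i])) {
          u[i] <- 0
          refr[i] <- lif$refractory_steps
        }
        last[i] <- t
      }
      prev <- emit
      prev_sign <- esign
    }
  }
  list(w = w, log = log)
}

# hand-built reservoir object for unit tests
toy_reservoir <- function(coords, input_map, edges, inhib = NULL,
                          channels = names(input_map)) {
  structure(list(coords = as.matrix(coords), channels = channels,
                 input_map = input_map, edges = edges,
                 inhib = if (is.null(inhib)) logical(nrow(edges)) else inhib,
                 radius_mm = NA_real_, swc = NULL),
            class = "snn_reservoir")
}

# spike_trains object from a plain matrix
toy_spikes <- function(m) {
  structure(list(spikes = m, source_len = ncol(m)), class = "spike_trains")
}

# random small network + random input for equivalence testing
random_toy <- function(seed) {
  set.seed(seed)
  n <- sample(3:5, 1)
  n_in <- sample(1:2, 1)
  n_edge <- sample(2:8, 1)
  pre <- sample(n, n_edge, replace = TRUE)
  post <- vapply(pre, function(p) sample(setdiff(seq_len(n), p), 1), 0L)
  ek <- !duplicated(paste(pre, post))
  edges <- data.frame(pre = pre[ek], post = post[ek],
                      weight = round(runif(sum(ek), 0.2, 1.5), 3))
  inhib <- runif(nrow(edges)) < 0.3
  edges$weight[inhib] <- -edges$weight[inhib]
  nT <- sample(10:20, 1)
  spikes <- matrix(sample(c(-1L, 0L, 1L), n_in * nT, replace = TRUE,
                          prob = c(0.2, 0.5, 0.3)), n_in, nT,
                   dimnames = list(paste0("ch", seq_len(n_in)), NULL))
  input_map <- stats::setNames(sample(n, n_in), rownames(spikes))
  lif <- lif_config(fire_threshold = runif(1, 0.3, 1),
                    leak = runif(1, 0.5, 0.95),
                    refractory_steps = sample(0:3, 1))
  stdp <- stdp_config(a_plus = runif(1, 0, 0.1), a_minus = runif(1, 0, 0.1),
                      tau_ms = runif(1, 2, 15), w_max = 2)
  list(n = n, edges = edges, inhib = inhib, spikes = spikes,
       input_map = input_map, lif = lif, stdp = stdp,
       passes = sample(1:2, 1))
}
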