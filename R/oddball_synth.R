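#' Generate a randomized auditory oddball stimulus schedule
#'
#' Builds the event sequence of a 4-tone auditory oddball task: each block
#' contains a fixed number of standard tones, white-noise bursts, targets and
#' distractors in randomized order, with inter-stimulus intervals drawn
#' uniformly from `isi_ms +/- jitter_ms`. With the defaults (2 blocks of
#' 90/18/18/18) the task comprises 288 stimuli of which 62.5% are standards
#' and 12.5% each are noise bursts, targets and distractors.
#'
#' @param block_count Number of blocks (nonnegative integer).
#' @param per_block Named integer vector of per-block event counts; names must
#'   be a subset of `standard`, `noise`, `target`, `distractor`.
#' @param isi_ms,jitter_ms Inter-stimulus interval and its uniform jitter (ms).
#' @param seed Integer seed; the schedule is deterministic given the seed.
#' @return An object of class `oddball_schedule`: a list with `events`
#'   (data.frame of `onset_ms`, `kind`), `block_count` and
#'   `per_block_counts`.
#' @examples
#' sch <- generate_schedule(seed = 1)
#' nrow(sch$events)          # 288
#' table(sch$events$kind)
#' @export
generate_schedule <- function(block_count = 2,
                              per_block = c(standard = 90, noise = 18,
                                            target = 18, distractor = 18),
                              isi_ms = 1100, jitter_ms = 100, seed = 1) {
  kinds <- c("standard", "noise", "target", "distractor")
  if (!all(names(per_block) %in% kinds)) {
    stop_snnerp("per_block names must be standard/noise/target/distractor",
                "snnerp_config_error")
  }
  if (block_count < 0 || any(per_block < 0)) {
    stop_snnerp("block_count and per-block counts must be nonnegative",
                "snnerp_config_error")
  }
  full <- stats::setNames(integer(4), kinds)
  full[names(per_block)] <- as.integer(per_block)

  events <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    kind <- unlist(lapply(seq_len(block_count), function(b) {
      sample(rep(kinds, full))
    }), use.names = FALSE)
    n <- length(kind)
    gaps <- if (n > 1) stats::runif(n - 1, isi_ms - jitter_ms, isi_ms + jitter_ms)
            else numeric(0)
    data.frame(onset_ms = cumsum(c(0, gaps))[seq_len(n)],
               kind = if (n) kind else character(0))
  })
  structure(list(events = events, block_count = block_count,
                 per_block_counts = full),
            class = "oddball_schedule")
}

# band used for waveform topographies: every channel, midline ones folded
# into the adjacent anatomical band
channel_band <- function(channels = montage_channels()) {
  reg <- load_fixture("regions_fig5")
  band <- stats::setNames(reg$site, reg$channel)
  mid <- c(FPZ = "frontal", FZ = "frontal",
           FCZ = "frontocentral", CZ = "frontocentral",
           CPZ = "centroparietal", PZ = "centroparietal",
           POZ = "occipitoparietal", OZ = "occipitoparietal")
  band[names(mid)] <- mid
  out <- band[channels]
  if (anyNA(out)) {
    stop_snnerp(paste("unknown channel(s):",
                      paste(channels[is.na(out)], collapse = ", ")),
                "snnerp_config_error")
  }
  out
}

#' Default ERP component templates
#'
#' Gaussian-in-time waveform components summed per channel through band-wise
#' topography gains. The target late positivity peaks over occipitoparietal
#' channels; the distractor late positivity is anterior-shifted (frontal
#' maximum), so stimulus anteriorisation is a plantable property of the
#' generator. Earlier negativities (100 ms, -4 uV; 200 ms, -3 uV) have a
#' frontocentral maximum for both stimuli.
#'
#' @param stimulus `"target"` or `"distractor"`.
#' @param channels Channel labels the topography must cover.
#' @return A list of components, each a list with `name`, `latency_ms`,
#'   `width_ms` (Gaussian SD), `amplitude_uv` and `topography` (named gains
#'   in `[-1, 1]` covering `channels`).
#' @export
erp_components <- function(stimulus = c("target", "distractor"),
                           channels = montage_channels()) {
  stimulus <- match.arg(stimulus)
  band <- channel_band(channels)
  gain <- function(g) stats::setNames(unname(g[band]), channels)
  n100 <- c(frontal = 0.7, frontocentral = 1, temporal = 0.6,
            centroparietal = 0.5, occipitoparietal = 0.2)
  n200 <- c(frontal = 0.9, frontocentral = 1, temporal = 0.5,
            centroparietal = 0.4, occipitoparietal = 0.2)
  p300 <- if (stimulus == "target") {
    c(frontal = 0.3, frontocentral = 0.5, temporal = 0.4,
      centroparietal = 0.9, occipitoparietal = 1)
  } else {
    c(frontal = 1, frontocentral = 0.8, temporal = 0.6,
      centroparietal = 0.6, occipitoparietal = 0.4)
  }
  list(
    list(name = "N100", latency_ms = 100, width_ms = 30, amplitude_uv = -4,
         topography = gain(n100)),
    list(name = "N200", latency_ms = 200, width_ms = 40, amplitude_uv = -3,
         topography = gain(n200)),
    list(name = "P300", latency_ms = if (stimulus == "target") 340 else 320,
         width_ms = 60, amplitude_uv = 6, topography = gain(p300))
  )
}

#' Specify a synthetic ERP cohort
#'
#' Collects the design and generative parameters of a synthetic averaged-ERP
#' cohort emulating a two-group mindfulness-intervention study: groups
#' `experimental` and `waitlist`, up to three assessment time points, target
#' and distractor stimuli, 62 channels, 1300-sample epochs at 1 kHz.
#'
#' @param n_per_group Participants per group.
#' @param time_points Subset of `c("T1","T2","T3")`.
#' @param stimuli Subset of `c("target","distractor")`.
#' @param epoch_len Epoch length in samples (stimulus onset at sample 1).
#' @param sample_rate_hz Sampling rate; 1000 means 1 sample per ms.
#' @param noise_sd_uv Marginal SD of the additive channel noise (uV).
#' @param noise_smooth_ms Temporal smoothness of the noise: SD (ms) of the
#'   Gaussian kernel that band-limits the white noise process. The default
#'   12 ms emulates a residual background dominated by alpha-band and
#'   slower activity, as in a well-averaged ERP; 0 gives white noise.
#' @param frontal_gain_delta Planted Time-by-Group effect: frontal-channel
#'   component gains of experimental-group samples at post-training time
#'   points (T2, T3) are multiplied by `1 + frontal_gain_delta`. The default
#'   1 (a doubling) matches the magnitude of reported post-training frontal
#'   connection-weight increases.
#' @param psychometric_coupling Correlation (in `[-1, 1]`) between the
#'   participant's latent right-frontal gain factor and the FFMQ score;
#'   mood scores (BDI, DASS) couple with the opposite sign.
#' @param latent_gain_sd SD of the participant latent right-frontal gain
#'   factor around 1.
#' @param seed Integer base seed; the cohort is byte-reproducible from it.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 10,
                        time_points = c("T1", "T2"),
                        stimuli = c("target", "distractor"),
                        epoch_len = 1300,
                        sample_rate_hz = 1000,
                        noise_sd_uv = 1,
                        noise_smooth_ms = 12,
                        frontal_gain_delta = 1,
                        psychometric_coupling = 0.6,
                        latent_gain_sd = 0.15,
                        seed = 1) {
  time_points <- match.arg(time_points, c("T1", "T2", "T3"), several.ok = TRUE)
  stimuli <- match.arg(stimuli, c("target", "distractor"), several.ok = TRUE)
  if (epoch_len <= 0 || n_per_group <= 0) {
    stop_snnerp("epoch_len and n_per_group must be positive",
                "snnerp_config_error")
  }
  if (noise_sd_uv < 0 || abs(psychometric_coupling) > 1 ||
      noise_smooth_ms < 0) {
    stop_snnerp("invalid noise/coupling parameters", "snnerp_config_error")
  }
  structure(list(n_per_group = n_per_group,
                 groups = c("experimental", "waitlist"),
                 time_points = time_points, stimuli = stimuli,
                 epoch_len = as.integer(epoch_len),
                 sample_rate_hz = sample_rate_hz,
                 noise_sd_uv = noise_sd_uv, noise_smooth_ms = noise_smooth_ms,
                 frontal_gain_delta = frontal_gain_delta,
                 psychometric_coupling = psychometric_coupling,
                 latent_gain_sd = latent_gain_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# band-limited Gaussian noise: white noise convolved with a Gaussian kernel
# of SD smooth_ms, rescaled to marginal SD sd per channel (time x channel).
# smooth_ms = 0 gives white noise.
smooth_noise <- function(n_time, n_chan, sd, smooth_ms) {
  if (sd == 0) return(matrix(0, n_time, n_chan))
  if (smooth_ms == 0) {
    return(matrix(stats::rnorm(n_time * n_chan, sd = sd), n_time, n_chan))
  }
  half <- ceiling(4 * smooth_ms)
  k <- stats::dnorm(seq(-half, half), sd = smooth_ms)
  pad <- n_time + 2 * half
  innov <- matrix(stats::rnorm(pad * n_chan), pad, n_chan)
  out <- stats::filter(innov, k, sides = 2)
  out <- out[(half + 1):(half + n_time), , drop = FALSE]
  # exact theoretical scaling of the convolved marginal SD
  out <- out * (sd / sqrt(sum(k^2)))
  matrix(as.numeric(out), n_time, n_chan)
}

#' Generate a synthetic averaged-ERP cohort with psychometrics
#'
#' Produces one averaged-ERP sample (channel x time matrix, uV) per
#' participant x time point x stimulus, plus a psychometric table (FFMQ, BDI,
#' DASS subscales). Each participant carries a latent right-frontal gain
#' factor; the FFMQ score correlates with it at `psychometric_coupling`
#' (mood scores inversely), and experimental-group post-training samples
#' receive the planted frontal gain increase.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `erp_cohort` with `samples` (list of `erp_sample`
#'   objects: `participant_id`, `group`, `time_point`, `stimulus`, `data`
#'   channels x time, `channels`) and `psychometrics` (one row per
#'   participant, including the latent `rf_gain`).
#' @examples
#' coh <- generate_cohort(cohort_spec(n_per_group = 2, epoch_len = 300))
#' length(coh$samples)
#' dim(coh$samples[[1]]$data)
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  channels <- montage_channels()
  reg <- load_fixture("regions_fig5")
  frontal <- reg$channel[!is.na(reg$site) & reg$site == "frontal"]
  frontal <- union(frontal, c("FPZ", "FZ"))  # midline frontal band
  rfront <- reg$channel[!is.na(reg$site) & reg$site == "frontal" &
                          reg$hemisphere == "right"]
  tt <- seq_len(spec$epoch_len) - 1
  tt <- tt * 1000 / spec$sample_rate_hz    # ms after stimulus onset

  ids <- unlist(lapply(spec$groups, function(g)
    sprintf("%s_%02d", substr(g, 1, 3), seq_len(spec$n_per_group))))
  groups <- rep(spec$groups, each = spec$n_per_group)

  # participant latents and psychometrics
  cc <- spec$psychometric_coupling
  psy <- do.call(rbind, lapply(seq_along(ids), function(i) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed_for(spec$seed, "participant", ids[i]))
    z1 <- stats::rnorm(1)
    mix <- function(rho) rho * z1 + sqrt(max(0, 1 - rho^2)) * stats::rnorm(1)
    data.frame(participant_id = ids[i], group = groups[i],
               rf_gain = 1 + spec$latent_gain_sd * z1,
               FFMQ = 130 + 15 * mix(cc),
               BDI = 10 + 6 * mix(-cc),
               DASS_Depression = 8 + 5 * mix(-cc),
               DASS_Anxiety = 6 + 4 * mix(-cc),
               DASS_Stress = 10 + 5 * mix(-cc))
  }))

  comps <- lapply(stats::setNames(spec$stimuli, spec$stimuli),
                  erp_components, channels = channels)
  samples <- list()
  for (i in seq_along(ids)) {
    for (tp in spec$time_points) {
      for (st in spec$stimuli) {
        gain_mult <- stats::setNames(rep(1, length(channels)), channels)
        if (groups[i] == "experimental" && tp != "T1") {
          gain_mult[frontal] <- gain_mult[frontal] * (1 + spec$frontal_gain_delta)
        }
        gain_mult[rfront] <- gain_mult[rfront] * psy$rf_gain[i]
        clean <- matrix(0, length(channels), spec$epoch_len,
                        dimnames = list(channels, NULL))
        for (cmp in comps[[st]]) {
          bump <- exp(-0.5 * ((tt - cmp$latency_ms) / cmp$width_ms)^2)
          clean <- clean + (cmp$amplitude_uv * cmp$topography[channels] *
                              gain_mult) %o% bump
        }
        noise <- local({
          old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
          on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
          set.seed(seed_for(spec$seed, "noise", ids[i], tp, st))
          t(smooth_noise(spec$epoch_len, length(channels),
                         spec$noise_sd_uv, spec$noise_smooth_ms))
        })
        dat <- clean + noise
        rownames(dat) <- channels
        samples[[length(samples) + 1L]] <- structure(
          list(participant_id = ids[i], group = groups[i], time_point = tp,
               stimulus = st, data = dat, channels = channels),
          class = "erp_sample")
      }
    }
  }
  structure(list(samples = samples, psychometrics = psy, spec = spec),
            class = "erp_cohort")
}

#' Write a cohort to a directory of delimited files
#'
#' One TSV per sample (rows = time, columns = channels, header = channel
#' labels), a `psychometrics.tsv` table and a JSON `manifest.json` recording
#' participant, group, time point, stimulus, file name and the generator
#' seed.
#'
#' @param cohort An `erp_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "erp_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  recs <- lapply(cohort$samples, function(s) {
    fn <- sprintf("%s_%s_%s.tsv", s$participant_id, s$time_point, s$stimulus)
    utils::write.table(t(s$data), file.path(dir, fn), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(participant_id = s$participant_id, group = s$group,
         time_point = s$time_point, stimulus = s$stimulus, file = fn)
  })
  utils::write.table(cohort$psychometrics, file.path(dir, "psychometrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(seed = cohort$spec$seed,
                            epoch_len = cohort$spec$epoch_len,
                            samples = recs),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}
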