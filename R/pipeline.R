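#' Full experiment configuration
#'
#' Bundles every stage configuration of the pipeline: cohort generation,
#' spike encoding, reservoir wiring, neuron dynamics, plasticity, the deSNN
#' output layer, baseline methods and the seed policy. All stage seeds are
#' derived from `base_seed` by stable hashing, so a configuration determines
#' the entire run.
#'
#' @param cohort A [cohort_spec()] describing the synthetic cohort (ignored
#'   when `run_experiment()` is given a cohort to analyse).
#' @param encoder,swc,lif,stdp,desnn Stage configurations.
#' @param baselines Baseline methods for the classification comparison
#'   (subset of `c("mlp", "svm", "mlr")`; empty to skip).
#' @param grid_n Reservoir size; `NULL` uses the full 1471-site grid,
#'   otherwise the grid is thinned with [subsample_grid()].
#' @param classify_stimulus Stimulus whose samples are classified across
#'   time points (`NULL` skips classification).
#' @param base_seed Integer base seed recorded in every output manifest.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(cohort = cohort_spec(),
                              encoder = encoder_config(),
                              swc = swc_config(),
                              lif = lif_config(),
                              stdp = stdp_config(),
                              desnn = desnn_config(),
                              baselines = c("svm", "mlr"),
                              grid_n = NULL,
                              classify_stimulus = "target",
                              base_seed = 1) {
  structure(list(cohort = cohort, encoder = encoder, swc = swc, lif = lif,
                 stdp = stdp, desnn = desnn, baselines = baselines,
                 grid_n = grid_n, classify_stimulus = classify_stimulus,
                 base_seed = as.integer(base_seed)),
            class = "experiment_config")
}

#' Train one unsupervised reservoir per sample
#'
#' One model per participant x time point x stimulus (a "model cell" is
#' the group x time x stimulus aggregate of these). Each
#' model starts from a fresh small-world initialisation seeded by the
#' sample's identity and learns its sample once by STDP.
#'
#' @param cohort An `erp_cohort`.
#' @param grid Reservoir coordinates.
#' @param encoder,swc,lif,stdp Stage configurations.
#' @param base_seed Integer base seed.
#' @param keep_logs Keep each model's training firing log (needed for FIN).
#' @return List of models: `reservoir`, `group`, `time_point`, `stimulus`,
#'   `participant_id` and optionally `firing_log`.
#' @export
train_cell_models <- function(cohort, grid = load_fixture("grid1471"),
                              encoder = encoder_config(),
                              swc = swc_config(), lif = lif_config(),
                              stdp = stdp_config(), base_seed = 1,
                              keep_logs = FALSE) {
  lapply(cohort$samples, function(s) {
    swc_i <- swc
    # one shared small-world initialisation per stimulus: training alone
    # differentiates participant/time models, so contrasts across
    # participants and time points are paired over the wiring draw
    swc_i$seed <- seed_for(base_seed, "wiring", s$stimulus)
    res <- build_reservoir(grid, swc = swc_i)
    fit <- run_stdp(res, encode_sample(s, encoder), lif, stdp)
    out <- list(reservoir = fit$reservoir, group = s$group,
                time_point = s$time_point, stimulus = s$stimulus,
                participant_id = s$participant_id)
    if (keep_logs) out$firing_log <- fit$firing_log
    out
  })
}

#' Run the full experiment from one configuration
#'
#' Generates (or accepts) a cohort, trains one unsupervised model per
#' sample, summarises connection weights regionally, runs the
#' repeated-measures ANOVA and Kendall-tau analyses, classifies samples
#' across time points with the deSNN and baselines, and writes every
#' artefact to `out_dir`. A rerun with the same configuration produces
#' byte-identical outputs.
#'
#' @param config An [experiment_config()].
#' @param out_dir Output directory.
#' @param cohort Optional pre-built `erp_cohort` (e.g. from [read_cohort()]);
#'   defaults to generating one from `config$cohort`.
#' @return Invisibly, a list with the in-memory results: `region_table`,
#'   `anova`, `kendall`, `classification`, `fin`, `out_dir`.
#' @export
run_experiment <- function(config, out_dir, cohort = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    message(sprintf("[%s] seed=%d %s", name, config$base_seed,
                    format(Sys.time(), "%H:%M:%S")))
    tryCatch(expr, error = function(e) {
      stop_snnerp(sprintf("stage '%s' failed: %s", name,
                          conditionMessage(e)), "snnerp_stage_error")
    })
  }
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(lapply(unclass(config), unclass), cfg_path,
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  cfg_hash <- unname(tools::md5sum(cfg_path))

  if (is.null(cohort)) {
    cohort <- stage("simulate", generate_cohort(config$cohort))
    stage("simulate", write_cohort(cohort, file.path(out_dir, "cohort")))
  }
  grid <- if (is.null(config$grid_n)) load_fixture("grid1471")
          else subsample_grid(config$grid_n)

  models <- stage("train", train_cell_models(
    cohort, grid, config$encoder, config$swc, config$lif, config$stdp,
    config$base_seed, keep_logs = TRUE))

  rwt <- stage("analyse", region_weight_table(models))
  utils::write.table(cbind(rwt$cells, config_hash = cfg_hash),
                     file.path(out_dir, "region_weights.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cbind(rwt$totals, config_hash = cfg_hash),
                     file.path(out_dir, "total_weights.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # FIN per group x time x stimulus cell, summed over participants
  fins <- stage("analyse", local({
    cells <- unique(lapply(models, function(m)
      list(m$group, m$time_point, m$stimulus)))
    out <- list()
    for (cl in cells) {
      sel <- Filter(function(m) identical(list(m$group, m$time_point,
                                               m$stimulus), cl), models)
      fin <- Reduce(`+`, lapply(sel, function(m)
        build_fin(m$firing_log, m$reservoir)))
      nm <- paste(unlist(cl), collapse = "_")
      write_fin(fin, file.path(out_dir, "fin"), nm)
      out[[nm]] <- fin
    }
    out
  }))

  # repeated-measures ANOVA on the lateral region means
  anova_res <- stage("report", local({
    long <- rwt$per_model[!is.na(rwt$per_model$mean_weight), ]
    within <- c("site", "hemisphere", "time_point", "stimulus")
    within <- within[vapply(within, function(v)
      length(unique(long[[v]])) > 1, TRUE)]
    if (length(within) == 0) return(NULL)
    rm_anova_gg(long, dv = "mean_weight", id = "participant_id",
                within = within, between = "group")
  }))
  if (!is.null(anova_res)) {
    utils::write.table(anova_res, file.path(out_dir, "anova.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # Kendall tau: baseline right-frontal weights vs psychometrics
  kendall_res <- stage("report", local({
    base_tp <- sort(unique(vapply(models, `[[`, "", "time_point")))[1]
    w <- NULL
    for (st in unique(vapply(models, `[[`, "", "stimulus"))) {
      sel <- Filter(function(m) m$time_point == base_tp && m$stimulus == st,
                    models)
      v <- vapply(sel, function(m) {
        rm_ <- region_means(m$reservoir)
        rm_$mean_weight[rm_$site == "frontal" & rm_$hemisphere == "right"]
      }, 0)
      df <- data.frame(participant_id = vapply(sel, `[[`, "", "participant_id"))
      df[[paste0("right_frontal_", st)]] <- v
      w <- if (is.null(w)) df else merge(w, df, by = "participant_id")
    }
    kendall_tau_matrix(w, cohort$psychometrics)
  }))
  utils::write.table(kendall_res, file.path(out_dir, "kendall.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # deSNN + baseline classification of one stimulus across time points
  classification <- NULL
  if (!is.null(config$classify_stimulus) &&
      length(unique(config$cohort$time_points)) > 1) {
    classification <- stage("classify", local({
      out <- list()
      for (g in unique(vapply(cohort$samples, `[[`, "", "group"))) {
        sel <- Filter(function(s) s$group == g &&
                        s$stimulus == config$classify_stimulus,
                      cohort$samples)
        labs <- vapply(sel, `[[`, "", "time_point")
        rep <- run_loocv(sel, labs, grid, config$encoder, config$swc,
                         config$lif, config$stdp, config$desnn,
                         base_seed = seed_for(config$base_seed, "loocv", g))
        bl <- if (length(config$baselines))
          run_baselines(sel, labs, config$baselines,
                        seed = seed_for(config$base_seed, "baseline", g))
          else NULL
        out[[g]] <- list(desnn = rep, baselines = bl)
        jsonlite::write_json(
          list(group = g, config_hash = cfg_hash,
               confusion = as.data.frame.matrix(rep$confusion),
               per_class_accuracy = as.list(100 * rep$per_class_accuracy),
               total_accuracy = 100 * rep$total_accuracy,
               macro_f1 = 100 * rep$macro_f1,
               baselines = as.list(100 * bl)),
          file.path(out_dir, sprintf("classification_%s.json", g)),
          auto_unbox = TRUE, pretty = TRUE, digits = NA)
      }
      out
    }))
  }
  invisible(list(region_table = rwt, anova = anova_res,
                 kendall = kendall_res, classification = classification,
                 fin = fins, config_hash = cfg_hash, out_dir = out_dir))
}

#' Read a cohort directory written by [write_cohort()]
#'
#' Samples are validated against the packaged montage (62 channels, the
#' manifest's epoch length) and channel order is normalised to the montage
#' order.
#'
#' @param dir Cohort directory containing `manifest.json`.
#' @return An `erp_cohort`.
#' @export
read_cohort <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) {
    stop_snnerp(sprintf("no manifest.json in %s", dir), "snnerp_format_error")
  }
  man <- jsonlite::read_json(mpath)
  channels <- montage_channels()
  allowed <- c("experimental", "waitlist")
  samples <- lapply(man$samples, function(rec) {
    if (!rec$group %in% allowed) {
      stop_snnerp(sprintf("file %s: unknown group '%s' (allowed: %s)",
                          rec$file, rec$group,
                          paste(allowed, collapse = ", ")),
                  "snnerp_format_error")
    }
    x <- utils::read.delim(file.path(dir, rec$file), check.names = FALSE)
    if (!setequal(names(x), channels) || ncol(x) != length(channels)) {
      stop_snnerp(sprintf("file %s: expected the 62 montage channels, got %d",
                          rec$file, ncol(x)), "snnerp_format_error")
    }
    if (nrow(x) != man$epoch_len) {
      stop_snnerp(sprintf("file %s: expected %d samples, got %d",
                          rec$file, man$epoch_len, nrow(x)),
                  "snnerp_format_error")
    }
    dat <- t(as.matrix(x[, channels]))
    structure(list(participant_id = rec$participant_id, group = rec$group,
                   time_point = rec$time_point, stimulus = rec$stimulus,
                   data = dat, channels = channels),
              class = "erp_sample")
  })
  psy_path <- file.path(dir, "psychometrics.tsv")
  psy <- if (file.exists(psy_path)) utils::read.delim(psy_path) else NULL
  structure(list(samples = samples, psychometrics = psy,
                 spec = list(seed = man$seed, epoch_len = man$epoch_len)),
            class = "erp_cohort")
}
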