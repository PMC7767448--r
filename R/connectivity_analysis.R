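#' Activation level of a trained reservoir
#'
#' The activation level is the mean of the connection-weight magnitudes over
#' all connections, a scalar summary of how strongly a trained model is
#' wired. The absolute value keeps inhibitory connections from cancelling
#' excitatory ones; `signed = TRUE` gives the raw mean instead.
#'
#' @param reservoir An `snn_reservoir` (or a numeric weight vector).
#' @param signed If `TRUE`, average signed weights.
#' @return A single number.
#' @export
activation_level <- function(reservoir, signed = FALSE) {
  w <- if (inherits(reservoir, "snn_reservoir")) reservoir$edges$weight
       else as.numeric(reservoir)
  if (length(w) == 0) {
    stop_snnerp("reservoir has no connections", "snnerp_analysis_error")
  }
  if (signed) mean(w) else mean(abs(w))
}

# internal: cluster assignment of reservoir neurons to input channels
# (Voronoi over the input neurons' coordinates)
neuron_clusters <- function(reservoir) {
  in_xyz <- reservoir$coords[reservoir$input_map, , drop = FALSE]
  d2 <- outer(rowSums(reservoir$coords^2), rowSums(in_xyz^2), `+`) -
    2 * reservoir$coords %*% t(in_xyz)
  stats::setNames(names(reservoir$input_map)[apply(d2, 1, which.min)], NULL)
}

# internal: (site, hemisphere) per reservoir neuron via its cluster channel
neuron_regions <- function(reservoir, attribution_xyz = NULL) {
  cl <- neuron_clusters(reservoir)
  reg <- load_fixture("regions_fig5")
  i <- match(cl, reg$channel)
  data.frame(channel = cl, site = reg$site[i], hemisphere = reg$hemisphere[i])
}

#' Regional mean connection weights of one trained reservoir
#'
#' Every reservoir neuron is assigned to the region of its nearest input
#' channel; a connection belongs to the region of its presynaptic neuron
#' (`attribution = "pre"`, default), its postsynaptic neuron (`"post"`) or
#' the input channel nearest its midpoint (`"mid"`). Midline-cluster
#' connections contribute to the model total but to no hemispheric cell.
#'
#' @param reservoir A trained `snn_reservoir`.
#' @param signed Average signed weights instead of magnitudes.
#' @param attribution One of `"pre"`, `"post"`, `"mid"`.
#' @return Data frame with `site`, `hemisphere`, `mean_weight`, `n_edges`
#'   covering the 5 x 2 lateral cells (NA mean where a cell has no member
#'   connections), plus attribute-free column values; model total available
#'   via [activation_level()].
#' @export
region_means <- function(reservoir, signed = FALSE,
                         attribution = c("pre", "post", "mid")) {
  attribution <- match.arg(attribution)
  nr <- neuron_regions(reservoir)
  e <- reservoir$edges
  if (nrow(e) == 0) {
    stop_snnerp("reservoir has no connections", "snnerp_analysis_error")
  }
  idx <- switch(attribution,
    pre = e$pre,
    post = e$post,
    mid = {
      mid_xyz <- (reservoir$coords[e$pre, , drop = FALSE] +
                    reservoir$coords[e$post, , drop = FALSE]) / 2
      in_xyz <- reservoir$coords[reservoir$input_map, , drop = FALSE]
      d2 <- outer(rowSums(mid_xyz^2), rowSums(in_xyz^2), `+`) -
        2 * mid_xyz %*% t(in_xyz)
      ch <- names(reservoir$input_map)[apply(d2, 1, which.min)]
      reg <- load_fixture("regions_fig5")
      j <- match(ch, reg$channel)
      site <- reg$site[j]; hemi <- reg$hemisphere[j]
      w <- if (signed) e$weight else abs(e$weight)
      return(region_cell_means(site, hemi, w))
    })
  w <- if (signed) e$weight else abs(e$weight)
  region_cell_means(nr$site[idx], nr$hemisphere[idx], w)
}

region_cell_means <- function(site, hemi, w) {
  sites <- c("frontal", "frontocentral", "temporal", "centroparietal",
             "occipitoparietal")
  cells <- expand.grid(site = sites, hemisphere = c("left", "right"),
                       stringsAsFactors = FALSE)
  cells$mean_weight <- NA_real_
  cells$n_edges <- 0L
  for (r in seq_len(nrow(cells))) {
    sel <- !is.na(site) & site == cells$site[r] & hemi == cells$hemisphere[r]
    cells$n_edges[r] <- sum(sel)
    if (any(sel)) cells$mean_weight[r] <- mean(w[sel])
  }
  cells
}

#' Region x hemisphere weight table across trained models
#'
#' Aggregates [region_means()] over a collection of trained per-participant
#' reservoirs into the cells of a group x time x stimulus x site x
#' hemisphere table (mean over the cell's participants), plus one total
#' weight per model. Cells without member connections in any contributing
#' model are reported as `NA` and flagged, never silently zeroed.
#'
#' @param models List of entries, each a list with `reservoir`, `group`,
#'   `time_point`, `stimulus`, `participant_id`.
#' @inheritParams region_means
#' @return List of class `region_weight_table` with `cells` (aggregated)
#'   and `totals` (per model).
#' @export
region_weight_table <- function(models, signed = FALSE,
                                attribution = c("pre", "post", "mid")) {
  attribution <- match.arg(attribution)
  per <- do.call(rbind, lapply(models, function(m) {
    rm_ <- region_means(m$reservoir, signed, attribution)
    rm_$group <- m$group
    rm_$time_point <- m$time_point
    rm_$stimulus <- m$stimulus
    rm_$participant_id <- m$participant_id
    rm_
  }))
  agg <- stats::aggregate(
    cbind(mean_weight, n_edges) ~ group + time_point + stimulus + site + hemisphere,
    data = per, FUN = mean, na.action = stats::na.pass)
  agg$missing <- is.na(agg$mean_weight)
  totals <- do.call(rbind, lapply(models, function(m) {
    data.frame(group = m$group, time_point = m$time_point,
               stimulus = m$stimulus, participant_id = m$participant_id,
               total_weight = activation_level(m$reservoir, signed))
  }))
  structure(list(cells = agg, totals = totals, per_model = per),
            class = "region_weight_table")
}

#' Feature interaction network from a firing log
#'
#' Counts spike transmissions between input-channel neuron clusters: a
#' firing of a neuron in cluster a delivers one spike along each of its
#' outgoing edges; the deliveries are tallied by the (source cluster,
#' destination cluster) pair.
#'
#' @param firing_log Firing log from [run_stdp()].
#' @param reservoir The `snn_reservoir` the log was produced on.
#' @param clusters Optional cluster label per reservoir neuron; defaults to
#'   the nearest-input-channel assignment (62 clusters).
#' @return Square nonnegative integer matrix (cluster x cluster), dimnames
#'   the cluster labels.
#' @export
build_fin <- function(firing_log, reservoir, clusters = NULL) {
  if (is.null(clusters)) clusters <- neuron_clusters(reservoir)
  if (length(clusters) != nrow(reservoir$coords) || anyNA(clusters)) {
    stop_snnerp("every reservoir neuron needs a cluster",
                "snnerp_config_error")
  }
  clusters <- as.character(clusters)
  labs <- if (all(clusters %in% reservoir$channels)) reservoir$channels
          else sort(unique(clusters))
  fin <- matrix(0L, length(labs), length(labs), dimnames = list(labs, labs))
  if (nrow(firing_log) == 0 || nrow(reservoir$edges) == 0) return(fin)
  fires <- tabulate(firing_log$neuron, nbins = nrow(reservoir$coords))
  e <- reservoir$edges
  src <- factor(clusters[e$pre], levels = labs)
  dst <- factor(clusters[e$post], levels = labs)
  tab <- tapply(fires[e$pre], list(src, dst), sum, default = 0L)
  fin[rownames(tab), colnames(tab)] <- as.integer(tab)
  fin
}

#' Export a FIN matrix as a square table and an edge list
#'
#' @param fin Matrix from [build_fin()].
#' @param dir Output directory.
#' @param prefix File name prefix.
#' @return `dir`, invisibly.
#' @export
write_fin <- function(fin, dir, prefix = "fin") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(fin, file.path(dir, paste0(prefix, "_matrix.tsv")),
                     sep = "\t", quote = FALSE)
  nz <- which(fin > 0, arr.ind = TRUE)
  el <- data.frame(from = rownames(fin)[nz[, 1]],
                   to = colnames(fin)[nz[, 2]], count = fin[nz])
  utils::write.table(el, file.path(dir, paste0(prefix, "_edges.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
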