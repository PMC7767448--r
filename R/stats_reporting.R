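#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Univariate repeated-measures ANOVA on a long table with one observation
#' per participant per within-cell, any number of crossed within-participant
#' factors and optional between-participant factors. Sphericity is handled
#' by the Greenhouse-Geisser epsilon: for every within effect with more than
#' one numerator degree of freedom the corrected degrees of freedom
#' (`eps * df`) and corrected p value are reported; two-level factors have
#' epsilon 1 by construction. Effect size is partial eta squared,
#' `SS_effect / (SS_effect + SS_error)`. Sums of squares are type III
#' (sum-to-zero contrasts on between factors), computed via [car::Anova()].
#'
#' @param data Long-format data.frame.
#' @param dv Name of the numeric response column.
#' @param id Name of the participant identifier column.
#' @param within Character vector of within-participant factor columns.
#' @param between Character vector of between-participant factor columns
#'   (may be empty).
#' @return Data frame of class `anova_gg` with one row per effect: `effect`,
#'   `F`, `df_num`, `df_den`, `p`, `partial_eta2`, `gg_epsilon`,
#'   `df_num_gg`, `df_den_gg`, `p_gg`.
#' @export
rm_anova_gg <- function(data, dv, id, within, between = character(0)) {
  stopifnot(length(within) >= 1)
  miss <- setdiff(c(dv, id, within, between), names(data))
  if (length(miss)) {
    stop_snnerp(paste("column(s) not in data:", paste(miss, collapse = ", ")),
                "snnerp_design_error")
  }
  for (v in c(within, between, id)) data[[v]] <- factor(data[[v]])

  cells <- interaction(data[, within, drop = FALSE], drop = FALSE, sep = ":")
  tab <- table(data[[id]], cells)
  if (any(tab != 1)) {
    bad <- which(tab != 1, arr.ind = TRUE)[1, ]
    stop_snnerp(sprintf(
      "design is not balanced/complete: participant %s has %d observation(s) in cell %s",
      rownames(tab)[bad[1]], tab[bad[1], bad[2]], colnames(tab)[bad[2]]),
      "snnerp_design_error")
  }

  idata <- expand.grid(lapply(rev(within), function(v) levels(data[[v]])),
                       stringsAsFactors = TRUE)
  names(idata) <- rev(within)
  idata <- idata[, within, drop = FALSE]
  # response matrix: participants x within-cells, columns in idata order
  key <- do.call(paste, c(data[within], sep = "\r"))
  colkey <- do.call(paste, c(idata, sep = "\r"))
  ids <- levels(data[[id]])
  Y <- matrix(NA_real_, length(ids), nrow(idata),
              dimnames = list(ids, colkey))
  Y[cbind(match(data[[id]], ids), match(key, colkey))] <- data[[dv]]

  btab <- unique(data[, c(id, between), drop = FALSE])
  btab <- btab[match(ids, btab[[id]]), , drop = FALSE]
  if (length(between)) {
    rhs <- paste(between, collapse = "*")
    contr <- stats::setNames(rep(list("contr.sum"), length(between)), between)
    mod <- stats::lm(stats::as.formula(paste("Y ~", rhs)), data = btab,
                     contrasts = contr)
  } else {
    mod <- stats::lm(Y ~ 1)
  }
  idesign <- stats::as.formula(paste("~", paste(within, collapse = "*")))
  aa <- car::Anova(mod, idata = idata, idesign = idesign, type = 3)
  # the Huynh-Feldt epsilon is computed alongside but not used; silence its
  # cosmetic "HF eps > 1 treated as 1" note
  ss <- withCallingHandlers(
    summary(aa, multivariate = FALSE),
    warning = function(w) {
      if (grepl("HF eps", conditionMessage(w))) invokeRestart("muffleWarning")
    })
  ut <- ss$univariate.tests
  eff <- setdiff(rownames(ut), "(Intercept)")

  adj <- ss$pval.adjustments
  out <- do.call(rbind, lapply(eff, function(e) {
    Fv <- ut[e, "F value"]
    df1 <- ut[e, "num Df"]
    df2 <- ut[e, "den Df"]
    p <- ut[e, "Pr(>F)"]
    pe2 <- ut[e, "Sum Sq"] / (ut[e, "Sum Sq"] + ut[e, "Error SS"])
    involves_within <- any(vapply(within, function(w) grepl(w, e, fixed = TRUE),
                                  TRUE))
    eps <- NA_real_
    pgg <- p
    if (involves_within) {
      eps <- 1
      if (!is.null(adj) && e %in% rownames(adj) &&
          is.finite(adj[e, "GG eps"])) {
        eps <- adj[e, "GG eps"]
        pgg <- adj[e, "Pr(>F[GG])"]
      }
    }
    data.frame(effect = e, F = Fv, df_num = df1, df_den = df2, p = p,
               partial_eta2 = pe2, gg_epsilon = eps,
               df_num_gg = if (is.na(eps)) df1 else eps * df1,
               df_den_gg = if (is.na(eps)) df2 else eps * df2,
               p_gg = pgg)
  }))
  rownames(out) <- NULL
  class(out) <- c("anova_gg", "data.frame")
  out
}

#' Kendall's tau correlations between region weights and psychometrics
#'
#' Tie-corrected (tau-b) Kendall correlations with two-sided p values for
#' every (weight variable, psychometric variable) pair, via
#' [stats::cor.test()]. Constant variables are flagged as undefined rather
#' than silently reported as zero.
#'
#' @param weights Data.frame of per-participant weight variables, first
#'   column a participant id.
#' @param psychometrics Data.frame of psychometric scores, first column the
#'   participant id (e.g. the cohort generator's table).
#' @param weight_vars,psych_vars Columns to correlate; default all numeric
#'   columns except the id.
#' @param p_adjust `"none"` (default) or `"BH"` for Benjamini-Hochberg
#'   adjusted p values in an extra column.
#' @return Data frame with `weight_var`, `psych_var`, `tau`, `p`, `n`,
#'   `undefined` (and `p_adj` when requested).
#' @export
kendall_tau_matrix <- function(weights, psychometrics,
                               weight_vars = setdiff(names(weights),
                                                     names(weights)[1]),
                               psych_vars = c("FFMQ", "BDI",
                                              "DASS_Depression",
                                              "DASS_Anxiety", "DASS_Stress"),
                               p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  idw <- names(weights)[1]
  idp <- names(psychometrics)[1]
  m <- merge(weights, psychometrics, by.x = idw, by.y = idp)
  if (nrow(m) < 3) {
    stop_snnerp("need at least 3 aligned participants", "snnerp_input_error")
  }
  miss <- setdiff(c(weight_vars, psych_vars), names(m))
  if (length(miss)) {
    stop_snnerp(paste("variable(s) not found:", paste(miss, collapse = ", ")),
                "snnerp_input_error")
  }
  out <- do.call(rbind, lapply(weight_vars, function(wv) {
    do.call(rbind, lapply(psych_vars, function(pv) {
      x <- m[[wv]]
      y <- m[[pv]]
      ok <- is.finite(x) & is.finite(y)
      if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        return(data.frame(weight_var = wv, psych_var = pv, tau = NA_real_,
                          p = NA_real_, n = sum(ok), undefined = TRUE))
      }
      ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = "kendall"))
      data.frame(weight_var = wv, psych_var = pv,
                 tau = unname(ct$estimate), p = ct$p.value, n = sum(ok),
                 undefined = FALSE)
    }))
  }))
  if (p_adjust == "BH") out$p_adj <- stats::p.adjust(out$p, "BH")
  rownames(out) <- NULL
  out
}
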