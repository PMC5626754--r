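# Split-plot (mixed) ANOVA, Fisher LSD post-hoc tests and Cohen's d,
# implemented from first principles.
#
# Model: one between-subject factor (group, possibly unbalanced) crossed with
# one or two within-subject factors, one observation per subject x within
# cell. Each within-subject effect (and its group interaction) is tested
# against its own effect x subject-within-group error stratum; the group
# effect is tested against subjects-within-groups. No sphericity correction.
#
# Mechanism: per-subject cell vectors are projected onto orthonormal
# within-subject contrasts (normalized Helmert), reducing every stratum to a
# one-way decomposition over subjects. The test suite checks this against an
# independent brute-force sums-of-squares oracle.

orth_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  sweep(C, 2, sqrt(colSums(C^2)), "/")
}

# orthonormal contrast columns for each within effect, given within factor
# level counts (named integer vector, slowest-varying factor first)
within_effect_contrasts <- function(levels) {
  f <- names(levels)
  mats <- lapply(seq_along(levels), function(i) {
    list(mean = matrix(1 / sqrt(levels[i]), levels[i], 1),
         eff = orth_contrasts(levels[i]))
  })
  effects <- list()
  if (length(levels) == 1) {
    effects[[f[1]]] <- mats[[1]]$eff
  } else {
    effects[[f[1]]] <- kronecker(mats[[1]]$eff, mats[[2]]$mean)
    effects[[f[2]]] <- kronecker(mats[[1]]$mean, mats[[2]]$eff)
    effects[[paste(f[1], f[2], sep = ":")]] <-
      kronecker(mats[[1]]$eff, mats[[2]]$eff)
  }
  effects
}

# weighted (per-subject) one-way decomposition of a score matrix Z
# (subjects x q contrasts): effect, effect x group, residual sums of squares
stratum_ss <- function(Z, g) {
  ng <- as.vector(table(g))
  grand <- colMeans(Z)
  gm <- t(vapply(levels(g),
                 function(l) colMeans(Z[g == l, , drop = FALSE]),
                 numeric(ncol(Z))))
  if (ncol(Z) == 1) gm <- matrix(gm, ncol = 1) # vapply drops to a row otherwise
  ss_eff <- nrow(Z) * sum(grand^2)
  ss_int <- sum(ng * rowSums(sweep(gm, 2, grand)^2))
  resid <- Z - gm[as.integer(g), , drop = FALSE]
  ss_res <- sum(resid^2)
  c(eff = ss_eff, int = ss_int, res = ss_res)
}

#' Split-plot mixed ANOVA
#'
#' Computes the classical univariate split-plot decomposition for a design
#' with one between-subject factor and one or two within-subject factors
#' (complete within-cells per subject; groups may be unbalanced). The
#' between-subject effect is tested against the subjects-within-groups mean
#' square; each within effect and its group interaction against its own
#' effect-by-subject-within-group mean square. Degrees of freedom are exact
#' integers (no sphericity correction).
#'
#' @param data data frame in long format.
#' @param dv name of the response column (amplitude, microvolts).
#' @param subject name of the subject identifier column.
#' @param between name of the group column.
#' @param within character vector (length 0, 1 or 2) of within-factor columns.
#'   With length 0 the model reduces to the classical one-way ANOVA.
#' @return An `ffr_anova`: data frame with one row per effect (and per error
#'   stratum), columns `effect`, `stratum`, `ss`, `df`, `ms`, `F`, `p`.
#' @export
mixed_anova <- function(data, dv = "amplitude", subject = "subject_id",
                        between = "group", within = c("region", "component")) {
  data <- as.data.frame(data)
  need <- c(dv, subject, between, within)
  miss <- setdiff(need, names(data))
  if (length(miss)) stopf("missing column(s): %s", paste(miss, collapse = ", "))
  if (any(!is.finite(data[[dv]]))) stopf("non-finite values in '%s'", dv)

  subj <- factor(data[[subject]])
  grp_of <- tapply(as.character(data[[between]]), subj, function(x) {
    u <- unique(x)
    if (length(u) != 1) stopf("subject with inconsistent group labels")
    u
  })
  g <- factor(grp_of[levels(subj)])
  a <- nlevels(g)
  if (a < 2) stopf("between factor needs >= 2 levels (got %d)", a)
  if (any(table(g) < 2)) stopf("every group needs >= 2 subjects")
  N <- nlevels(subj)

  wfac <- lapply(within, function(wf) factor(data[[wf]]))
  names(wfac) <- within
  lv <- vapply(wfac, nlevels, integer(1))
  J <- prod(c(lv, 1))

  # subjects x cells matrix, cells ordered with the first within factor slowest
  cell <- switch(as.character(length(within)),
                 "0" = factor(rep("cell", nrow(data))),
                 "1" = wfac[[1]],
                 "2" = interaction(wfac[[2]], wfac[[1]]), # 2nd factor fastest
                 stopf("at most 2 within factors supported"))
  tab <- table(subj, cell)
  if (any(tab != 1))
    stopf("each subject needs exactly one observation per within-cell crossing")
  Y <- matrix(NA_real_, N, J, dimnames = list(levels(subj), levels(cell)))
  Y[cbind(as.integer(subj), as.integer(cell))] <- data[[dv]]

  rows <- list()
  # Between stratum operates on subject mean scores scaled by sqrt(J); the
  # stratum's 'eff' piece is the (untestable) grand-mean SS, 'int' the group
  # SS about the weighted grand mean, 'res' the subjects-within-groups SS.
  m <- Y %*% rep(1 / sqrt(J), J)
  ssb <- stratum_ss(m, g)
  ss_subj <- ssb[["res"]]
  df_grp <- a - 1
  df_subj <- N - a
  ms_grp <- ssb[["int"]] / df_grp
  ms_subj <- ss_subj / df_subj
  rows[[length(rows) + 1]] <- data.frame(
    effect = between, stratum = "between", ss = ssb[["int"]], df = df_grp,
    ms = ms_grp, F = ms_grp / ms_subj,
    p = stats::pf(ms_grp / ms_subj, df_grp, df_subj, lower.tail = FALSE))
  rows[[length(rows) + 1]] <- data.frame(
    effect = "subjects(group)", stratum = "between", ss = ss_subj,
    df = df_subj, ms = ms_subj, F = NA_real_, p = NA_real_)

  if (length(within) > 0) {
    effs <- within_effect_contrasts(lv)
    for (en in names(effs)) {
      C <- effs[[en]]
      Z <- Y %*% C
      ss <- stratum_ss(Z, g)
      q <- ncol(C)
      df_e <- q
      df_i <- q * (a - 1)
      df_r <- q * (N - a)
      ms_e <- ss[["eff"]] / df_e
      ms_i <- ss[["int"]] / df_i
      ms_r <- ss[["res"]] / df_r
      rows[[length(rows) + 1]] <- data.frame(
        effect = en, stratum = en, ss = ss[["eff"]], df = df_e, ms = ms_e,
        F = ms_e / ms_r, p = stats::pf(ms_e / ms_r, df_e, df_r, lower.tail = FALSE))
      rows[[length(rows) + 1]] <- data.frame(
        effect = paste(between, en, sep = ":"), stratum = en, ss = ss[["int"]],
        df = df_i, ms = ms_i, F = ms_i / ms_r,
        p = stats::pf(ms_i / ms_r, df_i, df_r, lower.tail = FALSE))
      rows[[length(rows) + 1]] <- data.frame(
        effect = paste0(en, ":subjects(group)"), stratum = en, ss = ss[["res"]],
        df = df_r, ms = ms_r, F = NA_real_, p = NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$df <- as.integer(out$df)
  attr(out, "n_subjects") <- N
  attr(out, "n_within_cells") <- J
  attr(out, "group_sizes") <- as.integer(table(g))
  attr(out, "subject_means") <- stats::setNames(as.numeric(m) / sqrt(J), levels(subj))
  attr(out, "groups") <- g
  class(out) <- c("ffr_anova", class(out))
  out
}

#' @export
print.ffr_anova <- function(x, ...) {
  cat("Split-plot ANOVA\n")
  y <- as.data.frame(x)
  y$ss <- signif(y$ss, 5); y$ms <- signif(y$ms, 5)
  y$F <- ifelse(is.na(y$F), "", sprintf("%.3f", y$F))
  y$p <- ifelse(is.na(y$p), "", format.pval(y$p, digits = 3))
  print(y, row.names = FALSE)
  invisible(x)
}

#' One-way ANOVA within a single time region
#'
#' Convenience wrapper: [mixed_anova()] restricted to one region's rows, with
#' spectral component as the single within-subject factor.
#'
#' @param data long-format data frame containing one region's rows.
#' @param dv,subject,between,component column names.
#' @return An `ffr_anova`.
#' @export
oneway_within_region <- function(data, dv = "amplitude", subject = "subject_id",
                                 between = "group", component = "component") {
  mixed_anova(data, dv = dv, subject = subject, between = between,
              within = component)
}

#' Cohen's d (pooled standard deviation)
#'
#' `d = (mean(x) - mean(y)) / s_pooled` with `(n - 1)`-weighted pooling and no
#' small-sample correction.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @return numeric effect size.
#' @export
cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stopf("each sample needs n >= 2")
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  if (sp2 <= 0) stopf("pooled standard deviation is zero")
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Fisher LSD pairwise comparisons
#'
#' Unadjusted pairwise t-tests between group means using a common error mean
#' square: `t = (m_i - m_j) / sqrt(MSe (1/n_i + 1/n_j))` with the error df of
#' the ANOVA stratum, two-sided p, no multiplicity correction. By default the
#' error mean square and df are those of the one-way ANOVA on `x`; pass the
#' values from a fitted [mixed_anova()] stratum to use its error term.
#' Cohen's d is reported per pair from the raw samples.
#'
#' @param x numeric scores (one per subject).
#' @param g group factor.
#' @param error_ms error mean square; default: one-way residual MS of `x`.
#' @param error_df error degrees of freedom; default `N - k`.
#' @return data frame, one row per group pair: `group_i`, `group_j`,
#'   `mean_diff`, `t`, `df`, `p`, `cohens_d`.
#' @export
fisher_lsd <- function(x, g, error_ms = NULL, error_df = NULL) {
  g <- factor(g)
  if (nlevels(g) < 2) stopf("need >= 2 groups")
  if (length(x) != length(g)) stopf("x and g lengths differ")
  if (is.null(error_ms) != is.null(error_df))
    stopf("provide both error_ms and error_df, or neither")
  ng <- tapply(x, g, length)
  means <- tapply(x, g, mean)
  if (is.null(error_ms)) {
    error_df <- length(x) - nlevels(g)
    if (error_df < 1) stopf("no residual degrees of freedom")
    error_ms <- sum(tapply(x, g, function(v) sum((v - mean(v))^2))) / error_df
  }
  if (error_ms <= 0) stopf("error mean square must be positive")
  pairs <- utils::combn(levels(g), 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    diff <- means[[i]] - means[[j]]
    tval <- diff / sqrt(error_ms * (1 / ng[[i]] + 1 / ng[[j]]))
    data.frame(group_i = i, group_j = j, mean_diff = diff, t = tval,
               df = error_df,
               p = 2 * stats::pt(abs(tval), error_df, lower.tail = FALSE),
               cohens_d = cohens_d(x[g == i], x[g == j]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# features (ffr_features data frame) -> long table for one model
features_long <- function(features, components, region = NULL) {
  f <- as.data.frame(features)
  if (!is.null(region)) f <- f[f$region == region, , drop = FALSE]
  long <- do.call(rbind, lapply(components, function(cmp) {
    data.frame(subject_id = f$subject_id, group = f$group, region = f$region,
               component = cmp, amplitude = f[[cmp]], stringsAsFactors = FALSE)
  }))
  rownames(long) <- NULL
  long
}

group_effect_row <- function(an, between = "group") {
  as.data.frame(an)[an$effect == between, , drop = FALSE]
}

# Fisher LSD for the group effect of a fitted mixed_anova, on subject-mean
# scores with the subjects-within-groups error stratum.
lsd_for_group_effect <- function(an) {
  m <- attr(an, "subject_means")
  g <- attr(an, "groups")
  J <- attr(an, "n_within_cells")
  tab <- as.data.frame(an)
  err <- tab[tab$effect == "subjects(group)", ]
  fisher_lsd(m, g, error_ms = err$ms / J, error_df = err$df)
}

#' Run the full group analysis on a cohort feature table
#'
#' Executes, on a per-subject spectral feature table:
#' 1. the global split-plot model: group (between) x time region (2) x
#'    spectral component (4: `f0_amp`, `f1_mean`, `non_f1_mean`, `mean_h`);
#' 2. the consonant model: group x component (`f0_amp`, `mean_h`);
#' 3. the vowel model: group x component (`f0_amp`, `f1_mean`, `non_f1_mean`);
#' 4. per-feature one-way group ANOVAs (consonant F0 and harmonics mean;
#'    vowel F0, formant mean, non-formant mean);
#' 5. Fisher LSD post-hoc tests with Cohen's d for every group effect with
#'    `p < alpha` (or for all group effects when `posthoc = "always"`).
#'
#' @param features an `ffr_features` data frame (two rows per subject).
#' @param alpha omnibus significance gate for post-hoc tests.
#' @param posthoc `"auto"` (gate on the omnibus p) or `"always"`.
#' @return A list of class `ffr_results` with elements `global`, `consonant`,
#'   `vowel`, `per_feature` (list of one-way `ffr_anova`), and `posthoc`
#'   (named list of LSD tables). Serializable with [results_to_json()].
#' @export
run_group_analysis <- function(features, alpha = 0.05,
                               posthoc = c("auto", "always")) {
  posthoc <- match.arg(posthoc)
  f <- as.data.frame(features)
  if (length(unique(f$group)) < 2)
    stopf("between factor needs >= 2 groups")
  comps4 <- c("f0_amp", "f1_mean", "non_f1_mean", "mean_h")
  global <- mixed_anova(features_long(f, comps4),
                        within = c("region", "component"))
  consonant <- oneway_within_region(
    features_long(f, c("f0_amp", "mean_h"), region = "consonant"))
  vowel <- oneway_within_region(
    features_long(f, c("f0_amp", "f1_mean", "non_f1_mean"), region = "vowel"))

  feature_tests <- list(
    consonant_f0 = c("consonant", "f0_amp"),
    consonant_mean_h = c("consonant", "mean_h"),
    vowel_f0 = c("vowel", "f0_amp"),
    vowel_f1 = c("vowel", "f1_mean"),
    vowel_non_f1 = c("vowel", "non_f1_mean")
  )
  per_feature <- lapply(feature_tests, function(ft) {
    sub <- f[f$region == ft[1], c("subject_id", "group", ft[2])]
    names(sub)[3] <- "amplitude"
    mixed_anova(sub, within = character(0))
  })

  models <- c(list(global = global, consonant = consonant, vowel = vowel),
              per_feature)
  post <- list()
  for (nm in names(models)) {
    gr <- group_effect_row(models[[nm]])
    if (posthoc == "always" || (is.finite(gr$p) && gr$p < alpha))
      post[[nm]] <- lsd_for_group_effect(models[[nm]])
  }
  structure(list(global = global, consonant = consonant, vowel = vowel,
                 per_feature = per_feature, posthoc = post, alpha = alpha),
            class = "ffr_results")
}

#' @export
print.ffr_results <- function(x, ...) {
  cat("=== Global model (group x region x component) ===\n"); print(x$global)
  cat("\n=== Consonant model ===\n"); print(x$consonant)
  cat("\n=== Vowel model ===\n"); print(x$vowel)
  for (nm in names(x$per_feature)) {
    gr <- group_effect_row(x$per_feature[[nm]])
    cat(sprintf("\nGroup effect on %-18s F(%d,%d) = %.3f, p = %.4f\n",
                paste0(nm, ":"), gr$df,
                as.data.frame(x$per_feature[[nm]])$df[2], gr$F, gr$p))
  }
  if (length(x$posthoc)) {
    cat("\n=== Fisher LSD post-hoc tests ===\n")
    for (nm in names(x$posthoc)) {
      cat(sprintf("-- %s --\n", nm))
      print(x$posthoc[[nm]], row.names = FALSE, digits = 4)
    }
  }
  invisible(x)
}

#' Serialize an analysis results bundle to JSON
#'
#' @param results an `ffr_results` from [run_group_analysis()].
#' @param path optional output file.
#' @return JSON string (invisibly if `path` given).
#' @export
results_to_json <- function(results, path = NULL) {
  stopifnot(inherits(results, "ffr_results"))
  strip <- function(an) as.data.frame(unclass(an))[, c("effect", "ss", "df", "ms", "F", "p")]
  doc <- list(
    alpha = results$alpha,
    global = strip(results$global),
    consonant = strip(results$consonant),
    vowel = strip(results$vowel),
    per_feature = lapply(results$per_feature, strip),
    posthoc = results$posthoc
  )
  js <- jsonlite::toJSON(doc, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
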