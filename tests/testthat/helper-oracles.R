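# Independent brute-force oracles used to cross-check the implementation.
# These are deliberately written with explicit loops over cells and classical
# textbook formulas, sharing no code with the package's projection-based
# engine.

# Classical one-way ANOVA F by closed form.
oracle_oneway_F <- function(x, g) {
  g <- factor(g)
  k <- nlevels(g)
  N <- length(x)
  grand <- mean(x)
  ssb <- 0
  ssw <- 0
  for (l in levels(g)) {
    xi <- x[g == l]
    ssb <- ssb + length(xi) * (mean(xi) - grand)^2
    ssw <- ssw + sum((xi - mean(xi))^2)
  }
  Fval <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = Fval, df1 = k - 1, df2 = N - k,
       p = pf(Fval, k - 1, N - k, lower.tail = FALSE))
}

# Brute-force split-plot decomposition: explicit loops over subjects and
# cells, classical weighted-means sums of squares, one or two within factors.
# data: long data frame with subject_id, group, dv column, and the within
# factor columns. Returns a named list of F statistics and df pairs.
oracle_split_plot <- function(data, dv = "amplitude", within = c("region", "component")) {
  subj <- unique(data$subject_id)
  grp <- sapply(subj, function(s) unique(data$group[data$subject_id == s]))
  groups <- sort(unique(grp))
  N <- length(subj)
  a <- length(groups)
  wlev <- lapply(within, function(w) sort(unique(data[[w]])))
  names(wlev) <- within
  J <- prod(sapply(wlev, length))

  cellval <- function(s, idx) {
    sel <- data$subject_id == s
    for (i in seq_along(within)) sel <- sel & data[[within[i]]] == idx[[i]]
    data[[dv]][sel]
  }
  # subject means
  m <- sapply(subj, function(s) mean(data[[dv]][data$subject_id == s]))
  M <- mean(m)
  Mg <- sapply(groups, function(g) mean(m[grp == g]))
  ng <- sapply(groups, function(g) sum(grp == g))
  ss_group <- J * sum(ng * (Mg - M)^2)
  ss_subj <- J * sum(sapply(seq_along(subj), function(i) (m[i] - Mg[grp[i] == groups])^2))
  out <- list()
  out$group <- list(F = (ss_group / (a - 1)) / (ss_subj / (N - a)),
                    df = c(a - 1, N - a))

  # helper: per-subject deviation scores for a within effect
  # eff = list of factor names contributing contrasts
  eff_scores <- function(fac) {
    # returns matrix subjects x cells(eff levels combination) of deviation terms
    if (length(fac) == 1) {
      lev <- wlev[[fac]]
      other <- setdiff(within, fac)
      mult <- if (length(other)) length(wlev[[other]]) else 1
      sc <- sapply(lev, function(l) {
        sapply(subj, function(s) {
          sel <- data$subject_id == s & data[[fac]] == l
          mean(data[[dv]][sel])
        })
      })
      sc <- sc - m # deviation from subject mean
      list(scores = sc, mult = mult, q = length(lev) - 1)
    } else {
      lev1 <- wlev[[fac[1]]]; lev2 <- wlev[[fac[2]]]
      cells <- expand.grid(l1 = lev1, l2 = lev2, stringsAsFactors = FALSE)
      sc <- apply(cells, 1, function(cc) {
        sapply(subj, function(s) {
          y <- cellval(s, list(cc[["l1"]], cc[["l2"]]))
          m1 <- mean(data[[dv]][data$subject_id == s & data[[fac[1]]] == cc[["l1"]]])
          m2 <- mean(data[[dv]][data$subject_id == s & data[[fac[2]]] == cc[["l2"]]])
          y - m1 - m2 + m[subj == s]
        })
      })
      list(scores = sc, mult = 1,
           q = (length(lev1) - 1) * (length(lev2) - 1))
    }
  }

  for (en in c(within, if (length(within) == 2) paste(within, collapse = ":"))) {
    fac <- strsplit(en, ":")[[1]]
    es <- eff_scores(fac)
    sc <- es$scores # subjects x eff cells
    Dall <- colMeans(sc)
    Dg <- t(sapply(groups, function(g) colMeans(sc[grp == g, , drop = FALSE])))
    ss_eff <- es$mult * N * sum(Dall^2)
    ss_int <- es$mult * sum(sapply(seq_along(groups), function(gi)
      ng[gi] * sum((Dg[gi, ] - Dall)^2)))
    ss_res <- es$mult * sum(sapply(seq_along(subj), function(i)
      sum((sc[i, ] - Dg[grp[i] == groups, ])^2)))
    q <- es$q
    out[[en]] <- list(F = (ss_eff / q) / (ss_res / (q * (N - a))),
                      df = c(q, q * (N - a)))
    out[[paste0("group:", en)]] <- list(
      F = (ss_int / (q * (a - 1))) / (ss_res / (q * (N - a))),
      df = c(q * (a - 1), q * (N - a)))
  }
  out
}

# Random long-format split-plot dataset
random_split_plot_data <- function(n_groups = 3, n_per_group = c(4, 5, 3),
                                   n_region = 2, n_component = 4, sd_subj = 1,
                                   two_within = TRUE) {
  groups <- LETTERS[seq_len(n_groups)]
  rows <- list()
  sid <- 0
  for (gi in seq_len(n_groups)) {
    for (s in seq_len(n_per_group[gi])) {
      sid <- sid + 1
      off <- rnorm(1, 0, sd_subj)
      for (r in seq_len(n_region)) {
        for (cmp in seq_len(n_component)) {
          rows[[length(rows) + 1]] <- data.frame(
            subject_id = sprintf("S%02d", sid), group = groups[gi],
            region = paste0("R", r), component = paste0("C", cmp),
            amplitude = off + rnorm(1),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}

# Exhaustive in-window scan oracle for peak extraction
oracle_peak_scan <- function(freqs, amp, center, bw) {
  lo <- center - bw / 2
  hi <- center + bw / 2
  best <- -Inf
  for (i in seq_along(freqs)) {
    if (freqs[i] >= lo && freqs[i] <= hi && freqs[i] > 0 && amp[i] > best)
      best <- amp[i]
  }
  best
}

# Frequency of the strongest local maximum within +/- search of center,
# by exhaustive bin scan (ties -> lowest frequency).
oracle_local_peak <- function(freqs, amp, center, search) {
  best_amp <- -Inf
  best_f <- NA_real_
  for (i in 2:(length(freqs) - 1)) {
    if (freqs[i] < center - search || freqs[i] > center + search) next
    if (amp[i] >= amp[i - 1] && amp[i] >= amp[i + 1] &&
        (amp[i] > amp[i - 1] || amp[i] > amp[i + 1]) && amp[i] > best_amp) {
      best_amp <- amp[i]
      best_f <- freqs[i]
    }
  }
  best_f
}
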