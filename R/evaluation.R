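#' Mean absolute error between predicted and reference pressures
#'
#' @param pred,truth numeric vectors of equal length (mmHg).
#' @return MAE in mmHg.
#' @export
bp_mae <- function(pred, truth) {
  stopifnot(length(pred) == length(truth), length(pred) >= 1)
  mean(abs(pred - truth))
}

#' Bland-Altman agreement statistics
#'
#' Mean paired difference and 95% limits of agreement
#' (`mean +/- 1.96 sd`). The difference is oriented `truth - pred`, so a
#' positive mean difference means the estimator under-reads the reference.
#'
#' @param pred,truth numeric vectors of equal length >= 2.
#' @return One-row tibble: `n`, `mean_diff`, `sd_diff`, `loa_low`,
#'   `loa_high`.
#' @export
bland_altman <- function(pred, truth) {
  stopifnot(length(pred) == length(truth), length(pred) >= 2)
  d <- truth - pred
  m <- mean(d); s <- sd(d)
  tibble(n = length(d), mean_diff = m, sd_diff = s,
         loa_low = m - 1.96 * s, loa_high = m + 1.96 * s)
}

#' Intraclass correlation (two-way, absolute agreement, single measures)
#'
#' Treats the estimator and the reference as two raters scoring the same
#' subjects and returns ICC(A,1): from the two-way ANOVA mean squares
#' (subjects `MSR`, raters `MSC`, residual `MSE`, k = 2 raters, n
#' subjects),
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`.
#' This absolute-agreement single-measure form is the default because it
#' penalises systematic offsets between methods, which a consistency ICC
#' would forgive; a consistency form ICC(C,1) is available via `form`.
#'
#' @param pred,truth numeric vectors of equal length >= 3.
#' @param form `"agreement"` (default) or `"consistency"`.
#' @return The ICC as a single number.
#' @export
icc_agreement <- function(pred, truth, form = c("agreement", "consistency")) {
  form <- match.arg(form)
  n <- length(pred)
  stopifnot(length(truth) == n, n >= 3)
  long <- data.frame(value = c(pred, truth),
                     subject = factor(rep(seq_len(n), 2)),
                     rater = factor(rep(c("pred", "truth"), each = n)))
  # F-test warnings on a perfect fit are irrelevant: only mean squares are used
  ms <- suppressWarnings(
    anova(lm(value ~ rater + subject, data = long))[["Mean Sq"]])
  msc <- ms[1]; msr <- ms[2]; mse <- ms[3]
  k <- 2
  if (form == "agreement") {
    (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Standard two-sample KS statistic with the asymptotic p-value (adequate
#' at the cohort sizes this package reports on; ties, which the asymptotic
#' distribution dislikes, are tolerated silently).
#'
#' @param a,b numeric samples.
#' @return One-row tibble: `statistic`, `p_value`.
#' @export
ks_two_sample <- function(a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  res <- suppressWarnings(ks.test(a, b, exact = FALSE))
  tibble(statistic = unname(res$statistic), p_value = unname(res$p.value))
}

#' Full agreement report for one prediction/truth pair
#'
#' @param pred,truth numeric vectors (mmHg).
#' @param label optional label recorded in the report row.
#' @return One-row tibble: `label`, `n`, `mae`, `icc`, `mean_diff`,
#'   `loa_low`, `loa_high`, `ks_statistic`, `ks_p`.
#' @export
evaluate_bp <- function(pred, truth, label = NA_character_) {
  ba <- bland_altman(pred, truth)
  ks <- ks_two_sample(pred, truth)
  tibble(label = label, n = length(pred),
         mae = bp_mae(pred, truth),
         icc = icc_agreement(pred, truth),
         mean_diff = ba$mean_diff, loa_low = ba$loa_low,
         loa_high = ba$loa_high,
         ks_statistic = ks$statistic, ks_p = ks$p_value)
}

#' Compare estimator variants against ground truth across groups
#'
#' Reproduces the hypothesis-test grid used to probe whether
#' subject-specific demographic information matters: within each group
#' (everyone, then each country and gender level when those labels are
#' present), the demographic and fixed variants are compared to each other
#' and to the truth (KS test on the distributions; MAE/ICC/Bland-Altman for
#' the paired variant-vs-truth rows), and, for each two-level grouping
#' variable, the group distributions are compared between levels for the
#' truth and for the demographic variant.
#'
#' @param results tibble with columns `sbp_true`, `dbp_true`,
#'   `sbp_demographic`, `dbp_demographic`, `sbp_fixed`, `dbp_fixed` and
#'   optionally grouping columns (default `country`, `gender`).
#' @param group_vars grouping columns to use (those present are kept).
#' @param alpha significance level annotated on the report (default 0.05);
#'   an annotation, not a gate.
#' @return Tibble with one row per (group, measure, comparison):
#'   `group`, `measure`, `comparison`, `n`, `mae`, `icc`, `mean_diff`,
#'   `loa_low`, `loa_high`, `ks_statistic`, `ks_p`, `significant`.
#' @export
compare_variants <- function(results, group_vars = c("country", "gender"),
                             alpha = 0.05) {
  need <- c("sbp_true", "dbp_true", "sbp_demographic", "dbp_demographic",
            "sbp_fixed", "dbp_fixed")
  missing <- setdiff(need, names(results))
  if (length(missing)) {
    abort(paste0("results missing column(s): ", paste(missing, collapse = ", ")),
          class = "videobp_input_error")
  }
  group_vars <- intersect(group_vars, names(results))

  paired_row <- function(df, group, measure, variant) {
    pred <- df[[paste0(measure, "_", variant)]]
    truth <- df[[paste0(measure, "_true")]]
    ba <- bland_altman(pred, truth); ks <- ks_two_sample(pred, truth)
    tibble(group = group, measure = measure,
           comparison = paste0(variant, "_vs_truth"), n = length(pred),
           mae = bp_mae(pred, truth), icc = icc_agreement(pred, truth),
           mean_diff = ba$mean_diff, loa_low = ba$loa_low,
           loa_high = ba$loa_high, ks_statistic = ks$statistic,
           ks_p = ks$p_value)
  }
  variant_row <- function(df, group, measure) {
    a <- df[[paste0(measure, "_demographic")]]
    b <- df[[paste0(measure, "_fixed")]]
    ks <- ks_two_sample(a, b)
    tibble(group = group, measure = measure,
           comparison = "demographic_vs_fixed", n = length(a),
           mae = bp_mae(a, b), icc = NA_real_, mean_diff = NA_real_,
           loa_low = NA_real_, loa_high = NA_real_,
           ks_statistic = ks$statistic, ks_p = ks$p_value)
  }
  group_rows <- function(df, group) {
    dplyr::bind_rows(lapply(c("sbp", "dbp"), function(m) {
      dplyr::bind_rows(variant_row(df, group, m),
                       paired_row(df, group, m, "demographic"),
                       paired_row(df, group, m, "fixed"))
    }))
  }

  out <- group_rows(results, "all")
  for (gv in group_vars) {
    for (lev in unique(results[[gv]])) {
      sub <- results[results[[gv]] == lev, , drop = FALSE]
      if (nrow(sub) >= 3) out <- dplyr::bind_rows(out, group_rows(sub, lev))
    }
    levs <- unique(results[[gv]])
    if (length(levs) == 2L) {
      a <- results[results[[gv]] == levs[1], , drop = FALSE]
      b <- results[results[[gv]] == levs[2], , drop = FALSE]
      for (m in c("sbp", "dbp")) {
        for (src in c("true", "demographic")) {
          ks <- ks_two_sample(a[[paste0(m, "_", src)]], b[[paste0(m, "_", src)]])
          out <- dplyr::bind_rows(out, tibble(
            group = paste(levs[1], "vs", levs[2]), measure = m,
            comparison = paste0("between_groups_", src),
            n = nrow(a) + nrow(b), mae = NA_real_, icc = NA_real_,
            mean_diff = NA_real_, loa_low = NA_real_, loa_high = NA_real_,
            ks_statistic = ks$statistic, ks_p = ks$p_value))
        }
      }
    }
  }
  out$significant <- out$ks_p < alpha
  out
}

#' Bland-Altman plot
#'
#' @param pred,truth numeric vectors (mmHg).
#' @param title plot title.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(pred, truth, title = "Bland-Altman agreement") {
  ba <- bland_altman(pred, truth)
  df <- tibble(mean_bp = (pred + truth) / 2, diff_bp = truth - pred)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_bp, y = .data$diff_bp)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_hline(yintercept = ba$mean_diff, colour = "#2166AC") +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high),
                        linetype = "dashed", colour = "#B2182B") +
    ggplot2::labs(x = "mean of methods (mmHg)",
                  y = "reference - estimate (mmHg)", title = title) +
    ggplot2::theme_minimal()
}

#' Overlayed face/hand pulse signals
#'
#' @param face,hand `vbp_ppg` signals.
#' @param window optional `c(from, to)` time window in seconds.
#' @return A ggplot object.
#' @export
plot_ppg_pair <- function(face, hand, window = NULL) {
  df <- dplyr::bind_rows(
    tibble(t = face$t, value = face$value, site = "face"),
    tibble(t = hand$t, value = hand$value, site = "hand"))
  if (!is.null(window)) df <- df[df$t >= window[1] & df$t <= window[2], ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$value,
                                   colour = .data$site)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(face = "#B2182B", hand = "#2166AC")) +
    ggplot2::labs(x = "time (s)", y = "pulse (a.u.)") +
    ggplot2::theme_minimal()
}
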