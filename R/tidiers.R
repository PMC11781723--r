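#' Tidy a blood-pressure estimate
#'
#' @param x a `vbp_bp`.
#' @param ... unused.
#' @return A long tibble with one row per (subject row, quantity):
#'   `row`, `term`, `estimate`.
#' @export
tidy.vbp_bp <- function(x, ...) {
  df <- as_tibble(x)
  df$row <- seq_len(nrow(df))
  tidyr::pivot_longer(
    df[, c("row", "sbp_mmHg", "dbp_mmHg", "ptt_s", "ptt_d", "pwv_s", "pwv_d")],
    cols = -"row", names_to = "term", values_to = "estimate")
}

#' One-row summary of a blood-pressure estimate
#'
#' @param x a `vbp_bp`.
#' @param ... unused.
#' @return Tibble with `n`, `variant`, mean pressures and transit times,
#'   and the number of quality flags.
#' @export
glance.vbp_bp <- function(x, ...) {
  tibble(n = nrow(x), variant = x$variant[1],
         sbp_mmHg = mean(x$sbp_mmHg), dbp_mmHg = mean(x$dbp_mmHg),
         ptt_s = mean(x$ptt_s), ptt_d = mean(x$ptt_d),
         n_qc_flags = length(attr(x, "qc")))
}

#' @export
tidy.vbp_transit <- function(x, ...) {
  tibble(term = c("ptt_s", "ptt_d"), estimate = c(x$ptt_s, x$ptt_d),
         n_pairs = c(x$n_pairs_s, x$n_pairs_d))
}

#' @export
glance.vbp_transit <- function(x, ...) {
  tibble(ptt_s = x$ptt_s, ptt_d = x$ptt_d, n_pairs_s = x$n_pairs_s,
         n_pairs_d = x$n_pairs_d, n_qc_flags = length(x$qc))
}

#' @export
print.vbp_config <- function(x, ...) {
  cat("<vbp_config>\n")
  cat(sprintf("  variant: %s; band-pass %g-%g Hz (order %d, zero-phase)\n",
              x$variant, x$low_hz, x$high_hz, x$filter_order))
  cat(sprintf("  CHROM window %g s (overlap %g); peak refractory %g s\n",
              x$chrom_window_s, x$chrom_overlap, x$min_peak_distance_s))
  k <- x$constants
  cat(sprintf("  constants: rho = %g, E0 = %g, alpha = %g\n", k$rho, k$E0, k$alpha))
  invisible(x)
}
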