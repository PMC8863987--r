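#' Burst variance analysis (BVA)
#'
#' Qualitative test for within-burst FRET dynamics. Each burst's
#' donor-excitation photons (streams 0 and 1) are cut into consecutive,
#' non-overlapping windows of `window_n` photons; each window yields a
#' window-wise `E`; the burst's score is the standard deviation of those
#' window E values. For a static molecule this standard deviation is set by
#' shot noise alone, `sqrt(E (1 - E) / window_n)` (the "semicircle"); bursts
#' lying above the semicircle indicate dynamic heterogeneity such as
#' within-burst interconversion.
#'
#' Bursts with fewer than `2 * window_n` donor-excitation photons cannot
#' yield a standard deviation and are skipped (their number is reported in
#' the `skipped` attribute).
#'
#' @param series A `photon_series` with assigned streams.
#' @param bursts A `burst_set` into `series`.
#' @param window_n Photons per window (default 5, standard BVA practice).
#' @return A data frame with one row per scored burst: `burst_id`, `E_raw`
#'   (burst-wise, donor-excitation photons), `sd_E` (across windows) and
#'   `n_windows`; attribute `skipped` counts bursts with too few photons.
#' @seealso [bva_bins()], [bva_semicircle()]
#' @export
bva <- function(series, bursts, window_n = 5L) {
  stopifnot(inherits(series, "photon_series"), inherits(bursts, "burst_set"))
  if (window_n < 2) stop("window_n must be at least 2")
  ids <- numeric(0); e <- numeric(0); s <- numeric(0); nw <- integer(0)
  skipped <- 0L
  for (b in seq_len(nrow(bursts))) {
    idx <- (bursts$i_start[b] + 1L):bursts$i_stop[b]
    str <- series$stream_index[idx]
    dex <- str[str %in% c(0L, 1L)]
    k <- length(dex) %/% window_n
    if (k < 2L) { skipped <- skipped + 1L; next }
    win <- matrix(dex[seq_len(k * window_n)], nrow = window_n)
    we <- colMeans(win == 1L)
    ids <- c(ids, bursts$burst_id[b])
    e <- c(e, mean(dex == 1L))
    s <- c(s, sd(we))
    nw <- c(nw, k)
  }
  structure(data.frame(burst_id = ids, E_raw = e, sd_E = s, n_windows = nw),
            skipped = skipped, window_n = window_n,
            class = c("bva_result", "data.frame"))
}

#' Shot-noise (static FRET) semicircle
#'
#' The standard deviation of window-wise E expected from shot noise alone
#' for a static state with efficiency `E` and windows of `n` photons.
#'
#' @param E Raw FRET efficiency (vectorized).
#' @param n Photons per BVA window.
#' @return `sqrt(E * (1 - E) / n)`.
#' @export
bva_semicircle <- function(E, n) sqrt(E * (1 - E) / n)

#' Bin BVA results along the E axis
#'
#' @param x A [bva()] result.
#' @param breaks E-axis bin boundaries (default 20 bins over \[0, 1\]).
#' @return Data frame `E_mid`, `mean_sd` (mean per-burst `sd_E`), `se_sd`
#'   (Monte-Carlo standard error of that mean) and `n_bursts` for non-empty
#'   bins.
#' @export
bva_bins <- function(x, breaks = seq(0, 1, by = 0.05)) {
  stopifnot(inherits(x, "bva_result"))
  bin <- cut(x$E_raw, breaks, include.lowest = TRUE)
  keep <- !is.na(bin)
  agg_m <- tapply(x$sd_E[keep], bin[keep], mean)
  agg_s <- tapply(x$sd_E[keep], bin[keep], function(v)
    if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_)
  agg_n <- tapply(x$sd_E[keep], bin[keep], length)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  ok <- !is.na(agg_m)
  data.frame(E_mid = mids[ok], mean_sd = agg_m[ok], se_sd = agg_s[ok],
             n_bursts = as.integer(agg_n[ok]), row.names = NULL)
}

#' @export
plot.bva_result <- function(x, ..., breaks = seq(0, 1, by = 0.05)) {
  wn <- attr(x, "window_n")
  plot(x$E_raw, x$sd_E, pch = 16, cex = 0.4, col = "#00000040",
       xlab = expression(E[raw]), ylab = expression(sd(E[raw])),
       xlim = c(0, 1), ...)
  ee <- seq(0, 1, length.out = 200)
  lines(ee, bva_semicircle(ee, wn), col = "red")
  bb <- bva_bins(x, breaks)
  points(bb$E_mid, bb$mean_sd, pch = 17, col = "blue")
  invisible(x)
}
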