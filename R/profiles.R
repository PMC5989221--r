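#' Locally weighted smoothing of a windowed profile
#'
#' Fits a loess regression (degree 2) of value against window midpoint,
#' separately per chromosome. The span is specified in bp and converted to
#' the fraction of that chromosome's windows it covers. Windows with missing
#' values are excluded from the fit and predicted only if they fall inside
#' the observed range (gaps are bridged, never extrapolated).
#'
#' @param profile data.frame `chrom`, `start`, `end`, `mid`, `value`.
#' @param span_bp smoothing span in bp (default 30000).
#' @param degree local polynomial degree (default 2).
#' @return the profile with `value` replaced by its smooth and attribute
#'   `smoothed = TRUE`.
#' @export
smooth_profile <- function(profile, span_bp = 30000, degree = 2) {
  out <- profile
  for (ch in unique(profile$chrom)) {
    wi <- which(profile$chrom == ch)
    x <- profile$mid[wi]
    y <- profile$value[wi]
    ok <- is.finite(y)
    if (sum(ok) < 10) next
    span_frac <- min(1, max(span_bp / (max(x) - min(x)),
                            (degree + 2) / sum(ok)))
    dat <- data.frame(xx = x[ok], yy = y[ok])
    fit <- stats::loess(yy ~ xx, data = dat, span = span_frac, degree = degree,
                        family = "gaussian",
                        control = stats::loess.control(surface = "direct"))
    inside <- x >= min(x[ok]) & x <= max(x[ok])
    pred <- rep(NA_real_, length(x))
    pred[inside] <- stats::predict(fit, newdata = data.frame(xx = x[inside]))
    out$value[wi] <- pred
  }
  attr(out, "smoothed") <- TRUE
  out
}

#' Mean replication time (Trep) profile from a sequencing time course
#'
#' Implements the windowed Trep construction: per-window ratios of S-phase
#' counts to a G1 (or halved G2) reference; per-timepoint multiplicative
#' adjustment so the genome median ratio equals the bulk DNA content of that
#' timepoint; per-window linear rescale of the ratio trajectory to `[1, 2]`;
#' Trep defined as the (linearly interpolated) time at which the scaled ratio
#' first crosses 1.5 upward; loess smoothing along each chromosome.
#'
#' @param samples a `replication_samples` object (see [sample_sequencing()]),
#'   or any list with `windows`, `counts`, `sheet` of the same shape.
#' @param reference_role `"G1"` or `"G2"`.
#' @param span_bp smoothing span in bp; `NULL` disables smoothing.
#' @param rescale `"window"` (each window's own trajectory min/max anchor the
#'   1-2 rescale; guarantees a 1.5 crossing for monotone trajectories) or
#'   `"timepoint"` (ratios are only centre-adjusted; trajectories already on
#'   the copy-number scale are used as-is).
#' @param center per-timepoint depth-adjustment statistic matched to the
#'   bulk DNA content: `"mean"` (default; unbiased when the supplied content
#'   is the genome mean copy number, which is what bulk flow-cytometry DNA
#'   content estimates) or `"median"` (the robust variant described in the
#'   replication-profiling literature; with mean-based content it
#'   systematically overshoots early-S ratios, because the genome median
#'   lags the mean while only origin-proximal loci have replicated).
#' @return list of class `timing_profile` with `profile` (data.frame `chrom`,
#'   `start`, `end`, `mid`, `value` in minutes, `flag`), `ratio_surface`
#'   (list: `windows`, `ratio` matrix, `dna_content`, `timepoints`) and
#'   `kind = "trep"`. Windows whose trajectory never crosses 1.5 carry
#'   `NA` with flag `"no_crossing"`; trajectories at 2 throughout are set to
#'   the first timepoint with flag `"early_saturated"`.
#' @export
compute_trep <- function(samples, reference_role = c("G1", "G2"),
                         span_bp = 30000, rescale = c("window", "timepoint"),
                         center = c("mean", "median")) {
  reference_role <- match.arg(reference_role)
  rescale <- match.arg(rescale)
  center <- match.arg(center)
  sheet <- samples$sheet
  s_idx <- which(sheet$role == "S")
  if (length(s_idx) < 3) stop("need at least 3 S-phase timepoints")
  tps <- sheet$timepoint[s_idx]
  ord <- order(tps)
  s_idx <- s_idx[ord]; tps <- tps[ord]
  ref_idx <- which(sheet$role == reference_role)
  if (length(ref_idx) != 1) stop("need exactly one ", reference_role, " sample")
  ref <- samples$counts[, ref_idx]
  if (reference_role == "G2") ref <- ref / 2
  keep <- ref > 0
  win <- samples$windows[keep, ]
  ratio <- samples$counts[keep, s_idx, drop = FALSE] / ref[keep]
  dna <- sheet$dna_content[s_idx]
  if (anyNA(dna)) stop("dna_content missing for S samples")
  # per-timepoint depth adjustment to the measured bulk DNA content
  for (j in seq_along(s_idx)) {
    ctr <- if (center == "median") stats::median(ratio[, j]) else
      mean(ratio[, j])
    if (ctr <= 0) stop("non-positive ratio centre at timepoint ", tps[j])
    ratio[, j] <- ratio[, j] * dna[j] / ctr
  }
  adj_ratio <- ratio
  trep <- rep(NA_real_, nrow(win))
  flag <- rep("", nrow(win))
  for (i in seq_len(nrow(win))) {
    traj <- ratio[i, ]
    if (rescale == "window") {
      lo <- min(traj); hi <- max(traj)
      if (hi - lo < 1e-9) {
        if (mean(traj) >= 1.5) { trep[i] <- tps[1]; flag[i] <- "early_saturated" }
        else flag[i] <- "no_crossing"
        next
      }
      traj <- 1 + (traj - lo) / (hi - lo)
    }
    if (traj[1] >= 1.5) { trep[i] <- tps[1]; flag[i] <- "early_saturated"; next }
    up <- which(traj[-length(traj)] < 1.5 & traj[-1] >= 1.5)
    if (!length(up)) { flag[i] <- "no_crossing"; next }
    k <- up[1]  # first upward crossing (earliest passage)
    trep[i] <- tps[k] + (1.5 - traj[k]) * (tps[k + 1] - tps[k]) /
      (traj[k + 1] - traj[k])
  }
  prof <- data.frame(chrom = win$chrom, start = win$start, end = win$end,
                     mid = win$mid, value = trep, flag = flag)
  if (!is.null(span_bp)) prof <- cbind(smooth_profile(prof, span_bp),
                                       raw = trep)[, c("chrom", "start", "end",
                                                       "mid", "value", "flag", "raw")]
  structure(list(profile = prof,
                 ratio_surface = list(windows = win, ratio = adj_ratio,
                                      dna_content = dna, timepoints = tps),
                 kind = "trep"),
            class = "timing_profile")
}

#' Marker frequency analysis (MFA) profile
#'
#' Ratio of exponential-phase to stationary-phase read counts per window,
#' after removing windows whose counts are interquartile-range outliers
#' (outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`, evaluated per track), then loess
#' smoothing. High ratios mark early-replicating loci.
#'
#' @param samples a `replication_samples` object containing `Expo` and `Stat`
#'   tracks, or a list with `windows` and a 2-column `counts` matrix named
#'   `Expo`, `Stat`.
#' @param span_bp smoothing span in bp; `NULL` disables smoothing.
#' @return list of class `timing_profile` with `profile`, `n_filtered`, and
#'   `kind = "mfa"`.
#' @export
compute_mfa <- function(samples, span_bp = 30000) {
  cn <- colnames(samples$counts)
  if (!all(c("Expo", "Stat") %in% cn)) stop("need Expo and Stat tracks")
  expo <- samples$counts[, "Expo"]
  stat <- samples$counts[, "Stat"]
  iqr_keep <- function(x) {
    q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
    spread <- q[2] - q[1]
    x >= q[1] - 1.5 * spread & x <= q[2] + 1.5 * spread
  }
  keep <- iqr_keep(expo) & iqr_keep(stat) & stat > 0
  win <- samples$windows[keep, ]
  prof <- data.frame(chrom = win$chrom, start = win$start, end = win$end,
                     mid = win$mid, value = expo[keep] / stat[keep])
  raw <- prof$value
  if (!is.null(span_bp)) { prof <- smooth_profile(prof, span_bp); prof$raw <- raw }
  structure(list(profile = prof, n_filtered = sum(!keep), kind = "mfa"),
            class = "timing_profile")
}

#' Normalize a timing profile to the unit interval
#'
#' Linear genome-wide map of values onto `[0, 1]` (minimum to 0, maximum
#' to 1); the ranking of loci is preserved exactly.
#'
#' @param profile a `timing_profile` or its `profile` data.frame.
#' @return same shape as the input with normalized `value` and kind
#'   `"normalized"`.
#' @export
normalize_timing <- function(profile) {
  is_tp <- inherits(profile, "timing_profile")
  df <- if (is_tp) profile$profile else profile
  v <- df$value
  rng <- range(v, na.rm = TRUE)
  if (!is.finite(diff(rng)) || diff(rng) < 1e-12)
    stop("cannot normalize a constant profile")
  df$value <- (v - rng[1]) / (rng[2] - rng[1])
  if (is_tp) {
    out <- profile; out$profile <- df; out$kind <- "normalized"
    out
  } else df
}

#' Look up profile values at arbitrary positions
#'
#' Returns the value of the window containing each position (NA outside the
#' profile or in dropped windows).
#'
#' @param profile a `timing_profile` or its `profile` data.frame.
#' @param chrom chromosome vector.
#' @param pos position vector (bp).
#' @return numeric vector of values.
#' @export
profile_value_at <- function(profile, chrom, pos) {
  df <- if (inherits(profile, "timing_profile")) profile$profile else profile
  out <- rep(NA_real_, length(pos))
  for (ch in unique(chrom)) {
    qi <- which(chrom == ch)
    sub <- df[df$chrom == ch, ]
    if (!nrow(sub)) next
    idx <- findInterval(pos[qi], sub$start)
    ok <- idx >= 1 & idx <= nrow(sub)
    ok[ok] <- pos[qi][ok] < sub$end[idx[ok]]
    out[qi[ok]] <- sub$value[idx[ok]]
  }
  out
}
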