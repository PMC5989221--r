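#' First-order numeric derivative of a windowed profile
#'
#' Difference-quotient slope `(y_i - y_{i-1}) / (x_i - x_{i-1})`, computed
#' per chromosome and reported at the interval midpoint
#' `(x_i + x_{i-1}) / 2` (the unbiased location for a first difference), so
#' each chromosome loses one point per differentiation. Windows with
#' missing values propagate `NA` (gaps are never bridged for derivatives).
#'
#' @param profile data.frame `chrom`, `mid` (bp), `value` (or a
#'   `timing_profile`).
#' @return data.frame `chrom`, `mid`, `value` of the derivative.
#' @export
numeric_derivative <- function(profile) {
  df <- if (inherits(profile, "timing_profile")) profile$profile else profile
  out <- lapply(unique(df$chrom), function(ch) {
    sub <- df[df$chrom == ch, ]
    sub <- sub[order(sub$mid), ]
    if (nrow(sub) < 2) return(NULL)
    dx <- diff(sub$mid)
    if (any(dx == 0)) stop("duplicate window coordinates on ", ch)
    data.frame(chrom = ch, mid = (sub$mid[-1] + sub$mid[-nrow(sub)]) / 2,
               value = diff(sub$value) / dx)
  })
  do.call(rbind, out)
}

#' Candidate origin positions from one timing profile
#'
#' Origins are curvature features of the smoothed profile: local minima of
#' the second derivative of a working signal (MFA as-is, Trep negated so
#' that initiation sites have the same curvature sign in both), located
#' where the third derivative crosses zero from negative to positive. Both
#' peaks and shoulders of the original curve produce such features. The
#' candidate coordinate is the linear interpolation of the zero crossing;
#' its amplitude is `|d2|` at the flanking grid points. Candidates below
#' `min_prominence` are discarded.
#'
#' @param profile a `timing_profile` (smoothed) or a data.frame
#'   `chrom`, `mid`, `value`; `kind` must be supplied for plain data.frames.
#' @param min_prominence amplitude threshold; `NULL` (default) uses half the
#'   median absolute second derivative of each chromosome. At realistic
#'   origin densities (one per ~47 kb) the whole profile is curvature, so
#'   the chromosome median is itself signal-scale; a sub-median threshold
#'   rejects grid noise (already suppressed by the stride and the merge)
#'   without discarding true initiation sites. Candidates below 2% of the
#'   chromosome's strongest amplitude are always dropped (smoothing
#'   artifacts on sparse chromosomes).
#' @param kind `"trep"` or `"mfa"`; taken from the profile object if absent.
#' @param merge_bp candidates closer than this are collapsed to the one with
#'   the largest amplitude (noise can split a single broad curvature dip
#'   into several nearby zero crossings); default 10000, 0 disables.
#' @param deriv_step stride, in windows, at which the derivative chain is
#'   evaluated (default 16, i.e. 8 kb on a 500 bp grid). Origin features
#'   live at the 20-50 kb scale, so sampling the smoothed curve every few
#'   kb retains them while suppressing the grid-scale residual wiggles that
#'   repeated differencing would otherwise amplify.
#' @return data.frame `chrom`, `pos`, `amplitude`, sorted by position.
#' @export
call_candidate_origins <- function(profile, min_prominence = NULL,
                                   kind = NULL, merge_bp = 10000,
                                   deriv_step = 16) {
  if (inherits(profile, "timing_profile")) {
    if (is.null(kind)) kind <- profile$kind
    df <- profile$profile
  } else {
    if (is.null(kind)) stop("kind required for plain data.frame input")
    df <- profile
  }
  if (!kind %in% c("trep", "mfa", "normalized"))
    stop("unknown profile kind: ", kind)
  sign_flip <- if (kind == "mfa") 1 else -1
  work <- data.frame(chrom = df$chrom, mid = df$mid,
                     value = sign_flip * df$value)
  out <- lapply(unique(work$chrom), function(ch) {
    sub <- work[work$chrom == ch & is.finite(work$value), ]
    if (nrow(sub) >= 5 * deriv_step)
      sub <- sub[seq(1, nrow(sub), by = deriv_step), ]
    if (nrow(sub) < 5) {
      warning("chromosome ", ch, " has fewer than 5 windows; no calls")
      return(NULL)
    }
    d1 <- numeric_derivative(sub)
    d2 <- numeric_derivative(d1)
    d3 <- numeric_derivative(d2)
    thr <- if (is.null(min_prominence))
      0.5 * stats::median(abs(d2$value), na.rm = TRUE) else min_prominence
    # numerical floor: curvature indistinguishable from float error on an
    # exactly smooth (e.g. linear) profile must never yield a candidate
    dx_min <- min(diff(sub$mid))
    thr <- max(thr, 1e3 * .Machine$double.eps * max(abs(sub$value)) / dx_min^2)
    n3 <- nrow(d3)
    if (n3 < 2) return(NULL)
    v3 <- d3$value
    cross <- which(v3[-n3] < 0 & v3[-1] >= 0)
    if (!length(cross)) return(NULL)
    pos <- d3$mid[cross] + (0 - v3[cross]) * (d3$mid[cross + 1] - d3$mid[cross]) /
      (v3[cross + 1] - v3[cross])
    # d2 grid leads d3 by one point; d2 values flanking the crossing
    amp <- vapply(cross, function(k) {
      i2 <- which(d2$mid >= d3$mid[k] - 1e-9 & d2$mid <= d3$mid[k + 1] + 1e-9)
      -min(d2$value[i2])
    }, 0)
    # chromosomes with sparse origins are mostly flat, so the median-based
    # threshold is tiny there; smoothing/edge artifacts sit orders of
    # magnitude below the weakest real dip and are cut by a fraction-of-max
    thr <- max(thr, 0.02 * max(amp, na.rm = TRUE))
    keep <- is.finite(pos) & amp >= thr
    if (!any(keep)) return(NULL)
    cand <- data.frame(chrom = ch, pos = pos[keep], amplitude = amp[keep])
    if (merge_bp > 0 && nrow(cand) > 1) {
      cand <- cand[order(-cand$amplitude), ]
      taken <- rep(FALSE, nrow(cand))
      for (r in seq_len(nrow(cand))) {
        if (taken[r]) next
        taken[abs(cand$pos - cand$pos[r]) < merge_bp & seq_len(nrow(cand)) != r] <- TRUE
      }
      cand <- cand[!taken, ]
    }
    cand
  })
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(chrom = character(0), pos = numeric(0),
                                      amplitude = numeric(0))
  res[order(res$chrom, res$pos), ]
}

#' Co-detection of origins across Trep and MFA candidates
#'
#' Active origins are retained only when a Trep candidate and an MFA
#' candidate fall within `max_separation` of each other. Matching is greedy
#' on the absolute coordinate difference (smallest first, each candidate
#' used at most once; ties broken by leftmost position), which makes it
#' symmetric in its two arguments. The consensus coordinate is the mean of
#' the two source coordinates.
#'
#' @param trep_candidates,mfa_candidates data.frames `chrom`, `pos`
#'   (and optional `amplitude`) from [call_candidate_origins()].
#' @param max_separation maximum coordinate difference in bp (default 10000).
#' @return list of class `origin_set`: `origins` (data.frame `chrom`,
#'   `trep_pos`, `mfa_pos`, `pos` consensus, `delta`, amplitudes, `id`),
#'   `unmatched_trep`, `unmatched_mfa`, and `delta_summary` (median and mean
#'   of `|delta|` in bp).
#' @export
co_detect <- function(trep_candidates, mfa_candidates, max_separation = 10000) {
  pairs <- list()
  un_t <- list(); un_m <- list()
  for (ch in union(unique(trep_candidates$chrom), unique(mfa_candidates$chrom))) {
    tc <- trep_candidates[trep_candidates$chrom == ch, ]
    mc <- mfa_candidates[mfa_candidates$chrom == ch, ]
    if (nrow(tc) && nrow(mc)) {
      cand <- expand.grid(i = seq_len(nrow(tc)), j = seq_len(nrow(mc)))
      cand$d <- abs(tc$pos[cand$i] - mc$pos[cand$j])
      cand <- cand[cand$d <= max_separation, ]
      cand <- cand[order(cand$d, tc$pos[cand$i]), ]
      used_i <- logical(nrow(tc)); used_j <- logical(nrow(mc))
      for (r in seq_len(nrow(cand))) {
        i <- cand$i[r]; j <- cand$j[r]
        if (used_i[i] || used_j[j]) next
        used_i[i] <- TRUE; used_j[j] <- TRUE
        pairs[[length(pairs) + 1]] <- data.frame(
          chrom = ch, trep_pos = tc$pos[i], mfa_pos = mc$pos[j],
          pos = (tc$pos[i] + mc$pos[j]) / 2,
          delta = mc$pos[j] - tc$pos[i],
          trep_amplitude = if ("amplitude" %in% names(tc)) tc$amplitude[i] else NA,
          mfa_amplitude = if ("amplitude" %in% names(mc)) mc$amplitude[j] else NA)
      }
      if (any(!used_i)) un_t[[ch]] <- tc[!used_i, ]
      if (any(!used_j)) un_m[[ch]] <- mc[!used_j, ]
    } else {
      if (nrow(tc)) un_t[[ch]] <- tc
      if (nrow(mc)) un_m[[ch]] <- mc
    }
  }
  origins <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(chrom = character(0), trep_pos = numeric(0),
               mfa_pos = numeric(0), pos = numeric(0), delta = numeric(0),
               trep_amplitude = numeric(0), mfa_amplitude = numeric(0))
  origins <- origins[order(origins$chrom, origins$pos), ]
  rownames(origins) <- NULL
  if (nrow(origins)) {
    rank <- stats::ave(origins$pos, origins$chrom, FUN = seq_along)
    origins$id <- sprintf("ORI_%s_%d", origins$chrom, rank)
  } else origins$id <- character(0)
  structure(list(
    origins = origins,
    unmatched_trep = if (length(un_t)) do.call(rbind, un_t) else NULL,
    unmatched_mfa = if (length(un_m)) do.call(rbind, un_m) else NULL,
    delta_summary = c(median = stats::median(abs(origins$delta)),
                      mean = mean(abs(origins$delta)))),
    class = "origin_set")
}

#' Write an origin set as BED6
#'
#' @param origin_set a [co_detect()] result (or data.frame with `chrom`,
#'   `pos`, `id`, optional amplitude for the score).
#' @param path output file.
#' @export
write_origins_bed <- function(origin_set, path) {
  df <- if (inherits(origin_set, "origin_set")) origin_set$origins else origin_set
  score <- if ("trep_amplitude" %in% names(df)) df$trep_amplitude else 0
  bed <- data.frame(chrom = df$chrom, start = floor(df$pos),
                    end = floor(df$pos) + 1, name = df$id,
                    score = signif(score, 4), strand = ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
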