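#' Annotate origins with physical and functional properties
#'
#' Computes, for every origin: distance to its chromosome's centromere,
#' to the nearest telomere (chromosome ends), to the nearest rearrangement
#' breakpoint, and to the nearest other origin (with that neighbour's
#' identity, category and efficiency). Lost origins should be supplied at
#' their projected position in the extant genome; their efficiency and
#' firing time are those of their orthologous origin in the sister genome.
#'
#' @param origins data.frame `origin_id`, `chrom`, `pos`, `category`
#'   (conserved/gained/lost), and optionally `efficiency`,
#'   `characteristic_time`.
#' @param chrom_lengths named vector (telomeres at 0 and the length).
#' @param centromeres data.frame `chrom`, `pos`; chromosomes without an
#'   entry get `NA` centromere distance.
#' @param breakpoints data.frame `chrom`, `pos`, or `NULL`.
#' @return the origin table with `dist_centromere`, `dist_telomere`,
#'   `dist_breakpoint`, `nearest_id`, `nearest_dist`, `nearest_category`,
#'   `nearest_efficiency` columns appended.
#' @export
annotate_origins <- function(origins, chrom_lengths, centromeres = NULL,
                             breakpoints = NULL) {
  n <- nrow(origins)
  out <- origins
  out$dist_centromere <- NA_real_
  out$dist_telomere <- NA_real_
  out$dist_breakpoint <- NA_real_
  out$nearest_id <- NA_character_
  out$nearest_dist <- NA_real_
  out$nearest_category <- NA_character_
  out$nearest_efficiency <- NA_real_
  for (i in seq_len(n)) {
    ch <- origins$chrom[i]; p <- origins$pos[i]
    if (!is.null(centromeres)) {
      cen <- centromeres$pos[centromeres$chrom == ch]
      if (length(cen)) out$dist_centromere[i] <- min(abs(p - cen))
    }
    L <- chrom_lengths[[ch]]
    if (!is.null(L)) out$dist_telomere[i] <- min(p, L - p)
    if (!is.null(breakpoints)) {
      bp <- breakpoints$pos[breakpoints$chrom == ch]
      if (length(bp)) out$dist_breakpoint[i] <- min(abs(p - bp))
    }
    others <- which(origins$chrom == ch & seq_len(n) != i)
    if (length(others)) {
      j <- others[which.min(abs(origins$pos[others] - p))]
      out$nearest_id[i] <- origins$origin_id[j]
      out$nearest_dist[i] <- abs(origins$pos[j] - p)
      if ("category" %in% names(origins))
        out$nearest_category[i] <- origins$category[j]
      if ("efficiency" %in% names(origins))
        out$nearest_efficiency[i] <- origins$efficiency[j]
    }
  }
  out
}

#' Nearest-origin composition and distance analysis
#'
#' For each origin category, reports the distribution of nearest-origin
#' distances (median) and the observed proportions of categories among the
#' nearest neighbours, against the expected proportions if neighbours were
#' sampled at random from the origin population (the global category
#' frequencies).
#'
#' @param annotations an [annotate_origins()] result with `category`,
#'   `nearest_category`, `nearest_dist`.
#' @return list `expected` (named proportions), `observed` (category x
#'   neighbour-category proportion matrix), `median_dist` (named vector).
#' @export
nearest_origin_analysis <- function(annotations) {
  cats <- sort(unique(annotations$category))
  if (length(cats) < 2) stop("need at least 2 categories")
  expected <- prop.table(table(factor(annotations$category, levels = cats)))
  ok <- !is.na(annotations$nearest_category)
  observed <- prop.table(table(factor(annotations$category[ok], levels = cats),
                               factor(annotations$nearest_category[ok],
                                      levels = cats)), margin = 1)
  med <- tapply(annotations$nearest_dist, annotations$category, stats::median,
                na.rm = TRUE)
  list(expected = c(expected), observed = unclass(observed),
       median_dist = c(med))
}

#' Two-sample chi-square test on binned continuous samples
#'
#' Bins the pooled values into equal-count quantile bins (merging sparse
#' bins until every bin's pooled count is at least `min_expected`), then
#' computes the classical two-sample chi-square statistic
#' `sum_b (K_X x_b - K_Y y_b)^2 / (x_b + y_b)` with
#' `K_X = sqrt(N_Y/N_X)`, `K_Y = sqrt(N_X/N_Y)`, and degrees of freedom
#' `bins - 1`.
#'
#' @param x,y numeric samples.
#' @param bins target number of quantile bins (default 10).
#' @param min_expected minimum pooled count per bin (default 5).
#' @return list `statistic`, `df`, `p.value`, `n_bins`.
#' @export
chisq_two_sample <- function(x, y, bins = 10, min_expected = 5) {
  pooled <- c(x, y)
  qs <- unique(stats::quantile(pooled, probs = seq(0, 1, length.out = bins + 1),
                               names = FALSE))
  if (length(qs) < 3) stop("fewer than 2 usable bins")
  qs[1] <- -Inf; qs[length(qs)] <- Inf
  cx <- table(cut(x, qs)); cy <- table(cut(y, qs))
  # merge sparse bins from the left
  merge_sparse <- function(cx, cy) {
    repeat {
      tot <- cx + cy
      k <- which(tot < min_expected)[1]
      if (is.na(k) || length(cx) < 3) break
      j <- if (k == length(cx)) k - 1 else k + 1
      cx[j] <- cx[j] + cx[k]; cy[j] <- cy[j] + cy[k]
      cx <- cx[-k]; cy <- cy[-k]
    }
    list(cx = cx, cy = cy)
  }
  m <- merge_sparse(as.numeric(cx), as.numeric(cy))
  cx <- m$cx; cy <- m$cy
  if (length(cx) < 2) stop("fewer than 2 usable bins")
  n_x <- sum(cx); n_y <- sum(cy)
  kx <- sqrt(n_y / n_x); ky <- sqrt(n_x / n_y)
  nonzero <- (cx + cy) > 0
  stat <- sum((kx * cx[nonzero] - ky * cy[nonzero])^2 /
                (cx[nonzero] + cy[nonzero]))
  df <- sum(nonzero) - 1
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df, lower.tail = FALSE),
       n_bins = sum(nonzero))
}

#' Median origin efficiency as a function of phylogenetic age
#'
#' Groups origin families by origination branch, computes the median and SD
#' of member-origin efficiencies per group, and regresses group medians on
#' group age (cumulated branch length from the focal ancestor).
#'
#' @param family_stats data.frame with one row per family: `origination`,
#'   `age`, `efficiency` (a family-level efficiency, e.g. the mean of its
#'   member origins).
#' @return list `groups` (data.frame `origination`, `age`,
#'   `median_efficiency`, `sd_efficiency`, `n`), `slope`, `r_squared`,
#'   `p.value`, `correlation`.
#' @export
efficiency_age_trend <- function(family_stats) {
  ok <- is.finite(family_stats$age) & is.finite(family_stats$efficiency)
  fs <- family_stats[ok, ]
  groups <- do.call(rbind, lapply(split(fs, fs$origination), function(g) {
    data.frame(origination = g$origination[1], age = mean(g$age),
               median_efficiency = stats::median(g$efficiency),
               sd_efficiency = stats::sd(g$efficiency), n = nrow(g))
  }))
  rownames(groups) <- NULL
  if (nrow(groups) < 3) stop("need at least 3 age groups")
  if (stats::sd(groups$age) < 1e-12) stop("degenerate ages")
  fit <- stats::lm(median_efficiency ~ age, data = groups)
  flat <- stats::sd(groups$median_efficiency) < 1e-12
  sm <- if (flat) NULL else summary(fit)
  list(groups = groups[order(groups$age), ],
       slope = unname(stats::coef(fit)[2]),
       r_squared = if (flat) 0 else sm$r.squared,
       p.value = if (flat) NA_real_ else sm$coefficients[2, 4],
       correlation = if (flat) NA_real_ else
         stats::cor(groups$age, groups$median_efficiency))
}

#' Regularity of inter-origin spacing
#'
#' Tests whether origins are more regularly spaced than uniform random
#' placement. The statistic is the coefficient of variation (CV) of
#' inter-origin distances pooled over chromosomes; the null places the same
#' number of origins uniformly at random on each chromosome. Low CV means
#' regular spacing; the empirical p-value is the fraction of null CVs at or
#' below the observed one.
#'
#' @param origins data.frame `chrom`, `pos`.
#' @param chrom_lengths named vector.
#' @param n_rand null replicates (default 1000).
#' @param seed RNG seed.
#' @return list `cv_observed`, `null_mean`, `null_sd`, `z`, `p_empirical`.
#' @export
spacing_regularity <- function(origins, chrom_lengths, n_rand = 1000,
                               seed = 1L) {
  set.seed(seed)
  chroms <- unique(origins$chrom)
  counts <- vapply(chroms, function(ch) sum(origins$chrom == ch), 0L)
  if (any(counts < 3)) stop("need >= 3 origins per analyzed chromosome")
  pooled_cv <- function(pos_by_chrom) {
    sp <- unlist(lapply(pos_by_chrom, function(p) diff(sort(p))))
    stats::sd(sp) / mean(sp)
  }
  obs <- pooled_cv(split(origins$pos, origins$chrom))
  null_cv <- vapply(seq_len(n_rand), function(r) {
    pooled_cv(lapply(stats::setNames(nm = chroms), function(ch)
      stats::runif(counts[[ch]], 0, chrom_lengths[[ch]])))
  }, 0)
  list(cv_observed = obs,
       null_mean = mean(null_cv), null_sd = stats::sd(null_cv),
       z = (obs - mean(null_cv)) / stats::sd(null_cv),
       p_empirical = mean(null_cv <= obs))
}
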