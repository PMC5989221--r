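#' Construct a stochastic replication kinetics model
#'
#' A `kinetics_model` is the generative object for all replication dynamics in
#' the package: a set of chromosomes, replication origins at fixed positions,
#' per-origin firing rates, and a single genome-wide fork speed. Origin firing
#' is modelled as a constant-probability (memoryless) process, so each
#' origin's firing time is exponentially distributed with its rate; forks then
#' progress bidirectionally at constant speed and a locus is replicated by
#' whichever fork (or local firing) reaches it first.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param origins data.frame with columns `chrom`, `pos` (bp, 0-based),
#'   `rate` (firings per minute, >= 0). An optional `id` column names each
#'   origin; defaults to `ORI_<chrom>_<rank>`.
#' @param fork_speed replication fork speed in bp per minute (> 0).
#'
#' @return an object of class `kinetics_model` with sorted origins.
#' @examples
#' m <- kinetics_model(c(chrI = 2e5),
#'                     data.frame(chrom = "chrI", pos = c(5e4, 1.5e5),
#'                                rate = c(0.1, 0.05)),
#'                     fork_speed = 2000)
#' @export
kinetics_model <- function(chrom_lengths, origins, fork_speed = 2000) {
  stopifnot(is.numeric(chrom_lengths), length(chrom_lengths) >= 1)
  if (is.null(names(chrom_lengths)) || anyNA(names(chrom_lengths)))
    stop("chrom_lengths must be a named vector")
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  stopifnot(is.data.frame(origins),
            all(c("chrom", "pos", "rate") %in% names(origins)))
  if (!all(origins$chrom %in% names(chrom_lengths)))
    stop("origin chromosome not in chrom_lengths")
  if (any(!is.finite(origins$rate)) || any(origins$rate < 0))
    stop("firing rates must be finite and >= 0")
  if (any(origins$pos < 0) ||
      any(origins$pos > chrom_lengths[origins$chrom]))
    stop("origin positions must lie within their chromosome")
  if (!is.numeric(fork_speed) || length(fork_speed) != 1 || fork_speed <= 0)
    stop("fork_speed must be a single positive number")
  missing_chrom <- setdiff(names(chrom_lengths), unique(origins$chrom))
  if (length(missing_chrom))
    stop("chromosome(s) without any origin: ",
         paste(missing_chrom, collapse = ", "))
  origins <- origins[order(match(origins$chrom, names(chrom_lengths)),
                           origins$pos), , drop = FALSE]
  if (is.null(origins$id)) {
    rank <- stats::ave(origins$pos, origins$chrom, FUN = seq_along)
    origins$id <- sprintf("ORI_%s_%d", origins$chrom, rank)
  }
  rownames(origins) <- NULL
  structure(list(chrom_lengths = chrom_lengths,
                 origins = origins,
                 fork_speed = fork_speed),
            class = "kinetics_model")
}

#' @export
print.kinetics_model <- function(x, ...) {
  cat(sprintf("kinetics_model: %d chromosome(s), %d origins, fork speed %g bp/min\n",
              length(x$chrom_lengths), nrow(x$origins), x$fork_speed))
  cat(sprintf("  rates: %.3g-%.3g /min\n",
              min(x$origins$rate), max(x$origins$rate)))
  invisible(x)
}

#' Tile a model's genome into fixed windows
#'
#' Windows are 0-based half-open intervals of `size` bp; the last window of
#' each chromosome is truncated at the chromosome end.
#'
#' @param model a [kinetics_model()] (or a named length vector).
#' @param size window size in bp (default 500).
#' @return data.frame with `chrom`, `start`, `end`, `mid`.
#' @export
genome_windows <- function(model, size = 500) {
  lens <- if (inherits(model, "kinetics_model")) model$chrom_lengths else model
  out <- lapply(names(lens), function(ch) {
    starts <- seq(0, lens[[ch]] - 1, by = size)
    ends <- pmin(starts + size, lens[[ch]])
    data.frame(chrom = ch, start = starts, end = ends,
               mid = (starts + ends) / 2)
  })
  do.call(rbind, out)
}

#' Simulate single-cell S phases
#'
#' Draws independent exponential firing times for every origin in every cell
#' and evaluates which origins fire actively (before a fork arriving from any
#' neighbour could replicate them passively). An origin with rate 0 never
#' fires (infinite firing time).
#'
#' @param model a [kinetics_model()].
#' @param n_cells number of cells (simulation runs).
#' @param seed integer RNG seed.
#' @return object of class `cell_replication`: list with `firing_times`
#'   (n_cells x n_origins, minutes, `Inf` for rate 0), `active` (logical
#'   matrix, same shape), and the model. Column order follows
#'   `model$origins`.
#' @export
simulate_cells <- function(model, n_cells, seed = 1L) {
  stopifnot(inherits(model, "kinetics_model"), n_cells >= 1)
  set.seed(seed)
  org <- model$origins
  n_o <- nrow(org)
  ft <- matrix(Inf, nrow = n_cells, ncol = n_o,
               dimnames = list(NULL, org$id))
  pos_rate <- org$rate > 0
  if (any(pos_rate)) {
    k <- sum(pos_rate)
    ft[, pos_rate] <- matrix(
      stats::rexp(n_cells * k, rate = rep(org$rate[pos_rate], each = n_cells)),
      nrow = n_cells)
  }
  active <- matrix(FALSE, nrow = n_cells, ncol = n_o,
                   dimnames = list(NULL, org$id))
  v <- model$fork_speed
  for (ch in unique(org$chrom)) {
    idx <- which(org$chrom == ch)
    o <- org$pos[idx]
    # replication time at each origin = min_j (T_j + d_ij / v); active iff
    # the origin's own firing strictly precedes every incoming fork
    for (i in seq_along(idx)) {
      incoming <- rep(Inf, n_cells)
      for (j in seq_along(idx)) {
        if (j == i) next
        incoming <- pmin(incoming, ft[, idx[j]] + abs(o[i] - o[j]) / v)
      }
      active[, idx[i]] <- ft[, idx[i]] < incoming
    }
  }
  structure(list(firing_times = ft, active = active, model = model),
            class = "cell_replication")
}

#' Per-cell replication time field
#'
#' Evaluates t(x) = min over origins of (T_i + |x - o_i| / v) at the given
#' positions of one chromosome, for each simulated cell.
#'
#' @param cells a [simulate_cells()] result.
#' @param chrom chromosome name.
#' @param positions numeric vector of bp positions on `chrom`.
#' @return matrix n_cells x length(positions) of replication times (min).
#' @export
cell_replication_times <- function(cells, chrom, positions) {
  model <- cells$model
  idx <- which(model$origins$chrom == chrom)
  if (!length(idx)) stop("no origins on chromosome ", chrom)
  o <- model$origins$pos[idx]
  v <- model$fork_speed
  t_field <- matrix(Inf, nrow = nrow(cells$firing_times),
                    ncol = length(positions))
  for (k in seq_along(idx)) {
    t_field <- pmin(t_field,
                    outer(cells$firing_times[, idx[k]],
                          abs(positions - o[k]) / v, `+`))
  }
  t_field
}

#' Population-average DNA copy number
#'
#' Expected copy number in `[1, 2]` at every genome window and timepoint.
#' With exponential firing the analytic form is
#' `c(x, t) = 2 - prod_i exp(-lambda_i * max(0, t - |x - o_i| / v))`:
#' a locus is still unreplicated only if no origin has fired early enough for
#' its fork to have arrived. Monte-Carlo mode instead simulates cells and
#' returns `1 +` the fraction of cells whose replication time at the window
#' is `<= t` (counted by exact interval union per cell).
#'
#' @param model a [kinetics_model()].
#' @param timepoints non-negative minutes, strictly increasing.
#' @param mode `"analytic"` or `"monte_carlo"`.
#' @param n_cells cells for Monte-Carlo mode.
#' @param seed RNG seed for Monte-Carlo mode.
#' @param window_size bp (default 500).
#' @return list with `windows` (data.frame) and `copy_number`
#'   (windows x timepoints matrix), plus `timepoints`.
#' @export
copy_number_surface <- function(model, timepoints, mode = c("analytic", "monte_carlo"),
                                n_cells = 10000, seed = 1L, window_size = 500) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "kinetics_model"),
            all(timepoints >= 0), !is.unsorted(timepoints, strictly = TRUE))
  win <- genome_windows(model, window_size)
  cn <- matrix(NA_real_, nrow = nrow(win), ncol = length(timepoints),
               dimnames = list(NULL, paste0("t", timepoints)))
  if (mode == "analytic") {
    for (ch in names(model$chrom_lengths)) {
      wi <- which(win$chrom == ch)
      idx <- which(model$origins$chrom == ch)
      x <- win$mid[wi]
      # log-survival: sum_i -lambda_i * (t - d_i/v)_+
      for (j in seq_along(timepoints)) {
        logs <- rep(0, length(x))
        for (k in idx) {
          lag <- timepoints[j] - abs(x - model$origins$pos[k]) / model$fork_speed
          logs <- logs - model$origins$rate[k] * pmax(0, lag)
        }
        cn[wi, j] <- 2 - exp(logs)
      }
    }
  } else {
    cells <- simulate_cells(model, n_cells, seed)
    v <- model$fork_speed
    for (ch in names(model$chrom_lengths)) {
      wi <- which(win$chrom == ch)
      idx <- which(model$origins$chrom == ch)
      o <- model$origins$pos[idx]
      for (j in seq_along(timepoints)) {
        t <- timepoints[j]
        cover <- numeric(length(wi) + 1)  # diff accumulator over window index
        for (cell in seq_len(n_cells)) {
          r <- v * (t - cells$firing_times[cell, idx])
          fired <- which(r >= 0)
          if (!length(fired)) next
          lo <- o[fired] - r[fired]
          hi <- o[fired] + r[fired]
          ord <- order(lo)
          lo <- lo[ord]; hi <- hi[ord]
          # merge overlapping replicated intervals of this cell
          m_lo <- lo[1]; m_hi <- hi[1]
          for (q in seq_along(lo)[-1]) {
            if (lo[q] <= m_hi[length(m_hi)]) {
              m_hi[length(m_hi)] <- max(m_hi[length(m_hi)], hi[q])
            } else {
              m_lo <- c(m_lo, lo[q]); m_hi <- c(m_hi, hi[q])
            }
          }
          # a window midpoint is replicated iff it falls inside an interval
          mids <- win$mid[wi]
          i1 <- findInterval(m_lo, mids) + 1   # first mid strictly > lo
          i1 <- pmax(i1, 1)
          i2 <- findInterval(m_hi, mids)       # last mid <= hi
          keep <- i1 <= i2
          if (any(keep)) {
            for (q in which(keep)) {
              cover[i1[q]] <- cover[i1[q]] + 1
              cover[i2[q] + 1] <- cover[i2[q] + 1] - 1
            }
          }
        }
        cn[wi, j] <- 1 + cumsum(cover[seq_along(wi)]) / n_cells
      }
    }
  }
  list(windows = win, copy_number = cn, timepoints = timepoints)
}

#' Analytic mean replication time (copy number = 1.5 crossing)
#'
#' Inverts the analytic copy-number form: the time at which
#' `sum_i lambda_i * (t - d_i/v)_+` reaches `log(2)` is the locus's mean
#' replication time. The left side is piecewise linear and non-decreasing in
#' `t`, so the crossing is found exactly segment by segment.
#'
#' @param model a [kinetics_model()].
#' @param chrom chromosome name.
#' @param positions bp positions.
#' @return numeric vector of times (min) where expected copy number is 1.5.
#' @export
analytic_trep <- function(model, chrom, positions) {
  idx <- which(model$origins$chrom == chrom)
  if (!length(idx)) stop("no origins on chromosome ", chrom)
  lam <- model$origins$rate[idx]
  target <- log(2)
  vapply(positions, function(x) {
    a <- abs(x - model$origins$pos[idx]) / model$fork_speed  # fork arrival lags
    ord <- order(a)
    a <- a[ord]; l <- lam[ord]
    keep <- l > 0
    if (!any(keep)) return(Inf)
    a <- a[keep]; l <- l[keep]
    cum_l <- cumsum(l)
    # f(t) = sum l_k (t - a_k)_+ evaluated at the knots
    f_knot <- vapply(a, function(t) sum(l * pmax(0, t - a)), 0)
    k <- which(f_knot >= target)[1]
    if (is.na(k)) {  # crossing beyond the last knot
      n <- length(a)
      return(a[n] + (target - f_knot[n]) / cum_l[n])
    }
    if (k == 1) return(a[1])  # f jumps from 0 only at knots; f_knot[1] = 0 unless ties
    a[k - 1] + (target - f_knot[k - 1]) / cum_l[k - 1]
  }, 0)
}

#' Simulation-based origin efficiencies
#'
#' Efficiency of an origin is the fraction of simulated cells in which it
#' fires actively, i.e. before any fork from a neighbouring origin reaches
#' it (passive replication).
#'
#' @param model a [kinetics_model()].
#' @param n_sims number of simulated cells (default 10000; SE <= 0.005).
#' @param seed RNG seed.
#' @return data.frame `id`, `chrom`, `pos`, `rate`, `efficiency`.
#' @export
simulate_efficiencies <- function(model, n_sims = 10000, seed = 1L) {
  stopifnot(n_sims >= 1)
  cells <- simulate_cells(model, n_sims, seed)
  out <- model$origins
  out$efficiency <- colMeans(cells$active)
  out
}
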