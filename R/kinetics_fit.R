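#' Initial firing rates from early time-course slopes
#'
#' For each origin, the copy number at its window grows approximately as
#' `c(t) = 1 + lambda t` while `t` is small (before interference from
#' neighbours), so the slope of the first two timepoints estimates the rate.
#' Rates are floored at a small positive constant.
#'
#' @param surface a copy-number surface: list with `windows`,
#'   `copy_number` (windows x timepoints) and `timepoints`.
#' @param origin_positions data.frame `chrom`, `pos`.
#' @param floor minimum rate (default 1e-4 per minute).
#' @return numeric vector of initial rates, one per origin row.
#' @export
initialize_rates <- function(surface, origin_positions, floor = 1e-4) {
  if (length(surface$timepoints) < 2) stop("need at least 2 timepoints")
  t1 <- surface$timepoints[1]; t2 <- surface$timepoints[2]
  rates <- numeric(nrow(origin_positions))
  for (i in seq_len(nrow(origin_positions))) {
    wi <- which(surface$windows$chrom == origin_positions$chrom[i] &
                surface$windows$start <= origin_positions$pos[i] &
                surface$windows$end > origin_positions$pos[i])
    if (!length(wi)) { rates[i] <- floor; next }
    slope <- (surface$copy_number[wi[1], 2] - surface$copy_number[wi[1], 1]) /
      (t2 - t1)
    rates[i] <- max(slope, floor)
  }
  if (all(rates <= floor)) warning("flat early signal; all rates at floor")
  rates
}

#' Fit the stochastic firing-kinetics model to copy-number data
#'
#' Holds origin positions fixed and fits per-origin firing rates plus one
#' genome-wide fork speed by minimizing the mean squared difference between
#' the observed copy-number surface and the analytic model surface. The
#' optimizer is a coordinate-wise iterative update with per-parameter
#' adaptive steps: a proposed move is accepted only if it lowers the
#' objective, its step then doubles, otherwise the step halves; rates are
#' projected to `>= 0` and fork speed to `> 0`. The objective trace over
#' accepted steps is therefore non-increasing by construction.
#'
#' @param surface observed copy-number surface (list with `windows`,
#'   `copy_number`, `timepoints`); values on the `[1, 2]` scale.
#' @param origin_positions data.frame `chrom`, `pos` (fixed).
#' @param init_rates initial rates; default from [initialize_rates()].
#' @param init_fork_speed initial fork speed in bp/min (default 1000).
#' @param chrom_lengths named vector; default inferred from the windows.
#' @param rel_tol stop when the relative objective improvement over a full
#'   sweep falls below this (default 1e-6).
#' @param max_sweeps maximum full parameter sweeps (default 10000).
#' @return list of class `kinetics_fit`: `model` (fitted [kinetics_model()]),
#'   `objective`, `trace`, `converged`, `n_sweeps`, and a per-origin table
#'   with `rate` and `characteristic_time = 1/rate`.
#' @export
fit_kinetics <- function(surface, origin_positions, init_rates = NULL,
                         init_fork_speed = 1000, chrom_lengths = NULL,
                         rel_tol = 1e-6, max_sweeps = 10000) {
  win <- surface$windows
  obs <- surface$copy_number
  tps <- surface$timepoints
  if (is.null(chrom_lengths)) {
    agg <- tapply(win$end, win$chrom, max)
    chrom_lengths <- stats::setNames(as.numeric(agg), names(agg))
  }
  if (is.null(init_rates)) init_rates <- initialize_rates(surface, origin_positions)
  org <- origin_positions[order(match(origin_positions$chrom, names(chrom_lengths)),
                                origin_positions$pos), , drop = FALSE]
  rates <- init_rates[order(match(origin_positions$chrom, names(chrom_lengths)),
                            origin_positions$pos)]
  n_o <- nrow(org)
  # precompute distances origin -> window midpoints, per chromosome block
  dist_mat <- matrix(NA_real_, nrow = nrow(win), ncol = n_o)
  for (k in seq_len(n_o)) {
    wi <- win$chrom == org$chrom[k]
    dist_mat[wi, k] <- abs(win$mid[wi] - org$pos[k])
  }
  model_surface <- function(rates, v) {
    logs <- matrix(0, nrow = nrow(win), ncol = length(tps))
    for (k in seq_len(n_o)) {
      wi <- which(!is.na(dist_mat[, k]))
      lag <- outer(-dist_mat[wi, k] / v, tps, `+`)  # t - d/v
      logs[wi, ] <- logs[wi, ] - rates[k] * pmax(lag, 0)
    }
    2 - exp(logs)
  }
  objective <- function(rates, v) mean((model_surface(rates, v) - obs)^2,
                                       na.rm = TRUE)
  v <- init_fork_speed
  steps <- c(pmax(rates, 1e-3) * 0.25, v * 0.25)  # per-parameter step sizes
  obj <- objective(rates, v)
  if (!is.finite(obj)) stop("non-finite objective at initialization")
  trace <- obj
  converged <- FALSE
  sweep <- 0L
  while (sweep < max_sweeps) {
    sweep <- sweep + 1L
    obj_start <- obj
    for (p in seq_len(n_o + 1)) {
      cur <- if (p <= n_o) rates[p] else v
      floor_p <- if (p <= n_o) 0 else 1e-6
      improved <- FALSE
      for (dir in c(1, -1)) {
        cand <- max(cur + dir * steps[p], floor_p)
        if (cand == cur) next
        if (p <= n_o) { r2 <- rates; r2[p] <- cand; o2 <- objective(r2, v) }
        else o2 <- objective(rates, cand)
        if (is.finite(o2) && o2 < obj) {
          if (p <= n_o) rates[p] <- cand else v <- cand
          obj <- o2
          improved <- TRUE
          break
        }
      }
      steps[p] <- if (improved) steps[p] * 2 else steps[p] / 2
    }
    trace <- c(trace, obj)
    flat <- obj_start - obj < rel_tol * max(obj_start, 1e-12)
    # steps keep halving on flat sweeps; once they are negligible relative to
    # the parameter scales no further move can matter
    tiny <- all(steps < 1e-7 * pmax(c(rates, v), 1e-3))
    if (flat && tiny) { converged <- TRUE; break }
  }
  fitted <- kinetics_model(chrom_lengths,
                           data.frame(chrom = org$chrom, pos = org$pos,
                                      rate = rates),
                           fork_speed = v)
  per_origin <- fitted$origins
  per_origin$characteristic_time <- ifelse(per_origin$rate > 0,
                                           1 / per_origin$rate, Inf)
  structure(list(model = fitted, objective = obj, trace = trace,
                 converged = converged, n_sweeps = sweep,
                 per_origin = per_origin),
            class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf("kinetics_fit: %d origins, fork speed %.1f bp/min, objective %.3g (%s, %d sweeps)\n",
              nrow(x$per_origin), x$model$fork_speed, x$objective,
              if (x$converged) "converged" else "max sweeps", x$n_sweeps))
  invisible(x)
}
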