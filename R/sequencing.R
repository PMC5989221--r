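#' Describe a sequencing experiment over S phase
#'
#' Bundles the sampling design used by [sample_sequencing()]: the S-phase
#' timepoints at which synchronized aliquots are sequenced, the expected read
#' depth per 500 bp window, and the count noise model.
#'
#' @param timepoints strictly increasing sampling times (min after release).
#' @param depth expected reads per window for a locus at copy number 1 (> 0).
#' @param noise `"poisson"` (counts ~ Poisson with mean depth x copy number)
#'   or `"none"` (counts equal their expectation; an infinite-depth limit).
#' @param s_duration length of the S-phase window (min) onto which cell ages
#'   of the exponential sample are mapped; defaults to `max(timepoints)`.
#' @return list of class `sequencing_design`.
#' @export
sequencing_design <- function(timepoints, depth = 100,
                              noise = c("poisson", "none"),
                              s_duration = NULL) {
  noise <- match.arg(noise)
  if (any(diff(timepoints) <= 0)) stop("timepoints must be strictly increasing")
  if (depth <= 0) stop("depth must be positive")
  if (is.null(s_duration)) s_duration <- max(timepoints)
  structure(list(timepoints = timepoints, depth = depth, noise = noise,
                 s_duration = s_duration),
            class = "sequencing_design")
}

#' Generate windowed read-count tracks for a replication experiment
#'
#' Produces everything the profile builders consume: one count track per
#' S-phase timepoint, G1 and G2 reference tracks (copy number 1 and 2
#' everywhere), an exponential-phase ("Expo") and a stationary-phase ("Stat")
#' track for marker frequency analysis, and a sample sheet with the bulk DNA
#' content of each timepoint (genome-length-weighted mean copy number).
#'
#' The Expo sample mixes cells of all ages of an asynchronous exponentially
#' growing culture: age `a` in `[0, 1]` has density `2 log(2) 2^(-a)` (younger
#' cells are over-represented because each division creates two of them), and
#' ages are mapped linearly onto the S-phase window `[0, s_duration]`.
#' The Stat sample is non-replicating (copy number 1).
#'
#' @param model a [kinetics_model()].
#' @param design a [sequencing_design()].
#' @param seed RNG seed for count noise.
#' @param window_size bp (default 500).
#' @return list of class `replication_samples` with `windows`, `counts`
#'   (windows x samples matrix) and `sheet` (data.frame `sample`, `timepoint`,
#'   `role`, `dna_content`).
#' @export
sample_sequencing <- function(model, design, seed = 1L, window_size = 500) {
  stopifnot(inherits(model, "kinetics_model"),
            inherits(design, "sequencing_design"))
  set.seed(seed)
  surf <- copy_number_surface(model, design$timepoints, mode = "analytic",
                              window_size = window_size)
  win <- surf$windows
  wlen <- win$end - win$start
  # Expo expectation: age-weighted mean copy number
  ages <- seq(0, 1, length.out = 101)
  w_age <- 2 * log(2) * 2^(-ages)
  w_age <- w_age / sum(w_age)
  expo_surf <- copy_number_surface(model, ages * design$s_duration,
                                   mode = "analytic", window_size = window_size)
  expo_cn <- as.vector(expo_surf$copy_number %*% w_age)

  expectations <- cbind(surf$copy_number,
                        G1 = rep(1, nrow(win)),
                        G2 = rep(2, nrow(win)),
                        Expo = expo_cn,
                        Stat = rep(1, nrow(win)))
  mu <- expectations * design$depth
  counts <- if (design$noise == "poisson") {
    matrix(stats::rpois(length(mu), lambda = mu), nrow = nrow(mu),
           dimnames = dimnames(mu))
  } else mu
  dna_content <- as.vector(crossprod(surf$copy_number, wlen) / sum(wlen))
  sheet <- data.frame(
    sample = colnames(expectations),
    timepoint = c(design$timepoints, NA, NA, NA, NA),
    role = c(rep("S", length(design$timepoints)), "G1", "G2", "Expo", "Stat"),
    dna_content = c(dna_content, 1, 2, NA, NA))
  structure(list(windows = win, counts = counts, sheet = sheet),
            class = "replication_samples")
}

#' Write count tracks as bedGraph files plus a sample sheet
#'
#' One `<prefix>_<sample>.bedGraph` per sample (chrom, start, end, count) and
#' `<prefix>_samples.tsv` with the sheet.
#'
#' @param samples a [sample_sequencing()] result.
#' @param prefix output path prefix.
#' @return invisibly, the vector of files written.
#' @export
write_tracks <- function(samples, prefix) {
  files <- character(0)
  for (s in colnames(samples$counts)) {
    f <- paste0(prefix, "_", s, ".bedGraph")
    utils::write.table(cbind(samples$windows[c("chrom", "start", "end")],
                             count = samples$counts[, s]),
                       f, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    files <- c(files, f)
  }
  sheet_f <- paste0(prefix, "_samples.tsv")
  utils::write.table(samples$sheet, sheet_f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(files, sheet_f))
}

#' Read a bedGraph track
#'
#' @param path headerless 4-column bedGraph (chrom, start, end, value).
#' @return data.frame `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "value"),
                          colClasses = c("character", "numeric", "numeric",
                                         "numeric"))
  df
}
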