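#' Project one species' timing onto another through orthologous genes
#'
#' For every ortholog pair, samples species A's timing profile at the gene's
#' midpoint in genome A and species B's profile at the gene's midpoint in
#' genome B. Pairs with missing timing in either species are dropped (and
#' counted).
#'
#' @param profileA,profileB `timing_profile` objects (or plain profile
#'   data.frames) of the two species.
#' @param orthologs data.frame `geneA`, `chromA`, `startA`, `endA`, `geneB`,
#'   `chromB`, `startB`, `endB`, and optionally `block_id`.
#' @return data.frame of class `projected_profile`: ortholog columns plus
#'   `timingA`, `timingB`; attribute `n_dropped`.
#' @export
project_timing <- function(profileA, profileB, orthologs) {
  midA <- (orthologs$startA + orthologs$endA) / 2
  midB <- (orthologs$startB + orthologs$endB) / 2
  tA <- profile_value_at(profileA, orthologs$chromA, midA)
  tB <- profile_value_at(profileB, orthologs$chromB, midB)
  keep <- is.finite(tA) & is.finite(tB)
  if (!any(keep)) stop("no ortholog pair with timing defined in both species")
  out <- cbind(orthologs[keep, , drop = FALSE],
               timingA = tA[keep], timingB = tB[keep])
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  class(out) <- c("projected_profile", class(out))
  out
}

#' Genome-wide conservation of replication timing
#'
#' Spearman rank correlation (mid-ranks for ties) between the two species'
#' timing values over all projected ortholog pairs.
#'
#' @param projected a [project_timing()] result.
#' @return Spearman's rho.
#' @export
conservation_rho <- function(projected) {
  if (nrow(projected) < 10) stop("need at least 10 ortholog pairs")
  stats::cor(projected$timingA, projected$timingB, method = "spearman")
}

#' Random-offset null distribution of timing conservation
#'
#' Re-computes the conservation correlation after circularly shifting the
#' gene coordinates of one species by a uniform random offset (independent
#' per chromosome), which destroys the positional correspondence while
#' preserving each genome's timing value multiset. The offset is re-drawn
#' `n_offsets` times in each direction (A shifted, then B shifted).
#'
#' @param profileA,profileB timing profiles.
#' @param orthologs ortholog table as in [project_timing()].
#' @param n_offsets replicates per direction (default 100).
#' @param seed RNG seed.
#' @return numeric vector of `2 * n_offsets` null rho values.
#' @export
offset_null <- function(profileA, profileB, orthologs, n_offsets = 100,
                        seed = 1L) {
  set.seed(seed)
  chrom_span <- function(profile) {
    df <- if (inherits(profile, "timing_profile")) profile$profile else profile
    agg <- tapply(df$end, df$chrom, max)
    stats::setNames(as.numeric(agg), names(agg))
  }
  shift_side <- function(orth, side, spans) {
    chrom <- orth[[paste0("chrom", side)]]
    for (ch in unique(chrom)) {
      L <- spans[[ch]]
      if (is.null(L) || !is.finite(L)) next
      off <- stats::runif(1, 0, L)
      rows <- chrom == ch
      for (col in paste0(c("start", "end"), side)) {
        orth[[col]][rows] <- (orth[[col]][rows] + off) %% L
      }
    }
    orth
  }
  spansA <- chrom_span(profileA); spansB <- chrom_span(profileB)
  rhos <- numeric(0)
  for (side in c("A", "B")) {
    for (r in seq_len(n_offsets)) {
      orth <- shift_side(orthologs, side,
                         if (side == "A") spansA else spansB)
      proj <- tryCatch(project_timing(profileA, profileB, orth),
                       error = function(e) NULL)
      rhos <- c(rhos, if (is.null(proj) || nrow(proj) < 10) NA_real_
                else conservation_rho(proj))
    }
  }
  rhos
}

#' Local timing correlation at a given distance from synteny breakpoints
#'
#' Splits each synteny block into regions of `window_genes` consecutive
#' ortholog pairs located `offset_genes` genes inward from each block edge,
#' computes Spearman's rho per region, and averages. Regions at offset 0
#' directly flank the breakpoints; large offsets probe the block interior.
#' To compare classes on equal footing the deepest class is subsampled to
#' the same number of regions as the smallest class (fixed seed).
#'
#' @param projected a [project_timing()] result carrying `block_id`.
#' @param window_genes region size in genes (default 5).
#' @param offset_genes vector of offsets to evaluate (default `c(0, 25)`).
#' @param seed subsampling seed.
#' @return data.frame `offset`, `n_regions`, `mean_rho`.
#' @export
local_rho <- function(projected, window_genes = 5, offset_genes = c(0, 25),
                      seed = 1L) {
  if (!"block_id" %in% names(projected)) stop("projected pairs need block_id")
  blocks <- split(seq_len(nrow(projected)), projected$block_id)
  region_rhos <- lapply(offset_genes, function(off) {
    rhos <- numeric(0)
    for (idx in blocks) {
      idx <- idx[order(projected$startA[idx])]
      n <- length(idx)
      if (n < 2 * (off + window_genes)) next  # both edges must fit disjointly
      left <- idx[(off + 1):(off + window_genes)]
      right <- idx[(n - off - window_genes + 1):(n - off)]
      for (reg in list(left, right)) {
        r <- suppressWarnings(stats::cor(projected$timingA[reg],
                                         projected$timingB[reg],
                                         method = "spearman"))
        if (is.finite(r)) rhos <- c(rhos, r)
      }
    }
    rhos
  })
  counts <- vapply(region_rhos, length, 0L)
  n_min <- if (any(counts > 0)) min(counts[counts > 0]) else 0L
  set.seed(seed)
  out <- data.frame(offset = offset_genes, n_regions = 0L,
                    mean_rho = NA_real_)
  for (k in seq_along(offset_genes)) {
    rr <- region_rhos[[k]]
    if (!length(rr)) next  # class empty: reported as NA with 0 regions
    if (length(rr) > n_min) rr <- sample(rr, n_min)
    out$n_regions[k] <- length(rr)
    out$mean_rho[k] <- mean(rr)
  }
  out
}

#' Timing differences between orthologous origins
#'
#' For each origin family with members in both species, the absolute
#' difference of normalized (0-1) replication timing between the family's
#' origins in the two genomes. Families with several members per species
#' contribute their per-species mean timing.
#'
#' @param norm_profileA,norm_profileB normalized timing profiles
#'   (see [normalize_timing()]).
#' @param families family table (`family_id`, `species`, `chrom`, `pos`; see
#'   [build_families()]).
#' @param speciesA,speciesB the two species names in `families`.
#' @return list with `differences` (numeric vector), `median`, `sd`.
#' @export
ortholog_origin_timing_diff <- function(norm_profileA, norm_profileB,
                                        families, speciesA, speciesB) {
  fa <- families[families$species == speciesA, ]
  fb <- families[families$species == speciesB, ]
  shared <- intersect(fa$family_id, fb$family_id)
  if (!length(shared)) stop("no family shared between the two species")
  diffs <- vapply(shared, function(f) {
    a <- fa[fa$family_id == f, ]
    b <- fb[fb$family_id == f, ]
    ta <- mean(profile_value_at(norm_profileA, a$chrom, a$pos), na.rm = TRUE)
    tb <- mean(profile_value_at(norm_profileB, b$chrom, b$pos), na.rm = TRUE)
    abs(ta - tb)
  }, 0)
  diffs <- diffs[is.finite(diffs)]
  if (!length(diffs)) stop("no shared family with timing defined")
  list(differences = unname(diffs), median = stats::median(diffs),
       sd = stats::sd(diffs))
}
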