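#' Per-species synteny block spans
#'
#' Summarizes an ortholog table into block intervals on one of the two
#' genomes, with the number of syntenic genes per block.
#'
#' @param orthologs ortholog table (`geneA`, `chromA`, `startA`, `endA`,
#'   `geneB`, ..., `block_id`).
#' @param side `"A"` or `"B"`: which genome to summarize on.
#' @return data.frame `chrom`, `start`, `end`, `n_genes`, `block_id`.
#' @export
synteny_block_spans <- function(orthologs, side = c("A", "B")) {
  side <- match.arg(side)
  ch <- orthologs[[paste0("chrom", side)]]
  s <- orthologs[[paste0("start", side)]]
  e <- orthologs[[paste0("end", side)]]
  out <- do.call(rbind, lapply(split(seq_len(nrow(orthologs)),
                                     orthologs$block_id), function(idx) {
    data.frame(chrom = ch[idx[1]], start = min(s[idx]), end = max(e[idx]),
               n_genes = length(idx), block_id = orthologs$block_id[idx[1]])
  }))
  rownames(out) <- NULL
  out[order(out$chrom, out$start), ]
}

#' Exclude subtelomeric origins
#'
#' Synteny conservation degrades towards chromosome ends, so origins lying
#' between a telomere and the first synteny block of at least
#' `min_block_genes` syntenic genes are removed before family construction.
#'
#' @param origins data.frame `chrom`, `pos` (plus any id columns).
#' @param blocks block spans on the same genome (see
#'   [synteny_block_spans()]); blocks from several pairwise comparisons may
#'   be concatenated.
#' @param min_block_genes minimum genes for a block to anchor the
#'   interstitial region (default 5).
#' @return list `kept`, `excluded` (both data.frames).
#' @export
filter_subtelomeric <- function(origins, blocks, min_block_genes = 5) {
  qual <- blocks[blocks$n_genes >= min_block_genes, ]
  keep <- logical(nrow(origins))
  for (ch in unique(origins$chrom)) {
    oi <- which(origins$chrom == ch)
    qb <- qual[qual$chrom == ch, ]
    if (!nrow(qb)) {
      warning("chromosome ", ch, " has no qualifying synteny block; ",
              "all its origins excluded")
      next
    }
    lo <- min(qb$start); hi <- max(qb$end)
    keep[oi] <- origins$pos[oi] >= lo & origins$pos[oi] <= hi
  }
  list(kept = origins[keep, , drop = FALSE],
       excluded = origins[!keep, , drop = FALSE])
}

#' Project origin positions onto another genome via flanking genes
#'
#' Each origin is located between its two nearest coding genes (by gene
#' midpoint). When both flanking genes have orthologs in the same synteny
#' block on the same target chromosome, the origin is projected to the
#' midpoint of the interval between the two orthologs; otherwise it is
#' marked unprojectable.
#'
#' @param origins data.frame `origin_id`, `chrom`, `pos` on genome A.
#' @param genesA gene annotation of genome A (`chrom`, `start`, `end`,
#'   `gene_id`).
#' @param orthologs A-to-B ortholog table (see [identity_orthologs()] for the
#'   column layout).
#' @return data.frame `origin_id`, `chrom`, `pos`, `projectable`, `chromB`,
#'   `posB`.
#' @export
project_origins <- function(origins, genesA, orthologs) {
  orthA <- match(genesA$gene_id, orthologs$geneA)
  out <- data.frame(origin_id = origins$origin_id, chrom = origins$chrom,
                    pos = origins$pos, projectable = FALSE,
                    chromB = NA_character_, posB = NA_real_)
  for (ch in unique(origins$chrom)) {
    gi <- which(genesA$chrom == ch)
    if (!length(gi)) next
    gmid <- (genesA$start[gi] + genesA$end[gi]) / 2
    ord <- order(gmid)
    gi <- gi[ord]; gmid <- gmid[ord]
    oi <- which(origins$chrom == ch)
    left_k <- findInterval(origins$pos[oi], gmid)
    for (q in seq_along(oi)) {
      kl <- left_k[q]; kr <- kl + 1
      if (kl < 1 || kr > length(gi)) next  # chromosome end: single flank
      ol <- orthA[gi[kl]]; or_ <- orthA[gi[kr]]
      if (is.na(ol) || is.na(or_)) next
      if (orthologs$block_id[ol] != orthologs$block_id[or_]) next
      if (orthologs$chromB[ol] != orthologs$chromB[or_]) next
      g1 <- c(orthologs$startB[ol], orthologs$endB[ol])
      g2 <- c(orthologs$startB[or_], orthologs$endB[or_])
      inner_lo <- min(g1[2], g2[2]); inner_hi <- max(g1[1], g2[1])
      out$projectable[oi[q]] <- TRUE
      out$chromB[oi[q]] <- orthologs$chromB[ol]
      out$posB[oi[q]] <- (inner_lo + inner_hi) / 2
    }
  }
  out
}

# count syntenic (ortholog-bearing) genes of the target genome whose midpoint
# lies strictly between two positions on the same chromosome
syntenic_genes_between <- function(chrom, pos1, pos2, synt_mid_by_chrom) {
  mids <- synt_mid_by_chrom[[chrom]]
  if (is.null(mids)) return(0L)
  lo <- pmin(pos1, pos2); hi <- pmax(pos1, pos2)
  sum(mids > lo & mids < hi)
}

#' Conserved origin pairs between two species
#'
#' Applies the delta rule: each projected origin is associated with its
#' nearest resident origin on the target genome; a pair `(a, b)` is conserved
#' iff the projection of `a` lands at most `delta` syntenic genes from `b`
#' AND, reciprocally, the projection of `b` lands at most `delta` syntenic
#' genes from `a`. Syntenic genes are ortholog-bearing genes lying strictly
#' between the projected position and the resident origin.
#'
#' @param originsA,originsB data.frames `origin_id`, `chrom`, `pos`.
#' @param projAB [project_origins()] output for A onto B.
#' @param projBA [project_origins()] output for B onto A.
#' @param orthologs the A-to-B ortholog table used for both projections.
#' @param delta maximum intervening syntenic genes (default 2).
#' @return data.frame `originA`, `originB` (ids), `genes_ab`, `genes_ba`.
#' @export
pair_conserved <- function(originsA, originsB, projAB, projBA, orthologs,
                           delta = 2) {
  mid_by_chrom <- function(chroms, starts, ends) {
    mids <- (starts + ends) / 2
    lapply(split(mids, chroms), sort)
  }
  syntB <- mid_by_chrom(orthologs$chromB, orthologs$startB, orthologs$endB)
  syntA <- mid_by_chrom(orthologs$chromA, orthologs$startA, orthologs$endA)
  half_link <- function(proj, residents, synt_mids) {
    links <- list()
    for (q in which(proj$projectable)) {
      pr <- proj[q, ]
      res <- residents[residents$chrom == pr$chromB, ]
      if (!nrow(res)) next
      b <- res[which.min(abs(res$pos - pr$posB)), ]
      d <- syntenic_genes_between(pr$chromB, pr$posB, b$pos, synt_mids)
      if (d <= delta)
        links[[length(links) + 1]] <- data.frame(from = pr$origin_id,
                                                 to = b$origin_id,
                                                 genes_between = d)
    }
    if (length(links)) do.call(rbind, links) else
      data.frame(from = character(0), to = character(0),
                 genes_between = integer(0))
  }
  ab <- half_link(projAB, originsB, syntB)
  # B->A projections land on genome A (their chromB/posB hold A coordinates)
  ba <- half_link(projBA, originsA, syntA)
  key_ab <- paste(ab$from, ab$to)
  key_ba <- paste(ba$to, ba$from)
  both <- key_ab %in% key_ba
  res <- data.frame(originA = ab$from[both], originB = ab$to[both],
                    genes_ab = ab$genes_between[both],
                    genes_ba = ba$genes_between[match(key_ab[both], key_ba)])
  unique(res)
}

#' Assemble origin families from conserved pairs
#'
#' Cross-species conserved pairs are edges of a graph whose nodes are
#' `(species, origin)` tuples; families are the connected components.
#' Origins belonging to no pair are singleton families.
#'
#' @param pairs data.frame `speciesA`, `originA`, `speciesB`, `originB`
#'   (concatenated over all species pairs, deduplicated).
#' @param all_origins data.frame `species`, `origin_id`, `chrom`, `pos`
#'   listing every origin under consideration.
#' @return list of class `origin_families`: `families` (data.frame
#'   `family_id`, `species`, `origin_id`, `chrom`, `pos`), `phyletic`
#'   (families x species 0/1 matrix), and `summary` (list with
#'   `n_families`, `n_multi_species`, `n_singletons`,
#'   `prop_multimember_species`).
#' @export
build_families <- function(pairs, all_origins) {
  node_id <- function(sp, ori) paste(sp, ori, sep = "|")
  all_nodes <- node_id(all_origins$species, all_origins$origin_id)
  if (anyDuplicated(all_nodes)) stop("duplicate (species, origin) rows")
  g <- igraph::make_empty_graph(n = length(all_nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = all_nodes)
  if (nrow(pairs)) {
    ea <- node_id(pairs$speciesA, pairs$originA)
    eb <- node_id(pairs$speciesB, pairs$originB)
    keep <- ea %in% all_nodes & eb %in% all_nodes
    g <- igraph::add_edges(g, rbind(ea[keep], eb[keep]))
  }
  comp <- igraph::components(g)$membership
  fam <- data.frame(family_id = sprintf("fam_%04d", comp[all_nodes]),
                    species = all_origins$species,
                    origin_id = all_origins$origin_id,
                    chrom = all_origins$chrom, pos = all_origins$pos)
  fam <- fam[order(fam$family_id, fam$species, fam$pos), ]
  rownames(fam) <- NULL
  species <- sort(unique(all_origins$species))
  tab <- table(fam$family_id, fam$species)
  phyletic <- matrix(0L, nrow = nrow(tab), ncol = length(species),
                     dimnames = list(rownames(tab), species))
  phyletic[, colnames(tab)] <- ifelse(tab > 0, 1L, 0L)
  n_sp <- rowSums(phyletic)
  multi_member <- apply(tab, 1, function(r) any(r > 1))
  summary <- list(
    n_families = nrow(phyletic),
    n_multi_species = sum(n_sp > 1),
    n_singletons = sum(n_sp == 1 & rowSums(tab) == 1),
    prop_multimember_species = mean(multi_member))
  structure(list(families = fam, phyletic = phyletic, summary = summary),
            class = "origin_families")
}

#' Constrained randomization of origin positions
#'
#' Draws one randomized origin set for a genome under three constraints:
#' (1) the inter-origin distance multiset on each chromosome equals the
#' observed multiset exactly (spacings are permuted, never altered);
#' (2) the first origin of each chromosome lies in
#' `(0, 2 x observed first position)`; (3) the number of intragenic origins
#' per chromosome equals the observed number, so the genome's
#' intra-/intergenic proportion is preserved.
#'
#' Given a spacing permutation, the whole chain is determined by the first
#' origin position `x0`; origin classifications are piecewise-constant in
#' `x0`, so the sampler enumerates the classification breakpoints of `x0`
#' over its admissible interval and draws `x0` uniformly from the sub-region
#' achieving the intragenic quota. If a permutation admits no such region a
#' fresh permutation is drawn (up to `max_attempts`); the closest achievable
#' quota is kept as a fallback and flagged.
#'
#' @param origins data.frame `chrom`, `pos` (observed set).
#' @param genes gene annotation for the same genome.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param seed RNG seed.
#' @param max_attempts spacing permutations to try per chromosome.
#' @return data.frame `chrom`, `pos` with attributes `quota_exact` (logical)
#'   and `seed`.
#' @export
randomize_origins <- function(origins, genes, chrom_lengths, seed = 1L,
                              max_attempts = 100) {
  set.seed(seed)
  is_intragenic <- function(chrom, pos) {
    g <- genes[genes$chrom == chrom, ]
    if (!nrow(g)) return(rep(FALSE, length(pos)))
    idx <- findInterval(pos, sort(g$start))
    gs <- g[order(g$start), ]
    ok <- idx >= 1
    ok[ok] <- pos[ok] < gs$end[idx[ok]]
    ok
  }
  out <- list()
  quota_exact <- TRUE
  for (ch in unique(origins$chrom)) {
    p <- sort(origins$pos[origins$chrom == ch])
    if (length(p) < 2) stop("need >= 2 origins on chromosome ", ch)
    d <- diff(p)
    f <- p[1]
    L <- chrom_lengths[[ch]]
    span <- sum(d)
    x0_max <- min(2 * f, L - span)
    if (x0_max <= 0) stop("no admissible first-origin position on ", ch)
    target <- sum(is_intragenic(ch, p))
    g <- genes[genes$chrom == ch, ]
    bnd <- sort(unique(c(g$start, g$end)))
    best <- NULL; best_dev <- Inf
    for (att in seq_len(max_attempts)) {
      dp <- if (length(d) > 1) sample(d) else d
      offs <- c(0, cumsum(dp))
      # x0 values where any origin crosses a gene boundary
      cuts <- as.vector(outer(bnd, offs, `-`))
      cuts <- sort(unique(c(0, cuts[cuts > 0 & cuts < x0_max], x0_max)))
      mids <- (cuts[-1] + cuts[-length(cuts)]) / 2
      counts <- vapply(mids, function(x0)
        sum(is_intragenic(ch, x0 + offs)), 0L)
      hit <- which(counts == target)
      if (length(hit)) {
        w <- cuts[hit + 1] - cuts[hit]
        seg <- if (length(hit) == 1) hit else sample(hit, 1, prob = w)
        x0 <- stats::runif(1, cuts[seg], cuts[seg + 1])
        best <- x0 + offs; best_dev <- 0
        break
      }
      dev <- min(abs(counts - target))
      if (dev < best_dev) {
        seg <- which.min(abs(counts - target))
        best <- stats::runif(1, cuts[seg], cuts[seg + 1]) + offs
        best_dev <- dev
      }
    }
    if (best_dev > 0) quota_exact <- FALSE
    out[[ch]] <- data.frame(chrom = ch, pos = best)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "quota_exact") <- quota_exact
  attr(res, "seed") <- seed
  res
}

#' Conserved pairs for every species pair at a given delta
#'
#' Convenience wrapper running [project_origins()] both ways and
#' [pair_conserved()] for each ortholog table.
#'
#' @param species_data named list; each element a list with `origins`
#'   (`origin_id`, `chrom`, `pos`) and `genes`.
#' @param orthologs_list named list of ortholog tables, names `"A|B"`.
#' @param delta delta rule threshold.
#' @return data.frame `speciesA`, `originA`, `speciesB`, `originB`,
#'   `genes_ab`, `genes_ba`.
#' @export
conserved_pairs_all <- function(species_data, orthologs_list, delta = 2) {
  out <- list()
  for (key in names(orthologs_list)) {
    sp <- strsplit(key, "|", fixed = TRUE)[[1]]
    orth <- orthologs_list[[key]]
    A <- species_data[[sp[1]]]; B <- species_data[[sp[2]]]
    projAB <- project_origins(A$origins, A$genes, orth)
    orth_rev <- data.frame(geneA = orth$geneB, chromA = orth$chromB,
                           startA = orth$startB, endA = orth$endB,
                           geneB = orth$geneA, chromB = orth$chromA,
                           startB = orth$startA, endB = orth$endA,
                           block_id = orth$block_id)
    projBA <- project_origins(B$origins, B$genes, orth_rev)
    pc <- pair_conserved(A$origins, B$origins, projAB, projBA, orth, delta)
    if (nrow(pc))
      out[[key]] <- cbind(speciesA = sp[1],
                          data.frame(originA = pc$originA),
                          speciesB = sp[2],
                          data.frame(originB = pc$originB,
                                     genes_ab = pc$genes_ab,
                                     genes_ba = pc$genes_ba))
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(speciesA = character(0), originA = character(0),
               speciesB = character(0), originB = character(0),
               genes_ab = integer(0), genes_ba = integer(0))
}

#' Calibrate the delta rule against the randomization null
#'
#' Evaluates every delta in `deltas`, on the real origin sets and on
#' `n_rand` constrained randomizations, reporting per delta: conserved-pair
#' counts (real, random mean), families with exactly one member in every
#' species, families with more members than species, and the proportion of
#' families with more than one member in some species. The recommended delta
#' maximizes the real-vs-random conserved-pair excess, with family-based
#' criteria as tie-breakers; the full table is always returned.
#'
#' @param species_data,orthologs_list as in [conserved_pairs_all()].
#' @param chrom_lengths named list per species of chromosome length vectors.
#' @param deltas candidate thresholds (default 0:6).
#' @param n_rand randomized replicates (default 10).
#' @param seed RNG seed.
#' @return list `table` (data.frame) and `recommended_delta`.
#' @export
calibrate_delta <- function(species_data, orthologs_list, chrom_lengths,
                            deltas = 0:6, n_rand = 10, seed = 1L) {
  n_species <- length(species_data)
  stats_for <- function(sp_data, delta) {
    pairs <- conserved_pairs_all(sp_data, orthologs_list, delta)
    all_org <- do.call(rbind, lapply(names(sp_data), function(s)
      cbind(species = s, sp_data[[s]]$origins)))
    fams <- build_families(pairs, all_org)
    tab <- table(fams$families$family_id, fams$families$species)
    sizes <- rowSums(tab)
    one_per_species <- sum(apply(tab, 1, function(r) all(r == 1)))
    list(pairs = nrow(pairs), full = one_per_species,
         oversize = sum(sizes > n_species),
         prop_multi = mean(apply(tab, 1, function(r) any(r > 1))))
  }
  rows <- list()
  for (delta in deltas) {
    real <- stats_for(species_data, delta)
    rnd_pairs <- numeric(n_rand); rnd_full <- numeric(n_rand)
    for (r in seq_len(n_rand)) {
      sp_rand <- species_data
      for (s in names(sp_rand)) {
        rnd <- randomize_origins(sp_rand[[s]]$origins, sp_rand[[s]]$genes,
                                 chrom_lengths[[s]],
                                 seed = seed + 1000L * r + match(s, names(sp_rand)))
        rnd$origin_id <- sprintf("rnd_%s_%03d", s, seq_len(nrow(rnd)))
        sp_rand[[s]]$origins <- rnd[, c("origin_id", "chrom", "pos")]
      }
      st <- stats_for(sp_rand, delta)
      rnd_pairs[r] <- st$pairs; rnd_full[r] <- st$full
    }
    rows[[length(rows) + 1]] <- data.frame(
      delta = delta, real_pairs = real$pairs,
      rand_pairs_mean = mean(rnd_pairs),
      pair_excess = real$pairs - mean(rnd_pairs),
      real_full_families = real$full, rand_full_families_mean = mean(rnd_full),
      real_oversize_families = real$oversize,
      prop_multimember = real$prop_multi)
  }
  tab <- do.call(rbind, rows)
  ord <- order(-tab$pair_excess,
               -(tab$real_full_families - tab$rand_full_families_mean),
               tab$real_oversize_families, tab$delta)
  list(table = tab, recommended_delta = tab$delta[ord[1]])
}
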