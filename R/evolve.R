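#' Build a regular synthetic gene annotation
#'
#' Lays out `genes_per_chrom` coding genes per chromosome, alternating with
#' intergenes, on a shared gene scaffold: gene identifiers are common to all
#' species that evolve on it, so cross-species ortholog maps are the identity
#' on conserved genes (one synteny block per chromosome).
#'
#' @param n_chrom number of chromosomes.
#' @param genes_per_chrom genes per chromosome.
#' @param gene_length gene length in bp.
#' @param intergene_length intergene length in bp.
#' @return list with `genes` (data.frame `chrom`, `start`, `end`, `gene_id`)
#'   and `chrom_lengths` (named vector).
#' @export
synthetic_genome <- function(n_chrom = 2, genes_per_chrom = 200,
                             gene_length = 1500, intergene_length = 500) {
  period <- gene_length + intergene_length
  chroms <- paste0("chr", seq_len(n_chrom))
  genes <- do.call(rbind, lapply(chroms, function(ch) {
    starts <- intergene_length + period * (seq_len(genes_per_chrom) - 1)
    data.frame(chrom = ch, start = starts, end = starts + gene_length,
               gene_id = sprintf("g_%s_%03d", ch, seq_len(genes_per_chrom)))
  }))
  lens <- stats::setNames(rep(genes_per_chrom * period + intergene_length,
                              n_chrom), chroms)
  list(genes = genes, chrom_lengths = lens)
}

#' Identity ortholog map between two species on a shared gene scaffold
#'
#' @param genes gene annotation from [synthetic_genome()].
#' @param conserved_frac fraction of genes kept as orthologous pairs
#'   (the rest are dropped at random to emulate lineage-specific genes).
#' @param seed RNG seed used when `conserved_frac < 1`.
#' @return data.frame `geneA`, `chromA`, `startA`, `endA`, `geneB`, `chromB`,
#'   `startB`, `endB`, `block_id` (one block per chromosome).
#' @export
identity_orthologs <- function(genes, conserved_frac = 1, seed = 1L) {
  keep <- seq_len(nrow(genes))
  if (conserved_frac < 1) {
    set.seed(seed)
    keep <- sort(sample(keep, round(conserved_frac * length(keep))))
  }
  g <- genes[keep, ]
  data.frame(geneA = g$gene_id, chromA = g$chrom, startA = g$start,
             endA = g$end, geneB = g$gene_id, chromB = g$chrom,
             startB = g$start, endB = g$end,
             block_id = paste0("blk_", g$chrom))
}

branch_label <- function(tree, child) {
  n_tip <- length(tree$tip.label)
  if (child <= n_tip) return(tree$tip.label[child])
  if (!is.null(tree$node.label) &&
      nzchar(tree$node.label[child - n_tip])) {
    return(tree$node.label[child - n_tip])
  }
  paste0("n", child)
}

#' Evolve an origin repertoire along a rooted tree
#'
#' Plays a birth-death process of active replication origins over a species
#' phylogeny: on each branch, gain and loss events arrive as Poisson
#' processes (rates per unit branch length), interleaved chronologically.
#' A gain places a new origin uniformly in the intergenic space of the shared
#' gene scaffold; a loss removes an origin chosen uniformly among those
#' currently present. A loss that would leave a chromosome without any origin
#' is re-drawn (and flagged in the log). Origin identity is preserved along
#' the tree, so leaf repertoires carry a built-in ground-truth orthology.
#'
#' @param tree rooted `phylo` with positive branch lengths.
#' @param ancestral_origins data.frame `chrom`, `pos`, `rate` (and optional
#'   `id`) giving the root repertoire.
#' @param genome a [synthetic_genome()] result (gene scaffold + lengths).
#' @param gain_rate,loss_rate events per unit branch length.
#' @param seed RNG seed.
#' @param new_rate function(n) drawing firing rates for gained origins;
#'   default: uniform on 0.02-0.2 per minute.
#' @return object of class `repertoire_evolution`: list with `tree`, `genome`,
#'   `ancestral` (origin data.frame), `events` (data.frame `branch`, `time`,
#'   `type`, `origin_id`, `chrom`, `pos`), `leaf_origins` (data.frame with a
#'   `species` column), `node_sets` (per-node origin id lists) and `flags`.
#' @export
evolve_repertoire <- function(tree, ancestral_origins, genome,
                              gain_rate = 0.5, loss_rate = 0.5, seed = 1L,
                              new_rate = function(n) stats::runif(n, 0.02, 0.2)) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (is.null(tree$edge.length) || any(tree$edge.length <= 0))
    stop("tree must have positive branch lengths")
  set.seed(seed)
  genes <- genome$genes
  lens <- genome$chrom_lengths
  anc <- ancestral_origins
  if (is.null(anc$id)) anc$id <- sprintf("anc_%03d", seq_len(nrow(anc)))
  origin_tab <- anc[, c("id", "chrom", "pos", "rate")]

  # intergenic intervals per chromosome, for uniform gain placement
  intergenes <- do.call(rbind, lapply(names(lens), function(ch) {
    g <- genes[genes$chrom == ch, ]
    g <- g[order(g$start), ]
    lo <- c(0, g$end)
    hi <- c(g$start, lens[[ch]])
    keep <- hi > lo
    data.frame(chrom = ch, lo = lo[keep], hi = hi[keep])
  }))
  ig_len <- intergenes$hi - intergenes$lo

  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  node_sets <- vector("list", max(tree$edge))
  node_sets[[root]] <- anc$id
  events <- list()
  flags <- character(0)
  gain_counter <- 0L

  draw_gain_pos <- function() {
    row <- sample(nrow(intergenes), 1, prob = ig_len)
    list(chrom = intergenes$chrom[row],
         pos = round(stats::runif(1, intergenes$lo[row], intergenes$hi[row])))
  }

  # preorder: repeatedly process edges whose parent set is already known
  remaining <- seq_len(nrow(tree$edge))
  while (length(remaining)) {
    ready <- remaining[!vapply(tree$edge[remaining, 1],
                               function(p) is.null(node_sets[[p]]), TRUE)]
    for (e in ready) {
      parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
      len <- tree$edge.length[e]
      lab <- branch_label(tree, child)
      present <- node_sets[[parent]]
      n_g <- stats::rpois(1, gain_rate * len)
      n_l <- stats::rpois(1, loss_rate * len)
      times <- sort(stats::runif(n_g + n_l, 0, len))
      types <- sample(c(rep("gain", n_g), rep("loss", n_l)))
      for (k in seq_along(times)) {
        if (types[k] == "gain") {
          gain_counter <- gain_counter + 1L
          gp <- draw_gain_pos()
          oid <- sprintf("gained_%03d", gain_counter)
          origin_tab <- rbind(origin_tab,
                              data.frame(id = oid, chrom = gp$chrom,
                                         pos = gp$pos, rate = new_rate(1)))
          present <- c(present, oid)
          events[[length(events) + 1]] <- data.frame(
            branch = lab, time = times[k], type = "gain", origin_id = oid,
            chrom = gp$chrom, pos = gp$pos)
        } else {
          if (!length(present)) { flags <- c(flags, "loss skipped: empty set"); next }
          chrom_of <- origin_tab$chrom[match(present, origin_tab$id)]
          counts <- table(chrom_of)
          # cannot lose the last origin of a chromosome
          eligible <- present[counts[chrom_of] > 1]
          if (!length(eligible)) {
            flags <- c(flags, sprintf("loss re-drawn then skipped on %s", lab))
            next
          }
          if (length(eligible) < length(present))
            flags <- c(flags, sprintf("loss re-drawn on %s (chromosome guard)", lab))
          victim <- if (length(eligible) == 1) eligible else sample(eligible, 1)
          present <- setdiff(present, victim)
          row <- match(victim, origin_tab$id)
          events[[length(events) + 1]] <- data.frame(
            branch = lab, time = times[k], type = "loss", origin_id = victim,
            chrom = origin_tab$chrom[row], pos = origin_tab$pos[row])
        }
      }
      node_sets[[child]] <- present
    }
    remaining <- setdiff(remaining, ready)
  }

  events <- if (length(events)) do.call(rbind, events) else
    data.frame(branch = character(0), time = numeric(0), type = character(0),
               origin_id = character(0), chrom = character(0), pos = numeric(0))
  leaf_origins <- do.call(rbind, lapply(seq_len(n_tip), function(i) {
    ids <- node_sets[[i]]
    rows <- origin_tab[match(ids, origin_tab$id), ]
    if (!nrow(rows)) return(NULL)
    cbind(species = tree$tip.label[i], rows)
  }))
  leaf_origins <- leaf_origins[order(leaf_origins$species, leaf_origins$chrom,
                                     leaf_origins$pos), ]
  rownames(leaf_origins) <- NULL
  structure(list(tree = tree, genome = genome, ancestral = anc,
                 events = events, leaf_origins = leaf_origins,
                 node_sets = node_sets, flags = flags),
            class = "repertoire_evolution")
}

#' Replay an event log from the ancestral set
#'
#' Applies the logged gains and losses along each root-to-leaf path and
#' returns the implied leaf repertoires, used to verify internal consistency
#' of [evolve_repertoire()] output.
#'
#' @param evo a `repertoire_evolution` object.
#' @return named list of origin id vectors, one per leaf species.
#' @export
replay_events <- function(evo) {
  tree <- evo$tree
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  labs <- vapply(tree$edge[, 2], function(ch) branch_label(tree, ch), "")
  out <- stats::setNames(vector("list", n_tip), tree$tip.label)
  for (i in seq_len(n_tip)) {
    # path of edges from root to leaf i
    path <- integer(0)
    node <- i
    while (node != root) {
      e <- which(tree$edge[, 2] == node)
      path <- c(e, path)
      node <- tree$edge[e, 1]
    }
    present <- evo$ancestral$id
    for (e in path) {
      ev <- evo$events[evo$events$branch == labs[e], ]
      ev <- ev[order(ev$time), ]
      for (k in seq_len(nrow(ev))) {
        present <- if (ev$type[k] == "gain") c(present, ev$origin_id[k])
                   else setdiff(present, ev$origin_id[k])
      }
    }
    out[[i]] <- present
  }
  out
}

#' Leaf kinetics models from an evolved repertoire
#'
#' @param evo a `repertoire_evolution` object.
#' @param fork_speed bp/min for all species.
#' @return named list of [kinetics_model()] objects, one per leaf.
#' @export
leaf_models <- function(evo, fork_speed = 2000) {
  lapply(stats::setNames(nm = evo$tree$tip.label), function(sp) {
    org <- evo$leaf_origins[evo$leaf_origins$species == sp, ]
    kinetics_model(evo$genome$chrom_lengths,
                   data.frame(chrom = org$chrom, pos = org$pos,
                              rate = org$rate, id = org$id),
                   fork_speed = fork_speed)
  })
}
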