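#' Phyletic presence/absence matrix from origin families
#'
#' @param families an `origin_families` object (see [build_families()]) or
#'   its `families` data.frame.
#' @param species character vector fixing the column order (e.g. tree tip
#'   labels); every species must occur in the family table.
#' @return integer matrix families x species with entries 0/1.
#' @export
build_phyletic_matrix <- function(families, species) {
  df <- if (inherits(families, "origin_families")) families$families else families
  absent <- setdiff(species, unique(df$species))
  if (length(absent))
    stop("species absent from the family graph: ",
         paste(absent, collapse = ", "))
  tab <- table(df$family_id, df$species)
  m <- matrix(0L, nrow = nrow(tab), ncol = length(species),
              dimnames = list(rownames(tab), species))
  m[, intersect(colnames(tab), species)] <-
    ifelse(tab[, intersect(colnames(tab), species)] > 0, 1L, 0L)
  m
}

# children-of lists and postorder node sequence for a rooted tree
tree_structure <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  children <- vector("list", n_node)
  for (e in seq_len(nrow(tree$edge)))
    children[[tree$edge[e, 1]]] <- c(children[[tree$edge[e, 1]]],
                                     tree$edge[e, 2])
  post <- integer(0)
  stack <- n_tip + 1L
  visited <- logical(n_node)
  while (length(stack)) {
    v <- stack[length(stack)]
    kids <- children[[v]]
    pending <- kids[!visited[kids]]
    if (length(pending)) {
      stack <- c(stack, pending)
    } else {
      post <- c(post, v)
      visited[v] <- TRUE
      stack <- stack[-length(stack)]
    }
  }
  list(n_tip = n_tip, root = n_tip + 1L, children = children,
       postorder = post)
}

# weighted Sankoff small parsimony for one binary pattern; enumerates every
# minimum-cost internal labeling. Root presence is charged gain_cost (the
# family must be created somewhere).
sankoff_pattern <- function(tree, struct, pattern, gain_cost, loss_cost) {
  trans <- matrix(c(0, loss_cost, gain_cost, 0), nrow = 2)  # trans[s+1, t+1]
  n_node <- max(tree$edge)
  cost <- matrix(Inf, nrow = 2, ncol = n_node)
  for (i in seq_len(struct$n_tip)) cost[pattern[i] + 1, i] <- 0
  for (v in struct$postorder) {
    kids <- struct$children[[v]]
    if (!length(kids)) next
    for (s in 0:1) {
      tot <- 0
      for (k in kids) tot <- tot + min(trans[s + 1, ] + cost[, k])
      cost[s + 1, v] <- tot
    }
  }
  root <- struct$root
  totals <- c(cost[1, root], gain_cost + cost[2, root])
  min_cost <- min(totals)
  # backtrack: enumerate optimal state assignments over all nodes
  labelings <- list()
  expand <- function(assign, frontier) {
    if (!length(frontier)) {
      labelings[[length(labelings) + 1]] <<- assign
      return(invisible())
    }
    v <- frontier[1]
    s <- assign[v]
    kids <- struct$children[[v]]
    # per child, the set of optimal states
    opt_sets <- lapply(kids, function(k) {
      vals <- trans[s + 1, ] + cost[, k]
      which(vals == min(vals)) - 1L
    })
    combos <- expand.grid(opt_sets)
    for (r in seq_len(nrow(combos))) {
      a2 <- assign
      a2[kids] <- as.integer(combos[r, ])
      inner <- kids[kids > struct$n_tip]
      expand(a2, c(inner, frontier[-1]))
    }
  }
  for (s in which(totals == min_cost) - 1L) {
    assign <- rep(NA_integer_, n_node)
    assign[seq_len(struct$n_tip)] <- pattern
    assign[root] <- s
    expand(assign, root)
  }
  list(min_cost = min_cost, labelings = labelings)
}

#' Infer origin gain/loss history by weighted parsimony
#'
#' Reconstructs, for every origin family, the minimum-cost ancestral
#' presence states on a rooted binary species tree under asymmetric event
#' costs (a gain of a new active origin costs 2, a loss costs 1; presence at
#' the root is charged one gain, since every family must be created
#' somewhere). When several labelings tie, per-branch event counts are
#' averaged over all minimum-cost labelings. Events on branches listed in
#' `exclude_branches` (by default none; typically the outgroup terminal
#' branch and its sister internal branch, where a loss on one cannot be
#' distinguished from a gain on the other) are tallied separately and left
#' out of the headline totals.
#'
#' @param matrix phyletic 0/1 matrix (families x species), columns matching
#'   the tree's tip labels.
#' @param tree rooted binary `phylo`.
#' @param gain_cost,loss_cost transition costs (defaults 2 and 1).
#' @param exclude_branches character vector of branch labels (a branch is
#'   labelled by its child node: tip label or internal node label/`n<k>`).
#' @param focal_ancestor label of the node from which family ages are
#'   measured; default is the root, or, when `exclude_branches` contains a
#'   tip, the most recent common ancestor of the remaining tips.
#' @return list of class `gain_loss_history`: `per_family` (data.frame
#'   `family`, `cost`, `n_labelings`, `ancestral` (presence at the focal
#'   ancestor, averaged), `origination`, `age`, `age_class`,
#'   `ambiguous_origin`), `branch_events` (data.frame `branch`, `gains`,
#'   `losses`, `excluded`), `per_family_branch` (list of per-branch averaged
#'   gain/loss matrices), plus the `tree`, costs and focal node.
#' @export
infer_gain_loss <- function(matrix, tree, gain_cost = 2, loss_cost = 1,
                            exclude_branches = character(0),
                            focal_ancestor = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (!ape::is.binary(tree)) stop("tree must be binary")
  if (!setequal(colnames(matrix), tree$tip.label))
    stop("matrix columns must match tree tip labels")
  if (any(rowSums(matrix) == 0)) stop("all-zero phyletic pattern")
  matrix <- matrix[, tree$tip.label, drop = FALSE]
  struct <- tree_structure(tree)
  n_tip <- struct$n_tip
  edge_labels <- vapply(tree$edge[, 2], function(ch) branch_label(tree, ch), "")
  depths <- ape::node.depth.edgelength(tree)  # distance from root
  # focal ancestor node
  focal <- struct$root
  if (!is.null(focal_ancestor)) {
    if (focal_ancestor %in% tree$tip.label) stop("focal ancestor must be internal")
    cand <- which(vapply(seq_len(max(tree$edge)), function(v)
      v > n_tip && branch_label(tree, v) == focal_ancestor, TRUE))
    if (!length(cand)) stop("focal ancestor node not found: ", focal_ancestor)
    focal <- cand[1]
  } else if (any(exclude_branches %in% tree$tip.label)) {
    ingroup <- setdiff(tree$tip.label, exclude_branches)
    focal <- ape::getMRCA(tree, ingroup)
  }
  excl <- edge_labels %in% exclude_branches
  # nodes inside the focal clade
  in_focal <- logical(max(tree$edge))
  in_focal[focal] <- TRUE
  for (e in order(depths[tree$edge[, 2]])) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    if (in_focal[p]) in_focal[ch] <- TRUE
  }

  fam_rows <- list()
  branch_gains <- stats::setNames(numeric(nrow(tree$edge)), edge_labels)
  branch_losses <- branch_gains
  excl_gains <- 0; excl_losses <- 0
  per_family_branch <- list()
  for (f in seq_len(nrow(matrix))) {
    pat <- as.integer(matrix[f, ])
    sk <- sankoff_pattern(tree, struct, pat, gain_cost, loss_cost)
    nl <- length(sk$labelings)
    g_avg <- numeric(nrow(tree$edge)); l_avg <- g_avg
    anc_avg <- 0
    ages <- numeric(0); classes <- character(0)
    for (lab in sk$labelings) {
      ps <- lab[tree$edge[, 1]]; cs <- lab[tree$edge[, 2]]
      g_avg <- g_avg + (ps == 0 & cs == 1)
      l_avg <- l_avg + (ps == 1 & cs == 0)
      anc_avg <- anc_avg + lab[focal]
      if (lab[focal] == 1) {
        ages <- c(ages, 0); classes <- c(classes, "ancestral")
      } else {
        gains_in <- which(ps == 0 & cs == 1 & in_focal[tree$edge[, 2]])
        if (length(gains_in)) {
          e0 <- gains_in[which.min(depths[tree$edge[gains_in, 1]])]
          ages <- c(ages, depths[tree$edge[e0, 1]] - depths[focal])
          classes <- c(classes,
                       if (tree$edge[e0, 2] <= n_tip) "terminal-branch"
                       else "internal-branch")
        } else {
          ages <- c(ages, NA_real_); classes <- c(classes, "outside-focal")
        }
      }
    }
    g_avg <- g_avg / nl; l_avg <- l_avg / nl
    branch_gains <- branch_gains + ifelse(excl, 0, g_avg)
    branch_losses <- branch_losses + ifelse(excl, 0, l_avg)
    excl_gains <- excl_gains + sum(g_avg[excl])
    excl_losses <- excl_losses + sum(l_avg[excl])
    # origination branch: dominant gain branch, or the focal ancestor
    orig <- if (anc_avg / nl >= 0.5) "ancestral" else {
      if (any(g_avg > 0)) edge_labels[which.max(g_avg)] else NA_character_
    }
    cls <- names(sort(table(classes), decreasing = TRUE))[1]
    fam_rows[[f]] <- data.frame(
      family = rownames(matrix)[f], cost = sk$min_cost, n_labelings = nl,
      ancestral = anc_avg / nl, origination = orig,
      age = mean(ages, na.rm = TRUE), age_class = cls,
      ambiguous_origin = nl > 1)
    per_family_branch[[rownames(matrix)[f]]] <-
      data.frame(branch = edge_labels, gains = g_avg, losses = l_avg)
  }
  structure(list(
    per_family = do.call(rbind, fam_rows),
    branch_events = data.frame(branch = edge_labels,
                               gains = unname(branch_gains),
                               losses = unname(branch_losses),
                               excluded = excl),
    excluded_events = c(gains = excl_gains, losses = excl_losses),
    per_family_branch = per_family_branch,
    tree = tree, gain_cost = gain_cost, loss_cost = loss_cost,
    focal_node = focal),
    class = "gain_loss_history")
}

#' Phylogenetic age of one origin family
#'
#' Age is the cumulated branch length between the focal ancestor and the
#' start of the family's origination branch; families already present at the
#' focal ancestor have age 0 and class `"ancestral"`. Families whose
#' minimum-cost placements are tied report the average age over placements
#' and are flagged.
#'
#' @param history a [infer_gain_loss()] result.
#' @param family family id (rowname of the phyletic matrix).
#' @return list `age`, `age_class`, `origination`, `ambiguous`.
#' @export
assign_age <- function(history, family) {
  row <- history$per_family[history$per_family$family == family, ]
  if (!nrow(row)) stop("unknown family: ", family)
  list(age = row$age, age_class = row$age_class,
       origination = row$origination, ambiguous = row$ambiguous_origin)
}

#' Classify recent origin events between two sister species
#'
#' For the given sister pair: conserved families have members in both
#' species; a family present only in one sister is a gain on that sister's
#' terminal branch, or a loss on the other's, according to the inferred
#' history (presence state at the pair's common ancestor). Origins that were
#' detected by only one of the two profiling methods (Trep-only or
#' MFA-only) are dubious and removed from the gained/lost lists together
#' with the implied event.
#'
#' @param families an `origin_families` object.
#' @param history a [infer_gain_loss()] result on the same families.
#' @param speciesA,speciesB sister species (must be sister tips in the
#'   tree).
#' @param detection data.frame `species`, `origin_id`, `codetected`
#'   (logical); `NULL` keeps everything.
#' @return list `conserved`, `gained` (data.frame `family`, `species`,
#'   `origin_id`), `lost` (data.frame `family`, `lost_in`,
#'   `evidence_origin`), and counts before/after the dubious-case filter.
#' @export
classify_recent_events <- function(families, history, speciesA, speciesB,
                                   detection = NULL) {
  tree <- history$tree
  ia <- match(speciesA, tree$tip.label); ib <- match(speciesB, tree$tip.label)
  if (is.na(ia) || is.na(ib)) stop("species not in tree")
  mrca <- ape::getMRCA(tree, c(speciesA, speciesB))
  desc <- tree$edge[tree$edge[, 1] == mrca, 2]
  if (!setequal(desc, c(ia, ib))) stop(speciesA, " and ", speciesB,
                                       " are not sister species")
  fam <- families$families
  phyl <- families$phyletic
  pf <- history$per_family
  inA <- phyl[, speciesA] == 1
  inB <- phyl[, speciesB] == 1
  fam_ids <- rownames(phyl)
  conserved <- fam_ids[inA & inB]
  codet <- function(sp, fid) {
    if (is.null(detection)) return(TRUE)
    ids <- fam$origin_id[fam$family_id == fid & fam$species == sp]
    d <- detection$codetected[detection$species == sp &
                                detection$origin_id %in% ids]
    length(d) > 0 && all(d)
  }
  one_sided <- function(sp_in, sp_out) {
    cand <- fam_ids[phyl[, sp_in] == 1 & phyl[, sp_out] == 0]
    gained <- character(0); lost <- character(0)
    for (fid in cand) {
      branchmat <- history$per_family_branch[[fid]]
      gain_here <- branchmat$gains[branchmat$branch == sp_in]
      loss_there <- branchmat$losses[branchmat$branch == sp_out]
      if (length(gain_here) && gain_here >= 0.5) gained <- c(gained, fid)
      else if (length(loss_there) && loss_there >= 0.5) lost <- c(lost, fid)
    }
    list(gained = gained, lost = lost)
  }
  sideA <- one_sided(speciesA, speciesB)
  sideB <- one_sided(speciesB, speciesA)
  gained <- rbind(
    if (length(sideA$gained)) data.frame(family = sideA$gained, species = speciesA),
    if (length(sideB$gained)) data.frame(family = sideB$gained, species = speciesB))
  lost <- rbind(
    if (length(sideA$lost)) data.frame(family = sideA$lost, lost_in = speciesB,
                                       evidence_species = speciesA),
    if (length(sideB$lost)) data.frame(family = sideB$lost, lost_in = speciesA,
                                       evidence_species = speciesB))
  n_before <- c(conserved = length(conserved),
                gained = if (is.null(gained)) 0L else nrow(gained),
                lost = if (is.null(lost)) 0L else nrow(lost))
  if (!is.null(detection)) {
    if (!is.null(gained) && nrow(gained))
      gained <- gained[mapply(codet, gained$species, gained$family), ,
                       drop = FALSE]
    if (!is.null(lost) && nrow(lost))
      lost <- lost[mapply(codet, lost$evidence_species, lost$family), ,
                   drop = FALSE]
  }
  list(conserved = conserved,
       gained = if (is.null(gained))
         data.frame(family = character(0), species = character(0)) else gained,
       lost = if (is.null(lost))
         data.frame(family = character(0), lost_in = character(0),
                    evidence_species = character(0)) else lost,
       n_before_filter = n_before,
       n_after_filter = c(conserved = length(conserved),
                          gained = if (is.null(gained)) 0L else nrow(gained),
                          lost = if (is.null(lost)) 0L else nrow(lost)))
}
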