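# Shared fixture builders. Everything is generated in code; no data files.

# five origins on one 500 kb chromosome, rates spanning weak to strong
fixture_model <- function() {
  kinetics_model(
    c(chrA = 5e5),
    data.frame(chrom = "chrA",
               pos = c(5e4, 1.5e5, 2.4e5, 3.5e5, 4.4e5),
               rate = c(0.15, 0.05, 0.2, 0.08, 0.12)),
    fork_speed = 2000)
}

# the study sequencing design: S-phase sampled every 5 min, deep coverage
fixture_design <- function(noise = "poisson", depth = 2000) {
  sequencing_design(timepoints = seq(2.5, 67.5, by = 5), depth = depth,
                    noise = noise)
}

# gene scaffold + regularly spaced ancestral origins (mostly intergenic)
fixture_world <- function(n_chrom = 2, genes_per_chrom = 150,
                          origin_spacing = 25000, seed = 1) {
  set.seed(seed)
  gen <- synthetic_genome(n_chrom = n_chrom, genes_per_chrom = genes_per_chrom)
  anc <- do.call(rbind, lapply(names(gen$chrom_lengths), function(ch) {
    pos <- seq(10000, gen$chrom_lengths[[ch]] - 10000, by = origin_spacing)
    data.frame(chrom = ch, pos = round(pos),
               rate = stats::runif(length(pos), 0.05, 0.2))
  }))
  list(genome = gen, ancestral = anc)
}

# eight-species rooted binary tree with Lachancea-like short terminal branches
fixture_tree <- function() {
  ape::read.tree(text = paste0(
    "(((A:0.1,B:0.1):0.2,(C:0.15,D:0.15):0.15):0.2,",
    "((E:0.1,F:0.1):0.25,(G:0.2,H:0.2):0.15):0.15):0.1;"))
}

# per-species origin/gene bundles + all-pairs identity ortholog maps
fixture_species_data <- function(evo) {
  sps <- evo$tree$tip.label
  species_data <- lapply(stats::setNames(nm = sps), function(sp) {
    org <- evo$leaf_origins[evo$leaf_origins$species == sp, ]
    list(origins = data.frame(origin_id = org$id, chrom = org$chrom,
                              pos = org$pos),
         genes = evo$genome$genes)
  })
  orth <- identity_orthologs(evo$genome$genes)
  ol <- list()
  for (i in seq_len(length(sps) - 1)) {
    for (j in seq(i + 1, length(sps))) {
      ol[[paste(sps[i], sps[j], sep = "|")]] <- orth
    }
  }
  list(species_data = species_data, orthologs = ol)
}

# windowed timing profile evaluated from the analytic copy-number inversion
fixture_analytic_profile <- function(model, window_size = 500) {
  win <- genome_windows(model, window_size)
  val <- unlist(lapply(names(model$chrom_lengths), function(ch)
    analytic_trep(model, ch, win$mid[win$chrom == ch])))
  data.frame(win, value = unname(val))
}

# independent families oracle: plain-loop flanking-gene projection on the
# shared identity-ortholog scaffold, nearest-resident association, reciprocal
# delta test, union-find transitive closure. Returns a normalized partition.
families_oracle_partition <- function(species_data, genes, delta = 2) {
  gmid <- sort((genes$start + genes$end) / 2)
  gsort <- genes[order((genes$start + genes$end) / 2), ]
  project_one <- function(pos) {
    kl <- findInterval(pos, gmid)
    if (kl < 1 || kl + 1 > nrow(gsort)) return(NA_real_)
    (gsort$end[kl] + gsort$start[kl + 1]) / 2
  }
  genes_between <- function(p, q) sum(gmid > min(p, q) & gmid < max(p, q))
  half_ok <- function(a_pos, b_set) {
    pj <- project_one(a_pos)
    if (!is.finite(pj)) return(NA_integer_)
    j <- which.min(abs(b_set - pj))
    if (genes_between(pj, b_set[j]) <= delta) j else NA_integer_
  }
  sps <- names(species_data)
  all_org <- do.call(rbind, lapply(sps, function(s)
    cbind(species = s, species_data[[s]]$origins)))
  nodes <- paste(all_org$species, all_org$origin_id)
  parent <- seq_along(nodes)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i1 in seq_len(length(sps) - 1)) for (i2 in seq(i1 + 1, length(sps))) {
    A <- species_data[[sps[i1]]]$origins
    B <- species_data[[sps[i2]]]$origins
    for (i in seq_len(nrow(A))) {
      j <- half_ok(A$pos[i], B$pos)
      if (is.na(j)) next
      if (identical(half_ok(B$pos[j], A$pos), i)) {
        ni <- match(paste(sps[i1], A$origin_id[i]), nodes)
        nj <- match(paste(sps[i2], B$origin_id[j]), nodes)
        parent[find(ni)] <- find(nj)
      }
    }
  }
  comp <- vapply(seq_along(nodes), find, 0L)
  unname(sort(vapply(split(nodes, comp), function(x)
    paste(sort(x), collapse = ";"), "")))
}

normalize_partition <- function(families_df) {
  nodes <- paste(families_df$species, families_df$origin_id)
  unname(sort(vapply(split(nodes, families_df$family_id), function(x)
    paste(sort(x), collapse = ";"), "")))
}

# brute-force weighted parsimony over all internal labelings of a rooted tree
brute_force_parsimony <- function(tree, pattern, gain_cost = 2,
                                  loss_cost = 1) {
  n_tip <- length(tree$tip.label)
  internals <- seq(n_tip + 1, max(tree$edge))
  best <- Inf
  for (mask in 0:(2^length(internals) - 1)) {
    st <- integer(max(tree$edge))
    st[seq_len(n_tip)] <- pattern
    st[internals] <- as.integer(intToBits(mask))[seq_along(internals)]
    cost <- if (st[n_tip + 1] == 1) gain_cost else 0
    p <- st[tree$edge[, 1]]; ch <- st[tree$edge[, 2]]
    cost <- cost + gain_cost * sum(p == 0 & ch == 1) +
      loss_cost * sum(p == 1 & ch == 0)
    if (cost < best) best <- cost
  }
  best
}
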