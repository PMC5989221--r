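test_that("subtelomeric origins outside the first qualifying blocks are excluded", {
  origins <- data.frame(origin_id = sprintf("o%02d", 1:10),
                        chrom = "c1",
                        pos = c(2000, 4000, seq(30000, 170000, by = 20000)))
  blocks <- data.frame(chrom = "c1", start = c(25000, 120000),
                       end = c(100000, 180000), n_genes = c(12, 9),
                       block_id = c("b1", "b2"))
  f <- filter_subtelomeric(origins, blocks, min_block_genes = 5)
  expect_equal(nrow(f$kept), 8)
  expect_setequal(f$excluded$origin_id, c("o01", "o02"))
  # a small block cannot anchor the interstitial region
  blocks$n_genes <- c(3, 9)
  f2 <- filter_subtelomeric(origins, blocks, min_block_genes = 5)
  expect_true(all(f2$kept$pos >= 120000))
  # no qualifying block at all
  blocks$n_genes <- c(3, 4)
  expect_warning(f3 <- filter_subtelomeric(origins, blocks), "qualifying")
  expect_equal(nrow(f3$kept), 0)
})

test_that("origins project through flanking-gene synteny onto the right intergene", {
  gen <- synthetic_genome(n_chrom = 1, genes_per_chrom = 30)
  orth <- identity_orthologs(gen$genes)
  origins <- data.frame(origin_id = "o1", chrom = "chr1", pos = 10250)
  pr <- project_origins(origins, gen$genes, orth)
  expect_true(pr$projectable)
  expect_equal(pr$chromB, "chr1")
  expect_equal(pr$posB, 10250)  # self-projection recovers the intergene
  # chromosome-end origin with a single flank is unprojectable
  edge <- data.frame(origin_id = "o2", chrom = "chr1", pos = 100)
  expect_false(project_origins(edge, gen$genes, orth)$projectable)
  # flanks in different blocks are rejected
  orth2 <- orth
  orth2$block_id[1:5] <- "other"
  mid <- data.frame(origin_id = "o3", chrom = "chr1",
                    pos = gen$genes$end[5] + 100)
  expect_false(project_origins(mid, gen$genes, orth2)$projectable)
})

test_that("the delta rule counts intervening syntenic genes reciprocally", {
  gen <- synthetic_genome(n_chrom = 1, genes_per_chrom = 40)
  orth <- identity_orthologs(gen$genes)
  between <- function(i) (gen$genes$end[i] + gen$genes$start[i + 1]) / 2
  originsA <- data.frame(origin_id = "a1", chrom = "chr1", pos = between(10))
  # resident three intergenes away: 3 syntenic genes in between
  originsB3 <- data.frame(origin_id = "b1", chrom = "chr1",
                          pos = between(13))
  prAB <- project_origins(originsA, gen$genes, orth)
  prBA3 <- project_origins(originsB3, gen$genes, orth)
  expect_equal(nrow(pair_conserved(originsA, originsB3, prAB, prBA3, orth,
                                   delta = 2)), 0)
  originsB1 <- data.frame(origin_id = "b1", chrom = "chr1",
                          pos = between(11))
  prBA1 <- project_origins(originsB1, gen$genes, orth)
  pc <- pair_conserved(originsA, originsB1, prAB, prBA1, orth, delta = 2)
  expect_equal(pc$originA, "a1")
  expect_equal(pc$genes_ab, 1)
  # delta = 0 still accepts same-intergene pairs
  pc0 <- pair_conserved(originsA, originsA, prAB, prAB, orth, delta = 0)
  expect_equal(nrow(pc0), 1)
})

test_that("families are connected components with singletons preserved", {
  pairs <- data.frame(speciesA = c("A", "B"), originA = c("a1", "b1"),
                      speciesB = c("B", "C"), originB = c("b1", "c1"))
  all_org <- data.frame(species = c("A", "B", "C", "C"),
                        origin_id = c("a1", "b1", "c1", "c9"),
                        chrom = "c", pos = c(1, 1, 1, 2) * 1e4)
  fams <- build_families(pairs, all_org)
  grp <- split(paste(fams$families$species, fams$families$origin_id),
               fams$families$family_id)
  sizes <- lengths(grp)
  expect_setequal(sizes, c(3, 1))
  expect_true(any(vapply(grp, function(g)
    setequal(g, c("A a1", "B b1", "C c1")), TRUE)))
  expect_equal(fams$summary$n_singletons, 1)
  expect_equal(unname(fams$phyletic[rowSums(fams$phyletic) == 3, ]),
               c(1L, 1L, 1L))
})

test_that("family construction matches exhaustive pairwise testing plus transitive closure", {
  w <- fixture_world(n_chrom = 1, genes_per_chrom = 120,
                     origin_spacing = 24000, seed = 4)
  tree3 <- ape::read.tree(text = "((A:0.3,B:0.3):0.2,C:0.5):0.1;")
  evo <- evolve_repertoire(tree3, w$ancestral, w$genome, gain_rate = 2,
                           loss_rate = 2, seed = 6)
  sd_ <- fixture_species_data(evo)
  expect_lte(nrow(evo$leaf_origins), 35)
  pairs <- conserved_pairs_all(sd_$species_data, sd_$orthologs, delta = 2)
  all_org <- do.call(rbind, lapply(names(sd_$species_data), function(s)
    cbind(species = s, sd_$species_data[[s]]$origins)))
  fams <- build_families(pairs, all_org)
  expect_setequal(normalize_partition(fams$families),
                  families_oracle_partition(sd_$species_data,
                                            evo$genome$genes))
})

test_that("pair testing one origin at a time cannot differ from batch testing", {
  # guard for the oracle above: batch projection equals per-origin projection
  gen <- synthetic_genome(n_chrom = 1, genes_per_chrom = 50)
  orth <- identity_orthologs(gen$genes)
  origins <- data.frame(origin_id = c("x", "y"), chrom = "chr1",
                        pos = c(20250, 60250))
  batch <- project_origins(origins, gen$genes, orth)
  single <- do.call(rbind, lapply(1:2, function(i)
    project_origins(origins[i, ], gen$genes, orth)))
  expect_equal(batch$posB, single$posB)
})

test_that("randomized origin sets satisfy all three constraints", {
  gen <- synthetic_genome(n_chrom = 2, genes_per_chrom = 100)
  set.seed(3)
  orig <- do.call(rbind, lapply(names(gen$chrom_lengths), function(ch)
    data.frame(chrom = ch,
               pos = round(seq(5000, gen$chrom_lengths[[ch]] - 5000,
                               by = 23000)) +
                 sample(c(0, 1200), 9, replace = TRUE))))
  is_intra <- function(df) vapply(seq_len(nrow(df)), function(i) {
    g <- gen$genes[gen$genes$chrom == df$chrom[i], ]
    any(df$pos[i] >= g$start & df$pos[i] < g$end)
  }, TRUE)
  for (r in 1:20) {
    rnd <- randomize_origins(orig, gen$genes, gen$chrom_lengths, seed = r)
    for (ch in unique(orig$chrom)) {
      expect_equal(sort(diff(sort(rnd$pos[rnd$chrom == ch]))),
                   sort(diff(sort(orig$pos[orig$chrom == ch]))))
      expect_lt(min(rnd$pos[rnd$chrom == ch]),
                2 * min(orig$pos[orig$chrom == ch]))
      expect_gt(min(rnd$pos[rnd$chrom == ch]), 0)
    }
    expect_equal(sum(is_intra(rnd)), sum(is_intra(orig)))
    expect_true(attr(rnd, "quota_exact"))
  }
})

test_that("delta calibration is monotone and separates real from random on conserved repertoires", {
  w <- fixture_world(n_chrom = 1, genes_per_chrom = 120,
                     origin_spacing = 24000, seed = 5)
  tree3 <- ape::read.tree(text = "((A:0.2,B:0.2):0.2,C:0.4):0.1;")
  evo <- evolve_repertoire(tree3, w$ancestral, w$genome, gain_rate = 1,
                           loss_rate = 1, seed = 2)
  sd_ <- fixture_species_data(evo)
  lens <- lapply(stats::setNames(nm = names(sd_$species_data)),
                 function(s) evo$genome$chrom_lengths)
  cal <- calibrate_delta(sd_$species_data, sd_$orthologs, lens,
                         deltas = c(0, 2, 4), n_rand = 3, seed = 1)
  tab <- cal$table
  expect_true(all(diff(tab$real_pairs) >= 0))  # relaxing delta adds pairs
  expect_true(all(tab$real_pairs >= tab$rand_pairs_mean))
  expect_gt(tab$pair_excess[tab$delta == 2], 0)
})
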