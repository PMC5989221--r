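test_that("self-projection with identity orthologs returns resident values", {
  w <- fixture_world(n_chrom = 2, genes_per_chrom = 80)
  m <- kinetics_model(w$genome$chrom_lengths, w$ancestral, 2000)
  prof <- fixture_analytic_profile(m)
  orth <- identity_orthologs(w$genome$genes)
  proj <- project_timing(prof, prof, orth)
  expect_equal(proj$timingA, proj$timingB)
  expect_equal(conservation_rho(proj), 1)
  # dropping orthologs changes the pair count, not survivor values
  sub <- orth[-sample(nrow(orth), round(0.1 * nrow(orth))), ]
  proj2 <- project_timing(prof, prof, sub)
  expect_equal(nrow(proj2), nrow(sub))
  m2 <- merge(proj, proj2, by = "geneA")
  expect_equal(m2$timingA.x, m2$timingA.y)
})

test_that("Spearman rho matches the small worked set and the reversed extreme", {
  proj <- data.frame(timingA = c(1, 2, 3, 1:10),
                     timingB = c(2, 1, 3, 1:10))
  # only the first three pairs informative requires >= 10 pairs; use exact set
  proj3 <- data.frame(timingA = c(1, 2, 3), timingB = c(2, 1, 3))
  expect_error(conservation_rho(proj3), "10")
  expect_equal(stats::cor(proj3$timingA, proj3$timingB, method = "spearman"),
               0.5)
  rev10 <- data.frame(timingA = 1:10, timingB = 10:1)
  expect_equal(conservation_rho(rev10), -1)
})

test_that("the circular-shift null keeps conserved profiles uncorrelated while preserving values", {
  w <- fixture_world(n_chrom = 4, genes_per_chrom = 200,
                     origin_spacing = 26000, seed = 2)
  m <- kinetics_model(w$genome$chrom_lengths, w$ancestral, 2000)
  profA <- fixture_analytic_profile(m)
  set.seed(3)
  profB <- profA
  profB$value <- profB$value + rnorm(nrow(profB), 0, 0.5)
  orth <- identity_orthologs(w$genome$genes)
  obs <- conservation_rho(project_timing(profA, profB, orth))
  expect_gt(obs, 0.9)
  nulls <- offset_null(profA, profB, orth, n_offsets = 25, seed = 4)
  expect_length(nulls, 50)
  expect_lt(stats::median(abs(nulls), na.rm = TRUE), 0.1)
})

test_that("conservation decreases with simulated divergence", {
  w <- fixture_world()
  tree2 <- ape::read.tree(text = "(A:1,B:1):0.1;")
  orth <- identity_orthologs(w$genome$genes)
  rho_at <- function(rate, seed) {
    evo <- evolve_repertoire(tree2, w$ancestral, w$genome, gain_rate = rate,
                             loss_rate = rate, seed = seed)
    mods <- leaf_models(evo)
    profA <- fixture_analytic_profile(mods$A)
    profB <- fixture_analytic_profile(mods$B)
    conservation_rho(project_timing(profA, profB, orth))
  }
  lo <- vapply(1:8, function(s) rho_at(0.5, s), 0)
  hi <- vapply(1:8, function(s) rho_at(6, s), 0)
  expect_gt(mean(lo), mean(hi))
  p <- stats::wilcox.test(lo, hi, alternative = "greater")$p.value
  expect_lt(p, 0.05)
})

test_that("local correlation drops only near corrupted breakpoints", {
  w <- fixture_world(n_chrom = 4, genes_per_chrom = 200,
                     origin_spacing = 26000, seed = 2)
  m <- kinetics_model(w$genome$chrom_lengths, w$ancestral, 2000)
  profA <- fixture_analytic_profile(m)
  orth <- identity_orthologs(w$genome$genes)
  idx <- stats::ave(seq_len(nrow(orth)), orth$chromA, FUN = seq_along)
  orth$block_id <- paste0(orth$chromA, "_b", (idx - 1) %/% 60)
  profB <- profA
  set.seed(7)
  for (bid in unique(orth$block_id)) {
    g <- orth[orth$block_id == bid, ]
    g <- g[order(g$startA), ]
    edge_genes <- rbind(utils::head(g, 5), utils::tail(g, 5))
    for (k in seq_len(nrow(edge_genes))) {
      sel <- profB$chrom == edge_genes$chromB[k] &
        profB$mid >= edge_genes$startB[k] - 250 &
        profB$mid <= edge_genes$endB[k] + 250
      profB$value[sel] <- stats::runif(sum(sel), min(profA$value),
                                       max(profA$value))
    }
  }
  proj <- project_timing(profA, profB, orth)
  lr <- local_rho(proj, window_genes = 5, offset_genes = c(0, 5, 10, 20, 25),
                  seed = 1)
  expect_lt(lr$mean_rho[lr$offset == 0], lr$mean_rho[lr$offset == 25])
  expect_true(all(diff(lr$mean_rho) >= -0.05))  # essentially non-decreasing
  # a perfectly conserved pair scores ~1 in both classes
  lr0 <- local_rho(project_timing(profA, profA, orth),
                   offset_genes = c(0, 25), seed = 1)
  expect_true(all(lr0$mean_rho > 0.99))
})

test_that("orthologous-origin timing differences behave like a folded difference", {
  w <- fixture_world(n_chrom = 2, genes_per_chrom = 200,
                     origin_spacing = 22000, seed = 3)
  m <- kinetics_model(w$genome$chrom_lengths, w$ancestral, 2000)
  prof <- normalize_timing(fixture_analytic_profile(m))
  fam <- do.call(rbind, lapply(c("sp1", "sp2"), function(sp)
    data.frame(family_id = sprintf("f%03d", seq_len(nrow(w$ancestral))),
               species = sp, origin_id = paste0(sp, seq_len(nrow(w$ancestral))),
               chrom = w$ancestral$chrom, pos = w$ancestral$pos)))
  d0 <- ortholog_origin_timing_diff(prof, prof, fam, "sp1", "sp2")
  expect_true(all(d0$differences == 0))
  # independent timing noise sigma on both sides: |diff| is folded normal
  sigma <- 0.08
  set.seed(9)
  profA <- prof; profA$value <- profA$value + rnorm(nrow(prof), 0, sigma)
  profB <- prof; profB$value <- profB$value + rnorm(nrow(prof), 0, sigma)
  dn <- ortholog_origin_timing_diff(profA, profB, fam, "sp1", "sp2")
  theo_median <- stats::qnorm(0.75) * sigma * sqrt(2)
  expect_equal(dn$median, theo_median, tolerance = 0.25)
  # two hand values
  pa <- prof[1:20, ]; pa$value <- 0.1
  pb <- prof[1:20, ]; pb$value <- 0.3
  fam1 <- fam[fam$family_id == "f001", ]
  fam1$chrom <- pa$chrom[1]; fam1$pos <- pa$mid[1]
  d1 <- ortholog_origin_timing_diff(pa, pb, fam1, "sp1", "sp2")
  expect_equal(d1$differences, 0.2)
})
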