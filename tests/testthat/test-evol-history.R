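test_that("phyletic matrix rows reflect family membership", {
  fam <- data.frame(family_id = c("f1", "f1", "f2"),
                    species = c("A", "B", "C"),
                    origin_id = c("a1", "b1", "c1"),
                    chrom = "c", pos = 1:3)
  m <- build_phyletic_matrix(fam, c("A", "B", "C"))
  expect_equal(m["f1", ], c(A = 1L, B = 1L, C = 0L))
  expect_equal(sum(m["f2", ]), 1L)
  expect_error(build_phyletic_matrix(fam, c("A", "B", "C", "D")), "absent")
})

test_that("small parsimony places the textbook events", {
  tree <- ape::read.tree(text = "(((A:1,B:1):1,C:2):1,D:3):0.5;")
  m <- rbind(clade = c(A = 1, B = 1, C = 0, D = 0),
             ubiquitous = c(A = 1, B = 1, C = 1, D = 1),
             private = c(A = 1, B = 0, C = 0, D = 0))
  h <- infer_gain_loss(m, tree)
  pf <- h$per_family
  # one gain on the (A,B) stem, nothing else, total cost 2
  expect_equal(pf$cost[pf$family == "clade"], 2)
  stem_ab <- h$per_family_branch$clade
  expect_equal(sum(stem_ab$gains), 1)
  expect_equal(sum(stem_ab$losses), 0)
  # present everywhere: ancestral, no branch events
  expect_equal(pf$origination[pf$family == "ubiquitous"], "ancestral")
  expect_equal(sum(h$per_family_branch$ubiquitous$gains), 0)
  # private family: single terminal gain
  expect_equal(pf$origination[pf$family == "private"], "A")
  expect_equal(pf$cost[pf$family == "private"], 2)
  expect_error(infer_gain_loss(rbind(none = c(A = 0, B = 0, C = 0, D = 0)),
                               tree), "all-zero")
})

test_that("dynamic-programming cost equals brute force for every pattern on a six-leaf tree", {
  tree <- ape::read.tree(
    text = "(((A:1,B:2):1,(C:1,D:1):2):1,(E:2,F:1):1):0.3;")
  for (code in 1:63) {
    pattern <- as.integer(intToBits(code))[1:6]
    m <- matrix(pattern, nrow = 1,
                dimnames = list("f", tree$tip.label))
    h <- infer_gain_loss(m, tree)
    expect_equal(h$per_family$cost,
                 brute_force_parsimony(tree, pattern),
                 info = paste("pattern", code))
  }
})

test_that("tie averaging distributes events and replay holds for unique labelings", {
  tree <- ape::read.tree(text = "(((A:1,B:1):1,C:2):1,D:3):0.5;")
  m <- rbind(f = c(A = 1, B = 1, C = 0, D = 0))
  h <- infer_gain_loss(m, tree)
  # unique optimum: replay root state + events along each path
  expect_equal(h$per_family$n_labelings, 1)
  bm <- h$per_family_branch$f
  replayed <- vapply(tree$tip.label, function(sp) {
    node <- match(sp, tree$tip.label)
    path <- character(0)
    while (node != length(tree$tip.label) + 1) {
      e <- which(tree$edge[, 2] == node)
      path <- c(bm$branch[e], path)
      node <- tree$edge[e, 1]
    }
    s <- 0  # root absent for this family
    for (b in path) {
      s <- s + bm$gains[bm$branch == b] - bm$losses[bm$branch == b]
    }
    s
  }, 0)
  expect_equal(unname(replayed), unname(m[1, tree$tip.label]))
})

test_that("branches can be excluded as indistinguishable and ages measure from the focal ancestor", {
  tree <- ape::read.tree(
    text = "((((A:1,B:1)nAB:1,C:2)nABC:1,D:3)nIN:1,OUT:4)r;")
  m <- rbind(anc = c(A = 1, B = 1, C = 1, D = 1, OUT = 0),
             young = c(A = 1, B = 1, C = 0, D = 0, OUT = 0),
             out_only = c(A = 0, B = 0, C = 0, D = 0, OUT = 1))
  h <- infer_gain_loss(m, tree, exclude_branches = c("OUT", "nIN"))
  # events on OUT and its sister branch are tallied apart
  expect_true(all(h$branch_events$gains[h$branch_events$excluded] == 0))
  expect_gt(sum(h$excluded_events), 0)
  pf <- h$per_family
  # focal ancestor defaults to the ingroup MRCA: the 'anc' family has age 0
  expect_equal(pf$age[pf$family == "anc"], 0)
  expect_equal(pf$age_class[pf$family == "anc"], "ancestral")
  # gain on nAB, whose start (nABC) sits one branch length below nIN
  expect_equal(pf$origination[pf$family == "young"], "nAB")
  expect_equal(pf$age[pf$family == "young"], 1)
})

test_that("recent events between sisters are classified and dubious cases filtered", {
  tree <- ape::read.tree(text = "(((A:1,B:1):1,C:2):1,D:3):0.5;")
  fam <- data.frame(
    family_id = c("c1", "c1", "c1", "c1", "g1", "l1", "l1", "g2"),
    species   = c("A",  "B",  "C",  "D",  "A",  "B",  "C",  "B"),
    origin_id = c("oa1", "ob1", "oc1", "od1", "oa2", "ob2", "oc2", "ob3"),
    chrom = "c", pos = c(1, 1, 1, 1, 2, 3, 3, 4) * 1e4)
  fams <- structure(list(families = fam,
                         phyletic = build_phyletic_matrix(fam,
                                                          tree$tip.label)),
                    class = "origin_families")
  h <- infer_gain_loss(fams$phyletic, tree)
  cls <- classify_recent_events(fams, h, "A", "B")
  expect_equal(cls$conserved, "c1")
  expect_setequal(cls$gained$family, c("g1", "g2"))
  expect_equal(cls$lost$family, "l1")       # present in B + outgroup context
  expect_equal(cls$lost$lost_in, "A")
  expect_error(classify_recent_events(fams, h, "A", "C"), "not sister")
  # dubious-case filter: the evidence origin must be co-detected
  det <- data.frame(species = c("A", "B", "B"),
                    origin_id = c("oa2", "ob2", "ob3"),
                    codetected = c(FALSE, TRUE, TRUE))
  cls2 <- classify_recent_events(fams, h, "A", "B", detection = det)
  expect_false("g1" %in% cls2$gained$family)  # oa2 single-method
  expect_true("g2" %in% cls2$gained$family)
  expect_equal(cls2$lost$family, "l1")
})
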