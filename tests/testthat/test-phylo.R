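test_that("p-distance counts mismatches over gap-free columns only", {
  expect_equal(p_distance("ACGT", "ACGA"), 0.25)
  expect_equal(p_distance("ACGT", "ACGT"), 0)
  expect_equal(p_distance("AC-T", "ACG-"), 0)   # two comparable columns
  expect_error(p_distance("--", "AA"), "comparable")
  expect_error(p_distance("AC", "ACG"), "length")
})

test_that("NJ recovers the additive 4-taxon example exactly", {
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- nj_tree(D)
  # topology: split AB|CD
  expect_true(ape::is.monophyletic(ape::root(tr, "C"), c("A", "B")))
  # exact branch lengths: path distances reproduce D
  expect_equal(ape::cophenetic.phylo(tr)[rownames(D), colnames(D)], D)
})

test_that("NJ on 3 taxa uses the closed-form star resolution", {
  D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(D)
  expect_equal(ape::Ntip(tr), 3)
  expect_equal(ape::cophenetic.phylo(tr)[rownames(D), colnames(D)], D)
  expect_error(nj_tree(D[1:2, 1:2]), "at least 3")
})

test_that("NJ recovers random additive trees; ape::nj agrees as cross-check", {
  set.seed(21)
  for (rep in 1:25) {
    n <- sample(5:8, 1)
    gen <- ape::rtree(n, tip.label = paste0("t", 1:n))
    gen$edge.length <- stats::runif(nrow(gen$edge), 0.05, 1)
    D <- ape::cophenetic.phylo(gen)
    D <- D[sort(rownames(D)), sort(colnames(D))]
    tr <- nj_tree(D)
    expect_equal(ape::cophenetic.phylo(tr)[rownames(D), colnames(D)], D,
                 tolerance = 1e-8)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(gen), tr)), 0)
    # independent oracle: ape's own NJ gives the same topology
    expect_equal(as.numeric(ape::dist.topo(ape::nj(D), tr)), 0)
  }
})

test_that("non-additive input clamps negative branch lengths with a warning", {
  D <- matrix(c(0, 2, 3, 4,
                2, 0, 1, 5,
                3, 1, 0, 2,
                4, 5, 2, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  expect_warning(tr <- nj_tree(D), "clamped")
  expect_true(all(tr$edge.length >= 0))
})

test_that("Dollo places the euteleost intron gain with zero losses", {
  tree <- fish_species_tree()
  gained <- c("medaka", "fugu", "stickleback", "tilapia", "platyfish",
              "cod", "molly")
  pres <- stats::setNames(rep(0, ape::Ntip(tree)), tree$tip.label)
  pres[gained] <- 1
  ev <- dollo_events(tree, pres)
  expect_setequal(ev$gain_clade, gained)
  expect_equal(ev$n_losses, 0)
  # the gain branch is the euteleost stem
  lab <- c(tree$tip.label, tree$node.label)
  expect_equal(lab[ev$gain_node], "Euteleostei")
  # and it dates to the printed window
  expect_equal(unname(date_event(tree, ev$gain_node)), c(190, 231))
})

test_that("Dollo boundary cases: single leaf, all present, all absent, unknowns", {
  tree <- fish_species_tree()
  one <- stats::setNames(rep(0, 11), tree$tip.label); one["medaka"] <- 1
  ev1 <- dollo_events(tree, one)
  expect_equal(ev1$gain_clade, "medaka")
  expect_equal(ev1$n_losses, 0)

  all1 <- stats::setNames(rep(1, 11), tree$tip.label)
  evA <- dollo_events(tree, all1)
  expect_equal(evA$gain_node, ape::Ntip(tree) + 1L)  # root branch

  all0 <- stats::setNames(rep(0, 11), tree$tip.label)
  ev0 <- dollo_events(tree, all0)
  expect_true(is.na(ev0$gain_node))
  expect_equal(ev0$n_losses, 0)

  # an unknown-only subtree never forces a loss
  unk <- stats::setNames(rep(1, 11), tree$tip.label)
  unk[c("zebrafish", "cavefish")] <- NA
  evU <- dollo_events(tree, unk)
  expect_equal(evU$n_losses, 0)
  # but a scored-absent clade inside the gain clade does
  lost <- stats::setNames(rep(1, 11), tree$tip.label)
  lost[c("zebrafish", "cavefish")] <- 0
  evL <- dollo_events(tree, lost)
  expect_equal(evL$n_losses, 1)
  expect_setequal(evL$loss_clades[[1]], c("zebrafish", "cavefish"))
})

test_that("Dollo equals the exhaustive-enumeration oracle on random trees", {
  set.seed(14)
  for (rep in 1:20) {
    n <- sample(5:12, 1)
    tree <- ape::rtree(n, tip.label = paste0("s", 1:n))
    pres <- stats::setNames(sample(c(0, 0, 1, 1, NA), n, replace = TRUE),
                            tree$tip.label)
    if (!any(!is.na(pres) & pres == 1)) pres[1] <- 1
    ev <- dollo_events(tree, pres)
    or <- dollo_oracle(tree, pres)
    expect_equal(ev$n_losses, or$min_losses)
    # scenario consistency: gain covers the present leaves, losses cover
    # every absent leaf below the gain
    below_gain <- ev$gain_clade
    absent <- names(pres)[!is.na(pres) & pres == 0]
    lost_leaves <- unlist(ev$loss_clades)
    expect_true(all(setdiff(absent, setdiff(absent, below_gain)) %in% lost_leaves))
    expect_false(any(names(pres)[!is.na(pres) & pres == 1] %in% lost_leaves))
  }
})

test_that("species-overlap flags duplication nodes and nothing else", {
  gt <- ape::read.tree(text = "((g1@Dre:1,g1@Ola:1):1,(g2@Dre:1,g2@Ola:1):1);")
  d <- duplication_nodes(gt)
  expect_equal(length(d), 1)
  expect_equal(unclass(d)[1], ape::Ntip(gt) + 1L)   # the root

  single <- ape::read.tree(text = "((a@sp1:1,a@sp2:1):1,a@sp3:1);")
  expect_equal(length(duplication_nodes(single)), 0)

  # three paralog clades joined by two duplication nodes
  gt3 <- ape::read.tree(text = paste0(
    "(((g1@Dre:1,g1@Ola:1):1,(g2@Dre:1,g2@Ola:1):1):1,",
    "(g3@Dre:1,g3@Ola:1):2);"))
  d3 <- duplication_nodes(gt3)
  expect_equal(length(d3), 2)

  untagged <- ape::read.tree(text = "((a:1,b:1):1,c:1);")
  expect_error(duplication_nodes(untagged), "species")
})

test_that("event dating brackets a branch by its child and parent ages", {
  tree <- fish_species_tree()
  lab <- c(tree$tip.label, tree$node.label)
  actino <- which(lab == "Actinopterygii")
  expect_equal(unname(date_event(tree, actino)), c(360, 416))
  expect_equal(format_age_interval(date_event(tree, actino)), "416–360 MYA")
  eutel <- which(lab == "Euteleostei")
  expect_equal(format_age_interval(date_event(tree, eutel)), "231–190 MYA")
  # zero-length branch gives a degenerate interval
  tz <- ape::read.tree(text = "((a:1,b:1):0,(c:1,d:1):0);")
  nd <- ape::getMRCA(tz, c("a", "b"))
  expect_equal(diff(unname(date_event(tz, nd))), 0)
  expect_error(date_event(ape::rtree(4), 5), "ultrametric")
})
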