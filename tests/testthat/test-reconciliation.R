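# Outgroup rooting, LCA mapping, duplication-loss counting, NJ helper.

SPTREE2 <- ape::read.tree(text = "(A:1,B:1)R;")
SPTREE3 <- ape::read.tree(text = "((A:1,B:1)AB:1,Out:2)Root;")

test_that("outgroup rooting places the root on the outgroup edge", {
  unr <- ape::unroot(ape::read.tree(text = "((a,b),c);"))
  rooted <- root_with_outgroup(unr, "c")
  expect_true(ape::is.rooted(rooted))
  kids <- toxdiverge:::phylo_children(rooted)[[toxdiverge:::phylo_root(rooted)]]
  tipsets <- lapply(kids, function(k)
    if (k <= 3) rooted$tip.label[k] else ape::extract.clade(rooted, k)$tip.label)
  expect_true(any(vapply(tipsets, function(s) identical(s, "c"), logical(1))))
  # idempotent
  again <- root_with_outgroup(rooted, "c")
  expect_true(ape::all.equal.phylo(again, rooted, use.edge.length = FALSE))
  expect_error(root_with_outgroup(unr, "zzz"), "absent")
})

test_that("rooting fails when the outgroup is not separable", {
  tr <- ape::unroot(ape::read.tree(text = "((a,x),(b,y));"))
  expect_error(root_with_outgroup(tr, c("x", "y")), "not separable")
})

test_that("LCA mapping matches the definition on known cases", {
  g <- ape::read.tree(text = "(a1,(a2,b1));")
  M <- lca_map(g, SPTREE2, c(a1 = "A", a2 = "A", b1 = "B"))
  root_s <- toxdiverge:::phylo_root(SPTREE2)
  expect_equal(M[4], root_s)  # gene root -> species root
  expect_equal(M[5], root_s)  # (a2,b1) -> species root
  # congruent tree: natural isomorphism
  gc <- ape::read.tree(text = "((a1:1,b1:1):1,o1:2);")
  Mc <- lca_map(gc, SPTREE3, c(a1 = "A", b1 = "B", o1 = "Out"))
  expect_equal(Mc[1:3], match(c("A", "B", "Out"), SPTREE3$tip.label))
  expect_equal(Mc[4], toxdiverge:::phylo_root(SPTREE3))
  # single-leaf gene tree maps to its species leaf
  g1 <- ape::read.tree(text = "(only:1);")
  M1 <- lca_map(g1, SPTREE3, c(only = "B"))
  expect_equal(M1[1], match("B", SPTREE3$tip.label))
  expect_error(lca_map(g, SPTREE2, c(a1 = "A", a2 = "A")), "without a species")
})

test_that("event counts match the canonical hand-worked reconciliations", {
  # congruent one-copy-per-species tree: no events
  gc <- ape::read.tree(text = "((a1:1,b1:1):1,o1:2);")
  rc <- reconcile(gc, SPTREE3, c(a1 = "A", b1 = "B", o1 = "Out"))
  expect_equal(rc$duplications, 0)
  expect_equal(rc$losses, 0)
  # root duplication with both sublineages retained
  g2 <- ape::read.tree(text = "((a1,b1),(a2,b2));")
  r2 <- reconcile(g2, SPTREE2, c(a1 = "A", b1 = "B", a2 = "A", b2 = "B"))
  expect_equal(r2$duplications, 1)
  expect_equal(r2$losses, 0)
  # duplication plus a loss in the B lineage
  g3 <- ape::read.tree(text = "(a1,(a2,b1));")
  r3 <- reconcile(g3, SPTREE2, c(a1 = "A", a2 = "A", b1 = "B"))
  expect_equal(r3$duplications, 1)
  expect_equal(r3$losses, 1)
  expect_equal(r3$loss_branches$species_branch, "B")
  expect_equal(glance(r3)$duplications, 1)
})

test_that("LCA reconciliation attains the brute-force minimum D + L", {
  set.seed(61)
  for (i in 1:40) {
    gt <- random_gene_tree(sample(3:7, 1))
    rec <- reconcile(gt$tree, SPTREE3, gt$map)
    expect_equal(rec$duplications + rec$losses,
                 oracle_min_reconciliation(gt$tree, SPTREE3, gt$map),
                 info = paste("case", i))
  }
})

test_that("duplication counts are invariant to consistent species relabeling", {
  set.seed(62)
  gt <- random_gene_tree(6)
  swapped <- ape::read.tree(text = "((B:1,A:1)AB:1,Out:2)Root;")
  r1 <- reconcile(gt$tree, SPTREE3, gt$map)
  r2 <- reconcile(gt$tree, swapped, gt$map)
  expect_equal(r1$duplications, r2$duplications)
  expect_equal(r1$losses, r2$losses)
})

test_that("true simulated event counts are recovered on loss-free histories", {
  cfg <- sim_config()
  stree <- ape::read.tree(text = cfg$species_tree)
  set.seed(63)
  checked_lossfree <- 0
  for (i in 1:40) {
    fam <- simulate_gene_family(cfg, list(birth = 8, death = 3, omega = 0.8),
                                name = "F")
    if (length(fam$tree$tip.label) < 2) next
    rec <- reconcile(fam$tree, stree,
                     stats::setNames(unname(fam$leaf_species),
                                     names(fam$leaf_species)))
    D_true <- sum(fam$true_events$duplications)
    L_true <- sum(fam$true_events$losses)
    # parsimony can never infer more events than actually happened
    expect_lte(rec$duplications, D_true)
    expect_lte(rec$losses, L_true)
    if (L_true == 0) {
      checked_lossfree <- checked_lossfree + 1
      expect_equal(rec$duplications, D_true)
    }
  }
  expect_gte(checked_lossfree, 3)
})

test_that("neighbor joining recovers additive trees and validates input", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):1);")
  d <- ape::cophenetic.phylo(tr)
  nj <- nj_tree(d)
  expect_equal(ape::dist.topo(ape::unroot(tr), nj), structure(0, names = "PH85"),
               ignore_attr = TRUE)
  # permuting taxa gives an isomorphic tree
  perm <- sample(rownames(d))
  nj2 <- nj_tree(d[perm, perm])
  expect_equal(ape::dist.topo(nj, nj2), structure(0, names = "PH85"),
               ignore_attr = TRUE)
  bad <- d; bad[1, 2] <- 99
  expect_error(nj_tree(bad), "symmetric")
  expect_error(nj_tree(d[1:2, 1:2]), "n >= 3")
})
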