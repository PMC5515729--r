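fake_sites <- function(p) {
  data.frame(molecule_id = "m", atom_index = seq_along(p),
             element = rep("C", length(p)), m = 1L, n = 1L, x = 0L,
             r = p, p = p, category = "likely",
             rank = metsite:::rank_sites(p, seq_along(p)),
             stringsAsFactors = FALSE)
}

chain_mol <- function(n) {
  parse_smiles(paste(rep("C", n), collapse = ""))[[1]]
}

test_that("top-k accuracy counts molecules with a hit in the top ranks", {
  mols <- list(m1 = chain_mol(5), m2 = chain_mol(5))
  preds <- list(m1 = fake_sites(c(0.9, 0.5, 0.1, 0, 0)),
                m2 = fake_sites(c(0.1, 0.2, 0.9, 0.05, 0)))
  truth <- list(m1 = 1L, m2 = 1L)
  expect_equal(topk_som_accuracy(preds, truth, 1, mols), 0.5)
  truth2 <- list(m1 = 1L, m2 = 2L)
  expect_equal(topk_som_accuracy(preds, truth2, 3, mols), 1.0)
  # rank-3 truth: top-1 and top-2 miss, top-3 hits
  truth3 <- list(m1 = 3L)
  p1 <- preds["m1"]
  expect_equal(topk_som_accuracy(p1, truth3, 1, mols), 0)
  expect_equal(topk_som_accuracy(p1, truth3, 2, mols), 0)
  expect_equal(topk_som_accuracy(p1, truth3, 3, mols), 1)
  # accuracy is non-decreasing in k
  accs <- vapply(1:5, function(k)
    topk_som_accuracy(preds, truth, k, mols), 1)
  expect_true(all(diff(accs) >= 0))
})

test_that("missing predictions count as misses with a warning", {
  mols <- list(m1 = chain_mol(4))
  truth <- list(m1 = 1L, m2 = 2L)
  preds <- list(m1 = fake_sites(c(1, 0, 0, 0)))
  expect_warning(acc <- topk_som_accuracy(preds, truth, 1, mols), "miss")
  expect_equal(acc, 0.5)
})

test_that("symmetry-aware credit accepts automorphic counterparts", {
  mol <- parse_smiles("COc1ccccc1")[[1]]   # ortho pair equivalent
  eq <- metsite:::atom_equiv_classes(mol)
  pair <- which(eq == eq[4])               # an ortho carbon pair
  expect_length(pair, 2)
  p <- rep(0, mol$n); p[pair[1]] <- 1
  preds <- list(m = fake_sites(p))
  truth <- list(m = pair[2])               # truth names the other one
  expect_equal(topk_som_accuracy(preds, truth, 1, list(m = mol)), 1)
})

test_that("AUC equals the exhaustive pair-counting oracle", {
  scores <- c(0.9, 0.8, 0.8, 0.4, 0.2, 0.0)
  labels <- c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE)
  got <- metsite:::.auc_mw(scores, labels)
  expect_equal(got, pair_count_auc(scores, labels))
  set.seed(8)
  for (i in 1:20) {
    s <- round(runif(10), 2)
    l <- runif(10) > 0.6
    if (!any(l) || all(l)) next
    expect_equal(metsite:::.auc_mw(s, l), pair_count_auc(s, l))
  }
})

test_that("AUC summary pools atoms and screens one-class molecules", {
  mols <- list(m1 = chain_mol(4), m2 = chain_mol(4))
  preds <- list(m1 = fake_sites(c(1, 0.2, 0.1, 0)),
                m2 = fake_sites(c(0, 0, 0, 0)))
  truth <- list(m1 = 1L)   # m2 all-negative
  expect_message(auc <- auc_metrics(preds, truth), "one-class")
  expect_equal(auc$n_molecules, 1)
  expect_equal(auc$mean, 1.0)
  expect_error(suppressMessages(
    auc_metrics(preds["m2"], list())), "one class")
  # perfect separation
  expect_equal(auc$overall,
               pair_count_auc(c(1, 0.2, 0.1, 0, 0, 0, 0, 0),
                              c(TRUE, rep(FALSE, 7))))
})

test_that("pooled AUC is invariant under monotone score rescaling", {
  preds1 <- list(m = fake_sites(c(0.9, 0.5, 0.2, 0.1, 0)))
  preds2 <- list(m = fake_sites(sqrt(c(0.9, 0.5, 0.2, 0.1, 0))))
  truth <- list(m = c(1L, 3L))
  a1 <- auc_metrics(preds1, truth)
  a2 <- auc_metrics(preds2, truth)
  expect_equal(a1$overall, a2$overall)
})

test_that("metabolite precision/recall/F1 match the worked arithmetic", {
  pred <- list(m = data.frame(
    product_smiles = c("CCO", "CCC", "CCN"), rank = 1:3,
    stringsAsFactors = FALSE))
  truth <- list(m = c("CCO", "CCCCO"))
  res <- metabolite_prf(pred, truth, k = 3)
  expect_equal(res$recall, 0.5)
  expect_equal(res$precision, 1 / 3)
  expect_equal(res$f1, 0.4)
  expect_equal(res$fp_count, 2)
  # empty predictions
  res0 <- metabolite_prf(list(m = NULL), truth, k = 3)
  expect_equal(res0$recall, 0)
  expect_equal(res0$precision, 0)
  expect_equal(res0$f1, 0)
  expect_equal(res0$fp_count, 0)
  # molecules without experimental metabolites warn and count nothing
  expect_warning(metabolite_prf(pred, list(m = character(0)), 1),
                 "excluded from recall")
})

test_that("metabolite identity ignores stereochemistry", {
  pred <- list(m = data.frame(product_smiles = "C[C@H](O)CC", rank = 1L,
                              stringsAsFactors = FALSE))
  truth <- list(m = "CC(O)CC")
  res <- metabolite_prf(pred, truth, 1)
  expect_equal(res$recall, 1)
})

test_that("the depth sweep reruns prediction per exact-match depth", {
  db <- fx_db()
  bench <- fx_benchmark()
  mols <- bench$mols[1:3]
  truth <- bench$truth[1:3]
  sweep <- depth_sweep(mols, truth, db, depths = c(3, 6))
  expect_equal(nrow(sweep), 2 * 3)
  # depth 3 equals the default pipeline
  for (id in names(mols)) {
    s <- predict_sites(mols[[id]], db)
    lab <- s$atom_index %in% truth[[id]]
    expect_equal(sweep$auc[sweep$depth == 3 & sweep$molecule_id == id],
                 metsite:::.auc_mw(s$p, lab))
  }
  # deeper exact matching retrieves at most as many molecules with hits
  expect_lte(sum(sweep$any_hit[sweep$depth == 6]),
             sum(sweep$any_hit[sweep$depth == 3]))
})

test_that("the analytic random baseline matches closed-form cases", {
  mol <- chain_mol(10)   # 10 atoms, equivalence collapses chain symmetry
  eq <- metsite:::atom_equiv_classes(mol)
  truth <- list(m = 1L)
  s <- sum(eq %in% eq[1])
  want <- 1 - choose(10 - s, 3) / choose(10, 3)
  expect_equal(random_topk_baseline(truth, list(m = mol), 3), want)
  expect_equal(random_topk_baseline(list(m = 1L),
                                    list(m = chain_mol(2)), 3), 1)
})
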