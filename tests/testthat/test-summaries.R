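toy_cmap <- function() {
  continent_map(cluster = c("Yoruba", "Mandenka", "Spain", "Britain",
                            "China"),
                region = c("WAfrica", "Senegambia", "SWEurope", "NWEurope",
                           "EAsia"),
                continent = c("Africa", "Africa", "Europe", "Europe",
                              "Asia/America"))
}

test_that("continental aggregation sums member clusters and conserves mass", {
  cmap <- toy_cmap()
  sols <- list(
    pA = c(Yoruba = 0.3, Mandenka = 0.2, Spain = 0.5, Britain = 0,
           China = 0),
    pB = c(Yoruba = 0.1, Mandenka = 0.0, Spain = 0.2, Britain = 0.3,
           China = 0.4))
  agg <- continental_aggregate(sols, cmap)
  expect_equal(agg["pA", "Africa"], 0.5)
  expect_equal(agg["pA", "Europe"], 0.5)
  expect_equal(agg["pB", "Asia/America"], 0.4)
  expect_lt(max(abs(rowSums(agg) - 1)), 1e-8)
  # everything on one continent
  sols1 <- list(p = c(Yoruba = 0.6, Mandenka = 0.4, Spain = 0, Britain = 0,
                      China = 0))
  expect_equal(unname(continental_aggregate(sols1, cmap)[, "Africa"]), 1)
  # unmapped cluster with positive weight errors by name
  sols2 <- list(p = c(Yoruba = 0.5, Mystery = 0.5))
  expect_error(continental_aggregate(sols2, toy_cmap()), "Mystery")
})

test_that("relative composition renormalizes and applies the exclusion rule", {
  cmap <- toy_cmap()
  sols <- list(
    keepme = c(Yoruba = 0.09, Mandenka = 0.01, Spain = 0.9, Britain = 0,
               China = 0),
    dropme = c(Yoruba = 0, Mandenka = 0, Spain = 0.5, Britain = 0.5,
               China = 0))
  rel <- relative_composition(sols, cmap, "Africa", min_total = 0.01)
  expect_equal(rownames(rel$proportions), "keepme")
  expect_equal(unname(rel$proportions["keepme", c("Yoruba", "Mandenka")]),
               c(0.9, 0.1))
  expect_named(rel$excluded, "dropme")
  # min_total = 0 keeps everything with any mass; a population with exactly
  # zero is still excluded (0 < 0 is false, but renormalizing 0 is undefined)
  rel0 <- relative_composition(sols["keepme"], cmap, "Africa", min_total = 0)
  expect_equal(nrow(rel0$proportions), 1)
  expect_lt(max(abs(rowSums(rel$proportions) - 1)), 1e-8)
  # region-level aggregation also conserves mass
  relr <- relative_composition(sols, cmap, "Europe", by = "region")
  expect_lt(max(abs(rowSums(relr$proportions) - 1)), 1e-8)
})

test_that("Ward trees are deterministic and match the Lance-Williams update", {
  m <- rbind(p1 = c(1, 0, 0), p2 = c(1, 0.02, 0), p3 = c(0, 1, 0),
             p4 = c(0, 0, 1))
  tr <- ward_tree(m)
  expect_s3_class(tr, "phylo")
  # hand-computed ward.D2 linkage via the Lance-Williams recurrence
  lw_ward <- function(m) {
    d2 <- as.matrix(dist(m))^2 # squared Euclidean
    n <- nrow(d2); sizes <- rep(1, n); active <- seq_len(n)
    heights <- numeric(0)
    while (length(active) > 1) {
      best <- c(NA, NA); bd <- Inf
      for (i in active) for (j in active) if (i < j && d2[i, j] < bd) {
        bd <- d2[i, j]; best <- c(i, j)
      }
      i <- best[1]; j <- best[2]
      heights <- c(heights, sqrt(bd))
      for (k in setdiff(active, c(i, j))) {
        ni <- sizes[i]; nj <- sizes[j]; nk <- sizes[k]
        d2[i, k] <- d2[k, i] <-
          ((ni + nk) * d2[i, k] + (nj + nk) * d2[j, k] - nk * bd) /
          (ni + nj + nk)
      }
      sizes[i] <- sizes[i] + sizes[j]
      active <- setdiff(active, j)
    }
    heights
  }
  expect_equal(attr(tr, "heights"), lw_ward(m), tolerance = 1e-10)
  # two identical vectors merge first
  pp <- ape::prop.part(tr)
  clades <- lapply(pp, function(ix) sort(attr(pp, "labels")[ix]))
  expect_true(any(vapply(clades, identical, TRUE, y = c("p1", "p2"))))
  # two populations: a single merge
  tr2 <- ward_tree(m[1:2, ])
  expect_equal(sort(tr2$tip.label), c("p1", "p2"))
  expect_error(ward_tree(m[1, , drop = FALSE]), ">= 2")
})

test_that("bootstrap of a single-member population returns the original", {
  groups <- c("A", "B")
  a <- array(0, dim = c(3, 2, 1),
             dimnames = list(paste0("c", 1:3), groups, "solo"))
  a[, "A", 1] <- c(10, 20, 30); a[, "B", 1] <- c(30, 20, 10)
  ps <- structure(list(sites = a, morgans = a, chunks = a,
                       loglik = matrix(0, 3, 1,
                                       dimnames = list(paste0("c", 1:3),
                                                       "solo")),
                       targets = "solo",
                       groups = groups, chroms = paste0("c", 1:3),
                       params = copying_model_params()),
                  class = "painting_set")
  reps <- bootstrap_populations(ps, n_reps = 20, seed = 1)
  obs <- copying_vectors(ps)["solo", ]
  for (r in 1:20) expect_equal(unname(reps[r, ]), unname(obs))
  # determinism
  sc <- small_scenario(seed = 121, n_recipients = 5)
  psr <- paint_panel(sc$panel, params = copying_model_params(ne = 50,
                                                             theta = 0.01))
  r1 <- bootstrap_populations(psr, 10, seed = 7)
  r2 <- bootstrap_populations(psr, 10, seed = 7)
  expect_identical(r1, r2)
  expect_false(identical(r1, bootstrap_populations(psr, 10, seed = 8)))
})

test_that("bootstrap replicate means agree with the observed vector", {
  sc <- small_scenario(seed = 131, n_recipients = 8)
  ps <- paint_panel(sc$panel, params = copying_model_params(ne = 50,
                                                            theta = 0.01))
  reps <- bootstrap_populations(ps, 400, seed = 9)
  obs <- colMeans(copying_vectors(ps))
  obs <- obs / sum(obs)
  bse <- apply(reps, 2, sd)
  for (g in colnames(reps))
    expect_lt(abs(mean(reps[, g]) - obs[g]), 3 * max(bse[g], 1e-4))
})

test_that("consensus retention is strictly greater than the threshold", {
  t_ab <- ape::read.tree(text = "((a,b),(c,d));")
  t_ac <- ape::read.tree(text = "((a,c),(b,d));")
  # clade {a,b} (and {c,d}) in exactly 800 of 1000 trees
  trees <- c(rep(list(t_ab), 800), rep(list(t_ac), 200))
  cons <- consensus_tree(trees, threshold = 0.8)
  expect_true(is.na(clade_support(cons, c("a", "b"))))   # 0.8 is not > 0.8
  cons79 <- consensus_tree(trees, threshold = 0.79)
  expect_equal(clade_support(cons79, c("a", "b")), 0.8)
  # 1000 identical trees reproduce the input topology with full support
  all_same <- rep(list(t_ab), 1000)
  cs <- consensus_tree(all_same, threshold = 0.8)
  expect_equal(suppressWarnings(ape::dist.topo(cs$tree, t_ab))[1], 0)
  expect_true(all(cs$support == 1))
})

test_that("consensus matches a hand bipartition tally on five small trees", {
  trees <- lapply(c("((a,b),(c,d));", "((a,b),(c,d));", "((a,b),(c,d));",
                    "((a,c),(b,d));", "(((a,b),c),d);"), function(s)
                      ape::read.tree(text = s))
  # hand tally of non-trivial rooted clades:
  # {a,b}: trees 1,2,3,5 -> 4/5; {c,d}: 1,2,3 -> 3/5; {a,c},{b,d}: 1/5;
  # {a,b,c}: 1/5
  cons <- consensus_tree(trees, threshold = 0.5)
  expect_equal(clade_support(cons, c("a", "b")), 0.8)
  expect_equal(clade_support(cons, c("c", "d")), 0.6)
  expect_true(is.na(clade_support(cons, c("a", "c"))))
  expect_true(is.na(clade_support(cons, c("a", "b", "c"))))
  expect_error(consensus_tree(list(t1 = trees[[1]],
                                   t2 = ape::read.tree(text = "((a,b),(c,e));")),
                              threshold = 0.8),
               "leaf sets")
  expect_error(consensus_tree(trees, threshold = 0.3), "threshold")
})

test_that("majority-rule clades are mutually compatible by construction", {
  set.seed(14)
  leaves <- letters[1:6]
  trees <- lapply(1:30, function(i) {
    m <- matrix(runif(18), 6, 3, dimnames = list(leaves, NULL))
    ward_tree(m)
  })
  for (th in c(0.5, 0.6, 0.8, 0.95)) {
    cons <- consensus_tree(trees, threshold = th)
    expect_s3_class(cons$tree, "phylo")
    expect_setequal(cons$tree$tip.label, leaves)
    expect_true(all(cons$support > th | lengths(cons$clades) == 6))
  }
})
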