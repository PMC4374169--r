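# a small donor-vector matrix: 6 donor individuals in 3 clusters, coordinates
# = the 3 cluster labels
toy_donor_vectors <- function() {
  dv <- rbind(
    c(0.60, 0.25, 0.15), c(0.58, 0.27, 0.15),
    c(0.20, 0.65, 0.15), c(0.22, 0.63, 0.15),
    c(0.15, 0.15, 0.70), c(0.15, 0.17, 0.68))
  rownames(dv) <- paste0("d", 1:6)
  colnames(dv) <- c("A", "B", "C")
  dv
}
toy_assignment <- function() setNames(c(1, 1, 2, 2, 3, 3), paste0("d", 1:6))
toy_labels <- function() setNames(c("A", "B", "C"), 1:3)

test_that("donor basis columns are normalized cluster means", {
  dv <- toy_donor_vectors()
  b_keep <- build_donor_basis(dv, toy_assignment(), self_copy = "keep",
                              cluster_labels = toy_labels())
  expect_equal(colnames(b_keep$C), c("A", "B", "C"))
  expect_lt(max(abs(colSums(b_keep$C) - 1)), 1e-8)
  expect_equal(unname(b_keep$C[, "A"]),
               unname(colMeans(dv[1:2, ]) / sum(colMeans(dv[1:2, ]))))
  b_zero <- build_donor_basis(dv, toy_assignment(),
                              self_copy = "zero-and-renormalize",
                              cluster_labels = toy_labels())
  expect_equal(unname(diag(b_zero$C)), c(0, 0, 0))
  expect_lt(max(abs(colSums(b_zero$C) - 1)), 1e-8)
  # the two treatments differ only via the diagonal: off-diagonal ratios match
  for (j in 1:3) {
    off <- setdiff(1:3, j)
    expect_equal(b_zero$C[off, j] / sum(b_zero$C[off, j]),
                 b_keep$C[off, j] / sum(b_keep$C[off, j]), tolerance = 1e-12)
  }
})

test_that("singleton clusters are excluded from the basis", {
  dv <- toy_donor_vectors()
  asg <- setNames(c(1, 1, 2, 2, 3, 4), paste0("d", 1:6)) # two singletons 3,4
  b <- build_donor_basis(dv, asg, self_copy = "keep")
  expect_equal(ncol(b$C), 2)
  asg2 <- setNames(c(1, 1, 2, 3, 4, 5), paste0("d", 1:6))
  expect_error(build_donor_basis(dv, asg2, self_copy = "keep"), ">= 2")
})

test_that("exact mixtures are recovered to numerical precision", {
  b <- build_donor_basis(toy_donor_vectors(), toy_assignment(),
                         self_copy = "keep", cluster_labels = toy_labels())
  # a basis column fits itself exactly
  sol <- fit_mixture(b$C[, "B"], b)
  expect_equal(unname(sol$proportions), c(0, 1, 0), tolerance = 1e-9)
  expect_lt(sol$residual_norm, 1e-9)
  # a constructed 0.3/0.7 blend
  tgt <- 0.3 * b$C[, "A"] + 0.7 * b$C[, "C"]
  sol2 <- fit_mixture(tgt, b)
  expect_equal(unname(sol2$proportions), c(0.3, 0, 0.7), tolerance = 1e-6)
})

test_that("duplicated basis columns split weight but not the fitted vector", {
  b <- build_donor_basis(toy_donor_vectors(), toy_assignment(),
                         self_copy = "keep", cluster_labels = toy_labels())
  tgt <- 0.5 * b$C[, "A"] + 0.5 * b$C[, "B"]
  base <- fit_mixture(tgt, b)
  C2 <- cbind(b$C, A2 = b$C[, "A"])
  dup <- fit_mixture(tgt, C2)
  fitted1 <- b$C %*% base$proportions
  fitted2 <- C2 %*% dup$proportions
  expect_lt(max(abs(fitted1 - fitted2)), 1e-8)
  expect_equal(unname(dup$proportions["A"] + dup$proportions["A2"]),
               unname(base$proportions["A"]), tolerance = 1e-6)
})

test_that("NNLS matches a dense simplex grid search on random problems", {
  set.seed(12)
  for (rep in 1:5) {
    C <- matrix(rgamma(12, 2), 4, 3)
    C <- sweep(C, 2, colSums(C), "/")
    rownames(C) <- paste0("g", 1:4); colnames(C) <- paste0("c", 1:3)
    tgt <- as.numeric(C %*% c(0.2, 0.5, 0.3)) + runif(4, 0, 0.02)
    tgt <- setNames(tgt / sum(tgt), rownames(C))
    sol <- fit_mixture(tgt, C)
    oracle <- grid_search_simplex3(C, tgt)
    fitted <- as.numeric(C %*% sol$proportions)
    expect_lt(sqrt(sum((fitted - oracle$fitted)^2)), 1e-3)
  }
})

test_that("masking deletes coordinates, renormalizes, and keeps components", {
  b <- build_donor_basis(toy_donor_vectors(), toy_assignment(),
                         self_copy = "keep", cluster_labels = toy_labels())
  tgt <- setNames(as.numeric(b$C %*% c(0.4, 0.3, 0.3)), rownames(b$C))
  # empty mask: identical to the plain fit
  plain <- fit_mixture(tgt, b)
  none <- mask_and_refit(tgt, b, character(0))
  expect_equal(none$proportions, plain$proportions)
  # masking a coordinate with no mass anywhere is vacuous
  C3 <- rbind(b$C, X = 0)
  tgt3 <- c(tgt, X = 0)
  vac <- mask_and_refit(tgt3, C3, "X")
  expect_equal(unname(vac$proportions), unname(plain$proportions),
               tolerance = 1e-8)
  expect_equal(vac$masked_groups, "X")
  # the masked column itself stays available as a component
  expect_equal(names(vac$proportions), colnames(b$C))
  # masking the coordinate that drives one component reduces its weight
  Cm <- cbind(G = c(0.8, 0.1, 0.1), H = c(0.1, 0.6, 0.3))
  rownames(Cm) <- c("G", "H", "I")
  t2 <- setNames(c(0.5, 0.3, 0.2), rownames(Cm))
  with_g <- fit_mixture(t2, Cm)$proportions["G"]
  without_g <- mask_and_refit(t2, Cm, "G")$proportions["G"]
  expect_lt(without_g, with_g)
  # masking everything the target has is an error
  t3 <- setNames(c(1, 0, 0), rownames(Cm))
  expect_error(mask_and_refit(t3, Cm, "G"), "zero the target")
  expect_error(mask_and_refit(t2, Cm, "ZZ"), "ZZ")
})

test_that("jackknife SE matches the closed form and is order-invariant", {
  # n = 2 with leave-one-out estimates 0.4 and 0.6: SE = 0.1
  reps <- rbind(c(0.4, 0.6), c(0.6, 0.4))
  expect_equal(unname(haplomix:::jk_se(reps)), c(0.1, 0.1))
  # constant replicates give zero
  expect_equal(unname(haplomix:::jk_se(rbind(c(0.5, 0.5), c(0.5, 0.5)))),
               c(0, 0))
  # general n: agrees with the formula evaluated longhand
  set.seed(13)
  r22 <- matrix(runif(22 * 3), 22, 3)
  long <- sqrt(21 / 22 * colSums(sweep(r22, 2, colMeans(r22))^2))
  expect_equal(unname(haplomix:::jk_se(r22)), unname(long))
  # permuting replicate (chromosome) order changes nothing
  expect_equal(haplomix:::jk_se(r22[sample(22), ]), haplomix:::jk_se(r22))
})

test_that("jackknife over painted chromosomes needs >= 2 and handles constants", {
  sc <- small_scenario(seed = 101, n_recipients = 4,
                       alpha = c(pop1 = 0.5, pop2 = 0.3, pop3 = 0.2))
  pm <- copying_model_params(ne = 50, theta = 0.01)
  pl <- run_ancestry_pipeline(sc$panel, params = pm, clustering = "labels",
                              jackknife = TRUE)
  se <- pl$fit$population$admixed$se
  expect_true(all(se >= 0))
  expect_length(se, 3)
  one_chrom <- pl$recipient_paintings
  for (nm in c("sites", "morgans", "chunks"))
    one_chrom[[nm]] <- one_chrom[[nm]][1, , , drop = FALSE]
  one_chrom$loglik <- one_chrom$loglik[1, , drop = FALSE]
  one_chrom$chroms <- one_chrom$chroms[1]
  expect_error(jackknife_se(one_chrom, pl$basis), ">= 2")
})

test_that("per-individual fits equal the population fit for identical members", {
  b <- build_donor_basis(toy_donor_vectors(), toy_assignment(),
                         self_copy = "keep", cluster_labels = toy_labels())
  # a painting set of two identical individuals over two chromosomes
  groups <- rownames(b$C)
  a <- array(0, dim = c(2, 3, 2),
             dimnames = list(c("c1", "c2"), groups, c("r1", "r2")))
  v <- c(0.5, 0.3, 0.2)
  for (cc in 1:2) for (t in 1:2) a[cc, , t] <- v * 100
  ps <- structure(list(sites = a, morgans = a, chunks = a,
                       loglik = matrix(0, 2, 2,
                                       dimnames = list(c("c1", "c2"),
                                                       c("r1", "r2"))),
                       targets = c("r1", "r2"), groups = groups,
                       chroms = c("c1", "c2"),
                       params = copying_model_params()),
                  class = "painting_set")
  fit <- individual_ancestry(ps, b,
                             populations = c(r1 = "P", r2 = "P"))
  expect_equal(fit$individual$r1$proportions,
               fit$population$P$solution$proportions)
  expect_equal(fit$individual_mean$P,
               fit$population$P$solution$proportions)
  expect_error(individual_ancestry(subset_painting(ps, character(0)), b,
                                   populations = character(0)),
               "target")
})

test_that("per-individual proportions track varying individual truth", {
  # recipients with individually varying pop1 fractions 0.2..0.8
  pool <- simulate_donor_pool(donor_pool_spec(
    2, 30, 600, divergence = 0.2, seed = 111,
    chrom_lengths_morgans = setNames(rep(1.2, 8), paste0("c", 1:8))))
  fracs <- seq(0.2, 0.8, length.out = 10)
  recs <- lapply(seq_along(fracs), function(i)
    simulate_admixed(pool, admixture_spec(
      c(pop1 = fracs[i], pop2 = 1 - fracs[i]), generations = 10,
      n_recipients = 1, seed = 200 + i), population = paste0("r", i)))
  panel <- Reduce(bind_panels, c(list(pool), lapply(recs, `[[`, "panel")))
  pm <- copying_model_params(ne = 60, theta = 0.01)
  pl <- run_ancestry_pipeline(panel, params = pm, clustering = "labels")
  fitted <- vapply(pl$fit$individual, function(s) s$proportions["pop1"], 1)
  truth <- vapply(seq_along(fracs), function(i) {
    tf <- true_ancestry_fractions(recs[[i]]$tracts, pool)
    if ("pop1" %in% names(tf)) tf[["pop1"]] else 0
  }, 1)
  expect_gte(cor(fitted, truth), 0.8)
})
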