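test_that("single-donor painting is the degenerate one-state chain", {
  set.seed(1)
  L <- 50
  donor <- matrix(rbinom(L, 1, 0.5), 1, L)
  target <- donor[1, ]
  target[c(3, 17)] <- 1L - target[c(3, 17)] # two mismatches
  gpos <- cumsum(runif(L, 0.001, 0.01))
  pm <- copying_model_params(ne = 10, theta = 0.05)
  pr <- paint_haplotype(target, donor, "A", gpos, pm)
  expect_equal(unname(pr$expected_copied_sites["A"]), L)
  expect_equal(unname(pr$expected_chunk_count["A"]), 1)
  # log-likelihood is just the summed log emissions
  expect_equal(pr$log_likelihood, 48 * log(0.95) + 2 * log(0.05))
})

test_that("a perfectly matching donor absorbs the copying posterior", {
  set.seed(2)
  L <- 50
  a <- rbinom(L, 1, 0.5)
  donors <- rbind(a, 1L - a) # B mismatches everywhere
  target <- a
  gpos <- seq(0, 0.5, length.out = L)
  pm <- copying_model_params(ne = 10, theta = 1e-4)
  pr <- paint_haplotype(target, donors, c("A", "B"), gpos, pm)
  cv <- pr$expected_copied_sites / sum(pr$expected_copied_sites)
  expect_gte(unname(cv["A"]), 0.999)
})

test_that("forward-backward matches the exhaustive path sum on a fixed toy", {
  target <- c(0L, 1L, 0L)
  donors <- rbind(c(0L, 1L, 1L), c(1L, 1L, 0L))
  gpos <- c(0, 0.3, 0.8)
  pm <- copying_model_params(ne = 1, theta = 0.1)
  pr <- paint_haplotype(target, donors, c("d1", "d2"), gpos, pm)
  oracle <- enum_copying_loglik(target, donors, gpos, 1, 0.1)
  expect_lt(abs(pr$log_likelihood - oracle) / abs(oracle), 1e-12)
})

test_that("per-site posteriors are a proper distribution and missing sites are neutral", {
  set.seed(3)
  L <- 30; k <- 5
  donors <- matrix(rbinom(k * L, 1, 0.5), k, L)
  target <- rbinom(L, 1, 0.5)
  target[c(4, 9)] <- NA
  gpos <- cumsum(runif(L, 1e-4, 0.02))
  pr <- paint_haplotype(target, donors, paste0("d", 1:k), gpos,
                        copying_model_params(ne = 30, theta = 0.01),
                        posterior = TRUE)
  expect_lt(max(abs(colSums(pr$posterior) - 1)), 1e-10)
  expect_equal(sum(pr$expected_copied_sites), L, tolerance = 1e-6)
  expect_gte(sum(pr$expected_chunk_count), 1)
  expect_true(is.finite(pr$log_likelihood))
})

test_that("expected chunk count increases with the recombination constant", {
  set.seed(4)
  L <- 40
  donors <- rbind(rbinom(L, 1, 0.5), rbinom(L, 1, 0.5))
  target <- ifelse(seq_len(L) %% 2 == 0, donors[1, ], donors[2, ])
  gpos <- seq_len(L) * 0.01
  chunks <- vapply(c(1, 10, 100, 1000), function(ne)
    sum(paint_haplotype(target, donors, c("a", "b"), gpos,
                        copying_model_params(ne = ne, theta = 0.05)
                        )$expected_chunk_count), 1)
  expect_true(all(diff(chunks) > 0))
})

test_that("panel painting is deterministic and additive over chromosomes", {
  sc <- small_scenario(seed = 51, n_recipients = 3)
  pm <- copying_model_params(ne = 50, theta = 0.01)
  ps1 <- paint_panel(sc$panel, params = pm)
  ps2 <- paint_panel(sc$panel, params = pm)
  expect_identical(ps1$sites, ps2$sites)
  # identical targets painted against the same donors get identical vectors
  dup <- sc$adm$panel
  two <- subset_samples(dup, dup$sample_ids[1])
  clone <- two
  clone$sample_ids <- "clone"
  names(clone$populations) <- names(clone$role) <- "clone"
  clone$hap_sample <- rep("clone", 2)
  rownames(clone$alleles) <- paste0("clone_", 1:2)
  pair <- bind_panels(sc$pool, bind_panels(two, clone))
  cv <- copying_vectors(paint_panel(pair, params = pm))
  expect_equal(unname(cv[1, ]), unname(cv[2, ]), tolerance = 1e-12)
  # whole-genome expectation equals the sum of per-chromosome parts
  total <- apply(ps1$sites, c(3, 2), sum)
  manual <- Reduce(`+`, lapply(seq_along(ps1$chroms), function(ci)
    ps1$sites[ci, , ]))
  expect_equal(unname(total), unname(t(manual)), tolerance = 1e-12)
})

test_that("copying vectors normalize, aggregate and weight correctly", {
  sc <- small_scenario(seed = 61, n_recipients = 4)
  ps <- paint_panel(sc$panel, params = copying_model_params(ne = 50,
                                                            theta = 0.01))
  iv <- copying_vectors(ps)
  expect_lt(max(abs(rowSums(iv) - 1)), 1e-8)
  pv <- copying_vectors(ps, level = "population",
                        populations = sc$panel$populations)
  expect_lt(max(abs(rowSums(pv) - 1)), 1e-8)
  # single-member population: population vector equals individual vector
  solo <- copying_vectors(subset_painting(ps, ps$targets[1]),
                          level = "population",
                          populations = sc$panel$populations)
  expect_equal(unname(solo[1, ]), unname(iv[1, ]), tolerance = 1e-12)
  # on a uniform map, site and Morgan weighting agree
  pool <- simulate_donor_pool(donor_pool_spec(
    2, 8, 60, chrom_lengths_morgans = c(u = 0.6), divergence = 0.3,
    seed = 62))
  pool$sites$gpos <- seq_len(60) * 0.01 # exactly uniform spacing
  adm <- simulate_admixed(pool, admixture_spec(c(pop1 = 0.5, pop2 = 0.5),
                                               5, 3, seed = 63))
  comb <- bind_panels(pool, adm$panel)
  ps_u <- paint_panel(comb, params = copying_model_params(ne = 20,
                                                          theta = 0.01))
  s <- copying_vectors(ps_u, weight = "sites")
  m <- copying_vectors(ps_u, weight = "morgans")
  expect_equal(s, m, tolerance = 1e-8)
})

test_that("a pure-ancestry recipient copies mostly from its source group", {
  pool <- simulate_donor_pool(donor_pool_spec(
    3, 20, 1000, divergence = 0.15, seed = 71))
  adm <- simulate_admixed(pool, admixture_spec(c(pop2 = 1), 10, 2,
                                               seed = 72))
  comb <- bind_panels(pool, adm$panel)
  cv <- copying_vectors(paint_panel(comb,
                                    params = copying_model_params(
                                      ne = 100, theta = 0.01)))
  for (r in seq_len(nrow(cv)))
    expect_equal(names(which.max(cv[r, ])), "pop2")
})

test_that("painting contracts: empty donor sets and bad inputs error", {
  sc <- small_scenario(seed = 81, n_recipients = 2)
  expect_error(paint_haplotype(c(0L, 1L), matrix(0L, 0, 2), character(0),
                               c(0, 0.1), copying_model_params()),
               "empty")
  expect_error(paint_haplotype(c(0L, 1L), matrix(0L, 1, 2), "a",
                               c(0, NaN), copying_model_params()),
               "distance")
  expect_error(paint_panel(sc$panel, targets = character(0)), "target")
  expect_error(copying_model_params(ne = -1), "ne")
  expect_error(copying_model_params(theta = 0.7), "theta")
})

test_that("EM contracts hold and the iteration default is ten", {
  sc <- small_scenario(seed = 91)
  expect_error(estimate_params_em(sc$panel, n_iter = 0), "n_iter")
  expect_equal(formals(estimate_params_em)$n_iter, 10)
  # one cheap cell runs and returns valid parameters
  em <- estimate_params_em(sc$panel, populations = "pop1",
                           chromosomes = "c1", n_iter = 2)
  expect_s3_class(em, "copying_model_params")
  expect_gt(em$ne, 0)
  expect_gt(em$theta, 0)
})
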