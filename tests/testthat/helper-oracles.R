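# Independent oracles used across tests. These deliberately share no code
# with the package implementation.

# brute-force likelihood of the copying HMM: sum over all k^L donor paths
enum_copying_loglik <- function(target, donors, gpos, ne, theta,
                                prior = NULL) {
  k <- nrow(donors); L <- length(target)
  if (is.null(prior)) prior <- rep(1 / k, k)
  gaps <- pmax(diff(gpos), 1e-9)
  emis <- function(d, l) {
    if (is.na(target[l])) return(1)
    if (donors[d, l] == target[l]) 1 - theta else theta
  }
  paths <- as.matrix(expand.grid(rep(list(seq_len(k)), L)))
  tot <- 0
  for (i in seq_len(nrow(paths))) {
    p <- prior[paths[i, 1]] * emis(paths[i, 1], 1)
    for (l in seq_len(L - 1)) {
      r <- exp(-ne * gaps[l])
      tr <- r * (paths[i, l + 1] == paths[i, l]) + (1 - r) * prior[paths[i, l + 1]]
      p <- p * tr * emis(paths[i, l + 1], l + 1)
    }
    tot <- tot + p
  }
  log(tot)
}

# all set partitions of n elements as restricted-growth strings
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, mx) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(mx + 1L)) rec(c(prefix, v), max(mx, v))
  }
  rec(1L, 1L)
  out
}

# direct Dirichlet-multinomial log marginal: log B(x + beta) - log B(beta)
# (multinomial coefficient omitted, matching the package's convention)
dm_log_marginal_direct <- function(counts, beta) {
  num <- sum(lgamma(counts + beta)) - lgamma(sum(counts + beta))
  den <- length(counts) * lgamma(beta) - lgamma(length(counts) * beta)
  num - den
}

# exhaustive MAP partition under the package's uniform-on-K prior
enum_map_partition <- function(X, beta = 1) {
  n <- nrow(X)
  parts <- all_partitions(n)
  ls2 <- haplomix:::log_stirling2(n)
  sc <- vapply(parts, function(a)
    partition_log_marginal(X, a, beta) +
      haplomix:::partition_log_prior(max(a), ls2, n), 1)
  list(map = parts[[which.max(sc)]], lp = max(sc), n_partitions = length(parts))
}

# relabel a partition into first-appearance order (the package's canon)
relabel_first <- function(asg) match(asg, unique(asg))

# dense grid search over the 2-simplex (3 mixture components) minimizing
# || target - C a ||; returns the best fitted vector
grid_search_simplex3 <- function(C, target, step = 0.001) {
  a1 <- seq(0, 1, step)
  best <- NULL; best_rss <- Inf
  for (x in a1) {
    a2 <- seq(0, 1 - x, step)
    A <- rbind(x, a2, pmax(1 - x - a2, 0))
    R <- C %*% A - as.numeric(target)
    rss <- colSums(R^2)
    j <- which.min(rss)
    if (rss[j] < best_rss) { best_rss <- rss[j]; best <- A[, j] }
  }
  list(a = best, fitted = as.numeric(C %*% best), rss = best_rss)
}

# small structured panel used by several io/painting tests
toy_panel <- function(n_samples = 3, n_sites = 5, seed = 1,
                      chrom = rep("1", n_sites), missing = NULL) {
  set.seed(seed)
  al <- matrix(rbinom(2 * n_samples * n_sites, 1, 0.5), 2 * n_samples,
               n_sites)
  if (!is.null(missing)) al[missing] <- NA
  ids <- paste0("s", seq_len(n_samples))
  haplotype_panel(al, ids,
                  setNames(rep(c("popA", "popB"),
                               length.out = n_samples), ids),
                  data.frame(chrom = chrom,
                             pos = seq_len(n_sites) * 1000L,
                             gpos = seq_len(n_sites) * 0.01),
                  setNames(rep("donor", n_samples), ids))
}

# donor pool + admixed recipients at desk scale, reused by pipeline tests
small_scenario <- function(n_pops = 3, haps_per_pop = 20, n_sites = 400,
                           divergence = 0.2, alpha = NULL, generations = 10,
                           n_recipients = 8, seed = 42,
                           chroms = setNames(rep(0.8, 6), paste0("c", 1:6))) {
  pool <- simulate_donor_pool(donor_pool_spec(
    n_pops = n_pops, haps_per_pop = haps_per_pop, n_sites = n_sites,
    chrom_lengths_morgans = chroms, divergence = divergence, seed = seed))
  if (is.null(alpha))
    alpha <- setNames(rep(1 / n_pops, n_pops), paste0("pop", seq_len(n_pops)))
  adm <- simulate_admixed(pool, admixture_spec(alpha, generations,
                                               n_recipients,
                                               seed = seed + 1L))
  list(pool = pool, adm = adm, panel = bind_panels(pool, adm$panel),
       alpha = alpha)
}
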