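# --- Dirichlet-multinomial partition model over chunk-count matrices -------
#
# Rows of X are donor individuals' chunk-count vectors (counts of genome
# chunks copied from each donor column). Individuals in the same cluster are
# assumed to draw their counts from a shared multinomial with a symmetric
# Dirichlet(beta) prior on its weights; integrating the weights out gives a
# Dirichlet-multinomial marginal per cluster, summed over clusters.

# log of the Dirichlet-multinomial marginal (without the multinomial
# coefficient, which is constant across partitions) for one aggregated
# count vector
dirmult_log_marginal <- function(counts, beta) {
  m <- length(counts)
  sum(lgamma(counts + beta)) - m * lgamma(beta) +
    lgamma(m * beta) - lgamma(sum(counts) + m * beta)
}

#' Log marginal likelihood of a partition under the chunk-count model
#'
#' Aggregates the rows of `X` by cluster and scores each cluster's summed
#' count vector with the symmetric Dirichlet-multinomial marginal (log-gamma
#' arithmetic throughout, so large counts do not overflow). The result is the
#' sum of per-cluster log marginals.
#'
#' @param X non-negative integer matrix, donor individuals x donor columns.
#' @param assignment integer (or factor-coercible) vector of cluster ids, one
#'   per row of `X`.
#' @param beta symmetric Dirichlet concentration, > 0.
#' @return log marginal likelihood (numeric scalar).
#' @export
partition_log_marginal <- function(X, assignment, beta = 1) {
  if (!is.numeric(beta) || beta <= 0) stop("beta must be > 0")
  if (length(assignment) != nrow(X))
    stop("assignment must have one entry per row of X")
  agg <- rowsum(X, assignment)
  sum(apply(agg, 1, dirmult_log_marginal, beta = beta))
}

# log Stirling numbers of the second kind, S(n, 1..n), by the standard
# recurrence in log space; used by the uniform-on-K partition prior
log_stirling2 <- function(n) {
  prev <- c(0) # S(1,1) = 1
  if (n == 1) return(prev)
  for (m in 2:n) {
    cur <- numeric(m)
    cur[1] <- 0 # S(m,1) = 1
    cur[m] <- 0 # S(m,m) = 1
    if (m > 2) for (k in 2:(m - 1)) {
      a <- log(k) + prev[k] # k * S(m-1, k)
      b <- prev[k - 1]      # S(m-1, k-1)
      cur[k] <- max(a, b) + log1p(exp(-abs(a - b)))
    }
    prev <- cur
  }
  prev
}

# log prior of a partition: uniform over K in 1..n, then uniform over the
# S(n, K) partitions with K clusters
partition_log_prior <- function(K, log_s2, n) {
  -log(n) - log_s2[K]
}

# dense relabelling 1..K in order of first appearance
relabel_partition <- function(assignment) {
  match(assignment, unique(assignment))
}

#' Cluster donor individuals by partition MCMC
#'
#' Metropolis-Hastings over set partitions of the rows of a chunk-count
#' matrix, with three move types: single-individual reassignment (to an
#' existing cluster or a new singleton), merge of two random clusters, and a
#' random binary split of one cluster, each with the exact Hastings
#' correction. The posterior is the Dirichlet-multinomial marginal times a
#' prior that is uniform over the number of clusters K and uniform over
#' partitions given K. Several independent chains are run (two by default,
#' mirroring standard practice) and the best Maximum A Posteriori state
#' across chains is returned.
#'
#' @param X non-negative integer matrix (donor individuals x donor columns);
#'   row names identify individuals.
#' @param n_iter iterations per chain (>= 1). Desk-scaled default 20000;
#'   production analyses use millions.
#' @param beta symmetric Dirichlet concentration.
#' @param seed integer seed.
#' @param n_chains number of independent chains.
#' @param init optional initial assignment (default: every row a singleton).
#' @return list of class `partition_mcmc`: `map` (named cluster assignment),
#'   `K`, `log_posterior`, `log_marginal`, `trace` (per-chain MAP
#'   log-posterior trace, thinned), `beta`.
#' @export
cluster_mcmc <- function(X, n_iter = 20000, beta = 1, seed = 1L,
                         n_chains = 2L, init = NULL) {
  if (!is.numeric(n_iter) || n_iter < 1) stop("n_iter must be >= 1")
  X <- as.matrix(X)
  if (any(X < 0)) stop("chunk counts must be non-negative")
  if (any(rowSums(X) == 0)) stop("every row of X must be non-zero")
  n <- nrow(X)
  ids <- rownames(X)
  if (is.null(ids)) ids <- paste0("ind", seq_len(n))
  log_s2 <- log_stirling2(n)
  log2c <- log(2)

  # cached per-cluster scores make each proposal O(columns)
  chain <- function(chain_seed) {
    set.seed(chain_seed)
    asg <- if (is.null(init)) seq_len(n) else relabel_partition(init)
    K <- max(asg)
    sums <- rowsum(X, asg)                       # K x m aggregated counts
    scores <- apply(sums, 1, dirmult_log_marginal, beta = beta)
    ll <- sum(scores)
    lp <- ll + partition_log_prior(K, log_s2, n)
    best <- list(asg = asg, lp = lp, ll = ll)
    trace <- numeric(0)
    n_splittable <- function(sizes) sum(sizes >= 2)
    sizes <- as.vector(table(factor(asg, levels = seq_len(K))))

    for (it in seq_len(n_iter)) {
      move <- sample.int(3L, 1L)
      if (move == 1L) { # reassign one individual
        i <- sample.int(n, 1L)
        ci <- asg[i]
        opts_new <- K - 1L + (sizes[ci] > 1L) # other clusters + maybe fresh
        if (opts_new == 0L) next
        # enumerate destinations: existing clusters != ci, plus "0" = fresh
        dests <- setdiff(seq_len(K), ci)
        if (sizes[ci] > 1L) dests <- c(dests, 0L)
        dest <- dests[sample.int(length(dests), 1L)]
        new_asg <- asg; new_sizes <- sizes
        xi <- X[i, ]
        if (dest == 0L) { # split off as a singleton
          newc <- K + 1L
          new_asg[i] <- newc
          new_sums_ci <- sums[ci, ] - xi
          sc_ci <- dirmult_log_marginal(new_sums_ci, beta)
          sc_new <- dirmult_log_marginal(xi, beta)
          new_ll <- ll - scores[ci] + sc_ci + sc_new
          new_K <- K + 1L
          new_sizes[ci] <- sizes[ci] - 1L
          new_sizes <- c(new_sizes, 1L)
        } else {
          new_asg[i] <- dest
          emptied <- sizes[ci] == 1L
          new_sums_dest <- sums[dest, ] + xi
          sc_dest <- dirmult_log_marginal(new_sums_dest, beta)
          if (emptied) {
            new_ll <- ll - scores[ci] - scores[dest] + sc_dest
            new_K <- K - 1L
          } else {
            new_sums_ci <- sums[ci, ] - xi
            sc_ci <- dirmult_log_marginal(new_sums_ci, beta)
            new_ll <- ll - scores[ci] - scores[dest] + sc_ci + sc_dest
            new_K <- K
          }
          new_sizes[dest] <- sizes[dest] + 1L
          new_sizes[ci] <- sizes[ci] - 1L
        }
        new_lp <- new_ll + partition_log_prior(new_K, log_s2, n)
        # reverse move: i moves back to ci. If i split off as a singleton,
        # the reverse has new_K - 1 destinations and no fresh option (= K);
        # if ci emptied, reverse re-creates it as fresh, giving new_K - 1 + 1
        # options (= K - 1); otherwise new_K - 1 + 1 (= K).
        opts_rev <- if (dest == 0L) K
                    else if (sizes[ci] == 1L) K - 1L
                    else K
        log_q_fwd <- -log(opts_new)
        log_q_rev <- -log(opts_rev)
        if (log(runif(1)) < new_lp - lp + log_q_rev - log_q_fwd) {
          # commit (compact labels lazily: only when a cluster empties)
          asg <- new_asg
          if (dest == 0L) {
            sums <- rbind(sums, xi)
            sums[ci, ] <- sums[ci, ] - xi
            scores <- c(scores, dirmult_log_marginal(xi, beta))
            scores[ci] <- dirmult_log_marginal(sums[ci, ], beta)
            K <- K + 1L
            sizes <- c(sizes, 1L); sizes[ci] <- sizes[ci] - 1L
          } else {
            sums[dest, ] <- sums[dest, ] + xi
            scores[dest] <- dirmult_log_marginal(sums[dest, ], beta)
            sizes[dest] <- sizes[dest] + 1L
            if (sizes[ci] == 1L) { # cluster emptied: drop it
              keep <- setdiff(seq_len(K), ci)
              relab <- integer(K); relab[keep] <- seq_along(keep)
              asg <- relab[asg]
              sums <- sums[keep, , drop = FALSE]
              scores <- scores[keep]
              sizes <- sizes[keep]
              K <- K - 1L
            } else {
              sums[ci, ] <- sums[ci, ] - xi
              scores[ci] <- dirmult_log_marginal(sums[ci, ], beta)
              sizes[ci] <- sizes[ci] - 1L
            }
          }
          ll <- new_ll; lp <- new_lp
        }
      } else if (move == 2L) { # merge two clusters
        if (K < 2L) next
        pair <- sample.int(K, 2L)
        a <- pair[1]; b <- pair[2]
        merged <- sums[a, ] + sums[b, ]
        sc_m <- dirmult_log_marginal(merged, beta)
        new_ll <- ll - scores[a] - scores[b] + sc_m
        new_lp <- new_ll + partition_log_prior(K - 1L, log_s2, n)
        s <- sizes[a] + sizes[b]
        n_spl_rev <- n_splittable(c(sizes[-c(a, b)], s))
        # forward: choose unordered pair; reverse: choose merged cluster among
        # splittable ones, then this particular binary split
        log_q_fwd <- -log(K * (K - 1) / 2)
        log_q_rev <- -log(n_spl_rev) -
          ((s - 1) * log2c + log1p(-2^(-(s - 1))))
        if (log(runif(1)) < new_lp - lp + log_q_rev - log_q_fwd) {
          keep <- setdiff(seq_len(K), c(a, b))
          relab <- integer(K); relab[keep] <- seq_along(keep)
          newc <- length(keep) + 1L
          relab[c(a, b)] <- newc
          asg <- relab[asg]
          sums <- rbind(sums[keep, , drop = FALSE], merged)
          scores <- c(scores[keep], sc_m)
          sizes <- c(sizes[keep], s)
          K <- K - 1L
          ll <- new_ll; lp <- new_lp
        }
      } else { # random binary split of one cluster
        spl <- which(sizes >= 2L)
        if (!length(spl)) next
        c0 <- spl[sample.int(length(spl), 1L)]
        members <- which(asg == c0)
        s <- length(members)
        repeat { # uniform over the 2^s - 2 ordered non-trivial splits
          side <- runif(s) < 0.5
          if (any(side) && !all(side)) break
        }
        xa <- colSums(X[members[side], , drop = FALSE])
        xb <- sums[c0, ] - xa
        sc_a <- dirmult_log_marginal(xa, beta)
        sc_b <- dirmult_log_marginal(xb, beta)
        new_ll <- ll - scores[c0] + sc_a + sc_b
        new_lp <- new_ll + partition_log_prior(K + 1L, log_s2, n)
        log_q_fwd <- -log(length(spl)) - ((s - 1) * log2c + log1p(-2^(-(s - 1))))
        log_q_rev <- -log((K + 1) * K / 2)
        if (log(runif(1)) < new_lp - lp + log_q_rev - log_q_fwd) {
          newb <- K + 1L
          asg[members[side]] <- newb
          # c0 keeps the !side members
          sums[c0, ] <- xb
          scores[c0] <- sc_b
          sums <- rbind(sums, xa)
          scores <- c(scores, sc_a)
          sizes[c0] <- s - sum(side)
          sizes <- c(sizes, sum(side))
          K <- K + 1L
          ll <- new_ll; lp <- new_lp
        }
      }
      if (it %% max(1L, n_iter %/% 200L) == 0L) trace <- c(trace, best$lp)
      if (lp > best$lp) best <- list(asg = asg, lp = lp, ll = ll)
    }
    best$trace <- trace
    best
  }

  seeds <- seed + seq_len(n_chains) * 10007L
  runs <- lapply(seeds, chain)
  lps <- vapply(runs, function(r) r$lp, 1)
  win <- runs[[which.max(lps)]]
  asg <- relabel_partition(win$asg)
  structure(list(map = setNames(asg, ids), K = max(asg),
                 log_posterior = unname(win$lp), log_marginal = unname(win$ll),
                 trace = lapply(runs, `[[`, "trace"), beta = beta),
            class = "partition_mcmc")
}

#' @export
print.partition_mcmc <- function(x, ...) {
  cat("partition_mcmc: MAP with K =", x$K, "clusters, log posterior",
      format(x$log_posterior, digits = 8), "\n")
  invisible(x)
}

#' Greedy cluster dendrogram from a MAP partition
#'
#' Starting from the MAP clusters, repeatedly merges the pair of clusters
#' whose merge least decreases the Dirichlet-multinomial log marginal,
#' recording the merge order as a binary tree relating the clusters
#' (the usual way a partition of donor individuals is displayed as a
#' hierarchy).
#'
#' @param X chunk-count matrix (rows = individuals).
#' @param assignment named cluster assignment (e.g. `$map` from
#'   [cluster_mcmc()]).
#' @param beta Dirichlet concentration used for scoring.
#' @param labels optional cluster labels; default `cl1..clK`.
#' @return an [ape::phylo] tree whose tips are clusters; branch "heights"
#'   encode the cumulative log-marginal cost of each merge. For K = 1 a
#'   single-tip degenerate tree is returned.
#' @export
cluster_tree <- function(X, assignment, beta = 1, labels = NULL) {
  asg <- relabel_partition(assignment)
  K <- max(asg)
  if (is.null(labels)) labels <- paste0("cl", seq_len(K))
  if (K == 1) {
    # degenerate single-tip tree (newick cannot express a lone leaf)
    return(structure(list(edge = matrix(c(2L, 1L), 1, 2),
                          tip.label = labels[1], Nnode = 1L),
                     class = "phylo"))
  }
  sums <- rowsum(as.matrix(X), asg)
  scores <- apply(sums, 1, dirmult_log_marginal, beta = beta)
  nodes <- as.list(labels) # newick fragments
  active <- seq_len(K)
  while (length(active) > 1) {
    best <- NULL
    for (i in seq_along(active)) for (j in seq_len(i - 1)) {
      a <- active[i]; b <- active[j]
      sc <- dirmult_log_marginal(sums[a, ] + sums[b, ], beta)
      delta <- sc - scores[a] - scores[b]
      if (is.null(best) || delta > best$delta)
        best <- list(a = a, b = b, sc = sc, delta = delta)
    }
    a <- best$a; b <- best$b
    sums[a, ] <- sums[a, ] + sums[b, ]
    scores[a] <- best$sc
    nodes[[a]] <- paste0("(", nodes[[a]], ",", nodes[[b]], ")")
    active <- setdiff(active, b)
  }
  ape::read.tree(text = paste0(nodes[[active]], ";"))
}

#' Remove singleton clusters from a partition
#'
#' Clusters containing a single individual are removed from the donor set
#' used downstream (they would distort the mixture decomposition).
#'
#' @param assignment named cluster assignment (individual -> cluster id).
#' @return list: `assignment` (relabelled, singletons dropped), `removed`
#'   (ids of excluded individuals).
#' @export
drop_singletons <- function(assignment) {
  tab <- table(assignment)
  singles <- names(tab)[tab == 1]
  keep <- !(as.character(assignment) %in% singles)
  if (!any(keep)) stop("no donors remain after removing singleton clusters")
  out <- assignment[keep]
  list(assignment = setNames(relabel_partition(out), names(out)),
       removed = names(assignment)[!keep])
}
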