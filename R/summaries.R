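#' Continent map for donor clusters
#'
#' A total mapping from donor cluster to a geographic region and from region
#' to continent (e.g. 13 regions within Africa, Europe and East Asia/America
#' in a genome-wide human analysis). Used to aggregate mixture proportions to
#' continental totals and to restrict them to one continent.
#'
#' @param cluster character vector of cluster labels.
#' @param region character vector of region labels (same length).
#' @param continent character vector of continent labels (same length).
#' @return a `continent_map` data.frame.
#' @export
continent_map <- function(cluster, region, continent) {
  if (anyDuplicated(cluster)) stop("duplicate cluster labels in continent map")
  structure(data.frame(cluster = cluster, region = region,
                       continent = continent, stringsAsFactors = FALSE),
            class = c("continent_map", "data.frame"))
}

solution_matrix <- function(solutions) {
  # accept a named list of mixture_solutions or of bare proportion vectors
  rows <- lapply(solutions, function(s)
    if (inherits(s, "mixture_solution")) s$proportions else s)
  m <- do.call(rbind, rows)
  rownames(m) <- names(solutions)
  m
}

#' Aggregate mixture proportions to continental totals
#'
#' @param solutions named list of `mixture_solution`s (or bare named
#'   proportion vectors), one per recipient population.
#' @param cmap a [continent_map()]; must cover every cluster with positive
#'   proportion.
#' @return matrix, populations x continents, rows summing to 1.
#' @export
continental_aggregate <- function(solutions, cmap) {
  m <- solution_matrix(solutions)
  unmapped <- setdiff(colnames(m)[colSums(m) > 0], cmap$cluster)
  if (length(unmapped))
    stop("cluster(s) with positive proportion not in continent map: ",
         paste(unmapped, collapse = ", "))
  cont <- setNames(cmap$continent, cmap$cluster)
  keep <- colnames(m) %in% cmap$cluster
  t(rowsum(t(m[, keep, drop = FALSE]), cont[colnames(m)[keep]]))
}

#' Relative ancestry composition within one continent
#'
#' Restricts each population's mixture proportions to the clusters of one
#' continent and renormalizes them to sum to 1. Populations whose continental
#' total is below `min_total` are excluded (a population with essentially no
#' ancestry from that continent has no meaningful relative composition there)
#' and reported.
#'
#' @param solutions named list of `mixture_solution`s or proportion vectors.
#' @param cmap a [continent_map()].
#' @param continent continent to restrict to.
#' @param min_total exclusion threshold on the continental total in \[0, 1);
#'   default 0.01.
#' @param by aggregate the restricted proportions by `"cluster"` (default) or
#'   `"region"` before renormalizing.
#' @return list of class `relative_ancestry`: `proportions` (matrix, retained
#'   populations x sources, rows sum to 1), `excluded` (named numeric vector
#'   of excluded populations' continental totals), `continent`.
#' @export
relative_composition <- function(solutions, cmap, continent,
                                 min_total = 0.01,
                                 by = c("cluster", "region")) {
  by <- match.arg(by)
  if (min_total < 0 || min_total >= 1) stop("min_total must be in [0, 1)")
  m <- solution_matrix(solutions)
  cl <- cmap$cluster[cmap$continent == continent]
  if (!length(cl)) stop("no clusters mapped to continent ", continent)
  cl <- intersect(colnames(m), cl)
  sub <- m[, cl, drop = FALSE]
  totals <- rowSums(sub)
  excl <- totals < min_total
  out <- sub[!excl, , drop = FALSE]
  if (!nrow(out)) stop("all populations excluded at min_total = ", min_total)
  if (by == "region") {
    reg <- setNames(cmap$region, cmap$cluster)
    out <- t(rowsum(t(out), reg[colnames(out)]))
  }
  out <- out / rowSums(out)
  structure(list(proportions = out,
                 excluded = setNames(totals[excl], rownames(sub)[excl]),
                 continent = continent),
            class = "relative_ancestry")
}

#' Ward hierarchical clustering of populations
#'
#' Euclidean distances between the populations' relative ancestry vectors,
#' clustered with Ward linkage in the squared-distance ("ward.D2")
#' convention. Populations are pre-sorted lexicographically so ties break
#' deterministically.
#'
#' @param rel a `relative_ancestry` (or a bare matrix of row vectors).
#' @return an [ape::phylo] tree over populations (class `phylo`), with merge
#'   heights preserved as branch lengths.
#' @export
ward_tree <- function(rel) {
  m <- if (inherits(rel, "relative_ancestry")) rel$proportions else rel
  if (nrow(m) < 2) stop("need >= 2 populations to build a tree")
  m <- m[order(rownames(m)), , drop = FALSE]
  hc <- hclust(dist(m, method = "euclidean"), method = "ward.D2")
  tr <- ape::as.phylo(hc)
  attr(tr, "heights") <- hc$height
  tr
}

#' Bootstrap replicate population copying vectors
#'
#' Emulates resampling of painted genomes: for each replicate and population
#' of size `n`, `n` pseudo-individuals are assembled by drawing, for every
#' chromosome independently, that chromosome's painting (both haplotypes of
#' one member together) uniformly with replacement from the population's
#' members. Each pseudo-individual's copying vector is the normalized sum of
#' its 22 (or however many) chromosome paintings; the replicate population
#' vector is the renormalized mean over pseudo-individuals.
#'
#' @param ps a `painting_set` of the population's member individuals.
#' @param n_reps number of bootstrap replicates (>= 1); production analyses
#'   use 1000.
#' @param seed integer seed.
#' @param members member sample ids; default all targets of `ps`.
#' @param weight `"sites"` or `"morgans"`.
#' @param per_haplotype if `TRUE`, the two haplotypes of a chromosome are
#'   resampled from (possibly) different members; default `FALSE` samples at
#'   the diploid-chromosome level.
#' @return matrix, n_reps x donor groups, each row a copying vector.
#' @export
bootstrap_populations <- function(ps, n_reps, seed = 1L, members = NULL,
                                  weight = "sites", per_haplotype = FALSE) {
  if (!is.numeric(n_reps) || n_reps < 1) stop("n_reps must be >= 1")
  if (is.null(members)) members <- ps$targets
  ps <- subset_painting(ps, members)
  a <- ps[[weight]]
  n <- length(members)
  n_chrom <- length(ps$chroms)
  if (any(apply(a, c(1, 3), sum) <= 0))
    stop("missing chromosome painting for some member")
  set.seed(seed)
  out <- matrix(0, n_reps, length(ps$groups),
                dimnames = list(NULL, ps$groups))
  for (r in seq_len(n_reps)) {
    pseudo <- matrix(0, n, length(ps$groups))
    for (i in seq_len(n)) {
      pick <- sample.int(n, n_chrom, replace = TRUE)
      v <- numeric(length(ps$groups))
      for (cc in seq_len(n_chrom)) {
        if (per_haplotype) {
          pick2 <- sample.int(n, 1L)
          v <- v + a[cc, , pick[cc]] / 2 + a[cc, , pick2] / 2
        } else {
          v <- v + a[cc, , pick[cc]]
        }
      }
      pseudo[i, ] <- v / sum(v)
    }
    pv <- colMeans(pseudo)
    out[r, ] <- pv / sum(pv)
  }
  out
}

#' Bootstrap consensus tree of relative continental ancestry
#'
#' For each bootstrap replicate: resample every population's painted
#' chromosomes ([bootstrap_populations()]), refit the mixture, restrict to
#' one continent and renormalize, and build the Ward tree; then return the
#' consensus of the replicate trees at the given support threshold.
#'
#' @param ps_by_pop named list of `painting_set`s, one per recipient
#'   population (targets = its member individuals), aggregated to the basis'
#'   coordinate groups.
#' @param basis a `donor_basis`.
#' @param cmap a [continent_map()].
#' @param continent continent to restrict to.
#' @param n_reps bootstrap replicates.
#' @param threshold support threshold (strictly greater-than retention).
#' @param masked coordinates masked in every refit.
#' @param min_total exclusion threshold passed to [relative_composition()].
#' @param seed integer seed.
#' @param by `"cluster"` or `"region"` aggregation of relative proportions.
#' @return list: `consensus` (a `supported_tree`), `trees` (replicate
#'   [ape::phylo] list), `observed` (the point-estimate Ward tree).
#' @export
bootstrap_consensus <- function(ps_by_pop, basis, cmap, continent,
                                n_reps = 1000, threshold = 0.8,
                                masked = character(0), min_total = 0.01,
                                seed = 1L, by = "cluster") {
  reps <- lapply(seq_along(ps_by_pop), function(i)
    bootstrap_populations(ps_by_pop[[i]], n_reps, seed = seed + i * 131L))
  names(reps) <- names(ps_by_pop)
  # observed (non-resampled) tree
  obs_sol <- lapply(names(ps_by_pop), function(p) {
    pops <- setNames(rep(p, length(ps_by_pop[[p]]$targets)),
                     ps_by_pop[[p]]$targets)
    cv <- copying_vectors(ps_by_pop[[p]], level = "population",
                          populations = pops)
    mask_and_refit(cv[p, ], basis, masked)
  })
  names(obs_sol) <- names(ps_by_pop)
  obs_rel <- relative_composition(obs_sol, cmap, continent,
                                  min_total = min_total, by = by)
  keep_pops <- rownames(obs_rel$proportions)
  trees <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    sols <- lapply(names(reps), function(p)
      mask_and_refit(reps[[p]][r, ], basis, masked))
    names(sols) <- names(reps)
    rel <- relative_composition(sols[keep_pops], cmap, continent,
                                min_total = 0, by = by)
    trees[[r]] <- ward_tree(rel)
  }
  list(consensus = consensus_tree(trees, threshold = threshold),
       trees = trees, observed = ward_tree(obs_rel))
}

#' Consensus tree with strict support threshold
#'
#' Tallies rooted clades across trees on a common leaf set and retains those
#' whose frequency is strictly greater than `threshold` (so a clade at
#' exactly the threshold is dropped). Retained clades are mutually compatible
#' for thresholds >= 0.5 and are assembled into a (possibly multifurcating)
#' rooted tree, with supports attached as internal node labels.
#'
#' @param trees list of rooted [ape::phylo] trees on identical leaf sets.
#' @param threshold retention threshold in \[0.5, 1).
#' @return a `supported_tree`: list with `tree` (an `ape::phylo`, node labels
#'   = supports), `clades` (list of retained leaf subsets), `support` (their
#'   frequencies).
#' @export
consensus_tree <- function(trees, threshold = 0.8) {
  if (threshold < 0.5 || threshold >= 1)
    stop("threshold must be in [0.5, 1)")
  if (!length(trees)) stop("no trees supplied")
  leaves <- sort(trees[[1]]$tip.label)
  for (t in trees)
    if (!identical(sort(t$tip.label), leaves))
      stop("trees have inconsistent leaf sets")
  n_tree <- length(trees)
  # tally rooted clades; ape::prop.part counts clades across the tree list
  pp <- ape::prop.part(trees)
  counts <- attr(pp, "number")
  labels_of <- attr(pp, "labels")
  clades <- lapply(pp, function(ix) sort(labels_of[ix]))
  freq <- counts / n_tree
  sel <- freq > threshold
  # always keep the root clade (all leaves), support 1 by construction
  keep_clades <- clades[sel]
  keep_freq <- freq[sel]
  # drop trivial singletons if any, ensure root present
  sz <- lengths(keep_clades)
  ord <- order(-sz)
  keep_clades <- keep_clades[ord]
  keep_freq <- keep_freq[ord]
  if (!length(keep_clades) || length(keep_clades[[1]]) < length(leaves)) {
    keep_clades <- c(list(leaves), keep_clades)
    keep_freq <- c(1, keep_freq)
  }
  # recursive nesting: children of a clade are the maximal retained clades
  # strictly inside it, plus bare leaves not covered by any child
  build <- function(ci) {
    clade <- keep_clades[[ci]]
    inside <- which(vapply(keep_clades, function(x)
      length(x) < length(clade) && all(x %in% clade), TRUE))
    # maximal ones only
    maximal <- inside[vapply(inside, function(i) {
      !any(vapply(inside, function(j)
        i != j && length(keep_clades[[i]]) < length(keep_clades[[j]]) &&
          all(keep_clades[[i]] %in% keep_clades[[j]]), TRUE))
    }, TRUE)]
    covered <- unique(unlist(keep_clades[maximal]))
    parts <- c(lapply(maximal, build),
               as.list(setdiff(clade, covered)))
    paste0("(", paste(unlist(parts), collapse = ","), ")",
           format(keep_freq[ci], digits = 3))
  }
  nwk <- paste0(build(1L), ";")
  tree <- ape::read.tree(text = nwk)
  structure(list(tree = tree, clades = keep_clades, support = keep_freq),
            class = "supported_tree")
}

#' @export
print.supported_tree <- function(x, ...) {
  cat("supported_tree with", length(x$tree$tip.label), "leaves and",
      length(x$clades), "retained clade(s)\n")
  print(x$tree)
  invisible(x)
}

#' Does a consensus tree contain a given clade?
#'
#' @param st a `supported_tree`.
#' @param members character vector of leaf labels.
#' @return the clade's support if present (numeric), otherwise `NA`.
#' @export
clade_support <- function(st, members) {
  members <- sort(members)
  for (i in seq_along(st$clades))
    if (identical(st$clades[[i]], members)) return(st$support[i])
  NA_real_
}
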