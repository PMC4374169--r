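#' Copying-model parameters
#'
#' Parameters of the Li-Stephens copying HMM: `ne`, the recombination scaling
#' constant (dimensionless; multiplies genetic distance in Morgans to give
#' the switch rate between donor haplotypes), `theta`, the per-site miscopy
#' ("mutation") probability, and an optional prior over donor haplotypes.
#' The shipped defaults `ne = 267`, `theta = 0.00043` are the values used for
#' genome-wide human panels after EM estimation; both can be re-estimated for
#' any data set with [estimate_params_em()].
#'
#' @param ne recombination scaling constant, > 0.
#' @param theta per-site miscopy probability in (0, 0.5).
#' @param donor_prior optional per-donor-haplotype prior weights (sum to 1);
#'   `NULL` means uniform.
#' @return a `copying_model_params` list.
#' @export
copying_model_params <- function(ne = 267, theta = 0.00043,
                                 donor_prior = NULL) {
  if (!is.numeric(ne) || ne <= 0) stop("ne must be > 0")
  if (!is.numeric(theta) || theta <= 0 || theta >= 0.5)
    stop("theta must be in (0, 0.5)")
  if (!is.null(donor_prior)) {
    if (any(donor_prior < 0) || abs(sum(donor_prior) - 1) > 1e-12)
      stop("donor_prior must be non-negative and sum to 1")
  }
  structure(list(ne = ne, theta = theta, donor_prior = donor_prior),
            class = "copying_model_params")
}

#' Paint one target haplotype against a set of donor haplotypes
#'
#' Runs the forward-backward algorithm of the copying HMM on one chromosome:
#' the hidden state at each site is the donor haplotype being copied;
#' transitions across an inter-site distance of `g` Morgans stay on the
#' current donor with probability `exp(-ne * g)` and otherwise jump to a
#' donor drawn from the prior (a jump landing on the same donor is not a
#' chunk boundary); emissions are `1 - theta` on allele match, `theta` on
#' mismatch, and 1 when the target allele is missing.
#'
#' @param target integer vector of 0/1/NA target alleles (one chromosome).
#' @param donors k x L matrix of donor alleles (0/1).
#' @param donor_groups length-k character vector assigning each donor
#'   haplotype to a donor group (e.g. population or cluster).
#' @param gpos length-L genetic positions in Morgans, non-decreasing.
#' @param params a [copying_model_params()].
#' @param posterior return the k x L per-site copying posterior?
#' @param viterbi return the most likely donor mosaic (site -> donor row)?
#' @param min_g floor for inter-site distances, Morgans.
#' @return a `painting_result` list: per-group `expected_chunk_count`,
#'   `expected_copied_sites`, `expected_copied_morgans`; `log_likelihood`;
#'   EM accumulators (`expected_mismatch`, `expected_jumps`, `n_observed`);
#'   optional `posterior` and `viterbi`.
#' @export
paint_haplotype <- function(target, donors, donor_groups, gpos, params,
                            posterior = FALSE, viterbi = FALSE,
                            min_g = 1e-9) {
  donors <- as.matrix(donors)
  storage.mode(donors) <- "integer"
  k <- nrow(donors)
  if (k == 0) stop("donor set is empty")
  if (length(donor_groups) != k)
    stop("donor_groups must have one entry per donor haplotype")
  if (length(gpos) != length(target) || ncol(donors) != length(target))
    stop("target, donors and gpos must cover the same sites")
  prior <- params$donor_prior
  if (is.null(prior)) prior <- rep(1 / k, k)
  if (length(prior) != k) stop("donor_prior length must equal donor count")
  res <- .ls_paint_cpp(as.integer(target), donors, site_gaps(gpos, min_g),
                       params$ne, params$theta, prior, posterior, viterbi)
  grp <- factor(donor_groups, levels = unique(donor_groups))
  agg <- function(v) drop(rowsum(v, grp))[levels(grp)]
  out <- list(expected_chunk_count = agg(res$expected_chunks),
              expected_copied_sites = agg(res$expected_sites),
              expected_copied_morgans = agg(res$expected_morgans),
              log_likelihood = res$log_likelihood,
              expected_mismatch = res$expected_mismatch,
              expected_jumps = res$expected_jumps,
              n_observed = res$n_observed)
  if (posterior) out$posterior <- res$posterior
  if (viterbi) out$viterbi <- res$viterbi
  class(out) <- "painting_result"
  out
}

#' Paint a set of target samples across a whole panel
#'
#' Paints both haplotypes of every target sample, chromosome by chromosome,
#' against the panel's donor haplotypes. In recipient mode (targets are not
#' donors) the full donor set is used; in donor-vs-donor mode
#' (`leave_self_out = TRUE`, the default) each target's own two haplotypes
#' are excluded from its donor set, which is how donors themselves are
#' painted prior to clustering.
#'
#' Per-chromosome expectations are retained separately (the jackknife and the
#' bootstrap need them); per-individual totals are sums over the two
#' haplotypes.
#'
#' @param panel a [haplotype_panel()].
#' @param targets sample ids to paint; default all recipient-role samples.
#' @param donor_grouping named character vector mapping donor sample id to a
#'   donor group; its names define the donor set. Default: all donor-role
#'   samples, grouped by population label. Use an identity mapping
#'   (`setNames(ids, ids)`) to keep per-donor-individual resolution for
#'   clustering.
#' @param params a [copying_model_params()].
#' @param leave_self_out exclude a target's own haplotypes from its donor set
#'   when the target is itself a donor (the standard donor-vs-donor
#'   protocol). `FALSE` keeps the target's own haplotypes in the pool, which
#'   places posterior mass on the exact self-match: only meaningful for
#'   calibrating a donor basis against recipients whose tracts are literal
#'   copies of pool haplotypes (see the methods vignette).
#' @return a `painting_set`: arrays `sites`, `morgans`, `chunks` with
#'   dimensions (chromosome, donor group, target sample), a `loglik`
#'   chromosome x target matrix, and metadata.
#' @export
paint_panel <- function(panel, targets = NULL, donor_grouping = NULL,
                        params = copying_model_params(),
                        leave_self_out = TRUE) {
  if (is.null(donor_grouping)) {
    don <- panel$sample_ids[panel$role == "donor"]
    donor_grouping <- setNames(unname(panel$populations[don]), don)
  }
  if (is.null(targets)) targets <- panel$sample_ids[panel$role == "recipient"]
  if (!length(targets)) stop("no target samples to paint")
  donors <- names(donor_grouping)
  bad <- setdiff(c(donors, targets), panel$sample_ids)
  if (length(bad)) stop("unknown sample id(s): ", paste(bad, collapse = ", "))
  groups <- unique(unname(donor_grouping))
  chrom_idx <- sites_by_chrom(panel)
  chroms <- names(chrom_idx)
  dn <- list(chroms, groups, targets)
  arr <- function() array(0, dim = c(length(chroms), length(groups),
                                     length(targets)), dimnames = dn)
  sites_a <- arr(); morgans_a <- arr(); chunks_a <- arr()
  loglik <- matrix(0, length(chroms), length(targets),
                   dimnames = list(chroms, targets))
  donor_rows_all <- which(panel$hap_sample %in% donors)
  for (t in seq_along(targets)) {
    tid <- targets[t]
    rows <- donor_rows_all
    if (tid %in% donors && leave_self_out)
      rows <- rows[panel$hap_sample[rows] != tid]
    if (!length(rows)) stop("empty donor set after self-exclusion for ", tid)
    hap_groups <- unname(donor_grouping[panel$hap_sample[rows]])
    target_rows <- which(panel$hap_sample == tid)
    for (ci in seq_along(chroms)) {
      idx <- chrom_idx[[ci]]
      gpos <- panel$sites$gpos[idx]
      dmat <- panel$alleles[rows, idx, drop = FALSE]
      for (tr in target_rows) {
        pr <- paint_haplotype(panel$alleles[tr, idx], dmat, hap_groups, gpos,
                              params)
        sites_a[ci, names(pr$expected_copied_sites), t] <-
          sites_a[ci, names(pr$expected_copied_sites), t] +
          pr$expected_copied_sites
        morgans_a[ci, names(pr$expected_copied_morgans), t] <-
          morgans_a[ci, names(pr$expected_copied_morgans), t] +
          pr$expected_copied_morgans
        chunks_a[ci, names(pr$expected_chunk_count), t] <-
          chunks_a[ci, names(pr$expected_chunk_count), t] +
          pr$expected_chunk_count
        loglik[ci, t] <- loglik[ci, t] + pr$log_likelihood
      }
    }
  }
  structure(list(sites = sites_a, morgans = morgans_a, chunks = chunks_a,
                 loglik = loglik, targets = targets, groups = groups,
                 chroms = chroms, params = params),
            class = "painting_set")
}

#' @export
print.painting_set <- function(x, ...) {
  cat("painting_set:", length(x$targets), "targets x", length(x$groups),
      "donor groups over", length(x$chroms), "chromosome(s)\n")
  invisible(x)
}

#' Re-aggregate a painting set under a coarser donor grouping
#'
#' Sums the per-group expectations of a `painting_set` according to a mapping
#' from current groups to coarser groups (e.g. donor individuals to MAP
#' clusters), so a panel painted once at individual resolution can be reused
#' at any clustering level.
#'
#' @param ps a `painting_set`.
#' @param mapping named character vector: current group -> new group.
#' @return a `painting_set` over the new groups.
#' @export
aggregate_painting <- function(ps, mapping) {
  miss <- setdiff(ps$groups, names(mapping))
  if (length(miss))
    stop("mapping is missing group(s): ", paste(miss, collapse = ", "))
  new_groups <- unique(unname(mapping[ps$groups]))
  squash <- function(a) {
    out <- array(0, dim = c(dim(a)[1], length(new_groups), dim(a)[3]),
                 dimnames = list(ps$chroms, new_groups, ps$targets))
    for (g in ps$groups) {
      ng <- unname(mapping[g])
      out[, ng, ] <- out[, ng, ] + a[, g, ]
    }
    out
  }
  ps$sites <- squash(ps$sites)
  ps$morgans <- squash(ps$morgans)
  ps$chunks <- squash(ps$chunks)
  ps$groups <- new_groups
  ps
}

#' Subset a painting set to a set of target samples
#'
#' @param ps a `painting_set`.
#' @param targets sample ids to retain.
#' @return the restricted `painting_set`.
#' @export
subset_painting <- function(ps, targets) {
  miss <- setdiff(targets, ps$targets)
  if (length(miss))
    stop("unknown painting target(s): ", paste(miss, collapse = ", "))
  for (nm in c("sites", "morgans", "chunks"))
    ps[[nm]] <- ps[[nm]][, , targets, drop = FALSE]
  ps$loglik <- ps$loglik[, targets, drop = FALSE]
  ps$targets <- targets
  ps
}

#' Copying vectors from a painting set
#'
#' The copying vector of an individual is its genome-wide expected copied
#' weight (SNP count or Morgans) from each donor group, over both haplotypes
#' and all chromosomes, normalized to sum to 1. A population's copying vector
#' is the mean of its members' vectors, renormalized.
#'
#' @param ps a `painting_set`.
#' @param level `"individual"` or `"population"`.
#' @param weight `"sites"` (default) or `"morgans"`.
#' @param populations named character vector mapping target sample id to
#'   population (required for `level = "population"`).
#' @param exclude_chrom optional chromosome name(s) to drop before summing
#'   (used by the jackknife).
#' @return matrix with one row per individual or population, columns = donor
#'   groups, rows summing to 1.
#' @export
copying_vectors <- function(ps, level = c("individual", "population"),
                            weight = c("sites", "morgans"),
                            populations = NULL, exclude_chrom = NULL) {
  level <- match.arg(level)
  weight <- match.arg(weight)
  a <- ps[[weight]]
  keep <- setdiff(ps$chroms, exclude_chrom)
  if (!length(keep)) stop("no chromosomes left")
  a <- a[keep, , , drop = FALSE]
  m <- apply(a, c(3, 2), sum)
  dimnames(m) <- list(ps$targets, ps$groups)
  tot <- rowSums(m)
  if (any(tot <= 0)) stop("zero total copied weight for some target")
  m <- m / tot
  if (level == "individual") return(m)
  if (is.null(populations)) stop("populations mapping required")
  pop <- unname(populations[rownames(m)])
  if (anyNA(pop)) stop("populations mapping missing some targets")
  # mean member vector renormalized == renormalized sum of member vectors
  pm <- rowsum(m, pop)
  pm / rowSums(pm)
}

#' Integer chunk-count matrix for donor clustering
#'
#' Sums expected chunk counts over chromosomes and both haplotypes per target
#' and rounds to the nearest integer, yielding the count matrix scored by the
#' Dirichlet-multinomial clustering model.
#'
#' @param ps a `painting_set` (typically donors painted leave-self-out at
#'   individual resolution).
#' @return integer matrix, targets x donor groups.
#' @export
chunk_count_matrix <- function(ps) {
  m <- apply(ps$chunks, c(3, 2), sum)
  dimnames(m) <- list(ps$targets, ps$groups)
  storage.mode(m) <- "double"
  m <- round(m)
  storage.mode(m) <- "integer"
  m
}

#' Estimate copying-model parameters by EM
#'
#' Runs expectation-maximization for the recombination scaling constant `ne`
#' and miscopy rate `theta` on a subset of (population, chromosome) cells,
#' then averages the per-cell estimates -- the standard practice of
#' estimating these nuisance parameters on a representative subset. Within a
#' cell, each donor individual of the population is painted leave-self-out
#' against all donors; the M-step sets `theta` to expected mismatch emissions
#' per observed site and `ne` to the value matching the expected number of
#' donor switches via `sum(1 - exp(-ne * g)) = E[switches]` (monotone 1-D
#' root solve).
#'
#' @param panel a [haplotype_panel()].
#' @param populations populations whose members are painted; default all
#'   donor populations.
#' @param chromosomes chromosomes to use; default all.
#' @param n_iter number of EM iterations (>= 1; default 10).
#' @param init initial [copying_model_params()].
#' @param donor_populations populations supplying the donor pool; default all
#'   donor-role samples (each painted target always excludes its own
#'   haplotypes).
#' @return the averaged [copying_model_params()], with attribute `per_cell`
#'   giving the per-(population, chromosome) estimates.
#' @export
estimate_params_em <- function(panel, populations = NULL, chromosomes = NULL,
                               n_iter = 10,
                               init = copying_model_params(ne = 100,
                                                           theta = 0.01),
                               donor_populations = NULL) {
  if (!is.numeric(n_iter) || n_iter < 1) stop("n_iter must be >= 1")
  donors <- panel$sample_ids[panel$role == "donor"]
  if (is.null(populations))
    populations <- unique(unname(panel$populations[donors]))
  pool <- if (is.null(donor_populations)) donors
          else donors[panel$populations[donors] %in% donor_populations]
  if (!length(pool)) stop("empty donor pool")
  if (is.null(chromosomes)) chromosomes <- unique(panel$sites$chrom)
  chrom_idx <- sites_by_chrom(panel)
  cells <- expand.grid(pop = populations, chrom = chromosomes,
                       stringsAsFactors = FALSE)
  if (!nrow(cells)) stop("empty (population, chromosome) subset")
  est <- matrix(NA_real_, nrow(cells), 2, dimnames = list(NULL, c("ne", "theta")))
  for (ce in seq_len(nrow(cells))) {
    pop <- cells$pop[ce]; cc <- cells$chrom[ce]
    tids <- donors[panel$populations[donors] == pop]
    if (!length(tids)) stop("no donor samples in population ", pop)
    idx <- chrom_idx[[cc]]
    gpos <- panel$sites$gpos[idx]
    gaps <- site_gaps(gpos)
    ne <- init$ne; theta <- init$theta
    for (it in seq_len(n_iter)) {
      pm <- copying_model_params(ne = ne, theta = theta)
      mismatch <- 0; observed <- 0; jumps <- 0; n_painted <- 0L
      for (tid in tids) {
        rows <- which(panel$hap_sample %in% pool & panel$hap_sample != tid)
        dmat <- panel$alleles[rows, idx, drop = FALSE]
        for (tr in which(panel$hap_sample == tid)) {
          pr <- paint_haplotype(panel$alleles[tr, idx], dmat,
                                rep("all", length(rows)), gpos, pm)
          mismatch <- mismatch + pr$expected_mismatch
          observed <- observed + pr$n_observed
          jumps <- jumps + pr$expected_jumps
          n_painted <- n_painted + 1L
        }
      }
      theta <- min(max(mismatch / observed, 1e-8), 0.499)
      f <- function(x) n_painted * sum(1 - exp(-x * gaps)) - jumps
      ne <- if (jumps <= 1e-12) 1e-6
            else if (f(1e8) < 0) 1e8
            else uniroot(f, c(1e-8, 1e8), tol = 1e-10)$root
    }
    est[ce, ] <- c(ne, theta)
  }
  out <- copying_model_params(ne = mean(est[, "ne"]),
                              theta = mean(est[, "theta"]))
  attr(out, "per_cell") <- cbind(cells, est)
  out
}
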