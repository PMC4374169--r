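#' Approximate genetic lengths of the 22 human autosomes
#'
#' Genetic lengths in Morgans (sex-averaged, build-37 scale, ~35.9 M total),
#' used as the default chromosome structure of the donor-pool generator so
#' that downstream leave-one-chromosome-out jackknifes run over 22
#' chromosomes, as in genome-wide human analyses.
#'
#' @return numeric vector of length 22, names "1".."22".
#' @export
human_autosome_lengths <- function() {
  setNames(c(2.86, 2.69, 2.23, 2.14, 2.04, 1.92, 1.87, 1.70, 1.68, 1.81,
             1.58, 1.75, 1.26, 1.20, 1.42, 1.35, 1.30, 1.19, 1.08, 1.08,
             0.62, 0.74),
           as.character(1:22))
}

#' Specification of a structured donor pool
#'
#' Per-population allele frequencies are drawn by Balding-Nichols beta
#' perturbation of a shared ancestral frequency: with divergence parameter
#' `F`, population frequency ~ Beta(p(1-F)/F, (1-p)(1-F)/F), so `F = 0`
#' means all populations share identical frequencies and larger `F` means
#' stronger drift apart.
#'
#' @param n_pops number of donor populations (>= 1).
#' @param haps_per_pop phased haplotypes per population (>= 2, i.e. >= 1
#'   diploid sample; must be even).
#' @param n_sites total number of SNP sites across all chromosomes (>= 2).
#' @param chrom_lengths_morgans per-chromosome genetic lengths in Morgans;
#'   defaults to the realistic 22-autosome map of
#'   [human_autosome_lengths()], so jackknife and bootstrap operate over 22
#'   chromosomes.
#' @param divergence Balding-Nichols divergence in \[0, 1\].
#' @param linkage_ne optional within-population copying rate (per Morgan)
#'   used to induce background linkage: each haplotype after the second is
#'   built as a mosaic of previously generated haplotypes of its population,
#'   with 5% residual site-wise resampling. `NULL` (default) draws all sites
#'   independently.
#' @param seed integer seed.
#' @return a `donor_pool_spec` list.
#' @export
donor_pool_spec <- function(n_pops, haps_per_pop, n_sites,
                            chrom_lengths_morgans = human_autosome_lengths(),
                            divergence = 0.1, linkage_ne = NULL, seed = 1L) {
  if (!is.numeric(n_pops) || n_pops < 1) stop("invalid n_pops: must be >= 1")
  if (!is.numeric(haps_per_pop) || haps_per_pop < 2)
    stop("invalid haps_per_pop: must be >= 2")
  if (haps_per_pop %% 2 != 0)
    stop("invalid haps_per_pop: must be even (two haplotypes per sample)")
  if (!is.numeric(n_sites) || n_sites < 2) stop("invalid n_sites: must be >= 2")
  if (!is.numeric(divergence) || divergence < 0 || divergence > 1)
    stop("invalid divergence: must be in [0, 1]")
  if (any(chrom_lengths_morgans <= 0))
    stop("invalid chrom_lengths_morgans: lengths must be positive")
  if (is.null(names(chrom_lengths_morgans)))
    names(chrom_lengths_morgans) <- as.character(seq_along(chrom_lengths_morgans))
  structure(list(n_pops = as.integer(n_pops),
                 haps_per_pop = as.integer(haps_per_pop),
                 n_sites = as.integer(n_sites),
                 chrom_lengths_morgans = chrom_lengths_morgans,
                 divergence = divergence, linkage_ne = linkage_ne,
                 seed = as.integer(seed)),
            class = "donor_pool_spec")
}

# lay n_sites out over chromosomes proportionally to genetic length, with
# strictly increasing genetic and physical positions (1 cM ~ 1 Mb)
make_site_table <- function(n_sites, chrom_lengths) {
  n_chrom <- length(chrom_lengths)
  per <- pmax(2L, floor(n_sites * chrom_lengths / sum(chrom_lengths)))
  # distribute the remainder over the longest chromosomes
  while (sum(per) > n_sites) {
    i <- which.max(per)
    per[i] <- per[i] - 1L
  }
  while (sum(per) < n_sites) {
    i <- which.max(chrom_lengths / per)
    per[i] <- per[i] + 1L
  }
  if (any(per < 2L))
    stop("too few sites (", n_sites, ") to place >= 2 on each of ", n_chrom,
         " chromosomes")
  do.call(rbind, lapply(seq_len(n_chrom), function(i) {
    g <- sort(runif(per[i], 0, chrom_lengths[i]))
    # enforce strict increase
    g <- cummax(g + seq_along(g) * 1e-12)
    pos <- as.integer(round(g * 1e8)) # 1 Morgan ~ 100 Mb
    pos <- pos + seq_along(pos)       # strictly increasing bp
    data.frame(chrom = names(chrom_lengths)[i], pos = pos, gpos = g,
               stringsAsFactors = FALSE)
  }))
}

#' Simulate a phased donor pool with population structure
#'
#' Draws a shared ancestral allele frequency per site, perturbs it per
#' population with the Balding-Nichols beta model, and samples phased
#' haplotypes site-wise from the population frequencies (optionally with
#' background linkage via a within-population copying process). Populations
#' are labelled `pop1..popN`, samples `pop<i>_s<j>`.
#'
#' @param spec a [donor_pool_spec()].
#' @return a [haplotype_panel()] of donors.
#' @export
simulate_donor_pool <- function(spec) {
  stopifnot(inherits(spec, "donor_pool_spec"))
  set.seed(spec$seed)
  sites <- make_site_table(spec$n_sites, spec$chrom_lengths_morgans)
  L <- nrow(sites)
  p_anc <- runif(L, 0.05, 0.95)
  F <- spec$divergence
  freqs <- matrix(0, spec$n_pops, L)
  for (i in seq_len(spec$n_pops)) {
    freqs[i, ] <- if (F == 0) {
      p_anc
    } else if (F >= 1) {
      rbinom(L, 1L, p_anc)
    } else {
      rbeta(L, p_anc * (1 - F) / F, (1 - p_anc) * (1 - F) / F)
    }
  }
  n_haps <- spec$n_pops * spec$haps_per_pop
  alleles <- matrix(0L, n_haps, L)
  row <- 0L
  gaps_by_chrom <- lapply(split(sites$gpos, sites$chrom)[unique(sites$chrom)],
                          site_gaps)
  chrom_idx <- split(seq_len(L), sites$chrom)[unique(sites$chrom)]
  for (i in seq_len(spec$n_pops)) {
    pf <- freqs[i, ]
    pop_rows <- integer(0)
    for (h in seq_len(spec$haps_per_pop)) {
      row <- row + 1L
      if (is.null(spec$linkage_ne) || h <= 2L) {
        alleles[row, ] <- rbinom(L, 1L, pf)
      } else {
        # mosaic of previously generated haplotypes of this population
        hap <- integer(L)
        for (ci in seq_along(chrom_idx)) {
          idx <- chrom_idx[[ci]]
          src <- sample(pop_rows, 1L)
          for (j in seq_along(idx)) {
            if (j > 1L &&
                runif(1) < 1 - exp(-spec$linkage_ne * gaps_by_chrom[[ci]][j - 1L]))
              src <- sample(pop_rows, 1L)
            hap[idx[j]] <- alleles[src, idx[j]]
          }
        }
        resample <- runif(L) < 0.05
        hap[resample] <- rbinom(sum(resample), 1L, pf[resample])
        alleles[row, ] <- hap
      }
      pop_rows <- c(pop_rows, row)
    }
  }
  n_samp <- n_haps %/% 2L
  samp_per_pop <- spec$haps_per_pop %/% 2L
  pops <- rep(paste0("pop", seq_len(spec$n_pops)), each = samp_per_pop)
  ids <- paste0(pops, "_s", rep(seq_len(samp_per_pop), spec$n_pops))
  haplotype_panel(alleles, ids, setNames(pops, ids), sites,
                  setNames(rep("donor", n_samp), ids))
}

#' Specification of an admixture event
#'
#' Recipients are built as mosaics of donor haplotypes: ancestry switch
#' points fall as a Poisson process on the genetic map with rate
#' `generations` per Morgan (the standard model for admixture-tract lengths
#' `generations` generations after a pulse of admixture), each tract's source
#' population is drawn from `proportions`, and the tract copies one randomly
#' chosen donor haplotype of that population.
#'
#' @param proportions named numeric vector of admixture proportions by donor
#'   population; non-negative, summing to 1 within 1e-12.
#' @param generations positive number of generations since admixture.
#' @param n_recipients number of diploid recipient individuals.
#' @param theta_sim per-site miscopy probability when copying donor tracts
#'   (default 0: exact copy, cleanest ground truth).
#' @param seed integer seed.
#' @return an `admixture_spec` list.
#' @export
admixture_spec <- function(proportions, generations, n_recipients,
                           theta_sim = 0, seed = 1L) {
  if (is.null(names(proportions)) || any(!nzchar(names(proportions))))
    stop("invalid proportions: must be named by donor population")
  if (any(proportions < 0)) stop("invalid proportions: must be non-negative")
  if (abs(sum(proportions) - 1) > 1e-12)
    stop("invalid proportions: must sum to 1 (got ", sum(proportions), ")")
  if (!is.numeric(generations) || generations <= 0)
    stop("invalid generations: must be > 0")
  if (!is.numeric(n_recipients) || n_recipients < 1)
    stop("invalid n_recipients: must be >= 1")
  if (theta_sim < 0 || theta_sim >= 0.5)
    stop("invalid theta_sim: must be in [0, 0.5)")
  structure(list(proportions = proportions, generations = generations,
                 n_recipients = as.integer(n_recipients),
                 theta_sim = theta_sim, seed = as.integer(seed)),
            class = "admixture_spec")
}

#' Simulate admixed recipients from a donor pool
#'
#' Walks the genetic map of each recipient haplotype, placing ancestry
#' switch points as a Poisson process of rate `generations` per Morgan,
#' drawing each tract's source population from the admixture proportions and
#' copying a random donor haplotype of that population over the tract.
#' Returns the recipients plus a ground-truth tract table (0-based,
#' half-open site intervals that tile each chromosome).
#'
#' @param panel donor [haplotype_panel()].
#' @param spec an [admixture_spec()].
#' @param population population label given to the recipients (default
#'   `"admixed"`); also used as the sample-id prefix, so several recipient
#'   populations can be simulated from one donor pool and combined with
#'   [bind_panels()].
#' @return list with elements `panel` (recipients only), `tracts`
#'   (data.frame: recipient_hap_id, chrom, start_site, end_site, source_pop,
#'   with site indices 0-based half-open, per chromosome), and `n_switches`
#'   (per recipient haplotype, the raw count of Poisson switch points, before
#'   any collapsing onto the site grid).
#' @export
simulate_admixed <- function(panel, spec, population = "admixed") {
  stopifnot(inherits(panel, "haplotype_panel"), inherits(spec, "admixture_spec"))
  pops <- names(spec$proportions)
  unknown <- setdiff(pops, unique(panel$populations))
  if (length(unknown))
    stop("unknown source population(s): ", paste(unknown, collapse = ", "))
  set.seed(spec$seed)
  hap_rows_by_pop <- lapply(setNames(pops, pops), function(p)
    which(panel$hap_sample %in% names(panel$populations)[panel$populations == p]))
  chrom_idx <- sites_by_chrom(panel)
  chroms <- names(chrom_idx)
  L <- n_sites(panel)
  n_hap <- 2L * spec$n_recipients
  alleles <- matrix(0L, n_hap, L)
  ids <- paste0(population, "_s", seq_len(spec$n_recipients))
  hap_ids <- paste0(rep(ids, each = 2L), "_", 1:2)
  tracts <- vector("list", n_hap * length(chroms))
  n_switches <- setNames(integer(n_hap), hap_ids)
  ti <- 0L
  for (h in seq_len(n_hap)) {
    for (ci in seq_along(chroms)) {
      idx <- chrom_idx[[ci]]
      g <- panel$sites$gpos[idx]
      len <- max(g) - min(g)
      n_sw <- rpois(1L, spec$generations * len)
      n_switches[h] <- n_switches[h] + n_sw
      sw <- sort(runif(n_sw, min(g), max(g)))
      # tract boundaries in site-index space: switch between sites l, l+1
      # when a switch point falls in (g_l, g_{l+1}]
      cuts <- unique(findInterval(sw, g, left.open = TRUE))
      cuts <- cuts[cuts > 0 & cuts < length(idx)]
      starts <- c(0L, cuts)
      ends <- c(cuts, length(idx))
      src_pops <- sample(pops, length(starts), replace = TRUE,
                         prob = spec$proportions)
      for (t in seq_along(starts)) {
        src_hap <- sample(hap_rows_by_pop[[src_pops[t]]], 1L)
        span <- idx[(starts[t] + 1L):ends[t]]
        seg <- panel$alleles[src_hap, span]
        if (spec$theta_sim > 0) {
          flip <- runif(length(seg)) < spec$theta_sim
          seg[flip] <- 1L - seg[flip]
        }
        alleles[h, span] <- seg
        ti <- ti + 1L
        tracts[[ti]] <- data.frame(
          recipient_hap_id = hap_ids[h], chrom = chroms[ci],
          start_site = starts[t], end_site = ends[t],
          source_pop = src_pops[t], stringsAsFactors = FALSE)
      }
    }
  }
  rec <- haplotype_panel(alleles, ids,
                         setNames(rep(population, length(ids)), ids),
                         panel$sites,
                         setNames(rep("recipient", length(ids)), ids))
  list(panel = rec, tracts = do.call(rbind, tracts[seq_len(ti)]),
       n_switches = n_switches)
}

#' True genome-wide ancestry fractions from a tract table
#'
#' Length-weighted (in Morgans) ancestry fractions per recipient haplotype
#' or pooled, computed from ground-truth tracts.
#'
#' @param tracts tract data.frame from [simulate_admixed()].
#' @param panel the donor (or combined) panel supplying site coordinates.
#' @param per_haplotype if `TRUE`, a matrix haplotype x population; otherwise
#'   pooled fractions.
#' @return named numeric vector (or matrix) of fractions summing to 1.
#' @export
true_ancestry_fractions <- function(tracts, panel, per_haplotype = FALSE) {
  chrom_idx <- sites_by_chrom(panel)
  gaps_by_chrom <- lapply(chrom_idx, function(i) site_gaps(panel$sites$gpos[i]))
  n_by_chrom <- vapply(chrom_idx, length, 1L)
  # a tract covering 1-based sites a..b owns its interior gaps fully plus
  # half of each boundary gap (the switch fell somewhere inside that gap)
  tract_len <- function(chrom, start0, end0) {
    a <- start0 + 1L; b <- end0
    gaps <- gaps_by_chrom[[chrom]]
    len <- if (b > a) sum(gaps[a:(b - 1L)]) else 0
    if (a > 1L) len <- len + gaps[a - 1L] / 2
    if (b < n_by_chrom[[chrom]]) len <- len + gaps[b] / 2
    len
  }
  lens <- mapply(tract_len, tracts$chrom, tracts$start_site, tracts$end_site)
  pops <- sort(unique(tracts$source_pop))
  if (per_haplotype) {
    haps <- unique(tracts$recipient_hap_id)
    out <- matrix(0, length(haps), length(pops),
                  dimnames = list(haps, pops))
    agg <- tapply(lens, list(tracts$recipient_hap_id, tracts$source_pop), sum)
    agg[is.na(agg)] <- 0
    out[rownames(agg), colnames(agg)] <- agg
    out / rowSums(out)
  } else {
    v <- tapply(lens, tracts$source_pop, sum)
    v <- v[pops]
    v / sum(v)
  }
}

#' Write a ground-truth tract table
#'
#' Tab-separated, with header, 0-based half-open site coordinates.
#'
#' @param tracts tract data.frame from [simulate_admixed()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(tracts, path) {
  need <- c("recipient_hap_id", "chrom", "start_site", "end_site", "source_pop")
  if (!all(need %in% names(tracts))) stop("tracts is missing required columns")
  write.table(tracts[, need], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
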