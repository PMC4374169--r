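#' Construct a phased haplotype panel
#'
#' The central container of the package: a phased 0/1 allele matrix over SNP
#' sites, together with sample metadata (population labels, donor/recipient
#' role) and per-site coordinates (chromosome, physical position in bp,
#' genetic position in Morgans). Each diploid sample owns exactly two
#' haplotype rows, named `<sample>_1` and `<sample>_2`.
#'
#' @param alleles integer matrix, haplotypes x sites, entries 0/1 or `NA`
#'   (missing). Row count must be twice the number of samples.
#' @param sample_ids character vector of unique sample identifiers.
#' @param populations named character vector mapping sample id to population
#'   label.
#' @param sites data.frame with columns `chrom`, `pos` (bp, integer) and
#'   `gpos` (genetic position, Morgans), one row per site, ordered by
#'   (chrom, pos).
#' @param role named character vector mapping sample id to `"donor"` or
#'   `"recipient"`.
#' @return an object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(alleles, sample_ids, populations, sites, role) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  n <- length(sample_ids)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (nrow(alleles) != 2L * n)
    stop("alleles must have exactly 2 haplotype rows per sample (",
         nrow(alleles), " rows for ", n, " samples)")
  rownames(alleles) <- paste0(rep(sample_ids, each = 2L), "_", 1:2)
  bad <- alleles[!is.na(alleles)]
  if (length(bad) && !all(bad %in% c(0L, 1L)))
    stop("alleles must be 0, 1 or NA")
  sites <- as.data.frame(sites)
  need <- c("chrom", "pos", "gpos")
  if (!all(need %in% names(sites)))
    stop("sites must have columns chrom, pos, gpos")
  if (nrow(sites) != ncol(alleles))
    stop("sites rows (", nrow(sites), ") != allele columns (", ncol(alleles), ")")
  sites$chrom <- as.character(sites$chrom)
  for (cc in unique(sites$chrom)) {
    g <- sites$gpos[sites$chrom == cc]
    if (length(g) > 1 && any(diff(g) < 0))
      stop("genetic positions must be non-decreasing within chromosome ", cc)
  }
  populations <- populations[sample_ids]
  role <- role[sample_ids]
  if (anyNA(populations)) stop("population label missing for some samples")
  if (anyNA(role) || !all(role %in% c("donor", "recipient")))
    stop("role must be 'donor' or 'recipient' for every sample")
  names(populations) <- names(role) <- sample_ids
  structure(
    list(alleles = alleles, sample_ids = sample_ids,
         hap_sample = rep(sample_ids, each = 2L),
         populations = populations, sites = sites, role = role),
    class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("haplotype_panel:", length(x$sample_ids), "samples (",
      sum(x$role == "donor"), "donors,", sum(x$role == "recipient"),
      "recipients ),", nrow(x$alleles), "haplotypes x", ncol(x$alleles),
      "sites on", length(unique(x$sites$chrom)), "chromosome(s)\n")
  pops <- table(x$populations)
  cat("populations:", paste0(names(pops), " (", pops, ")", collapse = ", "),
      "\n")
  invisible(x)
}

#' Number of sites / samples in a panel
#' @param panel a `haplotype_panel`.
#' @return integer count.
#' @export
n_sites <- function(panel) ncol(panel$alleles)

#' @rdname n_sites
#' @export
n_samples <- function(panel) length(panel$sample_ids)

#' Subset a panel by sample ids
#'
#' Keeps haplotype pairing and site order intact.
#'
#' @param panel a `haplotype_panel`.
#' @param keep character vector of sample ids to retain (in panel order).
#' @return a `haplotype_panel` with only the requested samples.
#' @export
subset_samples <- function(panel, keep) {
  keep <- panel$sample_ids[panel$sample_ids %in% keep]
  if (!length(keep)) stop("no samples left after subsetting")
  rows <- which(panel$hap_sample %in% keep)
  haplotype_panel(panel$alleles[rows, , drop = FALSE], keep,
                  panel$populations[keep], panel$sites, panel$role[keep])
}

#' Subset a panel by site indices
#' @param panel a `haplotype_panel`.
#' @param idx integer vector of site indices to retain (in order).
#' @return a `haplotype_panel` with only the requested sites.
#' @export
subset_sites <- function(panel, idx) {
  if (!length(idx)) stop("empty panel: no sites left after subsetting")
  haplotype_panel(panel$alleles[, idx, drop = FALSE], panel$sample_ids,
                  panel$populations, panel$sites[idx, , drop = FALSE],
                  panel$role)
}

#' Combine two panels sharing the same sites
#'
#' Used to join a donor pool with simulated recipients.
#'
#' @param a,b `haplotype_panel` objects with identical site tables.
#' @return the row-bound `haplotype_panel`.
#' @export
bind_panels <- function(a, b) {
  if (!isTRUE(all.equal(a$sites, b$sites)))
    stop("panels must share an identical site table")
  if (any(b$sample_ids %in% a$sample_ids))
    stop("sample ids overlap between panels")
  ids <- c(a$sample_ids, b$sample_ids)
  haplotype_panel(rbind(a$alleles, b$alleles), ids,
                  c(a$populations, b$populations), a$sites,
                  c(a$role, b$role))
}

# inter-site genetic distances (Morgans) for one chromosome's gpos vector,
# floored at min_g so HMM transitions stay valid
site_gaps <- function(gpos, min_g = 1e-9) {
  if (length(gpos) < 2) return(numeric(0))
  pmax(diff(gpos), min_g)
}

# split site indices by chromosome, preserving panel order
sites_by_chrom <- function(panel) {
  split(seq_len(n_sites(panel)), panel$sites$chrom)[
    unique(panel$sites$chrom)]
}
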