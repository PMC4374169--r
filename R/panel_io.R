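#' Write a panel as a phased VCF plus sample table
#'
#' Emits a minimal VCFv4.2 with phased GT fields (`0|1` style) and a
#' companion tab-separated sample table (`sample`, `population`, `role`).
#' Coordinates are written 1-based as VCF requires; internally the package is
#' 0-based half-open.
#'
#' @param panel a [haplotype_panel()].
#' @param vcf_path output VCF path (plain text).
#' @param sample_table_path output TSV path; default replaces the VCF
#'   extension with `.samples.tsv`.
#' @return `vcf_path`, invisibly.
#' @export
write_panel_vcf <- function(panel, vcf_path,
                            sample_table_path = sub("\\.vcf$", ".samples.tsv",
                                                    vcf_path)) {
  n <- n_samples(panel)
  L <- n_sites(panel)
  gt <- matrix("", L, n)
  for (j in seq_len(n)) {
    h1 <- panel$alleles[2L * j - 1L, ]
    h2 <- panel$alleles[2L * j, ]
    a1 <- ifelse(is.na(h1), ".", h1)
    a2 <- ifelse(is.na(h2), ".", h2)
    gt[, j] <- paste0(a1, "|", a2)
  }
  header <- c("##fileformat=VCFv4.2",
              "##source=haplomix",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", panel$sample_ids), collapse = "\t"))
  body <- data.frame(panel$sites$chrom, panel$sites$pos,
                     paste0("snp", seq_len(L)), "A", "G", ".", "PASS",
                     paste0("GP=", signif(panel$sites$gpos, 10)), "GT", gt,
                     stringsAsFactors = FALSE)
  con <- file(vcf_path, "w")
  on.exit(close(con))
  writeLines(header, con)
  write.table(body, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  write.table(data.frame(sample = panel$sample_ids,
                         population = unname(panel$populations),
                         role = unname(panel$role)),
              sample_table_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(vcf_path)
}

#' Read a phased biallelic VCF into a haplotype panel
#'
#' Accepts plain-text VCF with GT as the first FORMAT key. All records must
#' be biallelic SNPs with phased genotypes (`|` separator); unphased or
#' multi-allelic records are rejected with the offending site named. Sites
#' are ordered by (chrom, position); duplicate positions within a chromosome
#' are an error. Genetic positions are read from an optional `GP=` INFO key
#' (Morgans, as written by [write_panel_vcf()]); otherwise they are set to 0
#' and should be supplied via [attach_genetic_map()].
#'
#' @param vcf_path VCF path.
#' @param sample_table_path TSV with columns `sample`, `population`, `role`.
#' @return a [haplotype_panel()].
#' @export
read_panel <- function(vcf_path, sample_table_path) {
  if (!file.exists(vcf_path)) stop("no such file: ", vcf_path)
  if (!file.exists(sample_table_path)) stop("no such file: ", sample_table_path)
  lines <- readLines(vcf_path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop("not a VCF: missing #CHROM header line")
  cols <- strsplit(lines[hdr[1]], "\t", fixed = TRUE)[[1]]
  samples <- cols[-(1:9)]
  if (!length(samples)) stop("VCF has no sample columns")
  body <- lines[-seq_len(hdr[1])]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  L <- length(fields)
  if (!L) stop("empty panel: VCF contains no records")
  chrom <- vapply(fields, `[[`, "", 1L)
  pos <- as.integer(vapply(fields, `[[`, "", 2L))
  ref <- vapply(fields, `[[`, "", 4L)
  alt <- vapply(fields, `[[`, "", 5L)
  info <- vapply(fields, `[[`, "", 8L)
  multi <- grepl(",", alt, fixed = TRUE) | nchar(ref) != 1L | nchar(alt) != 1L
  if (any(multi))
    stop("non-biallelic-SNP record at ", chrom[multi][1], ":", pos[multi][1])
  gpos <- rep(0, L)
  has_gp <- grepl("(^|;)GP=", info)
  gpos[has_gp] <- as.numeric(sub(".*GP=([^;]+).*", "\\1", info[has_gp]))
  alleles <- matrix(NA_integer_, 2L * length(samples), L)
  for (l in seq_len(L)) {
    f <- fields[[l]]
    gts <- sub(":.*", "", f[-(1:9)])
    bad <- grepl("/", gts, fixed = TRUE)
    if (any(bad))
      stop("unphased genotype '", gts[bad][1], "' for sample ",
           samples[bad][1], " at ", f[1], ":", f[2])
    parts <- strsplit(gts, "|", fixed = TRUE)
    if (any(lengths(parts) != 2L))
      stop("malformed genotype at ", f[1], ":", f[2])
    m <- matrix(unlist(parts), nrow = 2L)
    m[m == "."] <- NA
    alleles[, l] <- as.integer(m)
  }
  ord <- order(chrom, pos)
  dup <- duplicated(data.frame(chrom, pos))
  if (any(dup))
    stop("duplicate position ", chrom[dup][1], ":", pos[dup][1])
  sites <- data.frame(chrom = chrom[ord], pos = pos[ord], gpos = gpos[ord],
                      stringsAsFactors = FALSE)
  alleles <- alleles[, ord, drop = FALSE]
  st <- read.table(sample_table_path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  if (!all(c("sample", "population", "role") %in% names(st)))
    stop("sample table must have columns sample, population, role")
  missing_meta <- setdiff(samples, st$sample)
  if (length(missing_meta))
    stop("samples absent from sample table: ",
         paste(missing_meta, collapse = ", "))
  st <- st[match(samples, st$sample), ]
  haplotype_panel(alleles, samples, setNames(st$population, samples), sites,
                  setNames(st$role, samples))
}

#' Write / read IMPUTE-style .haps/.sample files
#'
#' `.haps`: one row per SNP (`chrom id pos allele0 allele1` then one 0/1
#' column per haplotype, `?` for missing); `.sample`: the standard two-line
#' header then `ID_1 ID_2 missing` rows. Population and role are carried in
#' two extra columns of the `.sample` file.
#'
#' @param panel a [haplotype_panel()].
#' @param haps_path,sample_path output paths.
#' @return `haps_path`, invisibly.
#' @export
write_panel_haps <- function(panel, haps_path, sample_path) {
  al <- t(panel$alleles)
  al[is.na(al)] <- "?"
  df <- data.frame(panel$sites$chrom, paste0("snp", seq_len(n_sites(panel))),
                   panel$sites$pos, "A", "G", al, stringsAsFactors = FALSE)
  write.table(df, haps_path, sep = " ", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  con <- file(sample_path, "w")
  on.exit(close(con))
  writeLines(c("ID_1 ID_2 missing population role", "0 0 0 P R"), con)
  write.table(data.frame(panel$sample_ids, panel$sample_ids, 0,
                         unname(panel$populations), unname(panel$role)),
              con, sep = " ", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(haps_path)
}

#' @rdname write_panel_haps
#' @return for `read_panel_haps`, a [haplotype_panel()] (genetic positions 0;
#'   attach a map afterwards).
#' @export
read_panel_haps <- function(haps_path, sample_path) {
  if (!file.exists(haps_path)) stop("no such file: ", haps_path)
  hp <- data.table::fread(haps_path, header = FALSE, sep = " ",
                          na.strings = "?", data.table = FALSE)
  sm <- read.table(sample_path, header = TRUE, stringsAsFactors = FALSE)
  sm <- sm[-1, , drop = FALSE] # drop the "0 0 0" type line
  ids <- sm$ID_1
  alleles <- t(as.matrix(hp[, -(1:5), drop = FALSE]))
  sites <- data.frame(chrom = as.character(hp[[1]]), pos = hp[[3]], gpos = 0,
                      stringsAsFactors = FALSE)
  haplotype_panel(alleles, ids, setNames(sm$population, ids), sites,
                  setNames(sm$role, ids))
}

#' Write a HapMap-format genetic map
#'
#' Columns: chromosome, position (bp), recombination rate (cM/Mb), cumulative
#' genetic position (cM). One file covering all chromosomes.
#'
#' @param panel a [haplotype_panel()] whose site `gpos` (Morgans) defines the
#'   map knots.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genetic_map <- function(panel, path) {
  rows <- lapply(sites_by_chrom(panel), function(idx) {
    pos <- panel$sites$pos[idx]
    cm <- panel$sites$gpos[idx] * 100
    rate <- c(diff(cm) / (diff(pos) / 1e6), 0)
    data.frame(chrom = panel$sites$chrom[idx][1], position = pos,
               rate_cM_Mb = rate, map_cM = cm, stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Attach genetic-map positions to a panel
#'
#' Sets per-site genetic positions (Morgans) by linear interpolation of the
#' map's cumulative cM column at the panel's physical positions. Sites beyond
#' the map ends take the end value; zero inter-site distances are then
#' floored at `min_g` so copying-model transitions stay valid.
#'
#' @param panel a [haplotype_panel()].
#' @param map_path HapMap-format map file (columns: chromosome, position bp,
#'   rate cM/Mb, cumulative cM; header line required).
#' @param min_g floor for inter-site genetic distance, Morgans.
#' @return the panel with `gpos` replaced.
#' @export
attach_genetic_map <- function(panel, map_path, min_g = 1e-9) {
  mp <- data.table::fread(map_path, header = TRUE, data.table = FALSE)
  if (ncol(mp) < 4) stop("map must have 4 columns (chrom, pos, rate, cum cM)")
  names(mp)[1:4] <- c("chrom", "pos", "rate", "cm")
  mp$chrom <- as.character(mp$chrom)
  missing_chrom <- setdiff(unique(panel$sites$chrom), unique(mp$chrom))
  if (length(missing_chrom))
    stop("chromosome(s) absent from map: ",
         paste(missing_chrom, collapse = ", "))
  gpos <- panel$sites$gpos
  for (cc in unique(panel$sites$chrom)) {
    idx <- which(panel$sites$chrom == cc)
    knots <- mp[mp$chrom == cc, ]
    if (nrow(knots) == 1) {
      g <- rep(knots$cm, length(idx))
    } else {
      g <- approx(knots$pos, knots$cm, xout = panel$sites$pos[idx],
                  rule = 2, ties = "ordered")$y
    }
    g <- g / 100 # cM -> Morgans
    if (length(g) > 1) # floor zero inter-site distances
      g <- g[1] + c(0, cumsum(pmax(diff(g), min_g)))
    gpos[idx] <- g
  }
  panel$sites$gpos <- gpos
  panel
}

#' Filter sites and samples by call rate
#'
#' Drops SNPs whose haplotype call rate is below `min_rate`, then samples
#' whose call rate (over the retained SNPs) is below `min_rate` -- in that
#' order, mirroring common PLINK practice. The default threshold keeps only
#' markers and individuals with genotyping success above 98%.
#'
#' @param panel a [haplotype_panel()].
#' @param min_rate minimum call rate in (0, 1]; sites/samples strictly below
#'   it are removed.
#' @return the filtered panel, with a `qc_report` attribute listing counts of
#'   dropped sites and samples.
#' @export
filter_call_rate <- function(panel, min_rate = 0.98) {
  if (!is.numeric(min_rate) || min_rate <= 0 || min_rate > 1)
    stop("min_rate must be in (0, 1]")
  site_rate <- 1 - colMeans(is.na(panel$alleles))
  keep_sites <- which(site_rate >= min_rate)
  if (!length(keep_sites)) stop("empty panel: all sites dropped by call-rate filter")
  out <- subset_sites(panel, keep_sites)
  # per-sample call rate over its two haplotype rows
  m <- is.na(out$alleles)
  samp_rate <- 1 - (rowSums(m[seq(1, nrow(m), 2), , drop = FALSE]) +
                    rowSums(m[seq(2, nrow(m), 2), , drop = FALSE])) /
                   (2 * ncol(m))
  keep_samples <- out$sample_ids[samp_rate >= min_rate]
  if (!length(keep_samples)) stop("empty panel: all samples dropped by call-rate filter")
  res <- subset_samples(out, keep_samples)
  attr(res, "qc_report") <- list(
    sites_dropped = n_sites(panel) - length(keep_sites),
    samples_dropped = n_samples(panel) - length(keep_samples))
  res
}

#' Write a labelled matrix (chunk counts, copying vectors) as TSV
#'
#' @param m matrix with row and column names.
#' @param path output path.
#' @param rowname_header header for the first (row-name) column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, rowname_header = "id") {
  df <- data.frame(rownames(m), m, stringsAsFactors = FALSE,
                   check.names = FALSE)
  names(df) <- c(rowname_header, colnames(m))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Prune related samples from a kinship table
#'
#' Given precomputed pairwise kinship coefficients (e.g. KING output),
#' removes individuals until no pair exceeds `threshold`. From each offending
#' pair the member involved in more above-threshold pairs is removed
#' greedily; ties are broken by lower call rate, then lexicographic id. The
#' default threshold 0.0884 is the conventional cutoff between 3rd-degree
#' relatives and unrelated pairs.
#'
#' @param panel a [haplotype_panel()].
#' @param kin data.frame with columns `id1`, `id2`, `kinship`.
#' @param threshold kinship above which a pair is considered related (> 0).
#' @return the pruned panel, with attribute `removed` listing dropped ids.
#' @export
prune_kinship <- function(panel, kin, threshold = 0.0884) {
  if (!is.numeric(threshold) || threshold <= 0) stop("threshold must be > 0")
  if (!all(c("id1", "id2", "kinship") %in% names(kin)))
    stop("kin must have columns id1, id2, kinship")
  unknown <- setdiff(unique(c(kin$id1, kin$id2)), panel$sample_ids)
  if (length(unknown))
    stop("kinship table references unknown sample(s): ",
         paste(unknown, collapse = ", "))
  kin <- kin[kin$id1 != kin$id2, , drop = FALSE]
  call_rate <- setNames(
    1 - (rowSums(is.na(panel$alleles[seq(1, nrow(panel$alleles), 2), ,
                                     drop = FALSE])) +
         rowSums(is.na(panel$alleles[seq(2, nrow(panel$alleles), 2), ,
                                     drop = FALSE]))) / (2 * n_sites(panel)),
    panel$sample_ids)
  removed <- character(0)
  repeat {
    live <- !(kin$id1 %in% removed) & !(kin$id2 %in% removed)
    bad <- kin[live & kin$kinship > threshold, , drop = FALSE]
    if (!nrow(bad)) break
    counts <- table(c(bad$id1, bad$id2))
    cand <- names(counts)[counts == max(counts)]
    if (length(cand) > 1) {
      cr <- call_rate[cand]
      cand <- cand[cr == min(cr)]
      cand <- sort(cand)[1]
    }
    removed <- c(removed, cand[1])
  }
  out <- if (length(removed))
    subset_samples(panel, setdiff(panel$sample_ids, removed)) else panel
  attr(out, "removed") <- removed
  out
}
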