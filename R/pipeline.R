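#' Run the full ancestry-decomposition pipeline on a panel
#'
#' Convenience wrapper chaining the stages on a combined donor + recipient
#' panel: paint donors (at individual resolution), group them into clusters
#' (either their population labels or the MAP partition of the chunk-count
#' MCMC), build the donor-cluster basis, paint recipients, and fit the
#' population-level and per-individual mixture decompositions.
#'
#' @param panel a [haplotype_panel()] containing donor- and recipient-role
#'   samples.
#' @param params a [copying_model_params()]; pass the result of
#'   [estimate_params_em()] to mimic the EM-calibrated protocol.
#' @param clustering `"labels"` to group donors by their population labels,
#'   or `"mcmc"` to infer clusters with [cluster_mcmc()].
#' @param mcmc_iter,beta,seed MCMC settings (used when
#'   `clustering = "mcmc"`).
#' @param self_copy basis diagonal treatment, see [build_donor_basis()].
#' @param basis_include_self paint donors for the basis against the pool
#'   including their own haplotypes (`TRUE`, calibrated to recipients whose
#'   tracts are exact copies of pool haplotypes, as the bundled generator
#'   produces with `theta_sim = 0`); `FALSE` uses the standard leave-self-out
#'   protocol.
#' @param masked donor-cluster labels to mask in the mixture fits (surrogate
#'   donors).
#' @param jackknife compute leave-one-chromosome-out SEs for population fits.
#' @param weight copying-vector weighting, `"sites"` or `"morgans"`.
#' @return list of class `ancestry_pipeline`: `partition` (named donor
#'   cluster assignment), `cluster_of` (donor sample -> cluster label),
#'   `basis`, `fit` (an `ancestry_fit`), `recipient_paintings`
#'   (cluster-aggregated `painting_set`), `donor_paintings`
#'   (individual-resolution `painting_set`), `params`.
#' @export
run_ancestry_pipeline <- function(panel, params = copying_model_params(),
                                  clustering = c("labels", "mcmc"),
                                  mcmc_iter = 20000, beta = 1, seed = 1L,
                                  self_copy = "keep",
                                  basis_include_self = TRUE,
                                  masked = character(0), jackknife = FALSE,
                                  weight = "sites") {
  clustering <- match.arg(clustering)
  donors <- panel$sample_ids[panel$role == "donor"]
  recips <- panel$sample_ids[panel$role == "recipient"]
  if (!length(donors)) stop("panel has no donor samples")
  if (!length(recips)) stop("panel has no recipient samples")
  ident <- setNames(donors, donors)
  if (clustering == "mcmc") {
    ps_x <- paint_panel(panel, targets = donors, donor_grouping = ident,
                        params = params, leave_self_out = TRUE)
    X <- chunk_count_matrix(ps_x)
    mc <- cluster_mcmc(X, n_iter = mcmc_iter, beta = beta, seed = seed)
    partition <- mc$map
    cluster_of <- setNames(paste0("cl", partition), names(partition))
  } else {
    pops <- panel$populations[donors]
    partition <- setNames(as.integer(factor(pops)), donors)
    cluster_of <- setNames(unname(pops), donors)
  }
  labs <- setNames(unname(cluster_of[!duplicated(partition)]),
                   partition[!duplicated(partition)])
  # singleton clusters leave the donor set before any downstream painting
  tab <- table(partition)
  keep_donors <- names(partition)[as.character(partition) %in%
                                    names(tab)[tab >= 2]]
  ps_d <- paint_panel(panel, targets = keep_donors,
                      donor_grouping = setNames(keep_donors, keep_donors),
                      params = params,
                      leave_self_out = !basis_include_self)
  dv <- copying_vectors(aggregate_painting(ps_d, cluster_of[keep_donors]),
                        weight = weight)
  basis <- build_donor_basis(dv, partition[keep_donors],
                             self_copy = self_copy, cluster_labels = labs)
  ps_r <- paint_panel(panel, targets = recips,
                      donor_grouping = cluster_of[keep_donors],
                      params = params)
  fit <- individual_ancestry(ps_r, basis,
                             populations = panel$populations[recips],
                             masked = masked, jackknife = jackknife,
                             weight = weight)
  structure(list(partition = partition, cluster_of = cluster_of,
                 basis = basis, fit = fit, recipient_paintings = ps_r,
                 donor_paintings = ps_d, params = params),
            class = "ancestry_pipeline")
}

#' @export
print.ancestry_pipeline <- function(x, ...) {
  cat("ancestry_pipeline:", length(unique(x$partition)), "donor clusters;",
      length(x$fit$individual), "recipient individuals in",
      length(x$fit$population), "population(s)\n")
  for (p in names(x$fit$population)) {
    cat("\n", p, ":\n", sep = "")
    print(round(x$fit$population[[p]]$solution$proportions, 4))
  }
  invisible(x)
}
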