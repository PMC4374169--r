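# Lawson-Hanson active-set non-negative least squares: min ||b - A x||^2,
# x >= 0. Implemented in-package (no NNLS solver ships with the installed
# stack); validated in the tests against a simplex grid-search oracle.
nnls_solve <- function(A, b, tol = NULL) {
  A <- as.matrix(A)
  m <- ncol(A)
  if (is.null(tol)) tol <- 10 * .Machine$double.eps * max(abs(A)) * max(dim(A))
  # minimum-norm least squares via SVD; robust to (near-)duplicate columns
  ls_solve <- function(M, y) {
    sv <- svd(M)
    pos <- sv$d > max(sv$d) * 1e-12
    drop(sv$v[, pos, drop = FALSE] %*%
           (crossprod(sv$u[, pos, drop = FALSE], y) / sv$d[pos]))
  }
  passive <- rep(FALSE, m)
  x <- numeric(m)
  w <- drop(crossprod(A, b - A %*% x))
  iter <- 0L
  max_iter <- 30L * m
  while (any(!passive) && any(w[!passive] > tol) && iter < max_iter) {
    iter <- iter + 1L
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      s <- numeric(m)
      Ap <- A[, passive, drop = FALSE]
      s[passive] <- ls_solve(Ap, b)
      if (all(s[passive] > tol)) break
      neg <- passive & s <= tol
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive[passive & x <= tol] <- FALSE
      x[!passive] <- 0
    }
    x <- s
    w <- drop(crossprod(A, b - A %*% x))
  }
  pmax(x, 0)
}

#' Build the donor-cluster basis matrix
#'
#' One column per non-singleton donor cluster: the mean copying vector of the
#' cluster's member individuals (each painted the same way as the
#' recipients), renormalized to sum to 1. With
#' `self_copy = "zero-and-renormalize"` each column's own-cluster entry is
#' set to zero and the column renormalized, removing the inflation that
#' leave-self-out painting still leaves on the diagonal; `"keep"` retains it.
#'
#' @param donor_vectors matrix of donor individuals' copying vectors (rows =
#'   donor individuals, columns = donor clusters; rows sum to 1), e.g. from
#'   [copying_vectors()] on a leave-self-out painting aggregated to clusters.
#' @param assignment named cluster assignment of the donor individuals;
#'   values must correspond to the column labels via `cluster_labels`.
#' @param self_copy `"zero-and-renormalize"` (default) or `"keep"`.
#' @param cluster_labels optional mapping from cluster id to column label;
#'   default assumes columns are named `cl<id>` or match `unique(assignment)`
#'   coercion via `paste0("cl", id)`.
#' @return a `donor_basis`: list with `C` (coordinates x clusters matrix,
#'   columns sum to 1) and `self_copy`.
#' @export
build_donor_basis <- function(donor_vectors, assignment,
                              self_copy = c("zero-and-renormalize", "keep"),
                              cluster_labels = NULL) {
  self_copy <- match.arg(self_copy)
  tab <- table(assignment)
  keep_cl <- names(tab)[tab >= 2] # singleton clusters are excluded
  if (length(keep_cl) < 2)
    stop("need >= 2 non-singleton clusters to build a basis")
  asg <- assignment[as.character(assignment) %in% keep_cl]
  keep_ids <- names(asg)
  miss <- setdiff(keep_ids, rownames(donor_vectors))
  if (length(miss))
    stop("donor_vectors missing rows for: ", paste(miss, collapse = ", "))
  if (is.null(cluster_labels))
    cluster_labels <- setNames(paste0("cl", keep_cl), keep_cl)
  cols <- lapply(keep_cl, function(k) {
    v <- colMeans(donor_vectors[keep_ids[as.character(asg) == k], ,
                                drop = FALSE])
    v / sum(v)
  })
  C <- do.call(cbind, cols)
  colnames(C) <- unname(cluster_labels[as.character(keep_cl)])
  if (self_copy == "zero-and-renormalize") {
    for (j in seq_len(ncol(C))) {
      own <- rownames(C) == colnames(C)[j]
      if (any(own)) {
        C[own, j] <- 0
        C[, j] <- C[, j] / sum(C[, j])
      }
    }
  }
  structure(list(C = C, self_copy = self_copy), class = "donor_basis")
}

#' Decompose a copying vector as a non-negative mixture of donor clusters
#'
#' Solves `min || c - C a ||_2` subject to `a >= 0` and `sum(a) = 1` by
#' active-set NNLS on the system augmented with a heavily weighted sum-to-one
#' row (the standard way to impose the equality constraint with an NNLS
#' solver), followed by an exact renormalization of the solution. Numerical
#' dust (`|a| < 1e-12`) is clamped to zero. The residual norm is reported on
#' the final simplex solution.
#'
#' @param target copying vector (named by donor-group coordinate, sums to 1).
#' @param basis a [build_donor_basis()] result, or a bare matrix with
#'   coordinates as rows and mixture components as columns.
#' @return a `mixture_solution`: `proportions` (named, >= 0, sum 1),
#'   `residual_norm`, `masked_groups` (empty here).
#' @export
fit_mixture <- function(target, basis) {
  C <- if (inherits(basis, "donor_basis")) basis$C else as.matrix(basis)
  if (is.null(names(target)) || is.null(rownames(C)))
    stopifnot(length(target) == nrow(C))
  else {
    miss <- setdiff(rownames(C), names(target))
    if (length(miss))
      stop("target lacks coordinate(s): ", paste(miss, collapse = ", "))
    target <- target[rownames(C)]
  }
  lambda <- 1e4 # weight of the sum-to-one row; residuals are O(1) or less
  a <- nnls_solve(rbind(C, lambda), c(as.numeric(target), lambda))
  a[abs(a) < 1e-12] <- 0
  if (sum(a) <= 0)
    stop("all-zero mixture solution; the target is orthogonal to the basis ",
         "-- inspect the donor basis")
  a <- a / sum(a)
  names(a) <- colnames(C)
  structure(list(proportions = a,
                 residual_norm = sqrt(sum((as.numeric(target) - C %*% a)^2)),
                 masked_groups = character(0)),
            class = "mixture_solution")
}

#' @export
print.mixture_solution <- function(x, ...) {
  cat("mixture_solution (residual", format(x$residual_norm, digits = 4),
      if (length(x$masked_groups))
        paste0("; masked: ", paste(x$masked_groups, collapse = ",")) else "",
      ")\n")
  print(round(x$proportions, 4))
  invisible(x)
}

#' Mask coordinates and refit the mixture
#'
#' Deletes the masked donor-group coordinates from the target vector and from
#' every basis column, renormalizes all of them to sum to 1, and refits. The
#' masked groups' own basis columns remain available as mixture components --
#' only direct copying *from* them is removed. This is the treatment of a
#' drifted surrogate donor (e.g. an East Asian group standing in for
#' unsampled Native American sources) whose direct copying would otherwise be
#' over-weighted.
#'
#' @param target copying vector (named).
#' @param basis a `donor_basis` (or matrix).
#' @param masked character vector of coordinate labels to mask; empty means a
#'   plain [fit_mixture()].
#' @return a `mixture_solution` with `masked_groups` recorded.
#' @export
mask_and_refit <- function(target, basis, masked = character(0)) {
  C <- if (inherits(basis, "donor_basis")) basis$C else as.matrix(basis)
  if (!length(masked)) {
    out <- fit_mixture(target, C)
    return(out)
  }
  bad <- setdiff(masked, rownames(C))
  if (length(bad))
    stop("masked label(s) not among coordinates: ", paste(bad, collapse = ", "))
  keep <- setdiff(rownames(C), masked)
  tgt <- target[keep]
  if (sum(tgt) <= 0) stop("masking would zero the target vector")
  tgt <- tgt / sum(tgt)
  Cm <- C[keep, , drop = FALSE]
  csum <- colSums(Cm)
  if (any(csum <= 0))
    stop("masking zeroes basis column(s): ",
         paste(colnames(C)[csum <= 0], collapse = ", "))
  Cm <- sweep(Cm, 2, csum, "/")
  out <- fit_mixture(tgt, Cm)
  out$masked_groups <- masked
  out
}

#' Leave-one-chromosome-out jackknife standard errors
#'
#' For each chromosome `j`, the copying vector is recomputed from all
#' chromosomes except `j` and the mixture refit; the per-cluster standard
#' error is `sqrt((n - 1) / n * sum_j (a_j - abar)^2)` with `n` the number of
#' chromosomes (22 for human autosomes) and `abar` the mean of the
#' leave-one-out estimates.
#'
#' @param ps a `painting_set` holding the per-chromosome paintings of the
#'   population's member individuals (targets).
#' @param basis a `donor_basis`.
#' @param masked coordinates to mask in each refit.
#' @param members target sample ids forming the population; default all
#'   targets in `ps`.
#' @param weight copying-vector weighting, `"sites"` or `"morgans"`.
#' @return list: `se` (named per-cluster SE), `replicates` (n x clusters
#'   matrix of leave-one-out proportions).
#' @export
jackknife_se <- function(ps, basis, masked = character(0), members = NULL,
                         weight = "sites") {
  if (length(ps$chroms) < 2) stop("jackknife needs >= 2 chromosomes")
  if (is.null(members)) members <- ps$targets
  ps <- subset_painting(ps, members)
  pops <- setNames(rep("pop", length(members)), members)
  reps <- t(vapply(ps$chroms, function(cc) {
    cv <- copying_vectors(ps, level = "population", weight = weight,
                          populations = pops, exclude_chrom = cc)
    mask_and_refit(cv["pop", ], basis, masked)$proportions
  }, numeric(ncol(if (inherits(basis, "donor_basis")) basis$C else basis))))
  list(se = jk_se(reps), replicates = reps)
}

# jackknife SE over leave-one-out replicate rows:
# sqrt((n-1)/n * sum_j (a_j - abar)^2)
jk_se <- function(reps) {
  n <- nrow(reps)
  abar <- colMeans(reps)
  sqrt((n - 1) / n *
         colSums((reps - matrix(abar, n, ncol(reps), byrow = TRUE))^2))
}

#' Population- and individual-level ancestry decomposition
#'
#' Fits the mixture for each individual's copying vector and for the
#' population mean vector, with optional masking and jackknife SEs on the
#' population-level fit.
#'
#' @param ps a `painting_set` of the recipient individuals (aggregated to the
#'   basis' coordinate groups).
#' @param basis a `donor_basis`.
#' @param populations named mapping target sample id -> population.
#' @param masked coordinate labels to mask.
#' @param jackknife compute leave-one-chromosome-out SEs per population?
#' @param weight copying-vector weighting.
#' @return list of class `ancestry_fit`: `population` (list per population:
#'   `solution`, optional `se`), `individual` (list per sample of
#'   `mixture_solution`), `individual_mean` (per population, the mean of its
#'   members' individual proportions).
#' @export
individual_ancestry <- function(ps, basis, populations,
                                masked = character(0), jackknife = FALSE,
                                weight = "sites") {
  if (!length(ps$targets)) stop("painting set has no target individuals")
  iv <- copying_vectors(ps, level = "individual", weight = weight)
  ind <- lapply(setNames(rownames(iv), rownames(iv)), function(id)
    mask_and_refit(iv[id, ], basis, masked))
  pv <- copying_vectors(ps, level = "population", weight = weight,
                        populations = populations)
  pop_out <- list()
  for (p in rownames(pv)) {
    sol <- mask_and_refit(pv[p, ], basis, masked)
    entry <- list(solution = sol)
    if (jackknife) {
      members <- names(populations)[populations == p]
      members <- intersect(members, ps$targets)
      entry$se <- jackknife_se(ps, basis, masked, members = members,
                               weight = weight)$se
    }
    pop_out[[p]] <- entry
  }
  ind_mean <- lapply(setNames(rownames(pv), rownames(pv)), function(p) {
    members <- intersect(names(populations)[populations == p], ps$targets)
    colMeans(do.call(rbind, lapply(ind[members], `[[`, "proportions")))
  })
  structure(list(population = pop_out, individual = ind,
                 individual_mean = ind_mean),
            class = "ancestry_fit")
}

#' Write an ancestry table with jackknife SEs
#'
#' Tab-separated, one row per population, one column per donor cluster with
#' the fitted proportion and (when available) the jackknife standard error in
#' brackets, e.g. `0.412 (0.013)`.
#'
#' @param fit an `ancestry_fit` from [individual_ancestry()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ancestry_table <- function(fit, path) {
  pops <- names(fit$population)
  labs <- names(fit$population[[1]]$solution$proportions)
  rows <- t(vapply(pops, function(p) {
    pr <- fit$population[[p]]$solution$proportions
    se <- fit$population[[p]]$se
    if (is.null(se)) sprintf("%.4f", pr)
    else sprintf("%.4f (%.4f)", pr, se[labs])
  }, character(length(labs))))
  df <- data.frame(population = pops, rows, stringsAsFactors = FALSE,
                   check.names = FALSE)
  names(df) <- c("population", labs)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
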