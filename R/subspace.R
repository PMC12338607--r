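# Communication-subspace analytics: reduced-rank regression on model
# covariances, subset-averaged performance curves, dimensionality, and the
# frequency decomposition of communication.

#' Partition a covariance into source and target blocks
#'
#' @param C Full covariance (or frequency-specific covariance) matrix.
#' @param source_idx,target_idx Index sets into the rows of `C`; must be
#'   disjoint.
#' @return Object of class `covariance_partition` with `C1` (source),
#'   `C2` (target), `C3` (source x target cross-covariance).
#' @export
covariance_partition <- function(C, source_idx, target_idx) {
  if (length(intersect(source_idx, target_idx)) > 0L) {
    stop("source and target index sets must be disjoint", call. = FALSE)
  }
  structure(
    list(C1 = C[source_idx, source_idx, drop = FALSE],
         C2 = C[target_idx, target_idx, drop = FALSE],
         C3 = C[source_idx, target_idx, drop = FALSE],
         source_idx = source_idx, target_idx = target_idx),
    class = "covariance_partition"
  )
}

# Solve C1 x = b with a pseudo-inverse fallback (relative eigenvalue cutoff)
# or ridge regularization for ill-conditioned source covariances.
solve_source <- function(C1, B, reg = c("pinv", "ridge"), cutoff = 1e-12,
                         ridge = 1e-8) {
  reg <- match.arg(reg)
  ok <- tryCatch({
    kappa_est <- kappa(C1, exact = FALSE)
    kappa_est < 1e12
  }, error = function(e) FALSE)
  if (ok) {
    out <- tryCatch(solve(C1, B), error = function(e) NULL)
    if (!is.null(out)) return(out)
  }
  if (reg == "ridge") {
    lam <- ridge * mean(diag(C1))
    return(solve(C1 + diag(lam, nrow(C1)), B))
  }
  e <- eigen(0.5 * (C1 + t(C1)), symmetric = TRUE)
  keep <- e$values > cutoff * max(e$values)
  V <- e$vectors[, keep, drop = FALSE]
  V %*% (crossprod(V, B) / e$values[keep])
}

#' Reduced-rank communication-subspace analysis
#'
#' Given the source/target covariance partition, computes the optimal
#' linear readout `B_opt = C1^-1 C3`, the predicted target covariance
#' `C2_hat = C3^T C1^-1 C3`, its eigen-decomposition, the prediction
#' performance at every rank (cumulative explained target variance), the
#' full performance `Tr(C2_hat)/Tr(C2)`, and the subspace dimensionality.
#'
#' @param partition A [covariance_partition()].
#' @param reg Regularization for ill-conditioned source covariances:
#'   pseudo-inverse (default) or ridge.
#' @param criterion Dimensionality criterion, see [subspace_dimensionality()].
#' @return Object of class `subspace_result`: `B_opt`, `C2_hat`, `eigvals`,
#'   `eigvecs`, `performance` (length rank+1 curve, starting at rank 0),
#'   `full_performance`, `dimensionality`, `dimensionality_rank`.
#' @export
subspace_analysis <- function(partition, reg = c("pinv", "ridge"),
                              criterion = c("performance95", "rank")) {
  stopifnot(inherits(partition, "covariance_partition"))
  reg <- match.arg(reg)
  criterion <- match.arg(criterion)
  C1 <- partition$C1
  C2 <- partition$C2
  C3 <- partition$C3
  tr_c2 <- sum(diag(C2))
  B_opt <- solve_source(C1, C3, reg = reg)
  C2_hat <- t(C3) %*% B_opt
  C2_hat <- 0.5 * (C2_hat + t(C2_hat))
  e <- eigen(C2_hat, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  perf <- if (tr_c2 > 0) c(0, cumsum(lam) / tr_c2) else
    rep(0, length(lam) + 1L)
  full <- if (tr_c2 > 0) sum(diag(C2_hat)) / tr_c2 else 0
  res <- structure(
    list(B_opt = B_opt, C2_hat = C2_hat, eigvals = lam, eigvecs = e$vectors,
         performance = perf, full_performance = full),
    class = "subspace_result"
  )
  res$dimensionality <- subspace_dimensionality(res, criterion = criterion)
  res$dimensionality_rank <- subspace_dimensionality(res, criterion = "rank")
  res
}

#' @export
print.subspace_result <- function(x, ...) {
  cat("<subspace_result> full performance ",
      format(x$full_performance, digits = 4), ", dimensionality ",
      x$dimensionality, " (rank criterion: ", x$dimensionality_rank, ")\n",
      sep = "")
  invisible(x)
}

#' Dimensionality of a communication subspace
#'
#' Two criteria: `"performance95"` (default) is the smallest rank whose
#' prediction performance reaches 95% of the full performance; `"rank"`
#' counts eigenvalues above `1e-10` times the largest (the rank of the
#' predicted covariance, equal to the rank of the cross-covariance when the
#' source covariance is full rank).
#'
#' @param result A [subspace_analysis()] result (or a performance curve).
#' @param criterion `"performance95"` or `"rank"`.
#' @return Integer rank (0 for an all-zero curve).
#' @export
subspace_dimensionality <- function(result,
                                    criterion = c("performance95", "rank")) {
  criterion <- match.arg(criterion)
  if (inherits(result, "subspace_result")) {
    perf <- result$performance
    lam <- result$eigvals
  } else {
    perf <- result
    lam <- NULL
  }
  if (criterion == "rank") {
    if (is.null(lam)) stop("rank criterion needs eigenvalues", call. = FALSE)
    if (max(lam) <= 0) return(0L)
    return(sum(lam > 1e-10 * max(lam)))
  }
  full <- perf[length(perf)]
  if (full <= 0) return(0L)
  as.integer(which(perf >= 0.95 * full)[1L] - 1L)
}

#' Subset-averaged performance curves with SEM
#'
#' Repeatedly draws random source and target subsets (disjoint when drawn
#' from the same population), runs the subspace analysis on each draw, and
#' averages. Deterministic given `seed`.
#'
#' @param C Covariance (or frequency-specific covariance) matrix over
#'   channels.
#' @param source_pop,target_pop Channel index vectors of the two
#'   populations; identical vectors trigger the disjoint within-area
#'   protocol.
#' @param subset_size Neurons per subset (default 30).
#' @param n_repeats Subset draws (default 25).
#' @param seed Integer seed.
#' @param criterion Dimensionality criterion.
#' @return List: `performance` (mean curve over ranks 0..subset_size),
#'   `sem` (pointwise SEM), `full_performance` (mean), `full_sem`,
#'   `dimensionality` (mean), `dim_sem`, `n_repeats`.
#' @export
subset_averaged_performance <- function(C, source_pop, target_pop,
                                        subset_size = 30L, n_repeats = 25L,
                                        seed = 1L,
                                        criterion = c("performance95",
                                                      "rank")) {
  criterion <- match.arg(criterion)
  within <- identical(sort(source_pop), sort(target_pop))
  need <- if (within) 2L * subset_size else subset_size
  if (length(source_pop) < need || length(target_pop) < subset_size) {
    stop("population too small for subset size ", subset_size,
         call. = FALSE)
  }
  curves <- matrix(NA_real_, n_repeats, subset_size + 1L)
  fulls <- dims <- numeric(n_repeats)
  rng <- local({
    set.seed(seed)
    function(pop, k) sample(pop, k)
  })
  for (r in seq_len(n_repeats)) {
    if (within) {
      both <- rng(source_pop, 2L * subset_size)
      src <- both[seq_len(subset_size)]
      tgt <- both[subset_size + seq_len(subset_size)]
    } else {
      src <- rng(source_pop, subset_size)
      tgt <- rng(target_pop, subset_size)
    }
    res <- subspace_analysis(covariance_partition(C, src, tgt),
                             criterion = criterion)
    curves[r, ] <- res$performance
    fulls[r] <- res$full_performance
    dims[r] <- res$dimensionality
  }
  sem <- function(v) if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else 0
  list(performance = colMeans(curves),
       sem = apply(curves, 2L, sem),
       full_performance = mean(fulls), full_sem = sem(fulls),
       dimensionality = mean(dims), dim_sem = sem(dims),
       n_repeats = n_repeats)
}

#' Frequency-resolved communication analysis
#'
#' Runs the subset-averaged subspace analysis on the frequency-specific
#' covariance `Re S(f)` at every frequency of a spectral result, yielding
#' prediction performance and subspace dimensionality as functions of
#' frequency.
#'
#' @param spectral A [psd()] result over the channel populations.
#' @param source_pop,target_pop Channel indices (rows of the spectral
#'   channel matrix).
#' @param subset_size,n_repeats,seed Subset protocol, as in
#'   [subset_averaged_performance()].
#' @return `data.frame`: `freq`, `performance` (mean full performance),
#'   `perf_sem`, `dimensionality` (mean), `dim_sem`.
#' @export
frequency_resolved_communication <- function(spectral, source_pop,
                                             target_pop, subset_size = 30L,
                                             n_repeats = 25L, seed = 1L) {
  out <- lapply(seq_along(spectral$freqs), function(k) {
    Ck <- band_covariance(spectral, spectral$freqs[k])
    r <- subset_averaged_performance(Ck, source_pop, target_pop,
                                     subset_size = subset_size,
                                     n_repeats = n_repeats, seed = seed)
    data.frame(freq = spectral$freqs[k],
               performance = r$full_performance, perf_sem = r$full_sem,
               dimensionality = r$dimensionality, dim_sem = r$dim_sem)
  })
  do.call(rbind, out)
}
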