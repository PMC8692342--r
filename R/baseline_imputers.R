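# The five classical local imputers used as baselines: KNNImpute,
# SKNNImpute, IKNNImpute, LLSImpute, SLLSImpute.  All share the
# pairwise-complete distance of the graph module and preserve observed
# cells bit-for-bit.

#' KNN imputation
#'
#' For each missing cell, the `k` nearest genes (pairwise-complete
#' distance) that observe the sample donate their values; the estimate is
#' their inverse-distance weighted mean (unweighted mean with
#' `weighted = FALSE`).  No clustering: the donor pool is the whole gene
#' set, which makes this the single-cluster special case of
#' [impute_dataset()].
#'
#' @param m An [expression_matrix()].
#' @param h Availability mask.
#' @param k Neighbour count (>= 1).
#' @param weighted Inverse-distance weights (default) or plain mean.
#' @param dist Optional precomputed distance matrix.
#' @return An `ImputationResult`.
#' @export
knn_impute <- function(m, h = availability_mask(m), k = 15L,
                       weighted = TRUE, dist = NULL) {
  if (k < 1) stop_si("k must be >= 1", "parameter")
  miss <- which(!h, arr.ind = TRUE)
  out <- m$values
  prov <- empty_provenance(nrow(miss))
  if (nrow(miss) > 0L && is.null(dist)) dist <- pairwise_distances(m, h)
  for (r in seq_len(nrow(miss))) {
    i <- miss[r, 1L]; u <- miss[r, 2L]
    ns <- top_k_neighbors(m, h, NULL, i, u, k, dist = dist)
    out[i, u] <- blend_donors(m, ns, u, weighted)
    prov[r, ] <- list(i, u, 1L, ns$k_prime, FALSE)
  }
  completed <- m
  completed$values <- out
  structure(list(completed = completed, provenance = prov, model = NULL),
            class = "ImputationResult")
}

# weighted / unweighted aggregation of a NeighborSet's donor values
blend_donors <- function(m, ns, u, weighted) {
  vals <- m$values[ns$neighbor_indices, u]
  wts <- if (weighted) ns$weights else rep(1 / length(vals), length(vals))
  if (m$attr_kinds[u] == "categorical") {
    match(impute_categorical(wts, m$levels[[u]][vals]), m$levels[[u]])
  } else {
    impute_numeric(wts, vals)
  }
}

#' Sequential KNN imputation
#'
#' Genes are imputed in ascending missing-rate order (ties by row index).
#' The donor pool starts as the complete genes and grows: once a gene is
#' imputed, its completed row becomes eligible to donate to later genes.
#'
#' @inheritParams knn_impute
#' @return An `ImputationResult`.
#' @export
sknn_impute <- function(m, h = availability_mask(m), k = 15L,
                        weighted = TRUE) {
  sequential_impute(m, h, engine = "knn", k = k, weighted = weighted)
}

#' Iterative KNN imputation
#'
#' Missing cells start at their gene's observed mean; each iteration
#' re-imputes every originally-missing cell by KNN on the current
#' completed matrix, until the relative max-abs change drops below `tol`
#' or `max_iter` passes (non-convergence returns the last iterate with a
#' warning).
#'
#' @inheritParams knn_impute
#' @param max_iter Maximum sweeps.
#' @param tol Relative max-abs change threshold.
#' @return An `ImputationResult` with an `iterations` field.
#' @export
iknn_impute <- function(m, h = availability_mask(m), k = 15L,
                        max_iter = 20L, tol = 1e-4, weighted = TRUE) {
  if (k < 1) stop_si("k must be >= 1", "parameter")
  miss <- which(!h, arr.ind = TRUE)
  completed <- m
  if (nrow(miss) == 0L) {
    res <- structure(list(completed = completed,
                          provenance = empty_provenance(), model = NULL),
                     class = "ImputationResult")
    res$iterations <- 0L
    return(res)
  }
  x <- m$values
  rm_ <- rowMeans(x, na.rm = TRUE)
  rm_[is.nan(rm_)] <- mean(x, na.rm = TRUE)    # fully-missing gene: grand mean
  x[!h] <- rm_[miss[, 1L]]
  cur <- m; cur$values <- x
  hfull <- matrix(TRUE, nrow(x), ncol(x))
  iters <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    iters <- it
    dist <- pairwise_distances(cur, hfull)
    newx <- cur$values
    for (r in seq_len(nrow(miss))) {
      i <- miss[r, 1L]; u <- miss[r, 2L]
      ns <- top_k_neighbors(cur, h_not(hfull, i, u), NULL, i, u, k, dist = dist)
      newx[i, u] <- blend_donors(cur, ns, u, weighted)
    }
    delta <- max(abs(newx - cur$values)) / max(abs(cur$values), 1e-12)
    cur$values <- newx
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) warning("IKNN did not converge within max_iter; returning last iterate")
  prov <- empty_provenance(nrow(miss))
  prov$gene <- miss[, 1L]; prov$sample <- miss[, 2L]
  prov$cluster <- 1L; prov$k_used <- k
  res <- structure(list(completed = cur, provenance = prov, model = NULL),
                   class = "ImputationResult")
  res$iterations <- iters
  res
}

# mask that is TRUE everywhere except the one target cell, so
# top_k_neighbors sees the cell as missing but every donor as observed
h_not <- function(hfull, i, u) {
  hfull[i, u] <- FALSE
  hfull
}

#' Local least squares (LLS) imputation
#'
#' For each incomplete gene, the `k` most similar complete genes (L2 norm
#' on the target's observed samples, or Pearson correlation) form the
#' regressors; ridge-regularized least squares fits the target's observed
#' values on the donors' values at the same samples, and the fitted
#' coefficients predict the missing samples.  Being a regression, imputed
#' values may fall outside the donors' range.  With `ridge = 0` a
#' rank-deficient system falls back to the minimum-norm (pseudo-inverse)
#' solution.
#'
#' @inheritParams knn_impute
#' @param ridge Ridge penalty on the normal equations.
#' @param similarity `"l2"` (default) or `"pearson"`.
#' @param donor_pool Internal: donor row indices (defaults to the complete
#'   genes).
#' @return An `ImputationResult`.
#' @export
lls_impute <- function(m, h = availability_mask(m), k = 15L, ridge = 1e-6,
                       similarity = c("l2", "pearson"), donor_pool = NULL) {
  similarity <- match.arg(similarity)
  if (k < 1) stop_si("k must be >= 1", "parameter")
  if (any(m$attr_kinds == "categorical")) {
    stop_si("LLS-family imputers support numeric columns only", "invalid_input")
  }
  sets <- split_complete_incomplete(m, h)
  if (is.null(donor_pool)) donor_pool <- sets$complete
  if (length(donor_pool) == 0L) {
    stop_si("LLS needs at least one complete gene", "invalid_input")
  }
  out <- m$values
  nmiss <- sum(!h)
  prov <- empty_provenance(nmiss)
  r0 <- 0L
  for (j in sets$incomplete) {
    filled <- lls_fill_gene(m$values, h, j, donor_pool, k, ridge, similarity)
    mu <- which(!h[j, ])
    out[j, mu] <- filled
    for (u in mu) {
      r0 <- r0 + 1L
      prov[r0, ] <- list(j, u, 1L, min(k, length(donor_pool)), FALSE)
    }
  }
  completed <- m
  completed$values <- out
  structure(list(completed = completed, provenance = prov, model = NULL),
            class = "ImputationResult")
}

# regress gene j's observed samples on its k most similar donors; returns
# predictions at j's missing samples
lls_fill_gene <- function(x, h, j, donor_pool, k, ridge, similarity) {
  obs <- which(h[j, ])
  mis <- which(!h[j, ])
  donors <- setdiff(donor_pool, j)
  if (length(donors) == 0L) stop_si("no donors for LLS target", "invalid_input")
  tj <- x[j, obs]
  dmat <- x[donors, obs, drop = FALSE]
  sim_ord <- if (similarity == "pearson" && length(obs) >= 2L) {
    order(-abs(apply(dmat, 1L, function(v) {
      if (stats::sd(v) == 0 || stats::sd(tj) == 0) 0 else stats::cor(v, tj)
    })), donors)
  } else {
    order(sqrt(colSums((t(dmat) - tj)^2)), donors)
  }
  sel <- donors[sim_ord[seq_len(min(k, length(donors)))]]
  B <- t(x[sel, obs, drop = FALSE])            # n_obs x k
  A <- crossprod(B) + ridge * diag(length(sel))
  rhs <- crossprod(B, tj)
  coef <- tryCatch(solve(A, rhs), error = function(e) pinv_solve(A, rhs))
  drop(t(x[sel, mis, drop = FALSE]) %*% coef)
}

# minimum-norm solution via SVD pseudo-inverse
pinv_solve <- function(a, b, tol = 1e-10) {
  sv <- svd(a)
  pos <- sv$d > tol * max(sv$d)
  sv$v[, pos, drop = FALSE] %*% ((t(sv$u[, pos, drop = FALSE]) %*% b) / sv$d[pos])
}

#' Sequential LLS imputation
#'
#' [lls_impute()] applied gene by gene in ascending missing-rate order
#' (ties by row index), with previously imputed genes joining the donor
#' pool.
#'
#' @inheritParams lls_impute
#' @return An `ImputationResult`.
#' @export
slls_impute <- function(m, h = availability_mask(m), k = 15L, ridge = 1e-6,
                        similarity = c("l2", "pearson")) {
  similarity <- match.arg(similarity)
  sequential_impute(m, h, engine = "lls", k = k, ridge = ridge,
                    similarity = similarity)
}

# shared sequential driver for SKNN and SLLS: donor pool = complete genes,
# grown with each newly completed gene; imputation order = ascending
# missing rate, ties by row index
sequential_impute <- function(m, h, engine, k, weighted = TRUE,
                              ridge = 1e-6, similarity = "l2") {
  if (k < 1) stop_si("k must be >= 1", "parameter")
  sets <- split_complete_incomplete(m, h)
  if (length(sets$complete) == 0L) {
    stop_si("sequential imputation needs at least one complete gene",
            "invalid_input")
  }
  inc <- sets$incomplete
  ord <- inc[order(rowSums(!h[inc, , drop = FALSE]), inc)]
  cur <- m
  hcur <- h
  pool <- sets$complete
  nmiss <- sum(!h)
  prov <- empty_provenance(nmiss)
  r0 <- 0L
  for (j in ord) {
    mu <- which(!h[j, ])
    if (engine == "lls") {
      cur$values[j, mu] <- lls_fill_gene(cur$values, hcur, j, pool, k,
                                         ridge, similarity)
    } else {
      # donors ranked once per gene on its originally observed samples;
      # all pool members are complete rows at this point
      dvec <- vapply(pool, function(i) {
        tryCatch(pairwise_distance(cur$values[j, ], cur$values[i, ],
                                   cur$attr_kinds),
                 si_no_overlap = function(e) NA_real_)
      }, numeric(1))
      cand <- pool[!is.na(dvec)]
      dvec <- dvec[!is.na(dvec)]
      if (length(cand) == 0L) {
        stop_si("no donor with co-observed samples in sequential pool",
                "no_overlap")
      }
      o <- order(dvec, cand)
      keep <- o[seq_len(min(k, length(o)))]
      dd <- dvec[keep]
      wts <- if (dd[1L] == 0) {
        c(1, rep(0, length(dd) - 1L))
      } else if (weighted) neighbor_weights(dd) else {
        rep(1 / length(dd), length(dd))
      }
      for (u in mu) {
        vals <- cur$values[cand[keep], u]
        cur$values[j, u] <- if (cur$attr_kinds[u] == "categorical") {
          match(impute_categorical(wts, cur$levels[[u]][vals]), cur$levels[[u]])
        } else {
          impute_numeric(wts, vals)
        }
      }
    }
    hcur[j, ] <- TRUE
    pool <- c(pool, j)
    for (u in mu) {
      r0 <- r0 + 1L
      prov[r0, ] <- list(j, u, 1L, k, FALSE)
    }
  }
  structure(list(completed = cur, provenance = prov, model = NULL),
            class = "ImputationResult")
}
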