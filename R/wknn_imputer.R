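# The proposed imputer: spectral clustering followed by cluster-restricted
# inverse-distance weighted top-K' nearest-neighbour imputation.

#' Imputer configuration for the cluster-guided method
#'
#' @param k_prime Maximum neighbours used per imputed cell (>= 1).
#' @param graph A [graph_config()].
#' @param n_clusters Cluster count K, or `"auto"` for the eigengap
#'   heuristic.
#' @param seed Integer seed (K-means restarts).
#' @param fallback Policy when a missing cell has no in-cluster candidate
#'   observing its sample: `"widen_to_global"` ranks over all genes
#'   observing it; `"cluster_centroid"` substitutes the cluster mean of the
#'   sample (numeric) or the cluster majority level (categorical).
#' @param complete_only When `TRUE`, only complete genes may donate;
#'   default allows any gene that observes the target sample.
#' @param k_max Candidate ceiling for `n_clusters = "auto"`.
#' @return An `ImputerConfig` list.
#' @export
imputer_config <- function(k_prime = 15L, graph = graph_config(),
                           n_clusters = "auto", seed = 1L,
                           fallback = c("widen_to_global", "cluster_centroid"),
                           complete_only = FALSE, k_max = 10L) {
  fallback <- match.arg(fallback)
  if (!is.numeric(k_prime) || k_prime < 1) {
    stop_si("k_prime must be >= 1", "parameter")
  }
  structure(list(k_prime = as.integer(k_prime), graph = graph,
                 n_clusters = n_clusters, seed = as.integer(seed),
                 fallback = fallback, complete_only = complete_only,
                 k_max = as.integer(k_max)),
            class = "ImputerConfig")
}

#' Inverse-distance neighbour weights
#'
#' `P_i = (1/dist_i) / sum_j (1/dist_j)`: weights sum to 1 and closer
#' neighbours receive larger weight.  Undefined at distance 0 — callers
#' apply the exact-match shortcut (nearest neighbour at distance 0 donates
#' its value with weight 1) before calling this.
#'
#' @param distances Positive distances, ascending.
#' @return Weights summing to 1.
#' @export
neighbor_weights <- function(distances) {
  if (length(distances) == 0L || any(distances <= 0)) {
    stop_si("all distances must be > 0 (zero distance: use the exact-match shortcut)",
            "contract")
  }
  w <- 1 / distances
  w / sum(w)
}

#' Weighted numeric imputation
#'
#' `I = sum_i P_i * v_i`: a convex combination, so the imputed value lies
#' within the range of the neighbour values.
#'
#' @param weights Weights summing to 1.
#' @param neighbor_values Neighbour values at the target sample.
#' @return Scalar imputed value.
#' @export
impute_numeric <- function(weights, neighbor_values) {
  if (length(weights) != length(neighbor_values)) {
    stop_si("weights and values differ in length", "contract")
  }
  sum(weights * neighbor_values)
}

#' Weighted categorical imputation
#'
#' Each distinct category accumulates the weight of its supporters; the
#' category with the largest accumulated weight wins.  Ties resolve to the
#' lexicographically smallest label.
#'
#' @param weights Weights summing to 1.
#' @param neighbor_categories Character labels, same length as `weights`.
#' @return Winning label.
#' @export
impute_categorical <- function(weights, neighbor_categories) {
  if (length(weights) == 0L || length(weights) != length(neighbor_categories)) {
    stop_si("weights and categories must be non-empty and equal-length", "contract")
  }
  e <- tapply(weights, neighbor_categories, sum)
  winners <- names(e)[e == max(e)]
  sort(winners)[1L]
}

#' Top-K' nearest neighbours for one missing cell
#'
#' Candidates are the genes in the target's cluster (the whole gene set
#' when `model` is `NULL`) that observe sample `u`, excluding the target;
#' they are ranked by pairwise-complete distance to the target (ties by
#' row index) and truncated to `k_prime`.  With zero in-cluster candidates
#' the fallback policy applies.
#'
#' @param m An [expression_matrix()].
#' @param h Availability mask.
#' @param model A `ClusterModel` or `NULL` for unclustered (global) search.
#' @param target Target gene row index.
#' @param u Sample column index of the missing cell.
#' @param k_prime Maximum neighbours.
#' @param dist Optional precomputed distance matrix
#'   ([pairwise_distances()]); computed on the fly when `NULL`.
#' @param fallback `"widen_to_global"` or `"cluster_centroid"`.
#' @param complete_only Restrict donors to complete genes.
#' @return A `NeighborSet` list: `target_gene`, `attribute`,
#'   `neighbor_indices`, `distances` (ascending), `weights`, `k_prime`
#'   (count actually used), `fallback` flag; or a `"centroid"`-type result
#'   under the centroid fallback.
#' @export
top_k_neighbors <- function(m, h, model, target, u, k_prime,
                            dist = NULL,
                            fallback = c("widen_to_global", "cluster_centroid"),
                            complete_only = FALSE) {
  fallback <- match.arg(fallback)
  if (h[target, u]) stop_si("cell (target, u) is not missing", "contract")
  if (!any(h[, u])) {
    stop_si(sprintf("no gene observes sample %d: attribute unimputable", u),
            "unimputable_attribute")
  }
  pool <- if (is.null(model)) seq_len(nrow(h)) else {
    model$clusters[[as.character(model$assignments[target])]]
  }
  used_fallback <- FALSE
  cand <- candidate_donors(pool, h, target, u, complete_only)
  dvec <- donor_distances(m, h, target, cand, dist)
  cand <- cand[!is.na(dvec)]
  dvec <- dvec[!is.na(dvec)]
  if (length(cand) == 0L && !is.null(model)) {
    used_fallback <- TRUE
    if (fallback == "cluster_centroid") {
      return(centroid_fallback(m, h, model, target, u))
    }
    cand <- candidate_donors(seq_len(nrow(h)), h, target, u, complete_only)
    dvec <- donor_distances(m, h, target, cand, dist)
    cand <- cand[!is.na(dvec)]
    dvec <- dvec[!is.na(dvec)]
  }
  if (length(cand) == 0L) {
    stop_si(sprintf("no donor with co-observed samples for gene %d, sample %d",
                    target, u), "no_overlap")
  }
  ord <- order(dvec, cand)
  keep <- ord[seq_len(min(k_prime, length(ord)))]
  dd <- dvec[keep]
  wts <- if (dd[1L] == 0) c(1, rep(0, length(dd) - 1L)) else neighbor_weights(dd)
  list(type = "neighbors", target_gene = target, attribute = u,
       neighbor_indices = cand[keep], distances = dd, weights = wts,
       k_prime = length(keep), fallback = used_fallback)
}

candidate_donors <- function(pool, h, target, u, complete_only) {
  cand <- pool[h[pool, u] & pool != target]
  if (complete_only) cand <- cand[rowSums(h[cand, , drop = FALSE]) == ncol(h)]
  cand
}

donor_distances <- function(m, h, target, cand, dist) {
  if (length(cand) == 0L) return(numeric(0))
  if (!is.null(dist)) return(dist[target, cand])
  vapply(cand, function(i) {
    tryCatch(pairwise_distance(m$values[target, ], m$values[i, ], m$attr_kinds),
             si_no_overlap = function(e) NA_real_)
  }, numeric(1))
}

centroid_fallback <- function(m, h, model, target, u) {
  cl <- model$clusters[[as.character(model$assignments[target])]]
  obs <- cl[h[cl, u]]
  vals <- if (length(obs)) m$values[obs, u] else m$values[h[, u], u]
  v <- if (m$attr_kinds[u] == "categorical") {
    as.numeric(names(sort(table(vals), decreasing = TRUE))[1L])
  } else {
    mean(vals)
  }
  list(type = "centroid", target_gene = target, attribute = u,
       value = v, fallback = TRUE)
}

#' Impute a dataset with the cluster-guided weighted KNN method
#'
#' Three phases: (1) split genes into complete and incomplete sets; (2)
#' spectral-cluster *all* genes jointly (incomplete genes participate via
#' pairwise-complete distances); (3) for every missing cell, find the
#' top-K' nearest in-cluster donors observing that sample and impute by
#' inverse-distance weighting — numeric cells by the weighted mean,
#' categorical cells by the largest accumulated weight.  A donor at
#' distance exactly 0 short-circuits and donates its value.  Cells are
#' imputed independently from the originally observed data only (no
#' chaining).  Deterministic given the seed.
#'
#' @param m An [expression_matrix()].
#' @param cfg An [imputer_config()].
#' @param model Optional precomputed `ClusterModel` (skips phase 2).
#' @param dist Optional precomputed distance matrix.
#' @return An `ImputationResult`: list with `completed`
#'   (ExpressionMatrix, no missing cells), `provenance` (one row per
#'   imputed cell: gene, sample, cluster, k_used, fallback), and `model`.
#' @export
impute_dataset <- function(m, cfg = imputer_config(), model = NULL,
                           dist = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  h <- availability_mask(m)
  miss <- which(!h, arr.ind = TRUE)
  if (nrow(miss) == 0L) {
    return(structure(list(completed = m,
                          provenance = empty_provenance(), model = model),
                     class = "ImputationResult"))
  }
  sets <- split_complete_incomplete(m, h)
  if (length(sets$complete) == 0L && cfg$complete_only) {
    stop_si("no complete gene available and complete_only is set", "invalid_input")
  }
  if (is.null(model)) {
    model <- spectral_cluster(m, h, gcfg = cfg$graph, K = cfg$n_clusters,
                              seed = cfg$seed, k_max = cfg$k_max)
  }
  if (is.null(dist)) dist <- pairwise_distances(m, h)
  out <- m$values
  prov <- empty_provenance(nrow(miss))
  for (r in seq_len(nrow(miss))) {
    i <- miss[r, 1L]; u <- miss[r, 2L]
    ns <- top_k_neighbors(m, h, model, i, u, cfg$k_prime, dist = dist,
                          fallback = cfg$fallback,
                          complete_only = cfg$complete_only)
    if (ns$type == "centroid") {
      out[i, u] <- ns$value
      prov[r, ] <- list(i, u, model$assignments[i], 0L, TRUE)
      next
    }
    vals <- m$values[ns$neighbor_indices, u]
    if (m$attr_kinds[u] == "categorical") {
      lab <- impute_categorical(ns$weights, m$levels[[u]][vals])
      out[i, u] <- match(lab, m$levels[[u]])
    } else {
      out[i, u] <- impute_numeric(ns$weights, vals)
    }
    prov[r, ] <- list(i, u, model$assignments[i], ns$k_prime, ns$fallback)
  }
  completed <- m
  completed$values <- out
  structure(list(completed = completed, provenance = prov, model = model),
            class = "ImputationResult")
}

empty_provenance <- function(n = 0L) {
  data.frame(gene = integer(n), sample = integer(n), cluster = integer(n),
             k_used = integer(n), fallback = logical(n))
}

#' @export
print.ImputationResult <- function(x, ...) {
  cat(sprintf("ImputationResult: %d cell(s) imputed, %d via fallback\n",
              nrow(x$provenance), sum(x$provenance$fallback)))
  invisible(x)
}
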