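test_that("neighbor_weights is normalized inverse distance", {
  expect_equal(neighbor_weights(c(1, 1)), c(0.5, 0.5))
  expect_equal(neighbor_weights(c(1, 2, 4)), c(4, 2, 1) / 7, tolerance = 1e-12)
  for (seed in 1:10) {
    set.seed(seed)
    d <- sort(runif(sample(1:8, 1), 0.01, 10))
    p <- neighbor_weights(d)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(diff(p) <= 0))     # closer => larger weight
    expect_true(all(p > 0))
  }
  expect_error(neighbor_weights(c(0, 1)), class = "si_contract")
})

test_that("numeric imputation is the weighted convex combination", {
  expect_equal(impute_numeric(c(0.5, 0.5), c(2, 4)), 3)
  expect_equal(impute_numeric(c(4, 2, 1) / 7, c(7, 7, 7)), 7)
  expect_equal(impute_numeric(c(4, 2, 1) / 7, c(1, 2, 4)), 12 / 7,
               tolerance = 1e-12)
  expect_error(impute_numeric(c(1), c(1, 2)), class = "si_contract")
  for (seed in 1:10) {
    set.seed(seed)
    v <- rnorm(5)
    p <- neighbor_weights(sort(runif(5, 0.1, 3)))
    i <- impute_numeric(p, v)
    expect_gte(i, min(v)); expect_lte(i, max(v))
  }
})

test_that("categorical imputation takes the largest accumulated weight", {
  expect_equal(impute_categorical(c(0.6, 0.4), c("A", "B")), "A")
  expect_equal(impute_categorical(c(0.3, 0.3, 0.4), c("A", "A", "B")), "A")
  expect_equal(impute_categorical(c(0.5, 0.5), c("B", "A")), "A")  # tie rule
  expect_error(impute_categorical(numeric(0), character(0)),
               class = "si_contract")
})

test_that("top_k_neighbors ranks in-cluster donors and falls back", {
  sp <- synthetic_spec(30, 8, 3, separation = 6, noise_sd = 0.5, seed = 4)
  gen <- generate_clustered_expression(sp)
  m <- gen$matrix
  m$values[1, 3] <- NA
  h <- availability_mask(m)
  model <- spectral_cluster(m, h, K = 3, seed = 1)
  ns <- top_k_neighbors(m, h, model, 1, 3, k_prime = 4)
  expect_equal(ns$k_prime, 4L)
  expect_true(all(diff(ns$distances) >= 0))
  expect_equal(sum(ns$weights), 1, tolerance = 1e-12)
  expect_true(all(model$assignments[ns$neighbor_indices] == model$assignments[1]))
  expect_true(all(h[cbind(ns$neighbor_indices, 3)]))
  # exact duplicate comes first at distance zero with weight 1
  m2 <- m
  m2$values[2, ] <- m2$values[1, ]
  m2$values[2, 3] <- gen$matrix$values[1, 3]
  h2 <- availability_mask(m2)
  ns2 <- top_k_neighbors(m2, h2, model, 1, 3, k_prime = 3)
  expect_equal(ns2$neighbor_indices[1], 2L)
  expect_equal(ns2$distances[1], 0)
  expect_equal(ns2$weights, c(1, 0, 0))
  # truncation to cluster size
  small <- list(assignments = c(1L, 1L, 1L, rep(2L, 27)),
                clusters = split(1:30, c(1L, 1L, 1L, rep(2L, 27))))
  ns3 <- top_k_neighbors(m, h, small, 1, 3, k_prime = 200)
  expect_lte(ns3$k_prime, 2L)
  # cluster where nobody observes u: widen_to_global ranks over all genes
  m4 <- m
  m4$values[2:3, 3] <- NA
  h4 <- availability_mask(m4)
  ns4 <- top_k_neighbors(m4, h4, small, 1, 3, k_prime = 5)
  expect_true(ns4$fallback)
  expect_true(all(ns4$neighbor_indices > 3))
  # centroid fallback returns the cluster mean at u
  ns5 <- top_k_neighbors(m4, h4, small, 1, 3, k_prime = 5,
                         fallback = "cluster_centroid")
  expect_equal(ns5$type, "centroid")
  expect_error(top_k_neighbors(m, h, model, 1, 2, 3), class = "si_contract")
})

test_that("top-k neighbour lists match the exhaustive sort oracle", {
  for (seed in 1:6) {
    em <- rand_em(15, 6, miss_frac = 0.2, seed = seed)
    h <- availability_mask(em)
    miss <- which(!h, arr.ind = TRUE)
    if (nrow(miss) == 0) next
    d <- brute_dist_matrix(em)
    i <- miss[1, 1]; u <- miss[1, 2]
    cand <- setdiff(which(h[, u]), i)
    dv <- d[i, cand]
    keep <- !is.na(dv)
    ord <- order(dv[keep], cand[keep])
    want <- cand[keep][ord][seq_len(min(3, sum(keep)))]
    ns <- top_k_neighbors(em, h, NULL, i, u, 3)
    expect_identical(ns$neighbor_indices, want)
  }
})

test_that("impute_dataset completes matrices, preserves observed cells", {
  sp <- synthetic_spec(45, 10, 3, separation = 5, noise_sd = 1, seed = 8)
  gen <- generate_clustered_expression(sp)
  ms <- masking_spec(0.08, seed = 2, n_replicates = 1)
  inj <- inject_missing(gen$matrix, ms, 1)
  res <- impute_dataset(inj$masked, imputer_config(k_prime = 8, n_clusters = 3))
  expect_false(anyNA(res$completed$values))
  h <- availability_mask(inj$masked)
  expect_identical(res$completed$values[h], inj$masked$values[h])
  expect_equal(nrow(res$provenance), sum(!h))
  # convexity per imputed cell against its donor set at that sample
  for (r in seq_len(min(10, nrow(res$provenance)))) {
    i <- res$provenance$gene[r]; u <- res$provenance$sample[r]
    cl <- which(res$model$assignments == res$model$assignments[i])
    donors <- inj$masked$values[setdiff(cl[h[cl, u]], i), u]
    expect_gte(res$completed$values[i, u], min(donors) - 1e-12)
    expect_lte(res$completed$values[i, u], max(donors) + 1e-12)
  }
  # no missing cells -> identity
  res0 <- impute_dataset(gen$matrix, imputer_config(n_clusters = 3))
  expect_identical(res0$completed$values, gen$matrix$values)
  # determinism
  res2 <- impute_dataset(inj$masked, imputer_config(k_prime = 8, n_clusters = 3))
  expect_identical(res$completed$values, res2$completed$values)
})

test_that("exact duplicates and zero-noise blocks are recovered perfectly", {
  # every incomplete gene has an exact complete duplicate
  base <- matrix(rnorm(40), 8, 5)
  x <- rbind(base, base)
  x[1, 2] <- NA; x[3, 4] <- NA
  em <- toy_em(x)
  res <- impute_dataset(em, imputer_config(k_prime = 3, n_clusters = 2))
  expect_equal(res$completed$values[1, 2], base[1, 2])
  expect_equal(res$completed$values[3, 4], base[3, 4])

  # zero within-block noise: all imputed values equal the block value
  sp <- synthetic_spec(30, 8, 3, separation = 5, noise_sd = 0, seed = 9)
  gen <- generate_clustered_expression(sp)
  inj <- inject_missing(gen$matrix, masking_spec(0.05, seed = 5), 1)
  res2 <- impute_dataset(inj$masked, imputer_config(k_prime = 5, n_clusters = 3))
  expect_equal(rmse(inj$truth, res2$completed), 0, tolerance = 1e-12)
})

test_that("categorical cells impute through the weighted majority", {
  sp <- synthetic_spec(30, 10, 3, separation = 6, noise_sd = 0.5, seed = 12)
  gen <- generate_mixed_types(sp, n_categorical = 2, n_levels = 3)
  m <- gen$matrix
  cat_col <- which(m$attr_kinds == "categorical")[1]
  truth <- m$values[5, cat_col]
  m$values[5, cat_col] <- NA
  res <- impute_dataset(m, imputer_config(k_prime = 5, n_clusters = 3))
  expect_equal(res$completed$values[5, cat_col], truth)
})

test_that("gene-permutation equivariance holds", {
  sp <- synthetic_spec(24, 8, 3, separation = 5, noise_sd = 1, seed = 14)
  gen <- generate_clustered_expression(sp)
  m <- gen$matrix
  m$values[cbind(c(2, 7, 20), c(1, 5, 8))] <- NA
  cfg <- imputer_config(k_prime = 6, n_clusters = 3, seed = 2)
  res <- impute_dataset(m, cfg)
  set.seed(33)
  perm <- sample(24)
  mp <- m
  mp$values <- m$values[perm, ]
  mp$gene_ids <- m$gene_ids[perm]
  resp <- impute_dataset(mp, cfg)
  back <- resp$completed$values[order(perm), ]
  expect_equal(back, res$completed$values, tolerance = 1e-9)
})
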