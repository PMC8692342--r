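test_that("knn_impute matches a brute-force reimplementation cell-for-cell", {
  for (seed in 1:4) {
    em <- rand_em(6, 5, miss_frac = 0.2, seed = seed + 20)
    h <- availability_mask(em)
    res <- knn_impute(em, h, k = 3)
    d <- brute_dist_matrix(em)
    miss <- which(!h, arr.ind = TRUE)
    for (r in seq_len(nrow(miss))) {
      i <- miss[r, 1]; u <- miss[r, 2]
      cand <- setdiff(which(h[, u]), i)
      dv <- d[i, cand]
      cand <- cand[!is.na(dv)]; dv <- dv[!is.na(dv)]
      ord <- order(dv, cand)[seq_len(min(3, length(dv)))]
      dd <- dv[ord]
      want <- if (dd[1] == 0) em$values[cand[ord][1], u] else {
        w <- (1 / dd) / sum(1 / dd)
        sum(w * em$values[cand[ord], u])
      }
      expect_equal(res$completed$values[i, u], want, tolerance = 1e-12)
    }
  }
})

test_that("knn_impute special cases: duplicates, k = 1, identity", {
  base <- matrix(rnorm(24), 6, 4)
  x <- rbind(base, base)
  x[2, 3] <- NA
  em <- toy_em(x)
  res <- knn_impute(em, k = 4)
  expect_equal(res$completed$values[2, 3], base[2, 3])  # duplicate donor wins

  em2 <- rand_em(8, 5, miss_frac = 0.15, seed = 3)
  h2 <- availability_mask(em2)
  res1 <- knn_impute(em2, h2, k = 1)
  d <- brute_dist_matrix(em2)
  miss <- which(!h2, arr.ind = TRUE)
  i <- miss[1, 1]; u <- miss[1, 2]
  cand <- setdiff(which(h2[, u]), i)
  nn <- cand[order(d[i, cand], cand)][1]
  expect_equal(res1$completed$values[i, u], em2$values[nn, u])

  complete <- toy_em(matrix(rnorm(20), 4, 5))
  expect_identical(knn_impute(complete, k = 3)$completed$values,
                   complete$values)
})

test_that("single-cluster equivalence: proposed with K=1-like pool equals knn", {
  em <- rand_em(12, 6, miss_frac = 0.1, seed = 7)
  h <- availability_mask(em)
  # a degenerate one-cluster model
  model <- structure(list(K = 1L, assignments = rep(1L, 12),
                          clusters = list(`1` = 1:12)), class = "ClusterModel")
  res_prop <- impute_dataset(em, imputer_config(k_prime = 4), model = model)
  res_knn <- knn_impute(em, h, k = 4)
  expect_equal(res_prop$completed$values, res_knn$completed$values,
               tolerance = 1e-12)
})

test_that("sknn reuses previously imputed genes in missing-rate order", {
  # three complete anchor genes and two near-duplicate incomplete genes:
  # gene 4 completes first (tie with gene 5 broken by row index) and then
  # donates its *imputed* col-3 value to gene 5
  x <- rbind(c(0, 0, 0, 0),
             c(10, 10, 10, 10),
             c(20, 20, 20, 20),
             c(12, 12, NA, 12),
             c(12.1, 12.1, NA, 12.1))
  em <- toy_em(x)
  res <- sknn_impute(em, k = 2)
  # hand transcript, gene 4: donors {g2 d=4, g3 d=16}, weights (0.8, 0.2)
  v4 <- 0.8 * 10 + 0.2 * 20
  expect_equal(res$completed$values[4, 3], v4, tolerance = 1e-10)
  # gene 5: nearest pool donors are completed g4 then g2
  d54 <- brute_distance(c(12.1, 12.1, NA, 12.1), c(12, 12, v4, 12))
  d52 <- brute_distance(c(12.1, 12.1, NA, 12.1), c(10, 10, 10, 10))
  w <- (1 / c(d54, d52)) / sum(1 / c(d54, d52))
  expect_equal(res$completed$values[5, 3], w[1] * v4 + w[2] * 10,
               tolerance = 1e-10)
  # plain knn cannot use gene 4 at col 3 and answers differently
  res_knn <- knn_impute(em, k = 2)
  expect_false(isTRUE(all.equal(res_knn$completed$values[5, 3],
                                res$completed$values[5, 3])))
  # one incomplete gene only -> sknn == knn
  y <- matrix(rnorm(20), 5, 4)
  y[2, 1] <- NA
  em2 <- toy_em(y)
  expect_equal(sknn_impute(em2, k = 2)$completed$values,
               knn_impute(em2, k = 2)$completed$values, tolerance = 1e-12)
  # determinism
  expect_identical(sknn_impute(em, k = 2)$completed$values,
                   res$completed$values)
})

test_that("iknn iterates from row means and matches a hand transcript", {
  x <- rbind(c(1, 2, 3, 4),
             c(1, 2, NA, 4),
             c(5, 6, 7, 8),
             c(5, NA, 7, 8),
             c(9, 10, 11, 12))
  em <- toy_em(x)
  # duplicate-structure data: first pass already lands on the fixed point
  res <- iknn_impute(em, k = 1, max_iter = 10, tol = 1e-6)
  expect_lte(res$iterations, 3L)
  expect_equal(res$completed$values[2, 3], 3)
  expect_equal(res$completed$values[4, 2], 6)

  # tol = Inf degenerates to one KNN pass on the row-mean-initialised matrix
  em3 <- rand_em(7, 5, miss_frac = 0.15, seed = 5)
  res_one <- iknn_impute(em3, k = 2, max_iter = 10, tol = Inf)
  expect_equal(res_one$iterations, 1L)
  h <- availability_mask(em3)
  init <- em3$values
  rm_ <- rowMeans(init, na.rm = TRUE)
  miss <- which(!h, arr.ind = TRUE)
  init[!h] <- rm_[miss[, 1]]
  # transcript of one sweep: plain Euclidean distances on the filled matrix
  filled <- toy_em(init)
  d <- brute_dist_matrix(filled)
  want <- init
  for (r in seq_len(nrow(miss))) {
    i <- miss[r, 1]; u <- miss[r, 2]
    cand <- setdiff(seq_len(7), i)
    ord <- order(d[i, cand], cand)[1:2]
    dd <- d[i, cand][ord]
    w <- if (dd[1] == 0) c(1, 0) else (1 / dd) / sum(1 / dd)
    want[i, u] <- sum(w * init[cand[ord], u])
  }
  expect_equal(res_one$completed$values, want, tolerance = 1e-10)
})

test_that("lls recovers exact linear structure and handles edge cases", {
  set.seed(17)
  a <- rnorm(10); b <- rnorm(10)
  # distractor genes sit far away so the top-2 donors are exactly a and b
  x <- unname(rbind(a, b, 2 * a - b, rnorm(10) + 100, rnorm(10) - 100))
  truth <- x[3, 4]
  x[3, 4] <- NA
  em <- toy_em(x)
  res <- lls_impute(em, k = 2, ridge = 0)
  expect_equal(res$completed$values[3, 4], truth, tolerance = 1e-8)

  # k = 1: simple regression on the single most similar gene
  y <- unname(rbind(a, 1.1 * a, rnorm(10) + 100))
  ty <- y[2, 5]; y[2, 5] <- NA
  res1 <- lls_impute(toy_em(y), k = 1, ridge = 0)
  expect_equal(res1$completed$values[2, 5], ty, tolerance = 1e-8)

  # all-constant genes predict the constant
  z <- matrix(5, 4, 6)
  z[2, 3] <- NA
  resc <- lls_impute(toy_em(z), k = 2)
  expect_equal(resc$completed$values[2, 3], 5, tolerance = 1e-4)

  # rank-deficient design with ridge = 0 still returns finite values
  w <- unname(rbind(a, a, a, c(a[1:9], NA)))
  resr <- lls_impute(toy_em(w), k = 3, ridge = 0)
  expect_true(is.finite(resr$completed$values[4, 10]))
})

test_that("slls chains donors sequentially and matches a two-step transcript", {
  set.seed(23)
  base <- matrix(rnorm(28), 4, 7)
  g5 <- base[1, ] * 1.5 + 0.2          # close to gene 1
  g6 <- g5 * 2                          # close to (completed) gene 5
  x <- unname(rbind(base, g5, g6))
  x[5, 7] <- NA
  x[6, 6] <- NA; x[6, 7] <- NA
  em <- toy_em(x)
  res <- slls_impute(em, k = 1, ridge = 0)
  # transcript: gene 5 first (fewer missing), regressed on its top
  # complete donor; then gene 6 with gene 5 completed and eligible
  d5 <- vapply(1:4, function(i) brute_distance(x[5, ], x[i, ]), numeric(1))
  don5 <- which.min(d5)
  b5 <- x[don5, 1:6]; cf5 <- sum(b5 * x[5, 1:6]) / sum(b5^2)
  v57 <- x[don5, 7] * cf5
  expect_equal(res$completed$values[5, 7], v57, tolerance = 1e-10)
  x2 <- x; x2[5, 7] <- v57
  d6 <- vapply(1:5, function(i) brute_distance(x2[6, ], x2[i, ]), numeric(1))
  don6 <- which.min(d6)
  expect_equal(don6, 5L)                # the chained donor really is gene 5
  b6 <- x2[don6, 1:5]; cf6 <- sum(b6 * x2[6, 1:5]) / sum(b6^2)
  expect_equal(res$completed$values[6, 6], x2[don6, 6] * cf6, tolerance = 1e-10)
  expect_equal(res$completed$values[6, 7], x2[don6, 7] * cf6, tolerance = 1e-10)
  # one incomplete gene -> identical to lls
  y <- unname(rbind(base, g5))
  y[5, 2] <- NA
  em2 <- toy_em(y)
  expect_equal(slls_impute(em2, k = 2)$completed$values,
               lls_impute(em2, k = 2)$completed$values, tolerance = 1e-12)
})

test_that("all five baselines preserve observed cells and complete the matrix", {
  sp <- synthetic_spec(40, 10, 3, separation = 4, noise_sd = 1, seed = 41)
  gen <- generate_clustered_expression(sp)
  inj <- inject_missing(gen$matrix, masking_spec(0.1, seed = 6), 1)
  h <- availability_mask(inj$masked)
  fns <- list(knn = function(m) knn_impute(m, k = 5),
              sknn = function(m) sknn_impute(m, k = 5),
              iknn = function(m) iknn_impute(m, k = 5),
              lls = function(m) lls_impute(m, k = 5),
              slls = function(m) slls_impute(m, k = 5))
  for (nm in names(fns)) {
    res <- fns[[nm]](inj$masked)
    expect_false(anyNA(res$completed$values), label = nm)
    expect_identical(res$completed$values[h], inj$masked$values[h],
                     label = nm)
    # and identity on a complete matrix
    res0 <- fns[[nm]](gen$matrix)
    expect_identical(res0$completed$values, gen$matrix$values, label = nm)
  }
})
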