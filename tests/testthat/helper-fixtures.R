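# Fixture builders and independent brute-force oracles.  The oracles are
# written from the definitions, not from the package internals, so they
# stay valid as checks on the implementation.

toy_em <- function(vals, ...) {
  suppressWarnings(expression_matrix(as.matrix(vals), ...))
}

# random expression matrix with a given fraction of missing cells, every
# gene keeping at least one observed value
rand_em <- function(n, m, miss_frac = 0.1, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * m), n, m)
  nmiss <- floor(miss_frac * n * m)
  if (nmiss > 0) {
    cand <- sample(n * m, nmiss)
    x[cand] <- NA
    for (i in which(rowSums(!is.na(x)) == 0)) x[i, sample(m, 1)] <- rnorm(1)
  }
  toy_em(x)
}

# definitional pairwise-complete distance (independent of the package's
# vectorised path)
brute_distance <- function(a, b, kinds = rep("numeric", length(a))) {
  co <- which(!is.na(a) & !is.na(b))
  if (length(co) == 0) return(NA_real_)
  ss <- 0
  for (j in co) {
    ss <- ss + if (kinds[j] == "categorical") as.numeric(a[j] != b[j])
               else (a[j] - b[j])^2
  }
  sqrt(ss * length(a) / length(co))
}

brute_dist_matrix <- function(em) {
  n <- nrow(em$values)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) d[i, j] <- brute_distance(em$values[i, ], em$values[j, ],
                                          em$attr_kinds)
  }
  d
}

# all-pairs-sort kNN neighbour sets (ties at the k-th distance kept)
brute_knn_sets <- function(d, k) {
  n <- nrow(d)
  lapply(seq_len(n), function(i) {
    di <- d[i, -i]
    ids <- seq_len(n)[-i]
    ok <- !is.na(di)
    di <- di[ok]; ids <- ids[ok]
    if (length(ids) == 0) return(integer(0))
    kk <- min(k, length(ids))
    thr <- sort(di)[kk]
    sort(ids[di <= thr])
  })
}

# union-find connected-component count on an undirected edge list
uf_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(edges) > 0) {
    for (e in seq_len(nrow(edges))) {
      ri <- find(edges[e, 1]); rj <- find(edges[e, 2])
      if (ri != rj) parent[ri] <- rj
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

# SimilarityGraph from an explicit symmetric weight matrix (tests of the
# Laplacian machinery on hand-made graphs)
graph_from_w <- function(w) {
  structure(list(n = nrow(w),
                 w = Matrix::forceSymmetric(Matrix::Matrix(w, sparse = TRUE)),
                 sigma = 1, mode = "full"),
            class = "SimilarityGraph")
}

write_tsv_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# minimal synthetic GDS SOFT fixture: values is a numeric matrix possibly
# holding NA (written as the token "null")
write_soft_fixture <- function(values, ids = NULL) {
  n <- nrow(values); m <- ncol(values)
  if (is.null(ids)) ids <- paste0("probe", seq_len(n))
  hdr <- paste(c("ID_REF", "IDENTIFIER", paste0("GSM", 100 + seq_len(m))),
               collapse = "\t")
  rows <- vapply(seq_len(n), function(r) {
    cells <- ifelse(is.na(values[r, ]), "null",
                    sprintf("%.10g", values[r, ]))
    paste(c(ids[r], paste0("SYM", r), cells), collapse = "\t")
  }, character(1))
  path <- withr::local_tempfile(fileext = ".soft",
                                .local_envir = parent.frame())
  writeLines(c("^DATASET = SYNTH0001",
               "!dataset_title = synthetic fixture",
               "!dataset_table_begin", hdr, rows,
               "!dataset_table_end"), path)
  path
}
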