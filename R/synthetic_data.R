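# Synthetic complete expression matrices with planted block (cluster)
# structure: the local-similarity world the imputer assumes.

#' Synthetic data specification
#'
#' @param n_genes Number of genes N.
#' @param n_samples Number of samples M (must be >= `n_blocks`).
#' @param n_blocks Planted cluster count.
#' @param block_sizes Partition of N over the blocks; defaults to a
#'   near-even split.  May be unequal to probe small-cluster paths.
#' @param separation Target ratio of the expected between-block row
#'   distance to the expected within-block row distance (>= 1 for a
#'   meaningful geometry when `noise_sd > 0`).
#' @param noise_sd Within-block standard deviation per coordinate.
#' @param seed Integer seed; generation is a pure function of the spec.
#' @param noise `"gaussian"` or `"t3"` (t with 3 df, rescaled to sd
#'   `noise_sd`) for stress-testing heavy tails.
#' @return A `SyntheticSpec` list.
#' @export
synthetic_spec <- function(n_genes, n_samples, n_blocks = 3L,
                           block_sizes = NULL, separation = 5,
                           noise_sd = 1, seed = 1L,
                           noise = c("gaussian", "t3")) {
  noise <- match.arg(noise)
  if (is.null(block_sizes)) {
    base <- n_genes %/% n_blocks
    block_sizes <- rep(base, n_blocks)
    extra <- n_genes - sum(block_sizes)
    if (extra > 0) block_sizes[seq_len(extra)] <- block_sizes[seq_len(extra)] + 1L
  }
  if (sum(block_sizes) != n_genes) {
    stop_si("block_sizes must sum to n_genes", "parameter")
  }
  if (separation < 0 || noise_sd < 0) {
    stop_si("separation and noise_sd must be nonnegative", "parameter")
  }
  if (n_samples < n_blocks) {
    stop_si("need n_samples >= n_blocks for distinct block prototypes",
            "parameter")
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_samples = as.integer(n_samples),
                 n_blocks = as.integer(n_blocks),
                 block_sizes = as.integer(block_sizes),
                 separation = separation, noise_sd = noise_sd,
                 seed = as.integer(seed), noise = noise),
            class = "SyntheticSpec")
}

# Block prototypes sit at the vertices of a regular simplex (all pairwise
# prototype distances equal), randomly rotated.  The edge length delta is
# chosen so that  sqrt(delta^2 + 2 M sd^2) = separation * sqrt(2 M sd^2):
# the expected between-block row distance is `separation` times the
# expected within-block one.
block_prototypes <- function(spec) {
  M <- spec$n_samples
  B <- spec$n_blocks
  if (B == 1L) return(matrix(0, 1L, M))
  within2 <- 2 * M * spec$noise_sd^2
  delta <- if (spec$noise_sd > 0) {
    sqrt(within2 * max(spec$separation^2 - 1, 0))
  } else {
    spec$separation          # scale is arbitrary when rows are noiseless
  }
  proto <- matrix(0, B, M)
  proto[cbind(seq_len(B), seq_len(B))] <- delta / sqrt(2)
  q <- qr.Q(qr(matrix(stats::rnorm(M * M), M, M)))   # random rotation
  proto %*% q
}

#' Generate a complete clustered expression matrix
#'
#' Each block has a prototype profile; gene rows are the prototype plus
#' i.i.d. noise of sd `noise_sd`.  Prototypes are placed so the expected
#' between-block row distance is `separation` times the expected
#' within-block distance.  Deterministic per seed.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `matrix` (a complete [expression_matrix()]) and
#'   `labels` (planted block of each gene).
#' @export
generate_clustered_expression <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  with_seed(spec$seed, {
    proto <- block_prototypes(spec)
    labels <- rep(seq_len(spec$n_blocks), spec$block_sizes)
    n <- spec$n_genes
    M <- spec$n_samples
    eps <- switch(spec$noise,
      gaussian = matrix(stats::rnorm(n * M, sd = spec$noise_sd), n, M),
      t3 = matrix(stats::rt(n * M, df = 3) * spec$noise_sd / sqrt(3), n, M))
    x <- proto[labels, , drop = FALSE] + eps
    list(matrix = expression_matrix(x,
                                    gene_ids = sprintf("g%04d", seq_len(n)),
                                    sample_ids = sprintf("s%02d", seq_len(M))),
         labels = labels)
  })
}

#' Generate a clustered matrix with categorical sample columns
#'
#' The last `n_categorical` sample columns carry block-dependent category
#' labels: every gene of block b gets level `((b - 1) mod n_levels) + 1`
#' (pure majority, no category noise), exercising the categorical
#' imputation path.  The remaining columns are numeric as in
#' [generate_clustered_expression()].
#'
#' @param spec A [synthetic_spec()].
#' @param n_categorical Number of trailing categorical columns
#'   (`<= n_samples`, and the numeric remainder must still fit
#'   `n_blocks` prototypes).
#' @param n_levels Number of category levels.
#' @return List with `matrix` and `labels` as above.
#' @export
generate_mixed_types <- function(spec, n_categorical = 0L, n_levels = 2L) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  if (n_categorical > spec$n_samples) {
    stop_si("n_categorical cannot exceed n_samples", "parameter")
  }
  if (n_categorical == 0L) return(generate_clustered_expression(spec))
  nspec <- spec
  nspec$n_samples <- spec$n_samples - n_categorical
  if (nspec$n_samples < spec$n_blocks) {
    stop_si("too many categorical columns: numeric part needs >= n_blocks columns",
            "parameter")
  }
  num <- generate_clustered_expression(nspec)
  labels <- num$labels
  lev <- paste0("L", seq_len(n_levels))
  codes <- ((labels - 1L) %% n_levels) + 1L
  cat_block <- matrix(rep(codes, n_categorical), ncol = n_categorical)
  vals <- cbind(num$matrix$values, cat_block)
  kinds <- c(rep("numeric", nspec$n_samples), rep("categorical", n_categorical))
  levels <- c(vector("list", nspec$n_samples),
              rep(list(lev), n_categorical))
  m <- expression_matrix(vals,
                         gene_ids = num$matrix$gene_ids,
                         sample_ids = sprintf("s%02d", seq_len(spec$n_samples)),
                         attr_kinds = kinds, levels = levels)
  list(matrix = m, labels = labels)
}
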