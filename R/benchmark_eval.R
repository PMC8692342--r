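# Artificial-missingness injection (MCAR / MAR), masked-cell RMSE, the
# thirty-replicate benchmarking protocol, and the neighbour-count sweep.

#' Masking specification
#'
#' @param rate Target missing fraction in (0, 1); the benchmarks use 0.05
#'   to 0.25.
#' @param mechanism `"mcar"` (uniform deletion) or `"mar"` (missingness
#'   driven by the observed values of an anchor sample).
#' @param mar_anchor Sample column whose observed values drive MAR
#'   missingness; never masked itself.
#' @param seed Master seed; each replicate derives its own stream.
#' @param n_replicates Number of replicate masks (the protocol uses 30).
#' @return A `MaskingSpec` list.
#' @export
masking_spec <- function(rate, mechanism = c("mcar", "mar"), mar_anchor = 1L,
                         seed = 1L, n_replicates = 30L) {
  mechanism <- match.arg(mechanism)
  if (!is.numeric(rate) || rate <= 0 || rate >= 1) {
    stop_si("rate must lie strictly between 0 and 1", "parameter")
  }
  if (n_replicates < 1L) stop_si("n_replicates must be >= 1", "parameter")
  structure(list(rate = rate, mechanism = mechanism,
                 mar_anchor = as.integer(mar_anchor), seed = as.integer(seed),
                 n_replicates = as.integer(n_replicates)),
            class = "MaskingSpec")
}

# deterministic per-(seed, replicate, rate-index) substream, kept < 2^31
replicate_seed <- function(seed, replicate, salt = 0L) {
  as.integer((as.double(seed) * 48271 + replicate * 9973 + salt * 131) %%
               2147483629 + 1)
}

#' Inject artificial missingness into a complete matrix
#'
#' Masks exactly `round(rate * N * M)` cells.  MCAR draws them uniformly
#' without replacement; MAR draws cell (i, j) with probability
#' proportional to `logistic((x[i, anchor] - median) / IQR)` — genes with
#' high anchor-sample expression lose more cells — with the anchor column
#' itself never masked.  Either way no gene loses all of its cells
#' (violating draws are repaired deterministically), and the mask is a
#' pure function of `(spec$seed, replicate)`.
#'
#' @param m A complete [expression_matrix()].
#' @param spec A [masking_spec()].
#' @param replicate Replicate index (1-based).
#' @return List with `masked` (ExpressionMatrix) and `truth` (data frame
#'   `gene`, `sample`, `value` of the masked cells).
#' @export
inject_missing <- function(m, spec, replicate = 1L) {
  stopifnot(inherits(m, "ExpressionMatrix"), inherits(spec, "MaskingSpec"))
  x <- m$values
  if (anyNA(x)) stop_si("inject_missing requires a complete matrix", "invalid_input")
  n <- nrow(x); M <- ncol(x)
  n_mask <- round(spec$rate * n * M)
  if (n_mask == 0L) {
    return(list(masked = m,
                truth = data.frame(gene = integer(0), sample = integer(0),
                                   value = numeric(0))))
  }
  eligible_cols <- seq_len(M)
  if (spec$mechanism == "mar") {
    eligible_cols <- setdiff(eligible_cols, spec$mar_anchor)
  }
  # each gene must keep >= 1 observed cell; a never-masked anchor column
  # guarantees that by itself
  max_feasible <- if (length(eligible_cols) < M) {
    n * length(eligible_cols)
  } else {
    n * (M - 1L)
  }
  if (n_mask > max_feasible) {
    stop_si("rate too high: cannot mask without emptying a gene", "parameter")
  }
  cells <- as.matrix(expand.grid(gene = seq_len(n), sample = eligible_cols))
  idx <- with_seed(replicate_seed(spec$seed, replicate), {
    if (spec$mechanism == "mcar") {
      sample.int(nrow(cells), n_mask)
    } else {
      anchor <- x[, spec$mar_anchor]
      iqr <- stats::IQR(anchor)
      if (iqr == 0) iqr <- 1
      p <- stats::plogis((anchor - stats::median(anchor)) / iqr)
      sample.int(nrow(cells), n_mask, prob = p[cells[, 1L]])
    }
  })
  sel <- logical(nrow(cells))
  sel[idx] <- TRUE
  # repair: a gene masked everywhere it could be gives back its cell with
  # the smallest selection order, swapped for the earliest unselected cell
  # of an unaffected gene (deterministic, count preserved)
  keeps_obs <- M - length(eligible_cols)   # columns that can never be masked
  if (keeps_obs == 0L) {
    masked_per_gene <- tabulate(cells[sel, 1L], n)
    full <- which(masked_per_gene >= M)
    for (gfull in full) {
      give_back <- which(sel & cells[, 1L] == gfull)[1L]
      per_gene <- tabulate(cells[sel, 1L], n)
      ok_rows <- which(!sel & per_gene[cells[, 1L]] < M - 1L)
      sel[give_back] <- FALSE
      sel[ok_rows[1L]] <- TRUE
    }
  }
  picked <- cells[sel, , drop = FALSE]
  xm <- x
  xm[picked] <- NA_real_
  masked <- m
  masked$values <- xm
  ord <- order(picked[, 1L], picked[, 2L])
  list(masked = masked,
       truth = data.frame(gene = picked[ord, 1L], sample = picked[ord, 2L],
                          value = x[picked[ord, , drop = FALSE]]))
}

#' Root mean square error over masked cells
#'
#' `sqrt(mean((true - imputed)^2))` on the original data scale, over the
#' artificially masked cells only.
#'
#' @param truth Data frame from [inject_missing()] (`gene`, `sample`,
#'   `value`).
#' @param imputed Completed [expression_matrix()] (or plain matrix).
#' @return Nonnegative scalar.
#' @export
rmse <- function(truth, imputed) {
  if (nrow(truth) == 0L) stop_si("RMSE undefined: no masked cells", "parameter")
  x <- if (inherits(imputed, "ExpressionMatrix")) imputed$values else imputed
  pred <- x[cbind(truth$gene, truth$sample)]
  if (anyNA(pred)) stop_si("imputed matrix still has missing masked cells", "contract")
  sqrt(mean((truth$value - pred)^2))
}

#' Replicate benchmark of imputation methods
#'
#' For each rate and replicate one mask is drawn; every method then
#' imputes the *same* masked matrix (paired design) and is scored by
#' masked-cell RMSE.  A method failure on a replicate is recorded as `NA`
#' and the run continues.
#'
#' @param m A complete [expression_matrix()].
#' @param methods Named list of imputer functions, each mapping a masked
#'   `ExpressionMatrix` to a completed one (an `ImputationResult` is also
#'   accepted).
#' @param rates Numeric vector of missing fractions.
#' @param spec A [masking_spec()] (its `rate` field is overridden by each
#'   element of `rates`).
#' @return An `EvalReport`: list with `results` (data frame method / rate /
#'   replicate / rmse), `aggregate` (mean and sd per method x rate), and
#'   the `spec`.
#' @export
replicate_benchmark <- function(m, methods, rates = spec$rate, spec) {
  stopifnot(length(names(methods)) == length(methods))
  rows <- list()
  for (ri in seq_along(rates)) {
    rspec <- spec
    rspec$rate <- rates[ri]
    rspec$seed <- replicate_seed(spec$seed, 0L, salt = ri)
    for (rep_i in seq_len(spec$n_replicates)) {
      inj <- inject_missing(m, rspec, rep_i)
      for (mn in names(methods)) {
        val <- tryCatch({
          res <- methods[[mn]](inj$masked)
          if (inherits(res, "ImputationResult")) res <- res$completed
          rmse(inj$truth, res)
        }, error = function(e) NA_real_)
        rows[[length(rows) + 1L]] <- data.frame(
          method = mn, rate = rates[ri], replicate = rep_i, rmse = val)
      }
    }
  }
  results <- do.call(rbind, rows)
  agg <- stats::aggregate(rmse ~ method + rate, data = results,
                          FUN = function(v) c(mean = mean(v), sd = stats::sd(v)),
                          na.action = stats::na.omit)
  aggregate <- data.frame(method = agg$method, rate = agg$rate,
                          mean_rmse = agg$rmse[, "mean"], sd_rmse = agg$rmse[, "sd"])
  structure(list(results = results, aggregate = aggregate, spec = spec),
            class = "EvalReport")
}

#' @export
print.EvalReport <- function(x, ...) {
  cat("EvalReport (mean RMSE over replicates):\n")
  print(x$aggregate, row.names = FALSE)
  invisible(x)
}

#' Sweep the neighbour count of an imputation method
#'
#' Runs the replicate protocol at a fixed rate (the parameter study uses
#' 5%) for each neighbour count in `k_values` and reports the mean RMSE
#' per k.  For efficiency, per-replicate work that does not depend on k
#' (the mask, the distance matrix, the cluster model) is computed once
#' when `method` is a *sweepable* method — see [sweepable_knn()] and
#' [sweepable_proposed()]; a plain `function(masked, k)` is also accepted.
#'
#' @param m A complete [expression_matrix()].
#' @param method A sweepable method object or `function(masked, k)`.
#' @param k_values Integer vector of neighbour counts.
#' @param spec A [masking_spec()] carrying the fixed rate.
#' @return Data frame with columns `k` and `mean_rmse`, plus attribute
#'   `per_replicate` (k x replicate RMSE matrix).
#' @export
neighbor_sweep <- function(m, method, k_values, spec) {
  per <- matrix(NA_real_, length(k_values), spec$n_replicates,
                dimnames = list(k = k_values, replicate = NULL))
  for (rep_i in seq_len(spec$n_replicates)) {
    inj <- inject_missing(m, spec, rep_i)
    if (inherits(method, "sweepable_method")) {
      state <- method$precompute(inj$masked)
      for (ki in seq_along(k_values)) {
        per[ki, rep_i] <- tryCatch(
          rmse(inj$truth, method$impute(state, k_values[ki])),
          error = function(e) NA_real_)
      }
    } else {
      for (ki in seq_along(k_values)) {
        per[ki, rep_i] <- tryCatch({
          res <- method(inj$masked, k_values[ki])
          if (inherits(res, "ImputationResult")) res <- res$completed
          rmse(inj$truth, res)
        }, error = function(e) NA_real_)
      }
    }
  }
  out <- data.frame(k = k_values, mean_rmse = rowMeans(per, na.rm = TRUE))
  attr(out, "per_replicate") <- per
  out
}

#' Sweepable KNN method for [neighbor_sweep()]
#'
#' Precomputes the pairwise-complete distance matrix once per masked
#' replicate and reuses it across every k.
#'
#' @param weighted Inverse-distance weighting flag.
#' @return A `sweepable_method` object.
#' @export
sweepable_knn <- function(weighted = TRUE) {
  structure(list(
    precompute = function(masked) {
      h <- availability_mask(masked)
      list(m = masked, h = h, dist = pairwise_distances(masked, h))
    },
    impute = function(state, k) {
      knn_impute(state$m, state$h, k = k, weighted = weighted,
                 dist = state$dist)$completed
    }),
    class = "sweepable_method")
}

#' Sweepable cluster-guided method for [neighbor_sweep()]
#'
#' Precomputes the distance matrix and the spectral cluster model once per
#' masked replicate (neither depends on k'), then imputes for each k'.
#'
#' @param cfg An [imputer_config()]; its `k_prime` is overridden by the
#'   sweep.
#' @return A `sweepable_method` object.
#' @export
sweepable_proposed <- function(cfg = imputer_config()) {
  structure(list(
    precompute = function(masked) {
      h <- availability_mask(masked)
      model <- spectral_cluster(masked, h, gcfg = cfg$graph,
                                K = cfg$n_clusters, seed = cfg$seed,
                                k_max = cfg$k_max)
      list(m = masked, dist = pairwise_distances(masked, h), model = model)
    },
    impute = function(state, k) {
      cfg$k_prime <- as.integer(k)
      impute_dataset(state$m, cfg, model = state$model,
                     dist = state$dist)$completed
    }),
    class = "sweepable_method")
}
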