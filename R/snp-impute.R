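#' Compute Illumina summary signals R and theta from raw intensities
#'
#' `R = X + Y` is the total fluorescence intensity (tracks total copy
#' number); `theta = (2/pi) * atan2(Y, X)` is the normalized allelic angle in
#' `[0, 1]` (tracks the allele/paralog ratio), following the platform
#' convention.  Wells with `X = Y = 0` carry no signal and return `NA`.
#'
#' @param x,y non-negative raw allele intensities (vectors of equal length).
#' @return `data.frame` with columns `r` and `theta`.
#' @export
#' @examples
#' compute_r_theta(1, 3)   # r = 4, theta = (2/pi) * atan(3)
compute_r_theta <- function(x, y) {
  if (any(x < 0, na.rm = TRUE) || any(y < 0, na.rm = TRUE)) {
    stop("intensities must be non-negative")
  }
  r <- x + y
  theta <- (2 / pi) * atan2(y, x)
  dead <- !is.na(r) & r == 0
  r[dead] <- NA_real_
  theta[dead] <- NA_real_
  data.frame(r = r, theta = theta)
}

#' Read a GenomeStudio-Final-Report-like SNP signal table
#'
#' Expects tab-separated columns `sample_id`, `snp_id`, `cohort` and either
#' raw intensities `x`, `y` or precomputed `r`, `theta`.  Missing `r`/`theta`
#' are derived via [compute_r_theta()].
#'
#' @param path path to the signal table.
#' @return `data.frame` with columns `sample_id`, `snp_id`, `x`, `y`, `r`,
#'   `theta`, `cohort`.
#' @export
read_snp_signals <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "snp_id", "cohort")
  if (!all(need %in% names(df))) {
    stop("signal table needs columns: ", paste(need, collapse = ", "))
  }
  if (!all(c("r", "theta") %in% names(df))) {
    if (!all(c("x", "y") %in% names(df))) {
      stop("signal table needs either (x, y) or (r, theta)")
    }
    rt <- compute_r_theta(df$x, df$y)
    df$r <- rt$r
    df$theta <- rt$theta
  }
  df
}

# Long signal table -> wide feature matrix with columns r_<snp>, theta_<snp>.
snp_feature_matrix <- function(signals, snps = NULL) {
  if (is.null(snps)) snps <- sort(unique(signals$snp_id))
  samples <- unique(signals$sample_id)
  feat <- matrix(NA_real_, length(samples), 2L * length(snps),
                 dimnames = list(samples, c(rbind(paste0("r_", snps),
                                                  paste0("theta_", snps)))))
  for (s in snps) {
    rows <- signals[signals$snp_id == s, , drop = FALSE]
    feat[rows$sample_id, paste0("r_", s)] <- rows$r
    feat[rows$sample_id, paste0("theta_", s)] <- rows$theta
  }
  feat
}

#' Screen SNPs for association with KIR copy number
#'
#' For every SNP and gene, fits the linear regression
#' `copy number ~ R + theta` within each imputed call dataset and takes the
#' overall F-test p-value against the intercept-only model; the m per-dataset
#' p-values are combined by their median.  A constant predictor is dropped
#' from the fit with a warning; a constant response yields `p = 1` by
#' convention (no variance to explain).
#'
#' @param signals long signal table (see [read_snp_signals()]).
#' @param calls character matrix (samples x m) of imputed joint group labels,
#'   rownames = sample ids (from [draw_imputations()]).
#' @param alpha significance threshold for the `passes` flag (default 0.05).
#' @return `data.frame` with `snp_id`, `gene`, `p_value`, `passes`.
#' @export
screen_snps <- function(signals, calls, alpha = 0.05) {
  snps <- sort(unique(signals$snp_id))
  m <- ncol(calls)
  out <- expand.grid(snp_id = snps, gene = c("3DS1", "3DL1"),
                     stringsAsFactors = FALSE)
  out$p_value <- NA_real_
  for (i in seq_len(nrow(out))) {
    rows <- signals[signals$snp_id == out$snp_id[i], , drop = FALSE]
    common <- intersect(rows$sample_id, rownames(calls))
    rows <- rows[match(common, rows$sample_id), , drop = FALSE]
    copy_of <- if (out$gene[i] == "3DS1") group_s else group_l
    ps <- vapply(seq_len(m), function(j) {
      copy <- copy_of(calls[common, j])
      regression_f_p(copy, rows$r, rows$theta)
    }, numeric(1))
    out$p_value[i] <- stats::median(ps)
  }
  out$passes <- out$p_value < alpha
  out
}

# Overall F-test p-value of copy ~ r + theta, with degenerate-input rules.
regression_f_p <- function(copy, r, theta) {
  ok <- stats::complete.cases(copy, r, theta)
  copy <- copy[ok]; r <- r[ok]; theta <- theta[ok]
  if (length(copy) < 4L || stats::var(copy) == 0) return(1)
  keep <- c(r = stats::var(r) > 0, theta = stats::var(theta) > 0)
  if (!any(keep)) return(1)
  if (!all(keep)) {
    warning("constant predictor dropped from copy-number screen: ",
            names(keep)[!keep])
  }
  X <- cbind(r, theta)[, keep, drop = FALSE]
  fit <- stats::lm(copy ~ X)
  f <- summary(fit)$fstatistic
  if (is.null(f)) return(1)
  unname(stats::pf(f[1L], f[2L], f[3L], lower.tail = FALSE))
}

# Standardization parameters from training features only.
feature_scaling <- function(train) {
  mu <- colMeans(train)
  sd <- apply(train, 2L, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(center = mu, scale = sd)
}

apply_scaling <- function(x, scaling) {
  scale(x, center = scaling$center, scale = scaling$scale)
}

# k nearest training rows for each query row (euclidean), ties on distance
# broken by smaller training index.  Returns index and distance matrices
# (n_query x k).  Queries are processed in blocks to bound memory.
knn_neighbours <- function(train, query, k, exclude_self = FALSE) {
  n <- nrow(train)
  if (k > n - as.integer(exclude_self)) {
    stop("k = ", k, " exceeds the number of available training samples")
  }
  nq <- nrow(query)
  idx <- matrix(0L, nq, k)
  dst <- matrix(0, nq, k)
  if (nq == 0L) return(list(index = idx, dist = dst))
  tr2 <- rowSums(train^2)
  block <- max(1L, floor(4e6 / n))
  for (start in seq(1L, nq, by = block)) {
    rows <- start:min(start + block - 1L, nq)
    q <- query[rows, , drop = FALSE]
    d2 <- outer(rowSums(q^2), tr2, "+") - 2 * tcrossprod(q, train)
    d2[d2 < 0] <- 0
    if (exclude_self) d2[cbind(seq_along(rows), rows)] <- Inf
    for (j in seq_along(rows)) {
      o <- order(d2[j, ], seq_len(n))[seq_len(k)]
      idx[rows[j], ] <- o
      dst[rows[j], ] <- sqrt(d2[j, o])
    }
  }
  list(index = idx, dist = dst)
}

# Majority vote with deterministic tie-breaking: (1) most neighbour votes,
# (2) smaller summed neighbour distance, (3) more frequent training class,
# (4) lexicographic group label order.
knn_vote <- function(nb_labels, nb_dist, class_freq) {
  votes <- table(nb_labels)
  top <- names(votes)[votes == max(votes)]
  if (length(top) > 1L) {
    dsum <- vapply(top, function(cl) sum(nb_dist[nb_labels == cl]), numeric(1))
    top <- top[dsum == min(dsum)]
  }
  if (length(top) > 1L) {
    fr <- class_freq[top]
    fr[is.na(fr)] <- 0
    top <- top[fr == max(fr)]
  }
  sort(top)[1L]
}

#' k-nearest-neighbour prediction of copy-number groups from SNP signals
#'
#' Classifies query samples by majority vote among the `k` nearest training
#' samples in standardized `(R, theta)` feature space (Euclidean distance;
#' features are z-scored with training-set parameters so that the
#' incommensurate R and theta scales contribute comparably).  When the
#' training labels form a matrix (one column per imputed qPCR call dataset),
#' one prediction per query per dataset is returned.
#'
#' @param train numeric feature matrix of the training samples.
#' @param labels training labels: character vector, or matrix (n x m) for
#'   multiply-imputed label sets.
#' @param query numeric feature matrix of the samples to classify (same
#'   columns as `train`).
#' @param k neighbour count (`1 <= k <= nrow(train)`).
#' @param standardize z-score features on the training data first
#'   (default `TRUE`).
#' @return character vector (or n_query x m matrix) of predicted groups.
#' @export
knn_predict <- function(train, labels, query, k, standardize = TRUE) {
  train <- as.matrix(train)
  query <- as.matrix(query)
  if (standardize) {
    sc <- feature_scaling(train)
    train <- apply_scaling(train, sc)
    query <- apply_scaling(query, sc)
  }
  nb <- knn_neighbours(train, query, k)
  lab_mat <- if (is.matrix(labels)) labels else matrix(labels, ncol = 1L)
  out <- matrix(NA_character_, nrow(query), ncol(lab_mat))
  for (j in seq_len(ncol(lab_mat))) {
    freq <- table(lab_mat[, j])
    out[, j] <- vapply(seq_len(nrow(query)), function(i) {
      knn_vote(lab_mat[nb$index[i, ], j], nb$dist[i, ], freq)
    }, character(1))
  }
  rownames(out) <- rownames(query)
  if (is.matrix(labels)) out else drop(out)
}

#' Leave-one-out cross-validation error of the knn classifier
#'
#' Each training sample is predicted from all others; the error is the
#' fraction whose prediction mismatches their (imputed) qPCR label, computed
#' per imputed label dataset and summarised by mean, min and max over the m
#' datasets.  With a cohort vector, errors are also computed within
#' cases-only and controls-only training sets, since batch shifts between
#' cohorts can make single-cohort training misleading.
#'
#' @param features numeric feature matrix (samples x features).
#' @param labels label vector or (n x m) matrix of imputed label sets.
#' @param k neighbour count.
#' @param cohort optional case/control vector aligned with rows.
#' @param standardize z-score features first (default `TRUE`).
#' @return `data.frame` with one row per cohort stratum (`combined`, plus
#'   each cohort level when given): `k`, `n`, `mean_error`, `min_error`,
#'   `max_error`.
#' @export
loocv_error <- function(features, labels, k, cohort = NULL, standardize = TRUE) {
  features <- as.matrix(features)
  lab_mat <- if (is.matrix(labels)) labels else matrix(labels, ncol = 1L)
  strata <- list(combined = seq_len(nrow(features)))
  if (!is.null(cohort)) {
    strata <- c(strata, split(seq_len(nrow(features)), cohort))
  }
  out <- lapply(names(strata), function(nm) {
    rows <- strata[[nm]]
    errs <- loocv_error_one(features[rows, , drop = FALSE],
                            lab_mat[rows, , drop = FALSE], k, standardize)
    data.frame(cohort = nm, k = k, n = length(rows),
               mean_error = mean(errs), min_error = min(errs),
               max_error = max(errs), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Per-dataset LOOCV error rates for one sample set; neighbour geometry is
# computed once and reused across the m label datasets.
loocv_error_one <- function(features, lab_mat, k, standardize = TRUE) {
  if (standardize) {
    sc <- feature_scaling(features)
    features <- apply_scaling(features, sc)
  }
  nb <- knn_neighbours(features, features, k, exclude_self = TRUE)
  vapply(seq_len(ncol(lab_mat)), function(j) {
    freq <- table(lab_mat[, j])
    pred <- vapply(seq_len(nrow(features)), function(i) {
      knn_vote(lab_mat[nb$index[i, ], j], nb$dist[i, ], freq)
    }, character(1))
    mean(pred != lab_mat[, j])
  }, numeric(1))
}

#' Select the best SNP subset and neighbour count by LOOCV
#'
#' Evaluates every candidate SNP subset against every `k` in the grid by the
#' mean LOOCV error over the imputed label datasets and returns the
#' minimiser.  Ties are broken towards the smaller subset, then the smaller
#' `k`, then candidate order.
#'
#' @param signals long signal table.
#' @param labels (n x m) matrix of imputed training labels (rownames =
#'   sample ids).
#' @param candidates named list of character vectors of SNP ids.
#' @param k_grid neighbour counts to try (default `1:30`).
#' @param standardize z-score features (default `TRUE`).
#' @return list with `best_set` (name), `best_snps`, `best_k`, and the full
#'   error `table`.
#' @export
select_knn_model <- function(signals, labels, candidates, k_grid = 1:30,
                             standardize = TRUE) {
  stopifnot(length(candidates) > 0)
  if (is.null(names(candidates))) {
    names(candidates) <- vapply(candidates, paste, character(1), collapse = "+")
  }
  grid <- list()
  for (nm in names(candidates)) {
    feat <- snp_feature_matrix(signals, candidates[[nm]])
    common <- intersect(rownames(feat), rownames(labels))
    feat <- feat[common, , drop = FALSE]
    lab <- labels[common, , drop = FALSE]
    for (k in k_grid) {
      errs <- loocv_error_one(feat, lab, k, standardize)
      grid[[length(grid) + 1L]] <- data.frame(
        set = nm, n_snps = length(candidates[[nm]]), k = k,
        mean_error = mean(errs), min_error = min(errs),
        max_error = max(errs), stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, grid)
  ord <- order(tab$mean_error, tab$n_snps, tab$k,
               match(tab$set, names(candidates)))
  best <- tab[ord[1L], ]
  list(best_set = best$set, best_snps = candidates[[best$set]],
       best_k = best$k, table = tab)
}

#' Learning curve: LOOCV error versus training-set size
#'
#' For each fraction of the training data, draws `n_repeats` random subsets,
#' computes the LOOCV error over the `k` grid within each subset, and
#' averages over repeats (and over imputed label datasets).  Used to judge
#' how many qPCR-typed samples are needed before the knn imputation error
#' stabilises.
#'
#' @param features numeric feature matrix.
#' @param labels label vector or (n x m) matrix.
#' @param fractions subset fractions in `(0, 1]`.
#' @param k_grid neighbour counts to evaluate.
#' @param n_repeats random subsets per fraction (default 25); fraction 1 uses
#'   a single (full) subset.
#' @param seed optional integer seed for the subset draws.
#' @param standardize z-score features within each subset (default `TRUE`).
#' @return `data.frame` with `fraction`, `n`, `k`, `mean_error` (average
#'   over repeats and imputations), `min_error`, `max_error`.
#' @export
training_size_curve <- function(features, labels, fractions, k_grid,
                                n_repeats = 25, seed = NULL,
                                standardize = TRUE) {
  stopifnot(all(fractions > 0 & fractions <= 1))
  if (!is.null(seed)) set.seed(seed)
  features <- as.matrix(features)
  lab_mat <- if (is.matrix(labels)) labels else matrix(labels, ncol = 1L)
  n <- nrow(features)
  out <- list()
  for (f in fractions) {
    size <- max(round(f * n), max(k_grid) + 1L)
    reps <- if (size >= n) 1L else n_repeats
    err <- array(NA_real_, c(reps, length(k_grid), ncol(lab_mat)))
    for (r in seq_len(reps)) {
      rows <- if (size >= n) seq_len(n) else sort(sample.int(n, size))
      for (ki in seq_along(k_grid)) {
        err[r, ki, ] <- loocv_error_one(features[rows, , drop = FALSE],
                                        lab_mat[rows, , drop = FALSE],
                                        k_grid[ki], standardize)
      }
    }
    for (ki in seq_along(k_grid)) {
      out[[length(out) + 1L]] <- data.frame(
        fraction = f, n = size, k = k_grid[ki],
        mean_error = mean(err[, ki, ]),
        min_error = min(err[, ki, ]), max_error = max(err[, ki, ]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
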