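#' Posterior responsibilities under a bivariate Gaussian mixture with
#' per-sample component masks
#'
#' Low-level E-step.  For sample `i` with allowed component set `M_i`
#' (its mask), the posterior of component `g` is
#' `pi_g * phi(z_i; mu_g, Sigma_g)` renormalized over `M_i`; masked
#' components get probability exactly 0.  Masks encode the hard-zero
#' constraint: a sample with a non-amplifying gene can only belong to groups
#' with zero copies of that gene.
#'
#' @param points numeric matrix (n x 2) of normalized delta-Ct coordinates.
#' @param weights component weights (sum to 1).
#' @param means matrix (G x 2) of component means.
#' @param covs array (2 x 2 x G) of component covariance matrices.
#' @param masks logical matrix (n x G) of allowed components; `NULL` means
#'   all allowed.
#' @return list with `posterior` (n x G matrix, rows sum to 1) and `loglik`
#'   (the total masked-mixture log-likelihood).
#' @export
mixture_posterior <- function(points, weights, means, covs, masks = NULL) {
  points <- as.matrix(points)
  n <- nrow(points)
  G <- length(weights)
  if (is.null(masks)) masks <- matrix(TRUE, n, G)
  logd <- matrix(-Inf, n, G)
  for (g in seq_len(G)) {
    logd[, g] <- log(weights[g]) + dmvnorm2_log(points, means[g, ], covs[, , g])
  }
  logd[!masks] <- -Inf
  mx <- apply(logd, 1L, max)
  lse <- mx + log(rowSums(exp(logd - mx)))
  post <- exp(logd - lse)
  post[!masks] <- 0
  dimnames(post) <- list(rownames(points), rownames(means))
  list(posterior = post, loglik = sum(lse))
}

# Log-density of a bivariate normal, via the closed-form 2x2 inverse.
dmvnorm2_log <- function(x, mu, sigma) {
  det_s <- sigma[1, 1] * sigma[2, 2] - sigma[1, 2] * sigma[2, 1]
  if (det_s <= 0) stop("non-positive-definite component covariance")
  d1 <- x[, 1] - mu[1]
  d2 <- x[, 2] - mu[2]
  q <- (sigma[2, 2] * d1^2 - 2 * sigma[1, 2] * d1 * d2 + sigma[1, 1] * d2^2) / det_s
  -log(2 * pi) - 0.5 * log(det_s) - 0.5 * q
}

# Clip the eigenvalues of a symmetric 2x2 matrix from below.
floor_eigen <- function(sigma, floor) {
  e <- eigen(sigma, symmetric = TRUE)
  v <- pmax(e$values, floor)
  sigma <- e$vectors %*% diag(v) %*% t(e$vectors)
  (sigma + t(sigma)) / 2
}

#' Fit the eight-component KIR copy-number mixture by EM
#'
#' Fits a mixture of eight bivariate Gaussians to the normalized
#' `(delta-Ct KIR3DS1, delta-Ct KIR3DL1)` plane, one component per
#' copy-number group, and assigns every sample posterior probabilities over
#' the eight groups.  Hard-zero samples participate with pseudo-coordinate 0
#' for the zeroed gene and a mask restricting them to the compatible
#' components, so they inform the zero-group parameters without being free to
#' move elsewhere.  Initialization is deterministic: points are assigned to
#' the nearest allowed expected centre (`kir_group_centers()`), giving
#' initial weights (floored), means and within-cluster covariances
#' (eigenvalue-floored).  The EM objective is the masked-mixture
#' log-likelihood, which is non-decreasing across iterations.
#'
#' @param records normalized, merged per-sample delta-Ct table (from
#'   [qpcr_pipeline()] or equivalent) with `dct_3ds1`, `dct_3dl1` and
#'   hard-zero flags; samples flagged `no_call` are excluded and reported.
#'   Alternatively a plain numeric matrix of coordinates (no masks).
#' @param tol convergence tolerance on the log-likelihood change
#'   (default 1e-8).
#' @param max_iter maximum EM iterations (default 500).
#' @param var_floor eigenvalue floor for component covariances, in squared
#'   normalized delta-Ct units (default 1e-4); prevents rare groups from
#'   collapsing to singular fits.
#' @param weight_floor floor applied to the initial component weights
#'   (default 1e-3) so that rare but biologically fixed groups stay alive.
#' @param freeze_weight components whose weight falls below this value keep
#'   their initialization parameters rather than being deleted
#'   (default 1e-6): the group set is biologically fixed.
#' @return object of class `kir_mixture`: component `weights`, `means`,
#'   `covs`, `loglik_trace`, posterior matrix (`posterior`), MAP calls
#'   (`map_call`), masks, excluded no-call sample ids, convergence info.
#' @export
fit_kir_mixture <- function(records, tol = 1e-8, max_iter = 500,
                            var_floor = 1e-4, weight_floor = 1e-3,
                            freeze_weight = 1e-6) {
  groups <- kir_groups()
  centers <- kir_group_centers(groups)
  G <- length(groups)

  if (is.matrix(records)) {
    points <- records
    masks <- matrix(TRUE, nrow(points), G)
    sample_ids <- rownames(points)
    no_call <- character(0)
  } else {
    no_call <- records$sample_id[records$no_call]
    rec <- records[!records$no_call, , drop = FALSE]
    x <- ifelse(rec$hard_zero_3ds1, 0, rec$dct_3ds1)
    y <- ifelse(rec$hard_zero_3dl1, 0, rec$dct_3dl1)
    points <- cbind(dct_3ds1 = x, dct_3dl1 = y)
    masks <- matrix(TRUE, nrow(points), G)
    masks[rec$hard_zero_3ds1, ] <- rep(group_s(groups) == 0L,
                                       each = sum(rec$hard_zero_3ds1))
    masks[rec$hard_zero_3dl1, ] <- masks[rec$hard_zero_3dl1, , drop = FALSE] &
      rep(group_l(groups) == 0L, each = sum(rec$hard_zero_3dl1))
    sample_ids <- rec$sample_id
  }
  if (!all(is.finite(points))) stop("non-finite coordinates in mixture input")
  n <- nrow(points)
  if (n < G) stop("need at least ", G, " samples to fit the mixture")

  # deterministic init: nearest allowed expected centre
  d2 <- outer(points[, 1], centers[, 1], "-")^2 +
        outer(points[, 2], centers[, 2], "-")^2
  d2[!masks] <- Inf
  assign0 <- max.col(-d2, ties.method = "first")
  w0 <- pmax(tabulate(assign0, G) / n, weight_floor)
  w0 <- w0 / sum(w0)
  mu0 <- centers
  cov0 <- array(0, c(2, 2, G))
  pooled <- NULL
  sizes <- tabulate(assign0, G)
  big <- which(sizes >= 3L)
  if (length(big)) {
    pooled <- Reduce(`+`, lapply(big, function(g) {
      stats::cov(points[assign0 == g, , drop = FALSE]) * (sizes[g] - 1)
    })) / (sum(sizes[big]) - length(big))
  }
  if (is.null(pooled) || !all(is.finite(pooled))) pooled <- diag(0.01, 2)
  for (g in seq_len(G)) {
    if (sizes[g] >= 3L) {
      mu0[g, ] <- colMeans(points[assign0 == g, , drop = FALSE])
      cov0[, , g] <- floor_eigen(stats::cov(points[assign0 == g, , drop = FALSE]),
                                 var_floor)
    } else {
      cov0[, , g] <- floor_eigen(pooled, var_floor)
    }
  }

  weights <- w0; means <- mu0; covs <- cov0
  init <- list(weights = w0, means = mu0, covs = cov0)
  trace <- numeric(0)
  prev_ll <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    e <- mixture_posterior(points, weights, means, covs, masks)
    trace <- c(trace, e$loglik)
    if (is.finite(prev_ll) && e$loglik < prev_ll - 1e-6) {
      stop("EM failed to improve the log-likelihood (iteration ", iter, ")")
    }
    if (is.finite(prev_ll) && abs(e$loglik - prev_ll) < tol) {
      converged <- TRUE
      break
    }
    prev_ll <- e$loglik
    r <- e$posterior
    ng <- colSums(r)
    weights <- ng / n
    for (g in seq_len(G)) {
      if (weights[g] < freeze_weight) {
        means[g, ] <- init$means[g, ]
        covs[, , g] <- init$covs[, , g]
        next
      }
      mu <- colSums(r[, g] * points) / ng[g]
      d <- sweep(points, 2L, mu)
      s <- crossprod(d * sqrt(r[, g])) / ng[g]
      means[g, ] <- mu
      covs[, , g] <- floor_eigen(s, var_floor)
    }
  }
  e <- mixture_posterior(points, weights, means, covs, masks)
  post <- e$posterior
  dimnames(post) <- list(sample_ids, groups)
  map_call <- groups[max.col(post, ties.method = "first")]
  names(map_call) <- sample_ids

  structure(list(
    groups = groups, weights = stats::setNames(weights, groups),
    means = means, covs = covs, loglik_trace = trace,
    posterior = post, map_call = map_call,
    points = points, masks = masks, no_call = no_call,
    converged = converged, n_iter = length(trace)
  ), class = "kir_mixture")
}

#' @export
print.kir_mixture <- function(x, ...) {
  cat("KIR3DS1/KIR3DL1 copy-number mixture (8 bivariate Gaussian components)\n")
  cat(sprintf("  %d samples, %d EM iterations (%sconverged), loglik %.3f\n",
              nrow(x$posterior), x$n_iter, if (x$converged) "" else "NOT ",
              utils::tail(x$loglik_trace, 1)))
  hp <- mean(apply(x$posterior, 1, max) > 0.99)
  cat(sprintf("  MAP posterior > 0.99 for %.1f%% of samples; %d no-call sample(s)\n",
              100 * hp, length(x$no_call)))
  print(table(factor(x$map_call, levels = x$groups)))
  invisible(x)
}

#' Draw multiply-imputed hard-call datasets from mixture posteriors
#'
#' Each imputed dataset assigns every sample one hard copy-number group drawn
#' from its posterior distribution; across many draws the empirical call
#' frequencies converge to the posteriors.  Downstream analyses run on each
#' dataset in parallel and are pooled by Rubin's rules.
#'
#' @param fit `kir_mixture` object, or a posterior matrix (rows sum to 1,
#'   columns named by group).
#' @param m number of imputed datasets (default 10).  `m = 1` triggers a
#'   warning since between-imputation variance is then undefined.
#' @param seed optional integer seed; fixed seeds reproduce the draw exactly.
#' @return character matrix (samples x m) of group labels.
#' @export
draw_imputations <- function(fit, m = 10, seed = NULL) {
  post <- if (inherits(fit, "kir_mixture")) fit$posterior else as.matrix(fit)
  if (m < 2) warning("m < 2: between-imputation variance is undefined")
  if (!is.null(seed)) set.seed(seed)
  groups <- colnames(post)
  out <- t(apply(post, 1L, function(p) sample(groups, m, replace = TRUE, prob = p)))
  if (m == 1L) out <- matrix(out, ncol = 1L, dimnames = list(rownames(post), NULL))
  rownames(out) <- rownames(post)
  out
}

#' Summarise MAP calls by copy-number group (and cohort)
#'
#' @param fit `kir_mixture` object.
#' @param cohort optional vector of cohort labels (e.g. case/control), named
#'   by sample id or aligned with the fit's samples.
#' @return `data.frame` of MAP-call counts per group (per cohort when given),
#'   with the fraction of samples whose maximum posterior exceeds 0.99
#'   attached as attribute `"high_posterior"`.
#' @export
call_summary <- function(fit, cohort = NULL) {
  calls <- factor(fit$map_call, levels = fit$groups)
  if (length(calls) == 0L) {
    out <- data.frame(group = character(0), n = integer(0))
    attr(out, "high_posterior") <- NA_real_
    return(out)
  }
  if (is.null(cohort)) {
    out <- as.data.frame(table(group = calls), responseName = "n")
  } else {
    if (!is.null(names(cohort))) cohort <- cohort[names(fit$map_call)]
    out <- as.data.frame(table(group = calls, cohort = cohort),
                         responseName = "n")
  }
  out <- out[out$n > 0L, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "high_posterior") <- mean(apply(fit$posterior, 1L, max) > 0.99)
  out
}
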