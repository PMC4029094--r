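#' Crude odds ratio with Woolf confidence interval
#'
#' For a 2x2 table with exposed cases `a`, exposed controls `b`, reference
#' cases `c` and reference controls `d`: `OR = (a d) / (b c)` with the Woolf
#' log-scale interval `exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.
#' Any zero cell leaves the OR undefined (flagged, no continuity
#' correction), matching the convention of leaving such table rows blank.
#'
#' @param a,b,c,d non-negative cell counts.
#' @param conf confidence level (default 0.95).
#' @return `data.frame` with `or`, `lo`, `hi`, `undefined`.
#' @export
#' @examples
#' crude_or_ci(257, 234, 457, 460)  # OR 1.11, 95% CI 0.89-1.38
crude_or_ci <- function(a, b, c, d, conf = 0.95) {
  stopifnot(all(c(a, b, c, d) >= 0))
  undefined <- (a == 0 | b == 0 | c == 0 | d == 0)
  or <- lo <- hi <- rep(NA_real_, length(undefined))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ok <- !undefined
  or[ok] <- (a[ok] * d[ok]) / (b[ok] * c[ok])
  se <- sqrt(1 / a[ok] + 1 / b[ok] + 1 / c[ok] + 1 / d[ok])
  lo[ok] <- exp(log(or[ok]) - z * se)
  hi[ok] <- exp(log(or[ok]) + z * se)
  data.frame(or = or, lo = lo, hi = hi, undefined = undefined)
}

#' Pool estimates across imputed datasets by Rubin's rules
#'
#' Point estimate = mean of the m estimates; within-imputation variance
#' `W` = mean of the variances; between-imputation variance `B` = sample
#' variance of the estimates; total variance `T = W + (1 + 1/m) B`.  Degrees
#' of freedom follow the Barnard-Rubin small-sample formula when a finite
#' complete-data df is supplied, else the classic large-sample formula; with
#' `B = 0` (all imputations agree) the estimate collapses to the
#' complete-data analysis.
#'
#' @param estimates numeric vector of m per-dataset estimates (e.g.
#'   log-odds).
#' @param variances numeric vector of their m squared standard errors.
#' @param dfcom complete-data degrees of freedom (default `Inf`).
#' @return `data.frame` with `estimate`, `W`, `B`, `total_var`, `se`, `df`,
#'   `p` (two-sided, from t(df)).
#' @export
#' @examples
#' rubin_pool(c(0, 1), c(1, 1))  # estimate 0.5, W 1, B 0.5, total 1.75
rubin_pool <- function(estimates, variances, dfcom = Inf) {
  m <- length(estimates)
  if (m < 2) stop("need m >= 2 imputed datasets to pool")
  stopifnot(length(variances) == m, all(variances > 0))
  qbar <- mean(estimates)
  W <- mean(variances)
  B <- stats::var(estimates)
  Tv <- W + (1 + 1 / m) * B
  if (B == 0) {
    df <- dfcom
  } else {
    gamma <- (1 + 1 / m) * B / Tv
    df_old <- (m - 1) / gamma^2
    if (is.finite(dfcom)) {
      df_obs <- (dfcom + 1) / (dfcom + 3) * dfcom * (1 - gamma)
      df <- 1 / (1 / df_old + 1 / df_obs)
    } else {
      df <- df_old
    }
  }
  se <- sqrt(Tv)
  p <- if (is.finite(df)) 2 * stats::pt(-abs(qbar) / se, df) else
    2 * stats::pnorm(-abs(qbar) / se)
  data.frame(estimate = qbar, W = W, B = B, total_var = Tv, se = se,
             df = df, p = p)
}

# D1-style pooled multivariate Wald test on a vector of coefficients.
# Qhat: m x q matrix of per-dataset estimates; Uhat: q x q x m covariances.
pooled_wald <- function(Qhat, Uhat) {
  m <- nrow(Qhat)
  q <- ncol(Qhat)
  qbar <- colMeans(Qhat)
  ubar <- apply(Uhat, c(1, 2), mean)
  B <- stats::cov(Qhat)
  r1 <- (1 + 1 / m) * sum(diag(B %*% solve(ubar))) / q
  D1 <- drop(t(qbar) %*% solve(ubar) %*% qbar) / (q * (1 + r1))
  t_ <- q * (m - 1)
  nu <- if (t_ > 4) {
    4 + (t_ - 4) * (1 + (1 - 2 / t_) / r1)^2
  } else {
    t_ * (1 + 1 / q) * (1 + 1 / r1)^2 / 2
  }
  p <- stats::pf(D1, q, nu, lower.tail = FALSE)
  list(statistic = D1, df1 = q, df2 = nu, p = p)
}

# Map joint "s-l" labels to the requested grouping with its reference level.
grouping_factor <- function(calls, grouping, reference = NULL) {
  values <- switch(grouping,
    joint = calls,
    `3DL1` = as.character(group_l(calls)),
    `3DS1` = as.character(group_s(calls)),
    stop("unknown grouping: ", grouping))
  if (is.null(reference)) {
    reference <- switch(grouping, joint = "0-2", `3DL1` = "2", `3DS1` = "0")
  }
  levels <- switch(grouping,
    joint = kir_groups(),
    `3DL1` = sort(unique(c(reference, values))),
    `3DS1` = sort(unique(c(reference, values))))
  f <- factor(values, levels = levels)
  stats::relevel(droplevels(f), ref = reference)
}

#' Multiply-imputed logistic-regression association test
#'
#' Within each imputed call dataset, fits
#' `status ~ copy-number group` (reference = the most common total-two
#' group: joint `0-2`, marginal KIR3DL1 `2`, marginal KIR3DS1 `0`) by
#' logistic regression; per-group log-odds are pooled across the m datasets
#' by Rubin's rules and the overall test is a pooled multivariate Wald test
#' on all non-reference coefficients.  Reported per-group counts are
#' MAP-call based when `map_calls` is supplied, else modal calls across the
#' imputations.
#'
#' @param imputations character matrix (samples x m) of joint group labels,
#'   rownames = sample ids.
#' @param phenotype `data.frame` with `sample_id` and `status`
#'   (`case`/`control`).
#' @param grouping `"joint"`, `"3DL1"` or `"3DS1"`.
#' @param reference reference group label (defaults per grouping as above).
#' @param map_calls optional named vector of MAP calls used for the count
#'   columns.
#' @return `data.frame` of class `kir_assoc`: per group `n_case`,
#'   `n_control`, `or`, `lo`, `hi`, `p` (reference row has OR 1, blank CI),
#'   with attributes `overall_p`, `m`, `reference`, `grouping`.
#' @export
logistic_mi <- function(imputations, phenotype,
                        grouping = c("joint", "3DL1", "3DS1"),
                        reference = NULL, map_calls = NULL) {
  grouping <- match.arg(grouping)
  common <- intersect(rownames(imputations), phenotype$sample_id)
  if (length(common) < 2L) stop("no overlap between imputations and phenotype")
  imp <- imputations[common, , drop = FALSE]
  status <- phenotype$status[match(common, phenotype$sample_id)]
  y <- as.integer(status == "case")
  m <- ncol(imp)
  if (m < 2) stop("need m >= 2 imputed datasets")

  fits <- lapply(seq_len(m), function(j) {
    f <- grouping_factor(imp[, j], grouping, reference)
    fit <- stats::glm(y ~ f, family = stats::binomial())
    list(coef = stats::coef(fit), vcov = stats::vcov(fit),
         levels = levels(f), dfcom = fit$df.residual)
  })
  reference <- sub("^f", "", names(fits[[1]]$coef)[1])
  all_levels <- unique(unlist(lapply(fits, `[[`, "levels")))
  ref <- fits[[1]]$levels[1]
  non_ref <- setdiff(all_levels, ref)
  terms <- paste0("f", non_ref)

  pooled <- lapply(terms, function(tm) {
    have <- vapply(fits, function(f) tm %in% names(f$coef) &&
                     is.finite(f$coef[tm]), logical(1))
    if (sum(have) < 2L) {
      return(data.frame(estimate = NA_real_, W = NA_real_, B = NA_real_,
                        total_var = NA_real_, se = NA_real_, df = NA_real_,
                        p = NA_real_, n_datasets = sum(have)))
    }
    est <- vapply(fits[have], function(f) f$coef[tm], numeric(1))
    va <- vapply(fits[have], function(f) f$vcov[tm, tm], numeric(1))
    out <- rubin_pool(est, va, dfcom = fits[[1]]$dfcom)
    out$n_datasets <- sum(have)
    out
  })
  pooled <- do.call(rbind, pooled)

  # overall test on the coefficients present in every dataset
  complete_terms <- terms[vapply(terms, function(tm)
    all(vapply(fits, function(f) tm %in% names(f$coef), logical(1))), logical(1))]
  overall <- if (length(complete_terms)) {
    Qhat <- t(vapply(fits, function(f) f$coef[complete_terms],
                     numeric(length(complete_terms))))
    if (length(complete_terms) == 1L) Qhat <- matrix(Qhat, ncol = 1L)
    Uhat <- array(NA_real_, c(length(complete_terms), length(complete_terms), m))
    for (j in seq_len(m)) Uhat[, , j] <- fits[[j]]$vcov[complete_terms,
                                                        complete_terms]
    pooled_wald(Qhat, Uhat)
  } else {
    list(statistic = NA_real_, df1 = NA_real_, df2 = NA_real_, p = NA_real_)
  }

  if (is.null(map_calls)) {
    map_calls <- apply(imp, 1L, function(z) names(which.max(table(z))))
  } else {
    map_calls <- map_calls[common]
  }
  grp <- grouping_factor(map_calls, grouping, ref)
  counts <- table(group = grp, status = factor(status, c("case", "control")))

  groups <- c(ref, non_ref)
  res <- data.frame(
    group = groups,
    n_case = as.integer(counts[match(groups, rownames(counts)), "case"]),
    n_control = as.integer(counts[match(groups, rownames(counts)), "control"]),
    or = c(1, exp(pooled$estimate)),
    lo = c(NA, exp(pooled$estimate - stats::qt(0.975, pooled$df) * pooled$se)),
    hi = c(NA, exp(pooled$estimate + stats::qt(0.975, pooled$df) * pooled$se)),
    p = c(NA, pooled$p),
    stringsAsFactors = FALSE)
  res$n_case[is.na(res$n_case)] <- 0L
  res$n_control[is.na(res$n_control)] <- 0L
  structure(res, class = c("kir_assoc", "data.frame"),
            overall_p = overall$p, overall = overall, m = m,
            reference = ref, grouping = grouping, pooled = pooled)
}

#' @export
print.kir_assoc <- function(x, ...) {
  cat(sprintf("Copy-number association (%s grouping, reference %s, m = %d)\n",
              attr(x, "grouping"), attr(x, "reference"), attr(x, "m")))
  df <- as.data.frame(x)
  df$or <- round(df$or, 2); df$lo <- round(df$lo, 2); df$hi <- round(df$hi, 2)
  df$p <- signif(df$p, 4)
  print(df, row.names = FALSE)
  cat(sprintf("Overall p = %.4f\n", attr(x, "overall_p")))
  invisible(x)
}

#' Association test within an HLA-epitope carrier subset
#'
#' Repeats [logistic_mi()] restricted to carriers of the relevant ligand
#' epitope: HLA-Bw4 (the KIR3DL1 ligand) pairs by default with the marginal
#' KIR3DL1 grouping, and the more restrictive HLA-Bw4-80I subset (the
#' putative KIR3DS1 ligand) with the marginal KIR3DS1 grouping.
#'
#' @param imputations,phenotype as in [logistic_mi()]; `phenotype` must also
#'   carry the epitope column (`bw4` or `bw4_80i`, values `carrier` /
#'   `non-carrier` / `unknown`).
#' @param epitope `"bw4"` or `"bw4_80i"`.
#' @param grouping grouping for the test; defaults to the epitope's partner
#'   gene.
#' @param ... passed to [logistic_mi()].
#' @return `kir_assoc` object for the carrier subset.
#' @export
subset_association <- function(imputations, phenotype,
                               epitope = c("bw4", "bw4_80i"),
                               grouping = NULL, ...) {
  epitope <- match.arg(epitope)
  if (is.null(grouping)) {
    grouping <- if (epitope == "bw4") "3DL1" else "3DS1"
  }
  carriers <- phenotype[!is.na(phenotype[[epitope]]) &
                          phenotype[[epitope]] == "carrier", , drop = FALSE]
  if (nrow(carriers) == 0L) stop("no ", epitope, " carriers in the phenotype table")
  keep <- intersect(rownames(imputations), carriers$sample_id)
  if (length(keep) == 0L) stop("no ", epitope, " carriers among the called samples")
  logistic_mi(imputations[keep, , drop = FALSE], carriers,
              grouping = grouping, ...)
}

#' Case-only chi-square test for KIR x HLA-epitope interaction
#'
#' Under gene-gene independence in the population, an interaction between
#' KIR copy number and an HLA epitope shows up as a difference in
#' copy-number frequencies across epitope strata *among cases*; this
#' case-only test is more powerful than subsetting the case-control
#' analysis.  Within each imputed dataset a Pearson chi-square (no
#' continuity correction) is computed on the KIR-by-epitope contingency
#' table; the m statistics are pooled by their mean, referred to the
#' chi-square distribution with the table's df.
#'
#' @param imputations character matrix (samples x m) of joint group labels.
#' @param phenotype phenotype table with `status` and the epitope column.
#' @param epitope `"bw4"` or `"bw4_80i"`.
#' @param collapse how to classify KIR genotypes: `"3DL1"` / `"3DS1"`
#'   (presence vs absence of that gene) or `"joint"` (the three observed
#'   presence patterns: 3DS1-/3DL1+, 3DS1+/3DL1-, 3DS1+/3DL1+).
#' @return list with `chi2` (pooled mean statistic), `df`, `p`,
#'   `per_dataset` statistics and the last dataset's `table`.
#' @export
case_only_chi2 <- function(imputations, phenotype,
                           epitope = c("bw4", "bw4_80i"),
                           collapse = c("3DL1", "3DS1", "joint")) {
  epitope <- match.arg(epitope)
  collapse <- match.arg(collapse)
  cases <- phenotype[phenotype$status == "case" &
                       !is.na(phenotype[[epitope]]) &
                       phenotype[[epitope]] %in% c("carrier", "non-carrier"), ,
                     drop = FALSE]
  keep <- intersect(rownames(imputations), cases$sample_id)
  if (length(keep) == 0L) stop("no cases with known ", epitope, " status")
  imp <- imputations[keep, , drop = FALSE]
  ep <- factor(cases[[epitope]][match(keep, cases$sample_id)],
               levels = c("non-carrier", "carrier"))
  stats_m <- numeric(ncol(imp))
  df <- NA_integer_
  tab <- NULL
  warned <- FALSE
  for (j in seq_len(ncol(imp))) {
    s <- group_s(imp[, j]); l <- group_l(imp[, j])
    kir <- switch(collapse,
      `3DL1` = factor(ifelse(l > 0, "3DL1+", "3DL1-"), c("3DL1-", "3DL1+")),
      `3DS1` = factor(ifelse(s > 0, "3DS1+", "3DS1-"), c("3DS1-", "3DS1+")),
      joint = factor(ifelse(s == 0, "3DS1-/3DL1+",
                     ifelse(l == 0, "3DS1+/3DL1-", "3DS1+/3DL1+")),
                     c("3DS1-/3DL1+", "3DS1+/3DL1-", "3DS1+/3DL1+")))
    tab <- table(kir, ep)
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    if (!warned && any(ct$expected < 1)) {
      warning("expected cell count below 1 in the case-only table")
      warned <- TRUE
    }
    stats_m[j] <- unname(ct$statistic)
    df <- unname(ct$parameter)
  }
  chi2 <- mean(stats_m)
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE),
       per_dataset = stats_m, table = tab)
}
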