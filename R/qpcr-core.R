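#' Read a LightCycler-style crossing-point export
#'
#' Parses a tab- or comma-separated table of per-well crossing-point (Ct)
#' readings for the three dye channels of the multiplexed assay (FAM, CY5 and
#' DFO).  An empty cell means the fluorescence never crossed the detection
#' threshold within 40 cycles; this is represented as `NA`, never as 0 or 40.
#'
#' @param path path to the export file.  Required columns: `plate_id`,
#'   `well`, `sample_id`, `role` (one of `sample`, `calibrator`, `water`),
#'   `ct_fam`, `ct_cy5`, `ct_dfo`.
#' @param sep field separator; `NULL` (default) auto-detects tab vs comma
#'   from the header line.
#' @return `data.frame` of well records, one row per well.  Water wells carry
#'   `NA` sample ids.
#' @export
read_ct_export <- function(path, sep = NULL) {
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("", "NA"),
                          colClasses = "character")
  validate_well_table(df)
}

# Shared validation so in-memory well tables get the same checks as files.
validate_well_table <- function(df) {
  need <- c("plate_id", "well", "sample_id", "role", "ct_fam", "ct_cy5", "ct_dfo")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("ct export is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  extra_ct <- setdiff(grep("^ct_", names(df), value = TRUE),
                      c("ct_fam", "ct_cy5", "ct_dfo"))
  if (length(extra_ct)) {
    stop("unknown Ct channel column(s): ", paste(extra_ct, collapse = ", "))
  }
  df <- df[need]
  for (col in c("ct_fam", "ct_cy5", "ct_dfo")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
    bad <- !is.na(df[[col]]) & (!is.finite(df[[col]]) |
                                df[[col]] <= 0 | df[[col]] > 40)
    if (any(bad)) {
      stop("Ct values must be finite and in (0, 40]; offending rows: ",
           paste(utils::head(which(bad), 5L), collapse = ", "))
    }
  }
  key <- paste(df$plate_id, df$well, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop("duplicate (plate, well): ", gsub("\r", "/", dup, fixed = TRUE))
  }
  bad_role <- setdiff(unique(df$role), c("sample", "calibrator", "water"))
  if (length(bad_role)) {
    stop("unknown role(s): ", paste(bad_role, collapse = ", "))
  }
  df$sample_id[df$role == "water"] <- NA_character_
  df
}

#' Compute per-sample delta-Ct values from well records
#'
#' For every well, the relative delta-Ct of a target gene is the Ct of the
#' DFO-labelled STAT6 reference minus the Ct of the gene's channel (STAT6 is
#' diploid in every sample, so larger delta-Ct means more target copies).
#' Per sample and plate, the delta-Ct is the median over the replicate wells
#' in which both channels crossed; replicate-level missingness is counted per
#' channel so that downstream QC and the hard-zero rule can act on it.
#'
#' @param wells well table as returned by [read_ct_export()].
#' @param dye_map named character vector mapping dye channels to genes.  The
#'   default follows the assay-design description (`FAM` = KIR3DS1, `CY5` =
#'   KIR3DL1); it is configurable because the two target probes can be
#'   conjugated either way round.
#' @return `data.frame` with one row per (sample, plate): `dct_3ds1`,
#'   `dct_3dl1` (possibly `NA`), replicate missingness counts
#'   `n_missing_3ds1`, `n_missing_3dl1`, `n_missing_ref`, well count and role.
#' @export
compute_delta_ct <- function(wells, dye_map = c(FAM = "KIR3DS1", CY5 = "KIR3DL1")) {
  wells <- validate_well_table(wells)
  if (!setequal(names(dye_map), c("FAM", "CY5")) ||
      !setequal(dye_map, c("KIR3DS1", "KIR3DL1"))) {
    stop("dye_map must map channels FAM and CY5 onto KIR3DS1 and KIR3DL1")
  }
  wells <- wells[wells$role != "water", , drop = FALSE]
  chan_col <- c(FAM = "ct_fam", CY5 = "ct_cy5")
  ct_3ds1 <- wells[[chan_col[names(dye_map)[dye_map == "KIR3DS1"]]]]
  ct_3dl1 <- wells[[chan_col[names(dye_map)[dye_map == "KIR3DL1"]]]]
  ct_ref <- wells$ct_dfo

  key <- interaction(wells$plate_id, wells$sample_id, drop = TRUE, sep = "\r")
  n_wells <- as.vector(table(key)[levels(key)])
  if (any(n_wells > 4L)) {
    bad <- levels(key)[which(n_wells > 4L)[1L]]
    stop("sample has more than 4 replicate wells on one plate: ",
         gsub("\r", " on plate ", rev(strsplit(bad, "\r")[[1]])[1]))
  }
  idx <- split(seq_len(nrow(wells)), key)
  rec <- lapply(idx, function(i) {
    d1 <- ct_ref[i] - ct_3ds1[i]
    d2 <- ct_ref[i] - ct_3dl1[i]
    data.frame(
      sample_id = wells$sample_id[i[1L]],
      plate_id = wells$plate_id[i[1L]],
      role = wells$role[i[1L]],
      dct_3ds1 = if (all(is.na(d1))) NA_real_ else stats::median(d1, na.rm = TRUE),
      dct_3dl1 = if (all(is.na(d2))) NA_real_ else stats::median(d2, na.rm = TRUE),
      n_missing_3ds1 = sum(is.na(ct_3ds1[i])),
      n_missing_3dl1 = sum(is.na(ct_3dl1[i])),
      n_missing_ref = sum(is.na(ct_ref[i])),
      n_wells = length(i),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rec)
  rownames(out) <- NULL
  out$normalized <- FALSE
  out
}

#' Quality-control filtering of delta-Ct records
#'
#' Two exclusion rules are applied, mirroring the bookkeeping of a plate-based
#' qPCR experiment:
#'
#' * *reference non-amplification*: samples whose STAT6 reference channel
#'   failed to cross in all four replicate wells are dropped (their delta-Ct
#'   is meaningless);
#' * *plate outlier*: a whole plate is dropped when, for either gene, the
#'   robust SD (1.4826 x MAD, pooled within the plate's two anchor clusters
#'   so that copy-number-group composition does not inflate it) exceeds
#'   `plate_sd_factor` times the median robust SD across plates, or when its
#'   two anchor clusters fail to separate (mean silhouette below
#'   `silhouette_min`).  This automates the visual plate-level judgement that
#'   an analyst would otherwise make.
#'
#' @param records delta-Ct table from [compute_delta_ct()].
#' @param plate_sd_factor multiplier on the cross-plate median robust SD
#'   above which a plate is declared an outlier (default 2.5).
#' @param silhouette_min minimum mean silhouette of the two-cluster anchor
#'   partition (default 0.25).
#' @param min_group_size minimum anchor cluster size used when judging
#'   silhouette feasibility (default 5).
#' @return list with `kept` (surviving records) and `dropped` (QC report:
#'   `sample_id`, `plate_id`, `rule`, `detail`).
#' @export
qc_filter <- function(records, plate_sd_factor = 2.5, silhouette_min = 0.25,
                      min_group_size = 5) {
  dropped <- records[0, c("sample_id", "plate_id")]
  dropped$rule <- character(0)
  dropped$detail <- character(0)

  ref_fail <- records$n_missing_ref >= 4L
  if (any(ref_fail)) {
    dropped <- rbind(dropped, data.frame(
      sample_id = records$sample_id[ref_fail],
      plate_id = records$plate_id[ref_fail],
      rule = "reference non-amplification",
      detail = "DFO-STAT6 Ct missing in all 4 replicate wells",
      stringsAsFactors = FALSE))
  }
  kept <- records[!ref_fail, , drop = FALSE]

  # plate-level dispersion / separability, per gene on the raw delta-Ct scale
  plates <- unique(kept$plate_id)
  bad_plates <- character(0)
  details <- character(0)
  for (gene in c("dct_3ds1", "dct_3dl1")) {
    sds <- vapply(plates, function(p) {
      x <- kept[[gene]][kept$plate_id == p]
      x <- x[!is.na(x)]
      if (length(x) < 2L) NA_real_ else plate_robust_sd(x, min_group_size)
    }, numeric(1))
    med_sd <- stats::median(sds, na.rm = TRUE)
    if (is.finite(med_sd) && med_sd > 0) {
      hit <- !is.na(sds) & sds > plate_sd_factor * med_sd
      bad_plates <- c(bad_plates, plates[hit])
      details <- c(details, sprintf("%s robust SD %.3f > %.1f x median %.3f",
                                    gene, sds[hit], plate_sd_factor, med_sd))
    }
    for (p in setdiff(plates, bad_plates)) {
      x <- kept[[gene]][kept$plate_id == p]
      x <- x[!is.na(x)]
      sil <- tryCatch(anchor_silhouette(x, min_group_size), error = function(e) NA_real_)
      if (!is.na(sil) && sil < silhouette_min) {
        bad_plates <- c(bad_plates, p)
        details <- c(details, sprintf("%s anchor silhouette %.3f < %.2f",
                                      gene, sil, silhouette_min))
      }
    }
  }
  if (length(bad_plates)) {
    keep_order <- !duplicated(bad_plates)
    bad_plates <- bad_plates[keep_order]
    details <- details[keep_order]
    for (i in seq_along(bad_plates)) {
      on_plate <- kept$plate_id == bad_plates[i]
      dropped <- rbind(dropped, data.frame(
        sample_id = kept$sample_id[on_plate],
        plate_id = bad_plates[i],
        rule = "plate outlier",
        detail = details[i],
        stringsAsFactors = FALSE))
      kept <- kept[!on_plate, , drop = FALSE]
    }
  }
  rownames(kept) <- NULL
  rownames(dropped) <- NULL
  list(kept = kept, dropped = dropped)
}

# Robust SD of a plate's delta-Ct values around their anchor clusters:
# the MAD is pooled within the two-medoid partition so that it measures
# plate noise rather than the plate's copy-number-group composition.
# Plates too sparse to partition return NA and are exempt from the rule
# (the raw MAD would conflate composition with noise).
plate_robust_sd <- function(x, min_group_size = 5) {
  part <- tryCatch(kmedoids2(x, min_group_size), error = function(e) NULL)
  if (is.null(part)) return(NA_real_)
  dev <- abs(x - stats::ave(part$x, part$cluster, FUN = stats::median))
  1.4826 * stats::median(dev)
}

# Mean silhouette of the 1-D two-medoid anchor partition.
anchor_silhouette <- function(x, min_group_size = 5) {
  part <- kmedoids2(x, min_group_size)
  sil <- cluster::silhouette(part$cluster, stats::dist(x))
  mean(sil[, "sil_width"])
}

#' Apply the hard-zero rule for non-amplifying target genes
#'
#' A gene whose channel failed to cross in three or more of the four
#' replicate wells is called as zero copies outright (`hard_zero_*` flag) and
#' its delta-Ct is set missing; with at most two missing replicates the gene
#' remains callable from the median of the available wells.  Samples
#' hard-zeroed for both genes are flagged `no_call` ("0-0" is not among the
#' modelled copy-number groups) and are excluded from the mixture fit but
#' reported.
#'
#' @param records QC-passed delta-Ct table.
#' @return the table with `hard_zero_3ds1`, `hard_zero_3dl1` and `no_call`
#'   columns added and the corresponding delta-Ct values set to `NA`.
#' @export
apply_hard_zero <- function(records) {
  records$hard_zero_3ds1 <- records$n_missing_3ds1 >= 3L
  records$hard_zero_3dl1 <- records$n_missing_3dl1 >= 3L
  records$dct_3ds1[records$hard_zero_3ds1] <- NA_real_
  records$dct_3dl1[records$hard_zero_3dl1] <- NA_real_
  records$no_call <- records$hard_zero_3ds1 & records$hard_zero_3dl1
  records
}

# Deterministic 1-D PAM with k = 2: initial medoids are the data points
# closest to the 25th/75th percentiles (lower index on ties), then the
# standard build/swap refinement from cluster::pam.
kmedoids2 <- function(x, min_group_size = 5) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2L * min_group_size) {
    stop("plate too sparse to anchor (", n, " values, need >= ",
         2L * min_group_size, ")")
  }
  if (diff(range(x)) < 1e-12) {
    stop("no separation: all delta-Ct values identical")
  }
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  i1 <- which.min(abs(x - q[1]))
  i2 <- which.min(abs(x - q[2]))
  if (i1 == i2) i2 <- which.max(x)
  fit <- cluster::pam(matrix(x, ncol = 1), k = 2, medoids = sort(c(i1, i2)),
                      do.swap = TRUE, keep.diss = FALSE, keep.data = FALSE)
  list(cluster = fit$clustering, medoids = as.vector(fit$medoids), x = x)
}

#' Locate the one- and two-copy anchor groups on a plate
#'
#' Runs 1-D k-medoids (PAM, k = 2, deterministic initialization) on the raw
#' delta-Ct values of one gene on one plate to find the two most
#' distinguishable copy-number groups.  Since delta-Ct increases with copy
#' number, the cluster with the smaller median is interpreted as the one-copy
#' group.
#'
#' @param x numeric vector of raw delta-Ct values (NAs dropped), or a
#'   delta-Ct table together with `plate` and `gene`.
#' @param min_group_size minimum cluster size (default 5); plates that cannot
#'   support two clusters of this size raise an error.
#' @return named numeric vector `c(m1 = , m2 = )`, the cluster medians with
#'   `m1 < m2`.
#' @export
locate_anchor_groups <- function(x, min_group_size = 5) {
  part <- kmedoids2(x, min_group_size)
  meds <- sort(vapply(1:2, function(g) stats::median(part$x[part$cluster == g]),
                      numeric(1)))
  if (diff(meds) < 1e-12) stop("no separation between anchor clusters")
  c(m1 = meds[1], m2 = meds[2])
}

#' Anchor every plate of a delta-Ct table
#'
#' @param records delta-Ct table (QC-passed, hard-zero applied).
#' @param min_group_size passed to [locate_anchor_groups()].
#' @return `data.frame` with columns `plate_id`, `gene` (`3DS1`/`3DL1`),
#'   `m1`, `m2`.
#' @export
anchor_plates <- function(records, min_group_size = 5) {
  plates <- unique(records$plate_id)
  out <- expand.grid(plate_id = plates, gene = c("3DS1", "3DL1"),
                     stringsAsFactors = FALSE)
  anc <- t(mapply(function(p, g) {
    col <- if (g == "3DS1") "dct_3ds1" else "dct_3dl1"
    locate_anchor_groups(records[[col]][records$plate_id == p], min_group_size)
  }, out$plate_id, out$gene))
  out$m1 <- anc[, "m1"]
  out$m2 <- anc[, "m2"]
  out
}

#' Normalize delta-Ct across plates via the anchor groups
#'
#' Applies, per plate and gene, the linear map sending the one- and two-copy
#' anchor medians to 1 and 2: `x -> 1 + (x - m1) / (m2 - m1)`.  Negative
#' normalized values are then clamped to exactly 0, reflecting their expected
#' zero-copy state; the pre-clamp values are retained in `*_preclamp` columns
#' for diagnostics.
#'
#' @param records delta-Ct table.
#' @param anchors anchor table from [anchor_plates()]; computed from
#'   `records` when `NULL`.
#' @param min_group_size passed on when anchors are computed here.
#' @return the table with normalized (clamped) `dct_3ds1`, `dct_3dl1`,
#'   pre-clamp copies, and `normalized = TRUE`.
#' @export
normalize_plates <- function(records, anchors = NULL, min_group_size = 5) {
  if (is.null(anchors)) anchors <- anchor_plates(records, min_group_size)
  if (any(anchors$m2 <= anchors$m1)) {
    stop("invalid anchors: m2 <= m1 on plate ",
         anchors$plate_id[which(anchors$m2 <= anchors$m1)[1]])
  }
  for (g in c("3DS1", "3DL1")) {
    col <- paste0("dct_", tolower(g))
    pre <- paste0(col, "_preclamp")
    records[[pre]] <- NA_real_
    for (p in unique(records$plate_id)) {
      a <- anchors[anchors$plate_id == p & anchors$gene == g, , drop = FALSE]
      if (nrow(a) != 1L) stop("no anchors for plate ", p, ", gene ", g)
      i <- records$plate_id == p
      records[[pre]][i] <- 1 + (records[[col]][i] - a$m1) / (a$m2 - a$m1)
    }
    records[[col]] <- pmax(records[[pre]], 0)
  }
  records$normalized <- TRUE
  records
}

#' Collapse samples repeated across plates
#'
#' Samples assayed on several plates are summarised by the per-gene median of
#' their normalized delta-Ct values.  Hard-zero status is carried over by
#' majority among the plate-level records (ties resolve to callable).  A
#' reproducibility report (per-sample maximum pairwise difference of the
#' normalized values) is attached as attribute `"reproducibility"`.
#'
#' @param records normalized delta-Ct table.
#' @return one-row-per-sample table; `plate_id` is `"multiple"` for merged
#'   samples.
#' @export
merge_repeated_samples <- function(records) {
  stopifnot(all(records$normalized))
  idx <- split(seq_len(nrow(records)), records$sample_id)
  rep_report <- list()
  rec <- lapply(idx, function(i) {
    r <- records[i, , drop = FALSE]
    one <- r[1L, , drop = FALSE]
    if (length(i) > 1L) {
      one$plate_id <- "multiple"
      for (g in c("3ds1", "3dl1")) {
        col <- paste0("dct_", g)
        hz <- paste0("hard_zero_", g)
        one[[hz]] <- sum(r[[hz]]) > length(i) / 2
        vals <- r[[col]][!is.na(r[[col]])]
        one[[col]] <- if (one[[hz]] || !length(vals)) NA_real_ else stats::median(vals)
        one[[paste0(col, "_preclamp")]] <-
          if (one[[hz]]) NA_real_ else stats::median(r[[paste0(col, "_preclamp")]], na.rm = TRUE)
        one[[paste0("n_missing_", g)]] <- min(r[[paste0("n_missing_", g)]])
      }
      one$n_missing_ref <- min(r$n_missing_ref)
      one$no_call <- one$hard_zero_3ds1 && one$hard_zero_3dl1
      rep_report[[one$sample_id]] <<- data.frame(
        sample_id = one$sample_id,
        n_plates = length(i),
        max_diff_3ds1 = if (all(is.na(r$dct_3ds1))) NA_real_ else
          diff(range(r$dct_3ds1, na.rm = TRUE)),
        max_diff_3dl1 = if (all(is.na(r$dct_3dl1))) NA_real_ else
          diff(range(r$dct_3dl1, na.rm = TRUE)),
        stringsAsFactors = FALSE)
    }
    one
  })
  out <- do.call(rbind, rec)
  rownames(out) <- NULL
  attr(out, "reproducibility") <- if (length(rep_report)) {
    rr <- do.call(rbind, rep_report); rownames(rr) <- NULL; rr
  } else NULL
  out
}

#' Full qPCR preprocessing pipeline
#'
#' Convenience wrapper chaining [compute_delta_ct()], [qc_filter()],
#' [apply_hard_zero()], [normalize_plates()] and [merge_repeated_samples()].
#'
#' @param wells well table ([read_ct_export()] output or equivalent).
#' @param dye_map,plate_sd_factor,silhouette_min,min_group_size passed to the
#'   respective stages.
#' @return list with `calls_input` (merged, normalized per-sample table),
#'   `qc_report`, `anchors`, and `reproducibility`.
#' @export
qpcr_pipeline <- function(wells, dye_map = c(FAM = "KIR3DS1", CY5 = "KIR3DL1"),
                          plate_sd_factor = 2.5, silhouette_min = 0.25,
                          min_group_size = 5) {
  dct <- compute_delta_ct(wells, dye_map = dye_map)
  qc <- qc_filter(dct, plate_sd_factor = plate_sd_factor,
                  silhouette_min = silhouette_min,
                  min_group_size = min_group_size)
  hz <- apply_hard_zero(qc$kept)
  anchors <- anchor_plates(hz, min_group_size = min_group_size)
  norm <- normalize_plates(hz, anchors)
  merged <- merge_repeated_samples(norm)
  list(calls_input = merged, qc_report = qc$dropped, anchors = anchors,
       reproducibility = attr(merged, "reproducibility"))
}
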