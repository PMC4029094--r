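# Builders for small in-memory fixtures used across the tests.

# Well table for one or more samples; ct_* are per-well vectors (NA = no
# crossing), recycled to n_wells.
make_wells <- function(sample_id, plate_id = "P1", role = "sample",
                       ct_fam = 24, ct_cy5 = 24, ct_dfo = 25, n_wells = 4,
                       well_offset = 0) {
  data.frame(
    plate_id = plate_id,
    well = sprintf("%s%02d", LETTERS[1 + well_offset %/% 24],
                   (well_offset %% 24) + seq_len(n_wells)),
    sample_id = sample_id,
    role = role,
    ct_fam = rep_len(ct_fam, n_wells),
    ct_cy5 = rep_len(ct_cy5, n_wells),
    ct_dfo = rep_len(ct_dfo, n_wells),
    stringsAsFactors = FALSE
  )
}

rbind_wells <- function(...) do.call(rbind, list(...))

# Delta-Ct record table in the shape produced by compute_delta_ct().
make_dct <- function(sample_id, plate_id, dct_3ds1, dct_3dl1,
                     n_missing_3ds1 = 0, n_missing_3dl1 = 0,
                     n_missing_ref = 0, role = "sample") {
  data.frame(sample_id = sample_id, plate_id = plate_id, role = role,
             dct_3ds1 = dct_3ds1, dct_3dl1 = dct_3dl1,
             n_missing_3ds1 = n_missing_3ds1,
             n_missing_3dl1 = n_missing_3dl1,
             n_missing_ref = n_missing_ref,
             n_wells = 4L, normalized = FALSE, stringsAsFactors = FALSE)
}

# Two-plate synthetic delta-Ct table with one- and two-copy blobs per gene.
make_two_group_plates <- function(n_per_group = 20, plates = c("P1", "P2"),
                                  sd = 0.05, seed = 1) {
  set.seed(seed)
  out <- list()
  for (p in plates) {
    n <- 2 * n_per_group
    out[[p]] <- make_dct(
      sample_id = paste0(p, "_S", seq_len(n)),
      plate_id = p,
      dct_3ds1 = rnorm(n, rep(c(1, 2), each = n_per_group), sd),
      dct_3dl1 = rnorm(n, rep(c(2, 1), each = n_per_group), sd))
  }
  do.call(rbind, out)
}

# Brute-force optimal 1-D 2-medoid partition: in one dimension the optimal
# partition is a split of the sorted values; each side's medoid is the data
# point minimising the within-group absolute deviation.
brute_force_2medoid <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  best <- list(cost = Inf)
  side_cost <- function(v) {
    costs <- vapply(v, function(m) sum(abs(v - m)), numeric(1))
    min(costs)
  }
  for (s in 1:(n - 1)) {
    cost <- side_cost(xs[1:s]) + side_cost(xs[(s + 1):n])
    if (cost < best$cost) {
      best <- list(cost = cost, split = s,
                   m1 = median(xs[1:s]), m2 = median(xs[(s + 1):n]))
    }
  }
  best
}

# Gaussian blob helper for feature-space tests.
make_blobs <- function(centers, n_each, sd, seed = 1) {
  set.seed(seed)
  pts <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    cbind(rnorm(n_each, centers[i, 1], sd), rnorm(n_each, centers[i, 2], sd))
  }))
  labels <- rep(rownames(centers), each = n_each)
  rownames(pts) <- sprintf("B%04d", seq_len(nrow(pts)))
  list(x = pts, labels = labels)
}
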