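#' Copy-number groups of the KIR3DS1/KIR3DL1 locus
#'
#' The two paralogous genes occupy the same locus slot, so their copy numbers
#' trade off and are modelled jointly.  A group is written `"s-l"` where `s`
#' is the KIR3DS1 copy count and `l` the KIR3DL1 copy count.  Eight groups are
#' modelled: the three common total-two groups (`0-2`, `1-1`, `2-0`) and five
#' rarer ones (`2-1`, `1-2`, `0-1`, `1-0`, `3-0`).  The `0-0` configuration is
#' not a mixture component; samples with both genes absent are flagged
#' upstream as no-calls.
#'
#' @return Character vector of the eight group labels, in canonical order.
#' @export
#' @examples
#' kir_groups()
kir_groups <- function() {
  c("0-2", "1-1", "2-0", "2-1", "1-2", "0-1", "1-0", "3-0")
}

#' Expected group centres on the normalized delta-Ct scale
#'
#' After per-plate normalization the delta-Ct of a gene is anchored so that
#' the one- and two-copy medians sit at 1 and 2, hence the expected location
#' of group `s-l` is simply `(s, l)`.
#'
#' @param groups character vector of group labels (default all eight).
#' @return Numeric matrix with one row per group (rownames = labels) and
#'   columns `dct_3ds1`, `dct_3dl1`.
#' @export
#' @examples
#' kir_group_centers()["1-1", ]
kir_group_centers <- function(groups = kir_groups()) {
  m <- cbind(dct_3ds1 = group_s(groups), dct_3dl1 = group_l(groups))
  rownames(m) <- groups
  m
}

#' @rdname kir_group_centers
#' @export
group_s <- function(groups) {
  as.integer(sub("-.*$", "", groups))
}

#' @rdname kir_group_centers
#' @export
group_l <- function(groups) {
  as.integer(sub("^.*-", "", groups))
}
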