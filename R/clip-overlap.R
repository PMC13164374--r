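#' Database editing sites captured by expanded iCLIP footprints
#'
#' For each window size `w`, expands every footprint by `w` on both sides
#' (`w = 0` means the raw footprints) and reports the fraction of distinct
#' database editing sites overlapped by at least one expanded footprint. The
#' denominator — the total number of database sites — is constant across
#' `w`, so the curve is non-decreasing and bounded by 1. Expanding footprints
#' rather than sites is distance-equivalent and keeps that denominator fixed.
#' Strand is ignored.
#'
#' @param footprints iCLIP footprint intervals (e.g. from [read_bed()]).
#' @param db_sites Database editing sites as 1-bp intervals.
#' @param window_sizes Integer vector; default `c(0, 50, 250, 500, 1000)`.
#' @return An `accumulation_curve` over the database sites.
#' @export
footprint_site_overlap <- function(footprints, db_sites,
                                   window_sizes = c(0L, 50L, 250L, 500L, 1000L)) {
  if (!NROW(db_sites)) stop("footprint_site_overlap: empty database site set")
  if (!NROW(footprints)) stop("footprint_site_overlap: empty footprint set")
  n <- NROW(db_sites)
  n_over <- integer(length(window_sizes))
  for (k in seq_along(window_sizes)) {
    fp <- expand_intervals(footprints, as.integer(window_sizes[k]))
    n_over[k] <- count_overlapping_queries(db_sites, fp, "ignore")
  }
  out <- data.frame(window_size = as.integer(window_sizes),
                    n_features = n, n_overlapping = n_over,
                    fraction = n_over / n)
  structure(out, geometry = "clip_expand",
            class = c("accumulation_curve", "data.frame"))
}
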