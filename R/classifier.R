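#' Filter rMATS events on read support, FDR and effect size
#'
#' An event is kept iff (i) in every replicate of both groups the inclusion
#' plus skipping junction counts sum to at least `min_reads`, (ii) its FDR is
#' at most `max_fdr`, and (iii) its |IncLevelDifference| (dPSI) is at least
#' `min_abs_dpsi`. The read-support clause is applied per replicate by
#' default; `read_rule = "group_mean"` relaxes it to the per-group mean.
#'
#' @param events Event data frame from [read_rmats_jc()].
#' @param min_reads Minimum ijc + sjc per replicate; default 20.
#' @param max_fdr FDR ceiling; default 0.05.
#' @param min_abs_dpsi Minimum |dPSI|; default 0.1.
#' @param read_rule `"per_replicate"` (default) or `"group_mean"`.
#' @return A list with `kept` (event data frame) and `removed` (data frame of
#'   `event_id` and the first failing `reason` among `read_support`, `fdr`,
#'   `dpsi`).
#' @export
filter_rmats <- function(events, min_reads = 20L, max_fdr = 0.05,
                         min_abs_dpsi = 0.1,
                         read_rule = c("per_replicate", "group_mean")) {
  read_rule <- match.arg(read_rule)
  n <- NROW(events)
  if (!n) return(list(kept = events,
                      removed = data.frame(event_id = character(),
                                           reason = character())))
  read_ok <- vapply(seq_len(n), function(i) {
    s1 <- events$ijc_g1[[i]] + events$sjc_g1[[i]]
    s2 <- events$ijc_g2[[i]] + events$sjc_g2[[i]]
    if (read_rule == "per_replicate") all(c(s1, s2) >= min_reads)
    else mean(s1) >= min_reads && mean(s2) >= min_reads
  }, logical(1))
  fdr_ok <- !is.na(events$fdr) & events$fdr <= max_fdr
  dpsi_ok <- !is.na(events$inc_level_difference) &
    abs(events$inc_level_difference) >= min_abs_dpsi
  keep <- read_ok & fdr_ok & dpsi_ok
  reason <- rep(NA_character_, n)
  reason[!read_ok] <- "read_support"
  reason[read_ok & !fdr_ok] <- "fdr"
  reason[read_ok & fdr_ok & !dpsi_ok] <- "dpsi"
  list(kept = { k <- events[keep, , drop = FALSE]; rownames(k) <- NULL; k },
       removed = data.frame(event_id = events$event_id[!keep],
                            reason = reason[!keep],
                            stringsAsFactors = FALSE))
}

#' Select null-control event sets
#'
#' `nonsignificant`: events with FDR > 0.05. `low_dpsi`: events significant
#' by FDR (<= 0.05) but with |dPSI| < 0.1. Together with the filtered
#' significant set these partition the events passing the read-support gate.
#'
#' @param events Event data frame.
#' @param mode `"nonsignificant"` or `"low_dpsi"`.
#' @param max_fdr,min_abs_dpsi Thresholds shared with [filter_rmats()].
#' @export
select_null_events <- function(events, mode = c("nonsignificant", "low_dpsi"),
                               max_fdr = 0.05, min_abs_dpsi = 0.1) {
  mode <- match.arg(mode)
  keep <- if (mode == "nonsignificant") {
    is.na(events$fdr) | events$fdr > max_fdr
  } else {
    !is.na(events$fdr) & events$fdr <= max_fdr &
      abs(events$inc_level_difference) < min_abs_dpsi
  }
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# all windows of a set of events as one interval frame with owner column
event_windows_frame <- function(events, exonic_bp, intronic_bp, ri_bp,
                                merged = TRUE) {
  pieces <- lapply(seq_len(NROW(events)), function(i) {
    ws <- build_event_windows(events[i, , drop = FALSE], exonic_bp,
                              intronic_bp, ri_bp)
    if (merged) ws <- merge_windows(ws)
    w <- ws$windows
    if (nrow(w)) w$owner <- i
    else w$owner <- integer()
    w
  })
  do.call(rbind, pieces)
}

#' Tag events as editing-dependent or editing-independent
#'
#' Builds the merged splice-junction windows of each event and intersects
#' them with the filtered called editing sites (as 1-bp intervals) and with
#' the database reference sites. An event with at least one hit from either
#' source is tagged `editing-dependent`, otherwise `editing-independent` —
#' a proximity label, not a causal claim. Strand is ignored in the
#' intersection, matching the `bedtools intersect` default.
#'
#' @param events Event data frame (already filtered as desired).
#' @param own_sites Site data frame (already filtered); may have zero rows.
#' @param db_sites Database 1-bp intervals; may have zero rows or be `NULL`.
#' @param exonic_bp,intronic_bp,ri_bp Window parameters (defaults 50/200/50).
#' @return A classification `data.frame`, one row per event, sorted by
#'   (`event_type`, `owner_id`): `owner_id`, `event_type`, `gene_symbol`,
#'   `chrom`, `strand`, `tag`, `n_own_sites`, `n_db_sites`, `hit_site_ids`
#'   (comma-joined, sorted), `fdr`, `inc_level_difference`, `window_exonic`,
#'   `window_intronic`.
#' @export
classify_events <- function(events, own_sites, db_sites = NULL,
                            exonic_bp = 50L, intronic_bp = 200L, ri_bp = 50L) {
  n <- NROW(events)
  if (!n) stop("no events to classify")
  wf <- event_windows_frame(events, exonic_bp, intronic_bp, ri_bp)
  n_own <- integer(n)
  n_db <- integer(n)
  hit_ids <- replicate(n, character(), simplify = FALSE)
  if (NROW(own_sites)) {
    oiv <- gintervals(own_sites$chrom, own_sites$pos, own_sites$pos + 1L,
                      own_sites$strand, own_sites$site_id)
    hits <- intersect_intervals(wf, oiv, "ignore")
    if (nrow(hits)) {
      owner <- wf$owner[hits$query]
      sid <- own_sites$site_id[hits$subject]
      for (gidx in split(seq_along(owner), owner)) {
        i <- owner[gidx[1]]
        ids <- unique(sid[gidx])
        n_own[i] <- length(ids)
        hit_ids[[i]] <- union(hit_ids[[i]], ids)
      }
    }
  }
  if (!is.null(db_sites) && NROW(db_sites)) {
    dlab <- paste0(db_sites$chrom, ":", db_sites$start)
    hits <- intersect_intervals(wf, db_sites, "ignore")
    if (nrow(hits)) {
      owner <- wf$owner[hits$query]
      sid <- dlab[hits$subject]
      for (gidx in split(seq_along(owner), owner)) {
        i <- owner[gidx[1]]
        ids <- unique(sid[gidx])
        n_db[i] <- length(ids)
        hit_ids[[i]] <- union(hit_ids[[i]], ids)
      }
    }
  }
  rec <- data.frame(
    owner_id = events$event_id,
    event_type = events$event_type,
    gene_symbol = events$gene_symbol,
    chrom = events$chrom,
    strand = events$strand,
    tag = ifelse(n_own + n_db >= 1L, "editing-dependent", "editing-independent"),
    n_own_sites = n_own,
    n_db_sites = n_db,
    hit_site_ids = vapply(hit_ids, function(v) paste(sort(v), collapse = ","), ""),
    fdr = events$fdr,
    inc_level_difference = events$inc_level_difference,
    window_exonic = as.integer(exonic_bp),
    window_intronic = as.integer(intronic_bp),
    stringsAsFactors = FALSE
  )
  rec <- rec[order(rec$event_type, rec$owner_id), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Fraction of features with a nearby editing site, per window size
#'
#' For each window size `w`, counts the features whose windows overlap at
#' least one editing site. Geometry `"deu_expand"` expands each feature body
#' symmetrically by `w`; `"event_windows"` builds splice-junction windows
#' with exonic, intronic and RI reach all set to `w`. Both geometries are
#' nested in `w`, so the curve is non-decreasing.
#'
#' @param features DEU data frame ([read_dexseq()]) for `"deu_expand"`, or an
#'   event data frame for `"event_windows"`.
#' @param sites Site data frame, or an interval data frame of 1-bp sites.
#' @param window_sizes Integer vector; default `c(50, 250, 500, 1000)`.
#' @param geometry `"deu_expand"` or `"event_windows"`.
#' @return An `accumulation_curve`: data frame with `window_size`,
#'   `n_features`, `n_overlapping`, `fraction`, plus a `geometry` attribute.
#' @export
accumulation_curve <- function(features, sites,
                               window_sizes = c(50L, 250L, 500L, 1000L),
                               geometry = c("deu_expand", "event_windows")) {
  geometry <- match.arg(geometry)
  n <- NROW(features)
  if (!n) stop("accumulation_curve: empty feature list (fraction undefined)")
  siv <- if (!is.null(sites$pos))
    gintervals(sites$chrom, sites$pos, sites$pos + 1L, sites$strand,
               sites$site_id)
  else sites
  n_over <- integer(length(window_sizes))
  for (k in seq_along(window_sizes)) {
    w <- as.integer(window_sizes[k])
    wf <- if (geometry == "deu_expand") {
      iv <- gintervals(features$chrom, pmax(0L, features$start - w),
                       features$end + w, features$strand, features$bin_id)
      iv$owner <- seq_len(n)
      iv
    } else {
      event_windows_frame(features, w, w, w)
    }
    if (NROW(siv) && nrow(wf)) {
      hits <- intersect_intervals(wf, siv, "ignore")
      n_over[k] <- length(unique(wf$owner[hits$query]))
    }
  }
  out <- data.frame(window_size = as.integer(window_sizes),
                    n_features = n, n_overlapping = n_over,
                    fraction = n_over / n)
  structure(out, geometry = geometry,
            class = c("accumulation_curve", "data.frame"))
}

#' @exportS3Method base::print
print.accumulation_curve <- function(x, ...) {
  cat(sprintf("accumulation curve (%s geometry), %d feature(s)\n",
              attr(x, "geometry"), x$n_features[1]))
  print.data.frame(x, ...)
  invisible(x)
}

#' Plot an accumulation curve
#'
#' @param x An `accumulation_curve`.
#' @param ... Passed to [graphics::plot()].
#' @exportS3Method graphics::plot
plot.accumulation_curve <- function(x, ...) {
  graphics::plot(x$window_size, x$fraction, type = "b", pch = 19,
                 xlab = "window size (bp)",
                 ylab = "fraction of features with editing site",
                 ylim = c(0, 1), ...)
  invisible(x)
}

#' Summarize dependence tags per event type
#'
#' At the event level, counts dependent/independent events per type. At the
#' gene level (`by = "gene"`), a gene (uppercased symbol) counts as dependent
#' if any of its events is.
#'
#' @param records Classification data frame from [classify_events()].
#' @param by `"event"` or `"gene"`.
#' @return A `data.frame` with `event_type`, `n_total`, `n_dependent`,
#'   `n_independent`, `fraction_dependent`.
#' @export
summarize_fractions <- function(records, by = c("event", "gene")) {
  by <- match.arg(by)
  types <- sort(unique(records$event_type))
  rows <- lapply(types, function(tp) {
    r <- records[records$event_type == tp, , drop = FALSE]
    if (by == "event") {
      ntot <- nrow(r)
      ndep <- sum(r$tag == "editing-dependent")
    } else {
      g <- toupper(r$gene_symbol)
      ntot <- length(unique(g))
      ndep <- length(unique(g[r$tag == "editing-dependent"]))
    }
    data.frame(event_type = tp, n_total = ntot, n_dependent = ndep,
               n_independent = ntot - ndep,
               fraction_dependent = if (ntot) ndep / ntot else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Intersect two splicing-event sets
#'
#' Cross-dataset comparison of rMATS event tables. Matching modes:
#' `"gene"` shares uppercased gene symbols; `"gene_and_type"` shares
#' (gene, event type) pairs; `"coordinates"` requires identical event type
#' and identical junction coordinate map.
#'
#' @param set_a,set_b Event data frames.
#' @param match_mode `"gene"`, `"gene_and_type"` or `"coordinates"`.
#' @return The rows of `set_a` whose key also occurs in `set_b`.
#' @export
compare_event_sets <- function(set_a, set_b,
                               match_mode = c("gene", "gene_and_type",
                                              "coordinates")) {
  match_mode <- match.arg(match_mode)
  key <- function(x) {
    switch(match_mode,
           gene = toupper(x$gene_symbol),
           gene_and_type = paste(toupper(x$gene_symbol), x$event_type),
           coordinates = {
             cc <- unique(unlist(lapply(rmats_coord_cols, names)))
             coords <- do.call(paste, c(lapply(cc, function(nm) x[[nm]]),
                                        sep = ":"))
             paste(x$event_type, x$chrom, coords)
           })
  }
  out <- set_a[key(set_a) %in% key(set_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a classification table
#'
#' Column order is fixed and rows are pre-sorted by [classify_events()], so
#' identical inputs and configuration yield byte-identical files.
#'
#' @param records Classification data frame.
#' @param path Output TSV path.
#' @export
write_classification <- function(records, path) {
  cols <- c("owner_id", "event_type", "gene_symbol", "chrom", "strand", "tag",
            "n_own_sites", "n_db_sites", "hit_site_ids", "fdr",
            "inc_level_difference", "window_exonic", "window_intronic")
  write.table(records[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write an accumulation-curve table
#'
#' @param curve An `accumulation_curve` (or a list of them).
#' @param path Output TSV path.
#' @export
write_curve <- function(curve, path) {
  curves <- if (inherits(curve, "accumulation_curve")) list(curve) else curve
  rows <- lapply(curves, function(cv)
    cbind(geometry = attr(cv, "geometry"),
          set = attr(cv, "set") %||% "all", as.data.frame(cv)))
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
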