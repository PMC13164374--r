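#' Splice-junction coordinates of an rMATS event
#'
#' Enumerates the junction coordinates whose neighbourhoods are scanned for
#' editing sites, together with which side of each junction lies inside an
#' exon of the event. The side is derived purely from the genomic geometry of
#' the event's exons, never from strand, since all rMATS coordinates are
#' genomic.
#'
#' Junction counts per class: SE 4, MXE 6, RI 2, A5SS/A3SS 3. For A5SS/A3SS
#' the three junctions are the variable boundary of the long exon, the
#' matching boundary of the short exon, and the flanking exon boundary facing
#' the alternative intron; which boundary columns those are depends on
#' whether the flanking exon lies genomically left or right of the
#' alternative exons.
#'
#' @param event One row of an event data frame from [read_rmats_jc()].
#' @return A `data.frame` with columns `coord`, `exon_direction` (`"left"` or
#'   `"right"`: the side of the junction inside an event exon) and `name`.
#' @export
junctions_of <- function(event) {
  stopifnot(nrow(event) == 1L)
  type <- event$event_type
  j <- function(coord, dir, name)
    data.frame(coord = as.integer(coord), exon_direction = dir, name = name,
               stringsAsFactors = FALSE)
  if (type == "SE") {
    out <- rbind(j(event$upstream_ee, "left", "upstreamEE"),
                 j(event$exon_start, "right", "exonStart"),
                 j(event$exon_end, "left", "exonEnd"),
                 j(event$downstream_es, "right", "downstreamES"))
  } else if (type == "MXE") {
    out <- rbind(j(event$upstream_ee, "left", "upstreamEE"),
                 j(event$exon1_start, "right", "exon1Start"),
                 j(event$exon1_end, "left", "exon1End"),
                 j(event$exon2_start, "right", "exon2Start"),
                 j(event$exon2_end, "left", "exon2End"),
                 j(event$downstream_es, "right", "downstreamES"))
  } else if (type == "RI") {
    out <- rbind(j(event$upstream_ee, "left", "upstreamEE"),
                 j(event$downstream_es, "right", "downstreamES"))
  } else if (type %in% c("A5SS", "A3SS")) {
    # flanking exon genomically right: variable boundaries are exon ends
    if (event$flanking_es >= event$long_exon_end) {
      out <- rbind(j(event$long_exon_end, "left", "longExonEnd"),
                   j(event$short_ee, "left", "shortEE"),
                   j(event$flanking_es, "right", "flankingES"))
    } else {
      out <- rbind(j(event$long_exon_start, "right", "longExonStart"),
                   j(event$short_es, "right", "shortES"),
                   j(event$flanking_ee, "left", "flankingEE"))
    }
  } else {
    stop(sprintf("unknown event_type '%s'", type))
  }
  out
}

new_window_set <- function(owner_id, windows, params) {
  structure(list(owner_id = owner_id, windows = windows, params = params),
            class = "window_set")
}

#' @exportS3Method base::print
print.window_set <- function(x, ...) {
  cat(sprintf("window_set for '%s': %d window(s)\n", x$owner_id,
              nrow(x$windows)))
  print(x$windows)
  invisible(x)
}

#' Build splice-junction windows for one event
#'
#' For every junction of a non-RI event, an exonic window extends `exonic_bp`
#' from the junction into the body of the adjoining exon and an intronic
#' window extends `intronic_bp` into the intron; for RI events a single
#' window of `ri_bp` on both sides of each junction is used. Windows are
#' clipped at position 0 and deliberately not clipped against neighbouring
#' exons, so an intronic window may reach into an adjacent exon when the
#' intron is short.
#'
#' @param event One event row.
#' @param exonic_bp,intronic_bp Window reach into exon/intron (bp); defaults
#'   50 and 200.
#' @param ri_bp Symmetric reach for RI junctions; default 50.
#' @return A `window_set`: `owner_id`, interval data frame `windows` with
#'   labels `junction|side`, and the parameters used.
#' @export
build_event_windows <- function(event, exonic_bp = 50L, intronic_bp = 200L,
                                ri_bp = 50L) {
  jx <- junctions_of(event)
  rows <- vector("list", 0L)
  add <- function(s, e, name, side) {
    s <- max(0L, as.integer(s)); e <- as.integer(e)
    if (s < e)
      rows[[length(rows) + 1L]] <<- data.frame(
        chrom = event$chrom, start = s, end = e, strand = event$strand,
        label = paste0(name, "|", side), stringsAsFactors = FALSE)
  }
  if (event$event_type == "RI") {
    for (i in seq_len(nrow(jx)))
      add(jx$coord[i] - ri_bp, jx$coord[i] + ri_bp, jx$name[i], "body")
  } else {
    for (i in seq_len(nrow(jx))) {
      co <- jx$coord[i]
      if (jx$exon_direction[i] == "right") {
        add(co, co + exonic_bp, jx$name[i], "exonic")
        add(co - intronic_bp, co, jx$name[i], "intronic")
      } else {
        add(co - exonic_bp, co, jx$name[i], "exonic")
        add(co, co + intronic_bp, jx$name[i], "intronic")
      }
    }
  }
  windows <- if (length(rows)) do.call(rbind, rows) else gintervals()
  new_window_set(event$event_id, windows,
                 list(exonic_bp = exonic_bp, intronic_bp = intronic_bp,
                      ri_bp = ri_bp))
}

#' Build the expanded-exon window for a DEU feature
#'
#' A differential exon-usage bin is expanded symmetrically by `flank_bp`,
#' giving a single body window `[max(0, start - flank), end + flank)`. For
#' `flank_bp >= 50` this is a superset of both boundary windows plus the exon
#' interior.
#'
#' @param exon One row of a DEU table from [read_dexseq()].
#' @param flank_bp Flank in bp (the scan grid uses 50, 250, 500, 1000).
#' @export
build_deu_windows <- function(exon, flank_bp) {
  stopifnot(nrow(exon) == 1L, exon$start < exon$end, flank_bp >= 0)
  w <- gintervals(exon$chrom, max(0L, exon$start - as.integer(flank_bp)),
                  exon$end + as.integer(flank_bp), exon$strand,
                  paste0(exon$bin_id, "|body"))
  new_window_set(exon$bin_id, w, list(deu_flank_bp = as.integer(flank_bp)))
}

#' Merge the windows of a window set
#'
#' Overlapping or adjacent windows are unioned ([union_intervals()]); total
#' covered length is preserved and labels concatenated.
#'
#' @param ws A `window_set`.
#' @export
merge_windows <- function(ws) {
  stopifnot(inherits(ws, "window_set"))
  new_window_set(ws$owner_id, union_intervals(ws$windows), ws$params)
}
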