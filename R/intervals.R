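#' Construct a set of genomic intervals
#'
#' Intervals are the package's single internal coordinate currency: 0-based,
#' half-open `[start, end)`, BED-style. rMATS `_0base` start columns map
#' directly; rMATS end columns are already exclusive; VCF and REDItools-style
#' positions are shifted by -1 on read.
#'
#' @param chrom Character vector of chromosome names (non-empty strings).
#' @param start Integer vector, 0-based inclusive starts, `>= 0`.
#' @param end Integer vector, 0-based exclusive ends, `> start`.
#' @param strand Character vector in `"+"`, `"-"`, `"."` (recycled).
#' @param label Character vector of free-text labels (recycled).
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `strand`,
#'   `label`, one row per interval.
#' @examples
#' gintervals("chr1", 99, 100, "+", "site")
#' @export
gintervals <- function(chrom = character(), start = integer(),
                       end = integer(), strand = ".", label = "") {
  if (length(chrom) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), label = character(),
                      stringsAsFactors = FALSE))
  }
  x <- data.frame(chrom = as.character(chrom),
                  start = as.integer(start),
                  end = as.integer(end),
                  strand = as.character(strand),
                  label = as.character(label),
                  stringsAsFactors = FALSE)
  validate_gintervals(x)
  x
}

validate_gintervals <- function(x) {
  stopifnot(is.data.frame(x),
            all(c("chrom", "start", "end", "strand") %in% names(x)))
  if (any(is.na(x$chrom) | !nzchar(x$chrom)))
    stop("interval with empty chromosome name")
  if (any(is.na(x$start) | is.na(x$end)))
    stop("interval with missing coordinates")
  if (any(x$start < 0L))
    stop("interval start < 0")
  bad <- which(x$start >= x$end)
  if (length(bad))
    stop(sprintf("interval with start >= end at row %d (%s:%d-%d)",
                 bad[1], x$chrom[bad[1]], x$start[bad[1]], x$end[bad[1]]))
  if (any(!x$strand %in% c("+", "-", ".")))
    stop("interval strand must be one of '+', '-', '.'")
  invisible(x)
}

#' Intersect two interval sets
#'
#' Reports every (query, subject) index pair whose intervals share a
#' chromosome and overlap under the half-open convention
#' (`q.start < s.end && s.start < q.end`). The default strand policy mirrors
#' `bedtools intersect` without `-s`: strand is ignored. Under
#' `strand_policy = "match"`, `.` matches anything.
#'
#' Implementation is a per-chromosome sort plus linear sweep over subject
#' starts, with subjects retired once their end falls at or before the current
#' query start; no quadratic behaviour on sorted non-overlapping input.
#'
#' @param queries,subjects Interval data frames from [gintervals()].
#' @param strand_policy `"ignore"` (default) or `"match"`.
#' @return A `data.frame` with integer columns `query` and `subject` (row
#'   indices into the inputs), sorted by query then subject.
#' @export
intersect_intervals <- function(queries, subjects,
                                strand_policy = c("ignore", "match")) {
  strand_policy <- match.arg(strand_policy)
  empty <- data.frame(query = integer(), subject = integer())
  if (!NROW(queries) || !NROW(subjects)) return(empty)
  out_q <- vector("list", 0L)
  out_s <- vector("list", 0L)
  for (ch in intersect(unique(queries$chrom), unique(subjects$chrom))) {
    qi <- which(queries$chrom == ch)
    si <- which(subjects$chrom == ch)
    so <- si[order(subjects$start[si], si)]
    ss <- subjects$start[so]
    se <- subjects$end[so]
    qo <- qi[order(queries$start[qi], qi)]
    alive <- rep(TRUE, length(so))
    # subjects sorted by end, for retirement as query starts advance
    by_end <- order(se)
    retire_ptr <- 1L
    for (u in qo) {
      qs <- queries$start[u]
      qe <- queries$end[u]
      while (retire_ptr <= length(by_end) && se[by_end[retire_ptr]] <= qs) {
        alive[by_end[retire_ptr]] <- FALSE
        retire_ptr <- retire_ptr + 1L
      }
      k <- findInterval(qe - 1L, ss)  # subjects with start < qe
      if (k > 0L) {
        hit <- which(alive[seq_len(k)])
        if (length(hit)) {
          out_q[[length(out_q) + 1L]] <- rep.int(u, length(hit))
          out_s[[length(out_s) + 1L]] <- so[hit]
        }
      }
    }
  }
  if (!length(out_q)) return(empty)
  res <- data.frame(query = unlist(out_q), subject = unlist(out_s))
  if (strand_policy == "match") {
    qstr <- queries$strand[res$query]
    sstr <- subjects$strand[res$subject]
    res <- res[qstr == "." | sstr == "." | qstr == sstr, , drop = FALSE]
  }
  res <- res[order(res$query, res$subject), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Count queries hit by at least one subject
#'
#' @inheritParams intersect_intervals
#' @return Number of distinct query indices appearing in the
#'   [intersect_intervals()] output.
#' @export
count_overlapping_queries <- function(queries, subjects,
                                      strand_policy = c("ignore", "match")) {
  length(unique(intersect_intervals(queries, subjects, strand_policy)$query))
}

#' Symmetrically expand intervals
#'
#' Each interval becomes `[max(0, start - flank_bp), end + flank_bp)`; strand
#' and label are preserved.
#'
#' @param intervals Interval data frame.
#' @param flank_bp Non-negative expansion in bp.
#' @export
expand_intervals <- function(intervals, flank_bp) {
  stopifnot(length(flank_bp) == 1L, flank_bp >= 0)
  if (!NROW(intervals)) return(intervals)
  intervals$start <- pmax(0L, as.integer(intervals$start - flank_bp))
  intervals$end <- as.integer(intervals$end + flank_bp)
  intervals
}

#' Union overlapping or adjacent intervals
#'
#' Intervals on the same chromosome that overlap or touch are merged; labels
#' of merged intervals are concatenated with `","` in coordinate order. Strand
#' is kept when uniform within a merged run and set to `"."` otherwise.
#'
#' @param intervals Interval data frame.
#' @export
union_intervals <- function(intervals) {
  if (NROW(intervals) <= 1L) return(intervals)
  o <- order(intervals$chrom, intervals$start, intervals$end)
  x <- intervals[o, , drop = FALSE]
  n <- nrow(x)
  grp <- integer(n)
  grp[1] <- 1L
  cur_end <- x$end[1]
  cur_chrom <- x$chrom[1]
  g <- 1L
  for (i in seq_len(n)[-1]) {
    if (x$chrom[i] == cur_chrom && x$start[i] <= cur_end) {
      cur_end <- max(cur_end, x$end[i])
    } else {
      g <- g + 1L
      cur_chrom <- x$chrom[i]
      cur_end <- x$end[i]
    }
    grp[i] <- g
  }
  merged <- lapply(split(seq_len(n), grp), function(idx) {
    s <- unique(x$strand[idx])
    data.frame(chrom = x$chrom[idx[1]],
               start = min(x$start[idx]),
               end = max(x$end[idx]),
               strand = if (length(s) == 1L) s else ".",
               label = paste(x$label[idx], collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, merged)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Subtract one interval set from another
#'
#' Returns the parts of `x` not covered by `y` (half-open arithmetic).
#' Labels and strand of the originating `x` interval are kept.
#'
#' @param x,y Interval data frames.
#' @export
subtract_intervals <- function(x, y) {
  if (!NROW(x)) return(x)
  if (!NROW(y)) return(x)
  yu <- union_intervals(y)
  pieces <- vector("list", 0L)
  for (i in seq_len(nrow(x))) {
    s <- x$start[i]
    e <- x$end[i]
    cov <- yu[yu$chrom == x$chrom[i] & yu$start < e & yu$end > s, , drop = FALSE]
    if (!nrow(cov)) {
      pieces[[length(pieces) + 1L]] <- x[i, , drop = FALSE]
      next
    }
    cov <- cov[order(cov$start), , drop = FALSE]
    cur <- s
    for (j in seq_len(nrow(cov))) {
      if (cov$start[j] > cur) {
        pieces[[length(pieces) + 1L]] <-
          data.frame(chrom = x$chrom[i], start = cur,
                     end = min(cov$start[j], e), strand = x$strand[i],
                     label = x$label[i], stringsAsFactors = FALSE)
      }
      cur <- max(cur, cov$end[j])
      if (cur >= e) break
    }
    if (cur < e) {
      pieces[[length(pieces) + 1L]] <-
        data.frame(chrom = x$chrom[i], start = cur, end = e,
                   strand = x$strand[i], label = x$label[i],
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(pieces)) return(gintervals())
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

# total covered bases (after union)
interval_coverage <- function(intervals) {
  if (!NROW(intervals)) return(0L)
  u <- union_intervals(intervals)
  sum(u$end - u$start)
}
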