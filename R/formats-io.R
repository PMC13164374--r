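#' @importFrom utils read.delim write.table read.table
NULL

# ---- BED ---------------------------------------------------------------

#' Read a BED3/BED6 file
#'
#' BED is already 0-based half-open, so coordinates are taken verbatim.
#' `track`/`browser`/comment lines are skipped. The BED name column becomes
#' the interval label.
#'
#' @param path Path to a BED file.
#' @return Interval data frame (see [gintervals()]).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(#|track\\b|browser\\b)", lines)]
  if (!length(lines)) return(gintervals())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop(sprintf("BED row %d has fewer than 3 fields", which(nf < 3L)[1]))
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end))
    stop("BED row with non-numeric coordinates")
  bad <- which(start >= end)
  if (length(bad))
    stop(sprintf("BED row %d has start >= end", bad[1]))
  label <- ifelse(nf >= 4L, vapply(fields, function(f) f[min(4L, length(f))], ""), ".")
  strand <- ifelse(nf >= 6L, vapply(fields, function(f) f[min(6L, length(f))], ""), ".")
  strand[!strand %in% c("+", "-")] <- "."
  gintervals(chrom, start, end, strand, label)
}

#' Write intervals as BED6
#'
#' Inverse of [read_bed()]: 0-based half-open coordinates are written
#' verbatim; empty labels become `"."`; score is written as 0.
#'
#' @param intervals Interval data frame.
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  label <- intervals$label
  label[is.na(label) | !nzchar(label)] <- "."
  df <- data.frame(intervals$chrom, intervals$start, intervals$end,
                   label, 0L, intervals$strand)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Load RADAR/DARNED database editing sites
#'
#' Reads the two database BED files (1-bp intervals) and merges them into a
#' single reference set with per-site provenance flags; a site present in both
#' databases is stored once with both flags set.
#'
#' @param radar_path,darned_path BED paths; either may be `NULL`.
#' @return Interval data frame with extra logical columns `in_radar`,
#'   `in_darned`.
#' @export
load_db_sites <- function(radar_path = NULL, darned_path = NULL) {
  pieces <- list()
  if (!is.null(radar_path)) {
    r <- read_bed(radar_path)
    if (nrow(r)) { r$in_radar <- TRUE; r$in_darned <- FALSE }
    else { r$in_radar <- logical(); r$in_darned <- logical() }
    pieces$radar <- r
  }
  if (!is.null(darned_path)) {
    d <- read_bed(darned_path)
    if (nrow(d)) { d$in_radar <- FALSE; d$in_darned <- TRUE }
    else { d$in_radar <- logical(); d$in_darned <- logical() }
    pieces$darned <- d
  }
  if (!length(pieces)) {
    out <- gintervals()
    out$in_radar <- logical()
    out$in_darned <- logical()
    return(out)
  }
  all <- do.call(rbind, pieces)
  key <- paste(all$chrom, all$start, all$end)
  out <- all[!duplicated(key), , drop = FALSE]
  okey <- paste(out$chrom, out$start, out$end)
  out$in_radar <- as.logical(tapply(all$in_radar, key, any)[okey])
  out$in_darned <- as.logical(tapply(all$in_darned, key, any)[okey])
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- rMATS JC tables ---------------------------------------------------

rmats_coord_cols <- list(
  SE = c(exon_start = "exonStart_0base", exon_end = "exonEnd",
         upstream_es = "upstreamES", upstream_ee = "upstreamEE",
         downstream_es = "downstreamES", downstream_ee = "downstreamEE"),
  MXE = c(exon1_start = "1stExonStart_0base", exon1_end = "1stExonEnd",
          exon2_start = "2ndExonStart_0base", exon2_end = "2ndExonEnd",
          upstream_es = "upstreamES", upstream_ee = "upstreamEE",
          downstream_es = "downstreamES", downstream_ee = "downstreamEE"),
  RI = c(ri_exon_start = "riExonStart_0base", ri_exon_end = "riExonEnd",
         upstream_es = "upstreamES", upstream_ee = "upstreamEE",
         downstream_es = "downstreamES", downstream_ee = "downstreamEE"),
  A5SS = c(long_exon_start = "longExonStart_0base", long_exon_end = "longExonEnd",
           short_es = "shortES", short_ee = "shortEE",
           flanking_es = "flankingES", flanking_ee = "flankingEE"),
  A3SS = c(long_exon_start = "longExonStart_0base", long_exon_end = "longExonEnd",
           short_es = "shortES", short_ee = "shortEE",
           flanking_es = "flankingES", flanking_ee = "flankingEE")
)

rmats_common_cols <- c("ID", "GeneID", "geneSymbol", "chr", "strand",
                       "IJC_SAMPLE_1", "SJC_SAMPLE_1", "IJC_SAMPLE_2",
                       "SJC_SAMPLE_2", "IncFormLen", "SkipFormLen",
                       "PValue", "FDR", "IncLevel1", "IncLevel2",
                       "IncLevelDifference")

split_int_list <- function(x) {
  lapply(strsplit(x, ",", fixed = TRUE), function(v) as.integer(v))
}

split_psi_list <- function(x) {
  lapply(strsplit(x, ",", fixed = TRUE), function(v) {
    v[v == "NA"] <- NA
    as.numeric(v)
  })
}

#' Read an rMATS *.MATS.JC.txt table
#'
#' Parses the junction-count (JC) dialect of an rMATS result table for one
#' event class. rMATS `_0base` start columns are taken as-is and end columns
#' treated as exclusive, so all coordinates land directly in the package's
#' 0-based half-open convention. Comma-separated per-replicate count and PSI
#' lists are split; `"NA"` PSI entries become missing.
#'
#' @param path Path to a tab-separated rMATS JC table with a header row.
#' @param event_type One of `"SE"`, `"MXE"`, `"RI"`, `"A5SS"`, `"A3SS"`.
#' @return A `data.frame` with one row per event: identifiers, genomic
#'   coordinates (columns depend on `event_type`; unused ones are `NA`),
#'   list-columns `ijc_g1`, `sjc_g1`, `ijc_g2`, `sjc_g2`, `inc_level_g1`,
#'   `inc_level_g2`, and scalar `inc_form_len`, `skip_form_len`, `p_value`,
#'   `fdr`, `inc_level_difference`.
#' @export
read_rmats_jc <- function(path, event_type = c("SE", "MXE", "RI", "A5SS", "A3SS")) {
  event_type <- match.arg(event_type)
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  coord_map <- rmats_coord_cols[[event_type]]
  needed <- c(rmats_common_cols, unname(coord_map))
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols))
    stop(sprintf("rMATS %s table %s is missing column '%s'",
                 event_type, path, missing_cols[1]))
  col1 <- function(nm) tab[[which(names(tab) == nm)[1]]]
  n <- nrow(tab)
  ev <- data.frame(
    event_id = if (n) paste0(event_type, "_", col1("ID")) else character(),
    rmats_id = as.integer(col1("ID")),
    event_type = rep(event_type, n),
    gene_id = col1("GeneID"),
    gene_symbol = col1("geneSymbol"),
    chrom = col1("chr"),
    strand = col1("strand"),
    stringsAsFactors = FALSE
  )
  all_coord_names <- unique(unlist(lapply(rmats_coord_cols, names)))
  for (nm in all_coord_names) ev[[nm]] <- rep(NA_integer_, n)
  for (nm in names(coord_map)) ev[[nm]] <- as.integer(col1(coord_map[[nm]]))
  ev$ijc_g1 <- split_int_list(col1("IJC_SAMPLE_1"))
  ev$sjc_g1 <- split_int_list(col1("SJC_SAMPLE_1"))
  ev$ijc_g2 <- split_int_list(col1("IJC_SAMPLE_2"))
  ev$sjc_g2 <- split_int_list(col1("SJC_SAMPLE_2"))
  ev$inc_level_g1 <- split_psi_list(col1("IncLevel1"))
  ev$inc_level_g2 <- split_psi_list(col1("IncLevel2"))
  ev$inc_form_len <- as.integer(col1("IncFormLen"))
  ev$skip_form_len <- as.integer(col1("SkipFormLen"))
  ev$p_value <- as.numeric(col1("PValue"))
  ev$fdr <- as.numeric(col1("FDR"))
  ev$inc_level_difference <- as.numeric(col1("IncLevelDifference"))
  for (i in seq_len(n)) {
    if (length(ev$ijc_g1[[i]]) != length(ev$sjc_g1[[i]]) ||
        length(ev$ijc_g2[[i]]) != length(ev$sjc_g2[[i]]))
      stop(sprintf("row %d of %s: replicate count list lengths differ", i, path))
  }
  ev
}

num17 <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, "")
  out
}

#' Write events in the rMATS JC dialect
#'
#' Inverse of [read_rmats_jc()]; floating-point columns are written with 17
#' significant digits so a read-back reproduces them exactly.
#'
#' @param events Event data frame (single `event_type`).
#' @param path Output path.
#' @export
write_rmats_jc <- function(events, path) {
  stopifnot(is.data.frame(events))
  if (nrow(events)) {
    type <- unique(events$event_type)
    stopifnot(length(type) == 1L)
  } else type <- "SE"
  coord_map <- rmats_coord_cols[[type]]
  join_int <- function(lst) vapply(lst, paste, "", collapse = ",")
  join_psi <- function(lst) vapply(lst, function(v) paste(num17(v), collapse = ","), "")
  out <- data.frame(ID = events$rmats_id, GeneID = events$gene_id,
                    geneSymbol = events$gene_symbol, chr = events$chrom,
                    strand = events$strand, check.names = FALSE,
                    stringsAsFactors = FALSE)
  for (nm in names(coord_map)) out[[coord_map[[nm]]]] <- events[[nm]]
  # rMATS emits the ID column a second time ahead of the count columns
  out2 <- data.frame(ID = events$rmats_id,
                     IJC_SAMPLE_1 = join_int(events$ijc_g1),
                     SJC_SAMPLE_1 = join_int(events$sjc_g1),
                     IJC_SAMPLE_2 = join_int(events$ijc_g2),
                     SJC_SAMPLE_2 = join_int(events$sjc_g2),
                     IncFormLen = events$inc_form_len,
                     SkipFormLen = events$skip_form_len,
                     PValue = num17(events$p_value),
                     FDR = num17(events$fdr),
                     IncLevel1 = join_psi(events$inc_level_g1),
                     IncLevel2 = join_psi(events$inc_level_g2),
                     IncLevelDifference = num17(events$inc_level_difference),
                     check.names = FALSE, stringsAsFactors = FALSE)
  full <- cbind(out, out2)
  write.table(full, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

# ---- DEXSeq-style DEU tables -------------------------------------------

#' Default column map for DEXSeq-style results
#'
#' DEXSeq output headers vary by version; the map is configurable. The
#' default matches a flattened `DEXSeqResults` table. `one_based = TRUE`
#' declares the on-disk coordinates as 1-based inclusive (the DEXSeq/GFF
#' convention); they are converted to 0-based half-open on read.
#'
#' @param bin_id,gene_id,chrom,start,end,strand,log2fc,p,fdr Column names.
#' @param one_based Are on-disk coordinates 1-based inclusive?
#' @export
dexseq_col_map <- function(bin_id = "featureID", gene_id = "groupID",
                           chrom = "genomicData.seqnames",
                           start = "genomicData.start",
                           end = "genomicData.end",
                           strand = "genomicData.strand",
                           log2fc = "log2fold", p = "pvalue", fdr = "padj",
                           one_based = TRUE) {
  list(bin_id = bin_id, gene_id = gene_id, chrom = chrom, start = start,
       end = end, strand = strand, log2fc = log2fc, p = p, fdr = fdr,
       one_based = one_based)
}

#' Read a DEXSeq-style differential exon usage table
#'
#' @param path Tab-separated table with a header row.
#' @param col_map Column map from [dexseq_col_map()].
#' @return A `data.frame` with columns `bin_id`, `gene_id`, `chrom`, `start`,
#'   `end` (0-based half-open), `strand`, `log2_fold_change`, `p_value`,
#'   `fdr`, and `direction` (`"included"` if log2FC > 0 else `"excluded"`).
#' @export
read_dexseq <- function(path, col_map = dexseq_col_map()) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  for (nm in c("bin_id", "gene_id", "chrom", "start", "end", "log2fc", "p", "fdr")) {
    if (!col_map[[nm]] %in% names(tab))
      stop(sprintf("DEU table %s is missing column '%s'", path, col_map[[nm]]))
  }
  start <- suppressWarnings(as.integer(tab[[col_map$start]]))
  end <- suppressWarnings(as.integer(tab[[col_map$end]]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop(sprintf("DEU table row %d: unmappable coordinates", bad[1]))
  if (isTRUE(col_map$one_based)) start <- start - 1L
  strand <- if (col_map$strand %in% names(tab)) tab[[col_map$strand]] else "."
  strand[!strand %in% c("+", "-")] <- "."
  l2fc <- as.numeric(tab[[col_map$log2fc]])
  data.frame(bin_id = as.character(tab[[col_map$bin_id]]),
             gene_id = as.character(tab[[col_map$gene_id]]),
             chrom = as.character(tab[[col_map$chrom]]),
             start = start, end = end, strand = strand,
             log2_fold_change = l2fc,
             p_value = as.numeric(tab[[col_map$p]]),
             fdr = as.numeric(tab[[col_map$fdr]]),
             direction = ifelse(l2fc > 0, "included", "excluded"),
             stringsAsFactors = FALSE)
}

# ---- editing-site tables -----------------------------------------------

make_editing_sites <- function(chrom, pos, strand, ref, alt, depth, edited) {
  o <- order(chrom, pos, strand, ref, alt)
  x <- data.frame(chrom = chrom[o], pos = as.integer(pos[o]),
                  strand = strand[o], ref = ref[o], alt = alt[o],
                  stringsAsFactors = FALSE)
  depth <- depth[o, , drop = FALSE]
  edited <- edited[o, , drop = FALSE]
  storage.mode(depth) <- "integer"
  storage.mode(edited) <- "integer"
  if (any(edited > depth, na.rm = TRUE))
    stop("editing site with edited_reads > depth")
  x$depth <- I(depth)
  x$edited <- I(edited)
  x$replicate_support <- as.integer(rowSums(edited >= 1L, na.rm = TRUE))
  x$in_radar <- FALSE
  x$in_darned <- FALSE
  x$region_repeat <- NA_character_
  x$region_gene <- NA_character_
  x$site_id <- paste0(x$chrom, ":", x$pos)
  x
}

#' Read per-sample editing-site tables
#'
#' Reads one REDItools-like TSV per sample and merges them into a single site
#' table keyed on (chrom, position, strand, ref, alt). On-disk positions are
#' 1-based and converted to 0-based. A site absent from a sample's file gets
#' depth 0 in that sample. The default column map (`chrom`, `pos`, `strand`,
#' `ref`, `alt`, `depth`, `edited`) is configurable for other dialects.
#'
#' @param paths Character vector of per-sample TSV paths.
#' @param sample_ids Sample names, defaulting to file basenames.
#' @param col_map Named list mapping internal names to on-disk column names.
#' @return A site `data.frame` with matrix columns `depth` and `edited`
#'   (sites x samples) and columns `replicate_support` (number of samples with
#'   at least one edited read), `in_radar`, `in_darned`, region annotations
#'   and `site_id`.
#' @export
read_editing_table <- function(paths, sample_ids = NULL,
                               col_map = list(chrom = "chrom", pos = "pos",
                                              strand = "strand", ref = "ref",
                                              alt = "alt", depth = "depth",
                                              edited = "edited")) {
  if (is.null(sample_ids))
    sample_ids <- sub("\\.[^.]*$", "", basename(paths))
  stopifnot(length(paths) == length(sample_ids))
  per <- lapply(paths, function(p) {
    tab <- read.delim(p, check.names = FALSE, stringsAsFactors = FALSE)
    for (nm in unlist(col_map))
      if (!nm %in% names(tab))
        stop(sprintf("editing table %s is missing column '%s'", p, nm))
    pos <- suppressWarnings(as.integer(tab[[col_map$pos]]))
    if (anyNA(pos) && nrow(tab))
      stop(sprintf("editing table %s row %d: malformed position",
                   p, which(is.na(pos))[1]))
    data.frame(chrom = as.character(tab[[col_map$chrom]]),
               pos = pos - 1L,
               strand = as.character(tab[[col_map$strand]]),
               ref = as.character(tab[[col_map$ref]]),
               alt = as.character(tab[[col_map$alt]]),
               depth = as.integer(tab[[col_map$depth]]),
               edited = as.integer(tab[[col_map$edited]]),
               stringsAsFactors = FALSE)
  })
  keys <- lapply(per, function(d) paste(d$chrom, d$pos, d$strand, d$ref, d$alt))
  all_keys <- unique(unlist(keys))
  proto <- do.call(rbind, per)[match(all_keys, unlist(keys)), , drop = FALSE]
  ns <- length(sample_ids)
  depth <- matrix(0L, length(all_keys), ns, dimnames = list(NULL, sample_ids))
  edited <- depth
  for (k in seq_len(ns)) {
    idx <- match(keys[[k]], all_keys)
    depth[idx, k] <- per[[k]]$depth
    edited[idx, k] <- per[[k]]$edited
  }
  make_editing_sites(proto$chrom, proto$pos, proto$strand, proto$ref,
                     proto$alt, depth, edited)
}

#' Write per-sample editing-site tables
#'
#' Inverse of [read_editing_table()]: one TSV per sample, positions written
#' 1-based.
#'
#' @param sites Site data frame.
#' @param paths One output path per sample column.
#' @export
write_editing_table <- function(sites, paths) {
  ns <- ncol(sites$depth)
  stopifnot(length(paths) == ns)
  for (k in seq_len(ns)) {
    df <- data.frame(chrom = sites$chrom, pos = sites$pos + 1L,
                     strand = sites$strand, ref = sites$ref, alt = sites$alt,
                     depth = sites$depth[, k], edited = sites$edited[, k])
    write.table(df, paths[k], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}

#' Read editing sites from a VCF
#'
#' Positions are converted from the 1-based VCF convention to the internal
#' 0-based one. Per-sample depth is taken from the `AD` FORMAT field (depth =
#' sum of allele depths, edited = first-ALT depth) with `DP` as fallback for
#' depth. VCF carries no strand, so sites are read with strand `"."`.
#'
#' @param path Path to a VCF v4.x file (plain text).
#' @return Site data frame as from [read_editing_table()].
#' @export
read_vcf_sites <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  if (!n) stop("VCF contains no records")
  samples <- colnames(v@gt)[-1]
  ns <- length(samples)
  depth <- matrix(NA_integer_, n, max(ns, 1L),
                  dimnames = list(NULL, if (ns) samples else "sample1"))
  edited <- depth
  fmt <- if (!is.null(v@gt)) v@gt[, 1] else character()
  has_ad <- ns > 0 && any(grepl("\\bAD\\b", fmt))
  has_dp <- ns > 0 && any(grepl("\\bDP\\b", fmt))
  if (has_ad) {
    ad <- vcfR::extract.gt(v, element = "AD")
    for (k in seq_len(ns)) {
      parts <- strsplit(ad[, k], ",", fixed = TRUE)
      depth[, k] <- vapply(parts, function(p)
        if (all(is.na(p))) NA_integer_ else sum(as.integer(p)), integer(1))
      edited[, k] <- vapply(parts, function(p)
        if (length(p) < 2 || is.na(p[2])) NA_integer_ else as.integer(p[2]),
        integer(1))
    }
  } else if (has_dp) {
    dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
    depth[] <- as.integer(dp)
    edited[] <- NA_integer_
    warning("VCF has no AD field; edited-read counts unavailable")
  } else {
    warning("VCF has no AD/DP depth information; depths marked missing")
  }
  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  if (anyNA(pos)) stop("VCF row with malformed POS")
  edited[!is.na(edited) & !is.na(depth) & edited > depth] <- NA_integer_
  x <- data.frame(chrom = fix[, "CHROM"], pos = pos - 1L, strand = ".",
                  ref = fix[, "REF"], alt = fix[, "ALT"],
                  stringsAsFactors = FALSE)
  o <- order(x$chrom, x$pos)
  x <- x[o, , drop = FALSE]
  depth <- depth[o, , drop = FALSE]
  edited <- edited[o, , drop = FALSE]
  x$depth <- I(depth)
  x$edited <- I(edited)
  x$replicate_support <- as.integer(rowSums(edited >= 1L, na.rm = TRUE))
  x$in_radar <- FALSE
  x$in_darned <- FALSE
  x$region_repeat <- NA_character_
  x$region_gene <- NA_character_
  x$site_id <- paste0(x$chrom, ":", x$pos)
  rownames(x) <- NULL
  x
}

# ---- GTF ---------------------------------------------------------------

#' Read a minimal gene-model GTF
#'
#' Uses `rtracklayer` for parsing; only `gene` and `exon` features are kept.
#' GTF 1-based inclusive coordinates are converted to 0-based half-open.
#'
#' @param path GTF path.
#' @return A list with interval data frames `genes` and `exons` (labels carry
#'   `gene_id`).
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- as.data.frame(gr)
  conv <- function(d) {
    if (!nrow(d)) return(gintervals())
    strand <- as.character(d$strand)
    strand[strand == "*"] <- "."
    gintervals(as.character(d$seqnames), d$start - 1L, d$end, strand,
               as.character(d$gene_id))
  }
  list(genes = conv(md[md$type == "gene", , drop = FALSE]),
       exons = conv(md[md$type == "exon", , drop = FALSE]))
}
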