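#' Keep only addressable A-to-I variants
#'
#' A-to-I editing is read by sequencers as A>G on the plus strand and T>C on
#' the minus strand. A site is retained iff (ref = A, alt = G) on strand `+`
#' or unknown (`.`), or (ref = T, alt = C) on strand `-`; everything else is
#' dropped. Unknown-strand sites are evaluated as A>G only, since without
#' strand a T>C call cannot be oriented. Order is preserved and the filter is
#' idempotent.
#'
#' @param sites Site data frame (see [read_editing_table()]).
#' @export
filter_addressable <- function(sites) {
  if (!NROW(sites)) return(sites)
  keep <- (sites$ref == "A" & sites$alt == "G" & sites$strand %in% c("+", ".")) |
          (sites$ref == "T" & sites$alt == "C" & sites$strand == "-")
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter editing sites on read support
#'
#' Implements the support rule: a site is retained iff its total depth summed
#' over all samples is at least `min_total_depth` AND it is either observed
#' (>= 1 edited read) in at least `min_replicates` samples or present in the
#' known-editing-site database. The depth gate is conjunctive: a database site
#' below the depth threshold is still dropped. `in_radar`/`in_darned` flags
#' are set on the returned sites as a side effect of the membership check.
#'
#' @param sites Site data frame.
#' @param min_total_depth Minimum summed depth across samples; default 5.
#' @param min_replicates Minimum samples with an edited read; default 2.
#' @param db_sites Database sites as 1-bp intervals, optionally with
#'   `in_radar`/`in_darned` columns (see [load_db_sites()]); may be `NULL`.
#' @export
filter_support <- function(sites, min_total_depth = 5L, min_replicates = 2L,
                           db_sites = NULL) {
  if (!NROW(sites)) return(sites)
  if (is.null(ncol(sites$depth)) || ncol(sites$depth) == 0L) {
    warning("sites carry no per-sample counts; all dropped")
    return(sites[integer(), , drop = FALSE])
  }
  total_depth <- rowSums(sites$depth, na.rm = TRUE)
  support <- rowSums(sites$edited >= 1L, na.rm = TRUE)
  in_db <- rep(FALSE, nrow(sites))
  if (!is.null(db_sites) && NROW(db_sites)) {
    as_iv <- gintervals(sites$chrom, sites$pos, sites$pos + 1L, sites$strand,
                        sites$site_id)
    hits <- intersect_intervals(as_iv, db_sites, "ignore")
    in_db[unique(hits$query)] <- TRUE
    if (!is.null(db_sites$in_radar)) {
      r <- tapply(db_sites$in_radar[hits$subject], hits$query, any)
      sites$in_radar[as.integer(names(r))] <- sites$in_radar[as.integer(names(r))] | unname(r)
    }
    if (!is.null(db_sites$in_darned)) {
      d <- tapply(db_sites$in_darned[hits$subject], hits$query, any)
      sites$in_darned[as.integer(names(d))] <- sites$in_darned[as.integer(names(d))] | unname(d)
    }
  }
  keep <- total_depth >= min_total_depth & (support >= min_replicates | in_db)
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-site differential editing between two sample groups
#'
#' For each site, edited and unedited read counts are summed within each
#' group into a 2x2 table (edited/unedited x group A/B) and tested with a
#' two-sided Fisher's exact test. A site with zero total depth in either
#' group is flagged untestable with a missing p-value. Raw p-values drive the
#' default significance call at `alpha`; Benjamini-Hochberg q-values across
#' all testable sites are reported alongside.
#'
#' @param sites Site data frame.
#' @param group_a,group_b Sample-id character vectors (column names of the
#'   depth matrix).
#' @param alpha Significance threshold on the raw p-value; default 0.05.
#' @return A `data.frame` with one row per site: the four table cells,
#'   `p_value`, `q_value`, `testable` and `significant`.
#' @export
differential_editing <- function(sites, group_a, group_b, alpha = 0.05) {
  stopifnot(NROW(sites) > 0, length(group_a) >= 1, length(group_b) >= 1)
  cn <- colnames(sites$depth)
  if (!all(c(group_a, group_b) %in% cn))
    stop("unknown sample id in group definition")
  sum_grp <- function(m, g) rowSums(m[, g, drop = FALSE], na.rm = TRUE)
  ed_a <- sum_grp(sites$edited, group_a)
  ed_b <- sum_grp(sites$edited, group_b)
  dp_a <- sum_grp(sites$depth, group_a)
  dp_b <- sum_grp(sites$depth, group_b)
  un_a <- dp_a - ed_a
  un_b <- dp_b - ed_b
  testable <- dp_a > 0 & dp_b > 0
  p <- rep(NA_real_, nrow(sites))
  for (i in which(testable)) {
    tab <- matrix(c(ed_a[i], un_a[i], ed_b[i], un_b[i]), nrow = 2)
    p[i] <- stats::fisher.test(tab)$p.value
  }
  q <- rep(NA_real_, nrow(sites))
  q[testable] <- stats::p.adjust(p[testable], method = "BH")
  data.frame(site_id = sites$site_id, chrom = sites$chrom, pos = sites$pos,
             edited_a = ed_a, unedited_a = un_a,
             edited_b = ed_b, unedited_b = un_b,
             p_value = p, q_value = q, testable = testable,
             significant = !is.na(p) & p < alpha,
             stringsAsFactors = FALSE)
}

#' Annotate sites with repeat and gene-model context
#'
#' Each site gains a repeat-region label (`Alu` if inside a repeat interval
#' whose label contains "Alu", `repetitive-nonAlu` inside any other repeat,
#' else `nonrepetitive`) and a gene-region label (`exonic` inside any exon,
#' else `intronic` inside a gene span, else `intergenic`).
#'
#' @param sites Site data frame.
#' @param repeats Repeat intervals; the label field carries the repeat class.
#' @param gene_model A list with `genes` and `exons` interval data frames
#'   (see [read_gtf()]).
#' @export
annotate_regions <- function(sites, repeats, gene_model) {
  if (!NROW(sites)) return(sites)
  iv <- gintervals(sites$chrom, sites$pos, sites$pos + 1L, sites$strand,
                   sites$site_id)
  rep_lab <- rep("nonrepetitive", nrow(sites))
  if (NROW(repeats)) {
    hits <- intersect_intervals(iv, repeats, "ignore")
    if (nrow(hits)) {
      is_alu <- grepl("alu", repeats$label[hits$subject], ignore.case = TRUE)
      alu_q <- unique(hits$query[is_alu])
      oth_q <- setdiff(unique(hits$query), alu_q)
      rep_lab[alu_q] <- "Alu"
      rep_lab[oth_q] <- "repetitive-nonAlu"
    }
  }
  gene_lab <- rep("intergenic", nrow(sites))
  if (NROW(gene_model$genes)) {
    gh <- intersect_intervals(iv, gene_model$genes, "ignore")
    gene_lab[unique(gh$query)] <- "intronic"
  }
  if (NROW(gene_model$exons)) {
    eh <- intersect_intervals(iv, gene_model$exons, "ignore")
    gene_lab[unique(eh$query)] <- "exonic"
  }
  sites$region_repeat <- rep_lab
  sites$region_gene <- gene_lab
  sites
}

#' Write a filtered site table with provenance columns
#'
#' @param sites Site data frame.
#' @param path Output TSV path.
#' @export
write_site_table <- function(sites, path) {
  df <- data.frame(site_id = sites$site_id, chrom = sites$chrom,
                   pos = sites$pos, strand = sites$strand, ref = sites$ref,
                   alt = sites$alt,
                   depth_total = rowSums(sites$depth, na.rm = TRUE),
                   replicate_support = sites$replicate_support,
                   in_radar = sites$in_radar, in_darned = sites$in_darned,
                   region_repeat = sites$region_repeat,
                   region_gene = sites$region_gene)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
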