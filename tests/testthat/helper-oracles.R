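# Independent oracles and fixture builders shared across the suite.

# All-pairs brute-force interval overlap (the oracle for the sweep engine).
brute_intersect <- function(queries, subjects, strand_policy = "ignore") {
  if (!NROW(queries) || !NROW(subjects))
    return(data.frame(query = integer(), subject = integer()))
  g <- expand.grid(query = seq_len(nrow(queries)),
                   subject = seq_len(nrow(subjects)))
  qs <- queries[g$query, ]
  ss <- subjects[g$subject, ]
  ok <- qs$chrom == ss$chrom & qs$start < ss$end & ss$start < qs$end
  if (strand_policy == "match")
    ok <- ok & (qs$strand == "." | ss$strand == "." | qs$strand == ss$strand)
  out <- data.frame(query = g$query[ok], subject = g$subject[ok])
  out <- out[order(out$query, out$subject), , drop = FALSE]
  rownames(out) <- NULL
  out
}

random_intervals <- function(n, chroms = paste0("chr", 1:3), max_pos = 5000L,
                             max_len = 200L) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  gintervals(sample(chroms, n, replace = TRUE), start,
             start + sample.int(max_len, n, replace = TRUE),
             sample(c("+", "-", "."), n, replace = TRUE),
             paste0("iv", seq_len(n)))
}

# Two-sided Fisher p by exhaustive enumeration of all tables with the
# observed margins, probabilities from log-binomial coefficients (no dhyper).
fisher_enum_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; N <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == N) return(1)
  xs <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, xs) + lchoose(r2, c1 - xs) - lchoose(N, c1)
  p_obs <- logp[xs == a]
  # standard rule: sum the mass of tables no more probable than the observed
  sum(exp(logp[logp <= p_obs + log(1 + 1e-7)]))
}

# one editing site per 2x2 table, two samples, so differential_editing
# reconstructs exactly that table
sites_from_tables <- function(tab) {
  n <- nrow(tab)
  depth <- cbind(s1 = tab$a + tab$b, s2 = tab$c + tab$d)
  edited <- cbind(s1 = tab$a, s2 = tab$c)
  data.frame(chrom = "chr1", pos = seq_len(n) * 10L, strand = "+",
             ref = "A", alt = "G", depth = I(depth), edited = I(edited),
             replicate_support = rowSums(edited >= 1),
             in_radar = FALSE, in_darned = FALSE,
             region_repeat = NA_character_, region_gene = NA_character_,
             site_id = paste0("chr1:", seq_len(n) * 10L),
             stringsAsFactors = FALSE)
}

make_se_event <- function(event_id = "SE_1", chrom = "chr1", strand = "+",
                          up_es = 1000L, up_ee = 1100L, ex_s = 1300L,
                          ex_e = 1400L, dn_es = 1600L, dn_ee = 1700L,
                          ijc1 = list(c(30L, 28L, 31L)),
                          sjc1 = list(c(10L, 12L, 9L)),
                          ijc2 = list(c(20L, 22L, 25L)),
                          sjc2 = list(c(20L, 18L, 15L)),
                          fdr = 0.01, dpsi = 0.2,
                          gene_symbol = "GENE1") {
  ev <- data.frame(event_id = event_id, rmats_id = 1L, event_type = "SE",
                   gene_id = tolower(gene_symbol), gene_symbol = gene_symbol,
                   chrom = chrom, strand = strand, stringsAsFactors = FALSE)
  for (nm in c("exon_start", "exon_end", "upstream_es", "upstream_ee",
               "downstream_es", "downstream_ee", "exon1_start", "exon1_end",
               "exon2_start", "exon2_end", "ri_exon_start", "ri_exon_end",
               "long_exon_start", "long_exon_end", "short_es", "short_ee",
               "flanking_es", "flanking_ee"))
    ev[[nm]] <- NA_integer_
  ev$upstream_es <- up_es; ev$upstream_ee <- up_ee
  ev$exon_start <- ex_s; ev$exon_end <- ex_e
  ev$downstream_es <- dn_es; ev$downstream_ee <- dn_ee
  ev$ijc_g1 <- ijc1; ev$sjc_g1 <- sjc1
  ev$ijc_g2 <- ijc2; ev$sjc_g2 <- sjc2
  ev$inc_level_g1 <- list(c(0.6, 0.58, 0.62))
  ev$inc_level_g2 <- list(c(0.4, 0.41, 0.43))
  ev$inc_form_len <- 198L; ev$skip_form_len <- 99L
  ev$p_value <- fdr / 2; ev$fdr <- fdr
  ev$inc_level_difference <- dpsi
  ev
}

make_ri_event <- function(event_id = "RI_1", chrom = "chr1", strand = "+",
                          up_es = 400L, up_ee = 500L, dn_es = 800L,
                          dn_ee = 900L) {
  ev <- make_se_event(event_id = event_id, chrom = chrom, strand = strand)
  ev$event_type <- "RI"
  ev$exon_start <- ev$exon_end <- NA_integer_
  ev$upstream_es <- up_es; ev$upstream_ee <- up_ee
  ev$downstream_es <- dn_es; ev$downstream_ee <- dn_ee
  ev$ri_exon_start <- up_es; ev$ri_exon_end <- dn_ee
  ev
}

make_sites <- function(chrom, pos, strand = "+", ref = "A", alt = "G",
                       depth = NULL, edited = NULL, n_samples = 6L) {
  n <- length(pos)
  if (is.null(depth))
    depth <- matrix(10L, n, n_samples,
                    dimnames = list(NULL, paste0("s", seq_len(n_samples))))
  if (is.null(edited))
    edited <- matrix(2L, n, n_samples, dimnames = dimnames(depth))
  chrom <- rep_len(chrom, n); strand <- rep_len(strand, n)
  ref <- rep_len(ref, n); alt <- rep_len(alt, n)
  data.frame(chrom = chrom, pos = as.integer(pos), strand = strand,
             ref = ref, alt = alt, depth = I(depth), edited = I(edited),
             replicate_support = as.integer(rowSums(edited >= 1)),
             in_radar = FALSE, in_darned = FALSE,
             region_repeat = NA_character_, region_gene = NA_character_,
             site_id = paste0(chrom, ":", pos), stringsAsFactors = FALSE)
}

build_filter_fixture <- function(n = 100L, n_pass = 37L, seed = 17) {
  # events constructed so that exactly n_pass satisfy all three gates;
  # the rest fail at least one, spread across the three reasons
  set.seed(seed)
  evs <- lapply(seq_len(n), function(i) {
    pass <- i <= n_pass
    fail_mode <- if (pass) "none" else sample(c("reads", "fdr", "dpsi"), 1)
    counts <- function(lo) list(as.integer(sample(lo:60, 3, TRUE)))
    ev <- make_se_event(event_id = sprintf("SE_%03d", i),
                        up_es = 1000L + i * 2000L,
                        up_ee = 1100L + i * 2000L,
                        ex_s = 1300L + i * 2000L, ex_e = 1400L + i * 2000L,
                        dn_es = 1600L + i * 2000L, dn_ee = 1700L + i * 2000L)
    ev$ijc_g1 <- counts(15); ev$ijc_g2 <- counts(15)
    ev$sjc_g1 <- counts(15); ev$sjc_g2 <- counts(15)
    if (fail_mode == "reads") {
      ev$ijc_g1[[1]][2] <- 7L; ev$sjc_g1[[1]][2] <- 12L  # 19 reads
    }
    ev$fdr <- if (fail_mode == "fdr") runif(1, 0.051, 1) else runif(1, 0, 0.05)
    ev$inc_level_difference <- if (fail_mode == "dpsi")
      runif(1, -0.099, 0.099) else sample(c(-1, 1), 1) * runif(1, 0.1, 0.6)
    ev$rmats_id <- i
    ev
  })
  do.call(rbind, evs)
}

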