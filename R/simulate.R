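#' Simulation configuration
#'
#' Collects every knob of the synthetic splicing/editing generator with
#' validated defaults. The defaults emulate the statistical shape of an
#' overexpression-vs-control comparison: half of the events differentially
#' spliced with |dPSI| >= 0.1, three replicates per group, junction depth
#' comfortably above the 20-read filter, editing sites as a sparse intronic
#' background plus an optional planted fraction inside event windows, and a
#' guard distance that keeps background sites out of reach of any window so
#' planted-fraction recovery is exact.
#'
#' @param seed Integer seed; every generator operation derives its RNG state
#'   from it.
#' @param n_chromosomes,chrom_length Toy genome shape.
#' @param n_genes Total genes across chromosomes.
#' @param exons_per_gene Length-2 integer range.
#' @param exon_length,intron_length,gene_spacing Gene geometry (bp).
#' @param event_types Event classes to simulate.
#' @param n_events_per_type Events per class; each event occupies its own
#'   gene.
#' @param frac_significant Fraction of events that are truly differentially
#'   spliced (count = `round(frac * n)`, deterministic).
#' @param dpsi_mean,dpsi_sd True |dPSI| distribution for significant events
#'   (normal, truncated to `[0.1, 0.6]`).
#' @param replicates_per_group,junction_depth Count structure per replicate.
#' @param planted_dependent_fraction Fraction of significant events given an
#'   editing site inside their merged 50/200 windows (count =
#'   `round(f * n_significant)`).
#' @param background_site_rate Background editing sites per kb of intron.
#' @param alu_fraction Fraction of each intron covered by an Alu interval.
#' @param db_site_fraction Share of planted sites echoed into the toy
#'   RADAR/DARNED database BEDs.
#' @param db_background_sites Database-only sites placed in guarded intronic
#'   space.
#' @param guard_distance Minimum distance (bp) between background sites and
#'   any event window; default 2000. Set 0 to let the background reach the
#'   windows (null-control mode).
#' @param depth_mean Per-sample site depth mean (Poisson).
#' @param clip_footprints_per_gene iCLIP footprints generated per gene.
#' @param clip_offset_sd SD (bp) of footprint offset from exon boundaries.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 3L, chrom_length = 2500000L,
                       n_genes = 90L, exons_per_gene = c(8L, 12L),
                       exon_length = 200L, intron_length = 1800L,
                       gene_spacing = 5000L,
                       event_types = c("SE", "MXE", "RI", "A5SS", "A3SS"),
                       n_events_per_type = 15L,
                       frac_significant = 0.5,
                       dpsi_mean = 0.25, dpsi_sd = 0.08,
                       replicates_per_group = 3L, junction_depth = 60L,
                       planted_dependent_fraction = 0.1,
                       background_site_rate = 0.2,
                       alu_fraction = 0.3,
                       db_site_fraction = 0.5,
                       db_background_sites = 30L,
                       guard_distance = 2000L,
                       depth_mean = 20,
                       clip_footprints_per_gene = 2L,
                       clip_offset_sd = 20) {
  cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
              chrom_length = as.integer(chrom_length), n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              exon_length = as.integer(exon_length),
              intron_length = as.integer(intron_length),
              gene_spacing = as.integer(gene_spacing),
              event_types = match.arg(event_types,
                                      c("SE", "MXE", "RI", "A5SS", "A3SS"),
                                      several.ok = TRUE),
              n_events_per_type = as.integer(n_events_per_type),
              frac_significant = frac_significant,
              dpsi_mean = dpsi_mean, dpsi_sd = dpsi_sd,
              replicates_per_group = as.integer(replicates_per_group),
              junction_depth = as.integer(junction_depth),
              planted_dependent_fraction = planted_dependent_fraction,
              background_site_rate = background_site_rate,
              alu_fraction = alu_fraction,
              db_site_fraction = db_site_fraction,
              db_background_sites = as.integer(db_background_sites),
              guard_distance = as.integer(guard_distance),
              depth_mean = depth_mean,
              clip_footprints_per_gene = as.integer(clip_footprints_per_gene),
              clip_offset_sd = clip_offset_sd)
  fr <- c("frac_significant", "planted_dependent_fraction", "alu_fraction",
          "db_site_fraction")
  for (nm in fr)
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1)
      stop(sprintf("sim_config: %s must be in [0, 1]", nm))
  if (any(c(cfg$chrom_length, cfg$exon_length, cfg$intron_length,
            cfg$n_genes, cfg$n_chromosomes) <= 0))
    stop("sim_config: lengths and counts must be positive")
  if (length(cfg$exons_per_gene) != 2L ||
      cfg$exons_per_gene[1] > cfg$exons_per_gene[2] ||
      cfg$exons_per_gene[1] < 4L)
    stop("sim_config: exons_per_gene must be a range with minimum >= 4")
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a toy genome
#'
#' Places non-overlapping genes with alternating fixed-length exons and
#' introns sequentially along each chromosome (strands alternate). Each
#' intron receives a centred Alu-labelled interval covering `alu_fraction` of
#' its bases. Deterministic under the config seed.
#'
#' @param config A [sim_config()].
#' @return A list of class `toy_genome` with `genes` and `exons` data frames,
#'   an `alu` interval frame, and the config.
#' @export
make_toy_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_ex <- sample(seq(config$exons_per_gene[1], config$exons_per_gene[2]),
                 config$n_genes, replace = TRUE)
  genes <- vector("list", config$n_genes)
  exons <- vector("list", config$n_genes)
  cursor <- rep(10000L, config$n_chromosomes)
  chrom_names <- paste0("chr", seq_len(config$n_chromosomes))
  ch <- 1L
  for (g in seq_len(config$n_genes)) {
    k <- n_ex[g]
    glen <- k * config$exon_length + (k - 1L) * config$intron_length
    tries <- 0L
    while (cursor[ch] + glen > config$chrom_length) {
      ch <- ch %% config$n_chromosomes + 1L
      tries <- tries + 1L
      if (tries > config$n_chromosomes)
        stop("make_toy_genome: genes do not fit the configured chromosomes")
    }
    gid <- sprintf("g%03d", g)
    strand <- if (g %% 2L) "+" else "-"
    ex_start <- cursor[ch] + (seq_len(k) - 1L) *
      (config$exon_length + config$intron_length)
    exons[[g]] <- data.frame(gene_id = gid, exon_index = seq_len(k),
                             chrom = chrom_names[ch], strand = strand,
                             start = ex_start,
                             end = ex_start + config$exon_length,
                             stringsAsFactors = FALSE)
    genes[[g]] <- data.frame(gene_id = gid, chrom = chrom_names[ch],
                             strand = strand, start = cursor[ch],
                             end = cursor[ch] + glen, n_exons = k,
                             stringsAsFactors = FALSE)
    cursor[ch] <- cursor[ch] + glen + config$gene_spacing
    ch <- ch %% config$n_chromosomes + 1L
  }
  genes <- do.call(rbind, genes)
  exons <- do.call(rbind, exons)
  alu <- gintervals()
  if (config$alu_fraction > 0) {
    alu_len <- round(config$alu_fraction * config$intron_length)
    rows <- list()
    for (g in seq_len(nrow(genes))) {
      ex <- exons[exons$gene_id == genes$gene_id[g], , drop = FALSE]
      if (nrow(ex) < 2L) next
      istart <- ex$end[-nrow(ex)]
      iend <- ex$start[-1]
      mid <- (istart + iend) %/% 2L
      rows[[g]] <- data.frame(chrom = ex$chrom[1],
                              start = mid - alu_len %/% 2L,
                              end = mid - alu_len %/% 2L + alu_len,
                              strand = ex$strand[1],
                              label = paste0("Alu|", genes$gene_id[g], "_i",
                                             seq_along(istart)),
                              stringsAsFactors = FALSE)
    }
    alu <- do.call(rbind, rows)
    rownames(alu) <- NULL
  }
  structure(list(genes = genes, exons = exons, alu = alu, config = config),
            class = "toy_genome")
}

#' Write a toy genome to GTF and BED
#'
#' @param genome A `toy_genome`.
#' @param gtf_path,alu_path Output paths.
#' @export
write_genome <- function(genome, gtf_path, alu_path) {
  g <- genome$genes
  e <- genome$exons
  gene_lines <- sprintf(
    "%s\tsplicedit_sim\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
    g$chrom, g$start + 1L, g$end, g$strand, g$gene_id)
  exon_lines <- sprintf(
    paste0("%s\tsplicedit_sim\texon\t%d\t%d\t.\t%s\t.\t",
           "gene_id \"%s\"; transcript_id \"%s.t1\"; exon_number \"%d\";"),
    e$chrom, e$start + 1L, e$end, e$strand, e$gene_id, e$gene_id,
    e$exon_index)
  writeLines(c(gene_lines, exon_lines), gtf_path)
  if (NROW(genome$alu)) write_bed(genome$alu, alu_path)
  else writeLines(character(), alu_path)
  invisible(genome)
}

psi_from_counts <- function(i, s, li, ls) {
  inc <- i / li
  skp <- s / ls
  ifelse(inc + skp > 0, inc / (inc + skp), NA_real_)
}

#' Simulate rMATS-style splicing events with known truth
#'
#' Events are placed on gene exon chains respecting each class's geometry
#' (upstream/downstream in genomic order, A5SS/A3SS orientation following
#' gene strand). For each replicate the inclusion count is binomial with the
#' junction-usage probability implied by the replicate group's true PSI after
#' length normalisation (psi = (I/LI) / (I/LI + S/LS)), at a fixed total
#' junction depth. A deterministic `round(frac_significant * n)` events per
#' class receive true |dPSI| in `[0.1, 0.6]` and a file FDR uniform in
#' (0, 0.05]; the rest get dPSI = 0 and FDR in (0.05, 1]. File-level
#' PValue/FDR are planted from the truth labels: the pipeline consumes rMATS
#' output, so fidelity of the file contract — not of the rMATS statistics —
#' is what is simulated.
#'
#' @param genome A `toy_genome`.
#' @param config The same [sim_config()].
#' @return A list with `events` (data frame in [read_rmats_jc()] layout) and
#'   `truth` (per-event data frame: `significant`, `true_psi_g1/g2`,
#'   `true_dpsi`, `planted_dependent`, `n_planted_sites`).
#' @export
simulate_events <- function(genome, config) {
  stopifnot(inherits(genome, "toy_genome"))
  set.seed(config$seed + 1L)
  types <- config$event_types
  n_per <- config$n_events_per_type
  total <- n_per * length(types)
  if (total > nrow(genome$genes))
    stop("simulate_events: need at least one gene per event; increase n_genes")
  gene_pick <- sample(genome$genes$gene_id, total)
  reps <- config$replicates_per_group
  li <- 198L
  ls <- 99L
  rows <- vector("list", total)
  truth <- vector("list", total)
  idx <- 0L
  for (tp in types) {
    n_sig <- round(config$frac_significant * n_per)
    sig_flags <- rep(FALSE, n_per)
    if (n_sig > 0) sig_flags[sample.int(n_per, n_sig)] <- TRUE
    for (e in seq_len(n_per)) {
      idx <- idx + 1L
      gid <- gene_pick[idx]
      gene <- genome$genes[genome$genes$gene_id == gid, ]
      ex <- genome$exons[genome$exons$gene_id == gid, , drop = FALSE]
      ex <- ex[order(ex$start), , drop = FALSE]
      k <- nrow(ex)
      co <- list()
      if (tp == "SE") {
        i <- sample(2:(k - 1L), 1L)
        co <- list(upstream_es = ex$start[i - 1], upstream_ee = ex$end[i - 1],
                   exon_start = ex$start[i], exon_end = ex$end[i],
                   downstream_es = ex$start[i + 1], downstream_ee = ex$end[i + 1])
      } else if (tp == "MXE") {
        i <- sample(seq_len(k - 3L), 1L)
        co <- list(upstream_es = ex$start[i], upstream_ee = ex$end[i],
                   exon1_start = ex$start[i + 1], exon1_end = ex$end[i + 1],
                   exon2_start = ex$start[i + 2], exon2_end = ex$end[i + 2],
                   downstream_es = ex$start[i + 3], downstream_ee = ex$end[i + 3])
      } else if (tp == "RI") {
        i <- sample(seq_len(k - 1L), 1L)
        co <- list(ri_exon_start = ex$start[i], ri_exon_end = ex$end[i + 1],
                   upstream_es = ex$start[i], upstream_ee = ex$end[i],
                   downstream_es = ex$start[i + 1], downstream_ee = ex$end[i + 1])
      } else {
        i <- sample(seq_len(k - 1L), 1L)
        delta <- sample(30:120, 1L)
        eL <- list(start = ex$start[i], end = ex$end[i])
        eR <- list(start = ex$start[i + 1], end = ex$end[i + 1])
        plus <- gene$strand == "+"
        # A5SS: alternative donor; A3SS: alternative acceptor
        ext_right <- (tp == "A5SS") == plus
        if (ext_right) {
          co <- list(long_exon_start = eL$start, long_exon_end = eL$end + delta,
                     short_es = eL$start, short_ee = eL$end,
                     flanking_es = eR$start, flanking_ee = eR$end)
        } else {
          co <- list(long_exon_start = eR$start - delta, long_exon_end = eR$end,
                     short_es = eR$start, short_ee = eR$end,
                     flanking_es = eL$start, flanking_ee = eL$end)
        }
      }
      sig <- sig_flags[e]
      if (sig) {
        mag <- min(max(stats::rnorm(1, config$dpsi_mean, config$dpsi_sd), 0.1), 0.6)
        d <- mag * sample(c(-1, 1), 1)
      } else d <- 0
      base <- stats::runif(1, 0.35, 0.65)
      psi1 <- base + d / 2
      psi2 <- base - d / 2
      p_inc <- function(psi) psi * li / (psi * li + (1 - psi) * ls)
      i1 <- stats::rbinom(reps, config$junction_depth, p_inc(psi1))
      s1 <- config$junction_depth - i1
      i2 <- stats::rbinom(reps, config$junction_depth, p_inc(psi2))
      s2 <- config$junction_depth - i2
      lvl1 <- psi_from_counts(i1, s1, li, ls)
      lvl2 <- psi_from_counts(i2, s2, li, ls)
      fdr <- if (sig) stats::runif(1, 0, 0.05) else stats::runif(1, 0.0500001, 1)
      row <- data.frame(event_id = paste0(tp, "_", e), rmats_id = e,
                        event_type = tp, gene_id = gid,
                        gene_symbol = toupper(gid), chrom = gene$chrom,
                        strand = gene$strand, stringsAsFactors = FALSE)
      for (nm in unique(unlist(lapply(rmats_coord_cols, names))))
        row[[nm]] <- if (!is.null(co[[nm]])) as.integer(co[[nm]]) else NA_integer_
      row$ijc_g1 <- list(as.integer(i1)); row$sjc_g1 <- list(as.integer(s1))
      row$ijc_g2 <- list(as.integer(i2)); row$sjc_g2 <- list(as.integer(s2))
      row$inc_level_g1 <- list(lvl1); row$inc_level_g2 <- list(lvl2)
      row$inc_form_len <- li; row$skip_form_len <- ls
      row$fdr <- fdr
      row$p_value <- fdr * stats::runif(1, 0.2, 1)
      row$inc_level_difference <- mean(lvl1, na.rm = TRUE) - mean(lvl2, na.rm = TRUE)
      rows[[idx]] <- row
      truth[[idx]] <- data.frame(event_id = row$event_id, event_type = tp,
                                 gene_id = gid, significant = sig,
                                 true_psi_g1 = psi1, true_psi_g2 = psi2,
                                 true_dpsi = d, planted_dependent = FALSE,
                                 n_planted_sites = 0L, stringsAsFactors = FALSE)
    }
  }
  list(events = do.call(rbind, rows), truth = do.call(rbind, truth))
}

place_in_intervals <- function(iv, n) {
  # n uniform positions over the union of intervals (weighted by length)
  len <- iv$end - iv$start
  pick <- sample.int(nrow(iv), n, replace = TRUE, prob = len)
  offs <- vapply(pick, function(j) sample.int(len[j], 1L) - 1L, integer(1))
  data.frame(chrom = iv$chrom[pick], pos = iv$start[pick] + offs,
             strand = iv$strand[pick], stringsAsFactors = FALSE)
}

#' Simulate editing sites, with planted window hits and guarded background
#'
#' A deterministic `round(planted_dependent_fraction * n_significant)` of the
#' truly significant events receive one addressable A>G (strand-oriented)
#' site placed uniformly inside their merged 50/200 windows. Background sites
#' are a Poisson process over intronic space at `background_site_rate` per
#' kb, excluding everything within `guard_distance` of any event window, so
#' with the default guard the dependence verdicts carry no sampling noise;
#' with `guard_distance = 0` no exclusion is applied and the background is
#' uniform over all intronic space (the null-control regime).
#' Per-sample depths are Poisson(`depth_mean`) over `2 * replicates_per_group`
#' samples and edited reads binomial with a Beta(2, 5) editing level; planted
#' sites are guaranteed detectable (at least two samples with an edited read
#' and total depth >= 5, enforced constructively). A `db_site_fraction` share
#' of planted sites is echoed into the toy RADAR/DARNED reference set,
#' alternating between the two databases, along with `db_background_sites`
#' database-only sites in guarded intronic space.
#'
#' @param genome A `toy_genome`.
#' @param events,truth Output of [simulate_events()].
#' @param config The same [sim_config()].
#' @return A list with `sites` (site data frame), `radar`/`darned` (1-bp
#'   interval frames), `truth_sites` (per-site provenance) and updated
#'   `truth` events.
#' @export
simulate_editing <- function(genome, events, truth, config) {
  set.seed(config$seed + 2L)
  reps <- config$replicates_per_group
  ns <- 2L * reps
  sample_ids <- c(paste0("ctrl", seq_len(reps)), paste0("oe", seq_len(reps)))
  sig_ids <- truth$event_id[truth$significant]
  n_plant <- round(config$planted_dependent_fraction * length(sig_ids))
  planted_ids <- if (n_plant > 0) sample(sig_ids, n_plant) else character()
  ev_strand <- stats::setNames(events$strand, events$event_id)
  site_rows <- list()
  for (eid in planted_ids) {
    ev <- events[events$event_id == eid, , drop = FALSE]
    ws <- merge_windows(build_event_windows(ev, 50L, 200L, 50L))
    w <- ws$windows
    len <- w$end - w$start
    j <- sample.int(nrow(w), 1L, prob = len)
    pos <- w$start[j] + sample.int(len[j], 1L) - 1L
    site_rows[[length(site_rows) + 1L]] <-
      data.frame(chrom = w$chrom[j], pos = pos, strand = ev$strand,
                 planted = TRUE, owner_event = eid, stringsAsFactors = FALSE)
  }
  # intronic space minus a guard zone around every event window
  introns <- list()
  for (gid in unique(genome$exons$gene_id)) {
    ex <- genome$exons[genome$exons$gene_id == gid, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) < 2L) next
    introns[[gid]] <- data.frame(chrom = ex$chrom[1],
                                 start = ex$end[-nrow(ex)],
                                 end = ex$start[-1], strand = ex$strand[1],
                                 label = gid, stringsAsFactors = FALSE)
  }
  introns <- do.call(rbind, introns)
  all_w <- event_windows_frame(events, 50L, 200L, 50L)
  allowed <- if (config$guard_distance > 0) {
    guard <- expand_intervals(all_w[, c("chrom", "start", "end", "strand",
                                        "label")],
                              config$guard_distance)
    subtract_intervals(introns, guard)
  } else introns  # guard 0: background is uniform over all intronic space
  if (NROW(allowed) && config$background_site_rate > 0) {
    kb <- sum(allowed$end - allowed$start) / 1000
    n_bg <- stats::rpois(1, config$background_site_rate * kb)
    if (n_bg > 0) {
      bg <- place_in_intervals(allowed, n_bg)
      bg$planted <- FALSE
      bg$owner_event <- NA_character_
      site_rows[[length(site_rows) + 1L]] <- bg
    }
  }
  sites_raw <- if (length(site_rows)) do.call(rbind, site_rows) else
    data.frame(chrom = character(), pos = integer(), strand = character(),
               planted = logical(), owner_event = character())
  sites_raw <- sites_raw[!duplicated(paste(sites_raw$chrom, sites_raw$pos)), ,
                         drop = FALSE]
  n_site <- nrow(sites_raw)
  ref <- ifelse(sites_raw$strand == "-", "T", "A")
  alt <- ifelse(sites_raw$strand == "-", "C", "G")
  depth <- matrix(stats::rpois(n_site * ns, config$depth_mean), n_site, ns,
                  dimnames = list(NULL, sample_ids))
  level <- stats::rbeta(max(n_site, 1L), 2, 5)[seq_len(n_site)]
  edited <- matrix(stats::rbinom(n_site * ns, as.vector(depth), rep(level, ns)),
                   n_site, ns, dimnames = list(NULL, sample_ids))
  if (any(sites_raw$planted)) {
    pl <- which(sites_raw$planted)
    depth[pl, 1:2][depth[pl, 1:2] < 1L] <- 1L
    edited[pl, 1:2][edited[pl, 1:2] < 1L] <- 1L
    edited[pl, ] <- pmin(edited[pl, ], depth[pl, ])
  }
  sites <- if (n_site) make_editing_sites(sites_raw$chrom, sites_raw$pos,
                                          sites_raw$strand, ref, alt,
                                          depth, edited)
  else make_editing_sites(character(), integer(), character(), character(),
                          character(), matrix(0L, 0, ns,
                                              dimnames = list(NULL, sample_ids)),
                          matrix(0L, 0, ns, dimnames = list(NULL, sample_ids)))
  # toy databases: echo of planted sites + guarded background-only sites
  n_echo <- round(config$db_site_fraction * sum(sites_raw$planted))
  echo_idx <- if (n_echo > 0) sample(which(sites_raw$planted), n_echo) else integer()
  db_rows <- list()
  if (length(echo_idx))
    db_rows$echo <- data.frame(chrom = sites_raw$chrom[echo_idx],
                               start = sites_raw$pos[echo_idx],
                               end = sites_raw$pos[echo_idx] + 1L,
                               strand = sites_raw$strand[echo_idx],
                               label = "db_echo", stringsAsFactors = FALSE)
  if (config$db_background_sites > 0 && NROW(allowed)) {
    dbg <- place_in_intervals(allowed, config$db_background_sites)
    db_rows$bg <- data.frame(chrom = dbg$chrom, start = dbg$pos,
                             end = dbg$pos + 1L, strand = dbg$strand,
                             label = "db_background", stringsAsFactors = FALSE)
  }
  db <- if (length(db_rows)) do.call(rbind, db_rows) else gintervals()
  db <- db[!duplicated(paste(db$chrom, db$start)), , drop = FALSE]
  in_radar <- seq_len(NROW(db)) %% 2L == 1L
  radar <- db[in_radar, , drop = FALSE]
  darned <- db[!in_radar, , drop = FALSE]
  rownames(radar) <- rownames(darned) <- NULL
  # region label for the per-site truth
  region <- rep("nonrepetitive", n_site)
  if (n_site && NROW(genome$alu)) {
    iv <- gintervals(sites_raw$chrom, sites_raw$pos, sites_raw$pos + 1L)
    hit <- intersect_intervals(iv, genome$alu, "ignore")
    region[unique(hit$query)] <- "Alu"
  }
  truth_sites <- data.frame(site_id = paste0(sites_raw$chrom, ":", sites_raw$pos),
                            chrom = sites_raw$chrom, pos = sites_raw$pos,
                            planted = sites_raw$planted,
                            owner_event = sites_raw$owner_event,
                            region = region, stringsAsFactors = FALSE)
  truth$planted_dependent <- truth$event_id %in% planted_ids
  tab <- table(sites_raw$owner_event[sites_raw$planted])
  truth$n_planted_sites <- as.integer(tab[truth$event_id])
  truth$n_planted_sites[is.na(truth$n_planted_sites)] <- 0L
  list(sites = sites, radar = radar, darned = darned,
       truth_sites = truth_sites, truth = truth, sample_ids = sample_ids)
}

#' Simulate iCLIP footprints near exon boundaries
#'
#' For each gene, `clip_footprints_per_gene` footprints of length 10-50 bp
#' are centred on randomly chosen exon boundaries with a normal offset
#' (`clip_offset_sd`). Deterministic under the config seed.
#'
#' @param genome A `toy_genome`.
#' @param config The same [sim_config()].
#' @return Interval data frame of footprints.
#' @export
simulate_clip <- function(genome, config) {
  set.seed(config$seed + 3L)
  if (config$clip_footprints_per_gene == 0L) return(gintervals())
  rows <- list()
  for (gid in unique(genome$exons$gene_id)) {
    ex <- genome$exons[genome$exons$gene_id == gid, , drop = FALSE]
    bounds <- c(ex$start, ex$end)
    for (f in seq_len(config$clip_footprints_per_gene)) {
      b <- sample(bounds, 1L)
      len <- sample(10:50, 1L)
      centre <- b + round(stats::rnorm(1, 0, config$clip_offset_sd))
      s <- max(0L, as.integer(centre - len %/% 2L))
      rows[[length(rows) + 1L]] <-
        data.frame(chrom = ex$chrom[1], start = s, end = s + len,
                   strand = ex$strand[1],
                   label = sprintf("fp_%s_%d", gid, f),
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full generator and write a self-contained run directory
#'
#' Writes `genome.gtf`, `alu.bed`, one `<TYPE>.MATS.JC.txt` per event class,
#' per-sample `edits_<sample>.tsv`, `radar.bed`, `darned.bed`, `clip.bed`,
#' `truth_events.tsv`, `truth_sites.tsv` and `config.yaml`.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with all in-memory objects (`genome`, `events`,
#'   `truth`, `sites`, `radar`, `darned`, `clip`, `sample_ids`, paths).
#' @export
simulate_run <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genome <- make_toy_genome(config)
  sim <- simulate_events(genome, config)
  ed <- simulate_editing(genome, sim$events, sim$truth, config)
  clip <- simulate_clip(genome, config)
  write_genome(genome, file.path(out_dir, "genome.gtf"),
               file.path(out_dir, "alu.bed"))
  rmats_paths <- character()
  for (tp in config$event_types) {
    p <- file.path(out_dir, paste0(tp, ".MATS.JC.txt"))
    write_rmats_jc(sim$events[sim$events$event_type == tp, , drop = FALSE], p)
    rmats_paths[tp] <- p
  }
  edit_paths <- file.path(out_dir, paste0("edits_", ed$sample_ids, ".tsv"))
  write_editing_table(ed$sites, edit_paths)
  write_bed(ed$radar, file.path(out_dir, "radar.bed"))
  write_bed(ed$darned, file.path(out_dir, "darned.bed"))
  if (NROW(clip)) write_bed(clip, file.path(out_dir, "clip.bed"))
  else writeLines(character(), file.path(out_dir, "clip.bed"))
  write.table(ed$truth, file.path(out_dir, "truth_events.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(ed$truth_sites, file.path(out_dir, "truth_sites.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
  invisible(list(genome = genome, events = sim$events, truth = ed$truth,
                 sites = ed$sites, radar = ed$radar, darned = ed$darned,
                 clip = clip, sample_ids = ed$sample_ids,
                 paths = list(out_dir = out_dir, rmats = rmats_paths,
                              edits = edit_paths)))
}
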