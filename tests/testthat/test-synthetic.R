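test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(frac_significant = 1.2), "frac_significant")
  expect_error(sim_config(alu_fraction = -0.1), "alu_fraction")
  expect_error(sim_config(n_genes = 0), "positive")
  expect_error(sim_config(exons_per_gene = c(2L, 3L)), "exons_per_gene")
})

test_that("toy genome places all genes within bounds, deterministically", {
  cfg <- sim_config(seed = 5, n_chromosomes = 2L, n_genes = 20L)
  g1 <- make_toy_genome(cfg)
  g2 <- make_toy_genome(cfg)
  expect_identical(g1$genes, g2$genes)
  expect_identical(g1$alu, g2$alu)
  expect_equal(nrow(g1$genes), 20L)
  expect_true(all(g1$genes$end <= cfg$chrom_length))
  expect_true(all(g1$genes$start >= 0))
  # genes on a chromosome do not overlap
  for (ch in unique(g1$genes$chrom)) {
    gg <- g1$genes[g1$genes$chrom == ch, ]
    gg <- gg[order(gg$start), ]
    if (nrow(gg) > 1) expect_true(all(gg$start[-1] >= gg$end[-nrow(gg)]))
  }
  # exons stay inside their gene
  m <- merge(g1$exons, g1$genes, by = "gene_id", suffixes = c("", ".g"))
  expect_true(all(m$start >= m$start.g & m$end <= m$end.g))
})

test_that("alu_fraction = 0 yields no Alu intervals; packing overflows error", {
  cfg0 <- sim_config(alu_fraction = 0)
  expect_equal(nrow(make_toy_genome(cfg0)$alu), 0L)
  expect_error(make_toy_genome(sim_config(n_genes = 500L,
                                          chrom_length = 100000L)),
               "do not fit")
})

test_that("length-normalized PSI follows the junction-count formula", {
  # I=30, S=10, LI=2, LS=1 -> psi = 15 / (15 + 10) = 0.6
  expect_equal(splicedit:::psi_from_counts(30, 10, 2, 1), 0.6)
  expect_equal(splicedit:::psi_from_counts(0, 0, 2, 1), NA_real_)
})

test_that("simulated events respect geometry, labels and the dPSI structure", {
  cfg <- sim_config(seed = 9)
  genome <- make_toy_genome(cfg)
  sim <- simulate_events(genome, cfg)
  ev <- sim$events
  expect_equal(nrow(ev), 75L)
  expect_equal(sum(sim$truth$significant), 40L)  # round(0.5 * 15) * 5
  # significant events carry FDR <= 0.05 and true |dPSI| >= 0.1
  sig <- sim$truth$significant
  expect_true(all(ev$fdr[sig] <= 0.05))
  expect_true(all(ev$fdr[!sig] > 0.05))
  expect_true(all(abs(sim$truth$true_dpsi[sig]) >= 0.1))
  expect_true(all(sim$truth$true_dpsi[!sig] == 0))
  # written IncLevelDifference equals the mean PSI difference
  for (i in seq_len(nrow(ev)))
    expect_equal(ev$inc_level_difference[i],
                 mean(ev$inc_level_g1[[i]], na.rm = TRUE) -
                   mean(ev$inc_level_g2[[i]], na.rm = TRUE),
                 tolerance = 1e-6)
  # SE geometry ordering
  se <- ev[ev$event_type == "SE", ]
  expect_true(all(se$upstream_es < se$upstream_ee &
                    se$upstream_ee <= se$exon_start &
                    se$exon_start < se$exon_end &
                    se$exon_end <= se$downstream_es &
                    se$downstream_es < se$downstream_ee))
})

test_that("frac_significant = 0 writes only non-significant FDRs", {
  cfg <- sim_config(seed = 11, frac_significant = 0,
                    event_types = "SE", n_events_per_type = 20L)
  genome <- make_toy_genome(cfg)
  sim <- simulate_events(genome, cfg)
  expect_true(all(sim$events$fdr > 0.05))
  expect_equal(sum(sim$truth$significant), 0L)
})

test_that("planted site counts follow the rounding rule and sit inside windows", {
  cfg <- sim_config(seed = 13, planted_dependent_fraction = 0.3)
  genome <- make_toy_genome(cfg)
  sim <- simulate_events(genome, cfg)
  ed <- simulate_editing(genome, sim$events, sim$truth, cfg)
  n_sig <- sum(sim$truth$significant)
  expect_equal(sum(ed$truth$planted_dependent), round(0.3 * n_sig))
  # every planted site lies inside its owner's merged 50/200 windows
  planted <- ed$truth_sites[ed$truth_sites$planted, ]
  for (i in seq_len(nrow(planted))) {
    ev <- sim$events[sim$events$event_id == planted$owner_event[i], ]
    w <- merge_windows(build_event_windows(ev))$windows
    expect_true(any(w$chrom == planted$chrom[i] &
                      w$start <= planted$pos[i] & planted$pos[i] < w$end))
  }
  # all generated sites are addressable and respect count invariants
  expect_identical(nrow(filter_addressable(ed$sites)), nrow(ed$sites))
  expect_true(all(ed$sites$edited <= ed$sites$depth))
  # planted sites survive the support filter by construction
  kept <- filter_support(ed$sites, 5L, 2L, NULL)
  expect_true(all(planted$site_id %in% kept$site_id))
})

test_that("background sites respect the guard distance around event windows", {
  cfg <- sim_config(seed = 15, planted_dependent_fraction = 0)
  genome <- make_toy_genome(cfg)
  sim <- simulate_events(genome, cfg)
  ed <- simulate_editing(genome, sim$events, sim$truth, cfg)
  expect_true(nrow(ed$sites) > 0)
  rec <- classify_events(sim$events[sim$truth$significant, ], ed$sites,
                         rbind(ed$radar, ed$darned))
  expect_equal(sum(rec$tag == "editing-dependent"), 0L)
})

test_that("clip footprints are reproducible and sized 10-50 bp", {
  cfg <- sim_config(seed = 19)
  genome <- make_toy_genome(cfg)
  c1 <- simulate_clip(genome, cfg)
  c2 <- simulate_clip(genome, cfg)
  expect_identical(c1, c2)
  expect_true(all(c1$end - c1$start >= 10 & c1$end - c1$start <= 50))
  expect_equal(nrow(c1), cfg$clip_footprints_per_gene * cfg$n_genes)
  cfg0 <- sim_config(seed = 19, clip_footprints_per_gene = 0L)
  expect_equal(nrow(simulate_clip(genome, cfg0)), 0L)
})

test_that("a run directory round-trips through the readers and is byte-stable", {
  cfg <- sim_config(seed = 25, n_events_per_type = 8L, n_genes = 60L)
  d1 <- file.path(withr::local_tempdir(), "r1")
  d2 <- file.path(withr::local_tempdir(), "r2")
  run1 <- simulate_run(cfg, d1)
  run2 <- simulate_run(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  se <- read_rmats_jc(file.path(d1, "SE.MATS.JC.txt"), "SE")
  se0 <- run1$events[run1$events$event_type == "SE", ]
  rownames(se0) <- NULL
  expect_identical(se$ijc_g1, se0$ijc_g1)
  expect_identical(se$fdr, se0$fdr)
  sites <- read_editing_table(run1$paths$edits, run1$sample_ids)
  expect_identical(sites$pos, run1$sites$pos)
  expect_identical(unclass(sites$depth), unclass(run1$sites$depth))
  db <- load_db_sites(file.path(d1, "radar.bed"), file.path(d1, "darned.bed"))
  expect_equal(nrow(db), nrow(run1$radar) + nrow(run1$darned))
})
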