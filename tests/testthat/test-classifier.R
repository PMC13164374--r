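test_that("rMATS filters keep exactly the constructed passing events", {
  events <- build_filter_fixture()
  flt <- filter_rmats(events)
  # independent re-evaluation of the three gates per event
  expect_pass <- vapply(seq_len(nrow(events)), function(i) {
    all(events$ijc_g1[[i]] + events$sjc_g1[[i]] >= 20) &&
      all(events$ijc_g2[[i]] + events$sjc_g2[[i]] >= 20) &&
      events$fdr[i] <= 0.05 && abs(events$inc_level_difference[i]) >= 0.1
  }, logical(1))
  expect_equal(sum(expect_pass), 37L)
  expect_equal(flt$kept$event_id, events$event_id[expect_pass])
  expect_equal(nrow(flt$removed), 63L)
  expect_true(all(flt$removed$reason %in% c("read_support", "fdr", "dpsi")))
})

test_that("a single replicate below 20 reads removes the event", {
  ev <- make_se_event(ijc1 = list(c(30L, 7L, 31L)),
                      sjc1 = list(c(10L, 12L, 9L)))
  flt <- filter_rmats(ev)
  expect_equal(nrow(flt$kept), 0L)
  expect_equal(flt$removed$reason, "read_support")
  # the laxer group-mean reading keeps it
  expect_equal(nrow(filter_rmats(ev, read_rule = "group_mean")$kept), 1L)
})

test_that("null-event selection partitions events passing the read gate", {
  events <- build_filter_fixture(n = 80L, n_pass = 30L, seed = 19)
  read_ok <- vapply(seq_len(nrow(events)), function(i)
    all(c(events$ijc_g1[[i]] + events$sjc_g1[[i]],
          events$ijc_g2[[i]] + events$sjc_g2[[i]]) >= 20), logical(1))
  pool <- events[read_ok, ]
  kept <- filter_rmats(events)$kept$event_id
  nonsig <- select_null_events(pool, "nonsignificant")$event_id
  lowd <- select_null_events(pool, "low_dpsi")$event_id
  expect_true(any(events$fdr > 0.5))  # fdr = 0.5 style rows land in nonsig
  expect_setequal(c(kept, nonsig, lowd), pool$event_id)
  expect_equal(anyDuplicated(c(kept, nonsig, lowd)), 0L)
})

test_that("classification tags events by window-site intersection", {
  se <- make_se_event()          # merged windows [1050, 1650)
  far <- make_se_event(event_id = "SE_2", up_es = 9000L, up_ee = 9100L,
                       ex_s = 9300L, ex_e = 9400L, dn_es = 9600L,
                       dn_ee = 9700L, gene_symbol = "GENE2")
  events <- rbind(se, far)
  own <- make_sites("chr1", 1200L)
  db <- gintervals("chr1", 1100L, 1101L, ".", "radar")
  db$in_radar <- TRUE; db$in_darned <- FALSE
  rec <- classify_events(events, own, db)
  r1 <- rec[rec$owner_id == "SE_1", ]
  expect_equal(r1$tag, "editing-dependent")
  expect_equal(r1$n_own_sites, 1L)
  expect_equal(r1$n_db_sites, 1L)
  expect_equal(r1$hit_site_ids, "chr1:1100,chr1:1200")
  r2 <- rec[rec$owner_id == "SE_2", ]
  expect_equal(r2$tag, "editing-independent")
  expect_equal(r2$hit_site_ids, "")
  # db-only hit is enough
  rec2 <- classify_events(events, own[0, ], db)
  expect_equal(rec2$tag[rec2$owner_id == "SE_1"], "editing-dependent")
  # tag partition holds
  expect_true(all(rec$tag %in% c("editing-dependent", "editing-independent")))
})

test_that("a site hit in both sources is counted once in the hit list", {
  se <- make_se_event()
  own <- make_sites("chr1", 1200L)
  db <- gintervals("chr1", 1200L, 1201L, ".", "radar")
  rec <- classify_events(se, own, db)
  expect_equal(rec$n_own_sites, 1L)
  expect_equal(rec$n_db_sites, 1L)
  expect_equal(rec$hit_site_ids, "chr1:1200")
})

test_that("enlarging the intronic window never flips dependent to independent", {
  cfg <- sim_config(seed = 23, guard_distance = 0L, background_site_rate = 0.6)
  genome <- make_toy_genome(cfg)
  sim <- simulate_events(genome, cfg)
  ed <- simulate_editing(genome, sim$events, sim$truth, cfg)
  rec200 <- classify_events(sim$events, ed$sites, NULL, 50L, 200L)
  rec600 <- classify_events(sim$events, ed$sites, NULL, 50L, 600L)
  dep200 <- rec200$owner_id[rec200$tag == "editing-dependent"]
  dep600 <- rec600$owner_id[rec600$tag == "editing-dependent"]
  expect_true(all(dep200 %in% dep600))
})

test_that("accumulation curves count first capture at the right window size", {
  # DEU exon [2000,2100); site exactly 600 bp from the right boundary
  exon <- data.frame(bin_id = "E1", gene_id = "g", chrom = "chr1",
                     start = 2000L, end = 2100L, strand = "+",
                     log2_fold_change = 1, p_value = 0.01, fdr = 0.01,
                     direction = "included")
  site <- make_sites("chr1", 2100L + 600L)
  cv <- accumulation_curve(exon, site, c(50L, 250L, 500L, 1000L), "deu_expand")
  expect_equal(cv$n_overlapping, c(0L, 0L, 0L, 1L))
  expect_equal(cv$fraction, c(0, 0, 0, 1))
  # site inside the exon body: flat curve
  cv2 <- accumulation_curve(exon, make_sites("chr1", 2050L),
                            c(50L, 250L, 500L, 1000L), "deu_expand")
  expect_equal(cv2$fraction, rep(1, 4))
  expect_error(accumulation_curve(exon[0, ], site), "empty feature")
})

test_that("event-window accumulation curves are non-decreasing", {
  cfg <- sim_config(seed = 29, guard_distance = 0L, background_site_rate = 0.4)
  genome <- make_toy_genome(cfg)
  sim <- simulate_events(genome, cfg)
  ed <- simulate_editing(genome, sim$events, sim$truth, cfg)
  cv <- accumulation_curve(sim$events, ed$sites, c(50L, 250L, 500L, 1000L),
                           "event_windows")
  expect_true(all(diff(cv$n_overlapping) >= 0))
  expect_equal(cv$fraction, cv$n_overlapping / cv$n_features)
})

test_that("fraction summaries partition counts per type and roll up to genes", {
  rec <- data.frame(owner_id = c("SE_1", "SE_2", "RI_1"),
                    event_type = c("SE", "SE", "RI"),
                    gene_symbol = c("Foo", "FOO", "BAR"),
                    tag = c("editing-dependent", "editing-independent",
                            "editing-independent"),
                    stringsAsFactors = FALSE)
  s <- summarize_fractions(rec)
  expect_equal(s$n_total, c(1L, 2L))
  expect_equal(s$n_dependent + s$n_independent, s$n_total)
  expect_equal(s$fraction_dependent[s$event_type == "SE"], 0.5)
  g <- summarize_fractions(rec, "gene")
  # Foo/FOO collapse to one gene, dependent because one event is
  expect_equal(g$n_total[g$event_type == "SE"], 1L)
  expect_equal(g$n_dependent[g$event_type == "SE"], 1L)
  all_indep <- rec; all_indep$tag <- "editing-independent"
  expect_true(all(summarize_fractions(all_indep)$fraction_dependent == 0))
})

test_that("event-set comparison matches by gene, type and coordinates", {
  a <- rbind(make_se_event(event_id = "SE_1", gene_symbol = "AAA"),
             make_se_event(event_id = "SE_2", up_es = 5000L, up_ee = 5100L,
                           ex_s = 5300L, ex_e = 5400L, dn_es = 5600L,
                           dn_ee = 5700L, gene_symbol = "BBB"))
  b_same <- a
  expect_equal(nrow(compare_event_sets(a, b_same, "coordinates")), 2L)
  expect_equal(nrow(compare_event_sets(a, b_same, "gene")), 2L)
  b_shift <- a
  b_shift$exon_start <- b_shift$exon_start + 10L
  expect_equal(nrow(compare_event_sets(a, b_shift, "coordinates")), 0L)
  expect_equal(nrow(compare_event_sets(a, b_shift, "gene_and_type")), 2L)
  b_other <- a
  b_other$gene_symbol <- c("XXX", "YYY")
  expect_equal(nrow(compare_event_sets(a, b_other, "gene")), 0L)
  # case-insensitive gene match
  b_case <- a; b_case$gene_symbol <- tolower(b_case$gene_symbol)
  expect_equal(nrow(compare_event_sets(a, b_case, "gene")), 2L)
})

test_that("planted coordinate-identical events are all recovered", {
  cfg <- sim_config(seed = 37, n_events_per_type = 15L)
  genome <- make_toy_genome(cfg)
  sim <- simulate_events(genome, cfg)
  se <- sim$events[sim$events$event_type == "SE", ]
  shared <- se[1:15, ]
  other <- se
  other$exon_start <- other$exon_start + 3L  # perturb all, then restore 15
  other[1:15, ] <- shared
  expect_equal(nrow(compare_event_sets(shared, other, "coordinates")), 15L)
})
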