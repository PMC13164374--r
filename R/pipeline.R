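read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop(sprintf("config file '%s' not found", config))
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config
}

log_open <- function(out_dir) {
  path <- file.path(out_dir, "run.log")
  if (file.exists(path)) unlink(path)
  function(fmt, ...) {
    line <- sprintf(fmt, ...)
    cat(line, "\n", sep = "", file = path, append = TRUE)
    message(line)
  }
}

write_manifest <- function(out_dir, config, inputs) {
  inputs <- inputs[!vapply(inputs, is.null, logical(1))]
  checksums <- lapply(inputs, function(p) unname(tools::md5sum(p)))
  manifest <- list(package = "splicedit",
                   version = as.character(utils::packageVersion("splicedit")),
                   seed = config$seed %||% NA,
                   config = config,
                   input_md5 = checksums)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

require_inputs <- function(paths) {
  paths <- unlist(paths)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop(sprintf("missing input file(s): %s", paste(missing, collapse = ", ")))
  invisible(paths)
}

#' Run the full dependence-classification pipeline
#'
#' Configuration keys (YAML file or list): `rmats` (named list event type ->
#' path), `edits` (per-sample table paths), `edit_samples` (optional sample
#' ids), `radar`/`darned` (optional BED paths), `seed`, and optional
#' thresholds `min_reads`, `max_fdr`, `min_abs_dpsi`, `min_total_depth`,
#' `min_replicates`, `exonic_bp`, `intronic_bp`, `ri_bp`, `curve_windows`.
#'
#' Stages: rMATS filters -> editing-site filters (addressable + support) ->
#' window intersection and tagging -> per-type and gene-level summaries ->
#' accumulation curves for the significant set and both null-control sets
#' (non-significant and low-dPSI). Every threshold used is echoed to the run
#' log and the machine-readable manifest; identical inputs and config yield
#' byte-identical outputs.
#'
#' @param config Path to a YAML config or an equivalent list.
#' @param out_dir Output directory.
#' @return Invisibly, a list with the in-memory results.
#' @export
run_classify <- function(config, out_dir) {
  cfg <- read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- log_open(out_dir)
  require_inputs(c(cfg$rmats, cfg$edits, cfg$radar, cfg$darned))
  set.seed(cfg$seed %||% 1L)
  min_reads <- cfg$min_reads %||% 20L
  max_fdr <- cfg$max_fdr %||% 0.05
  min_abs_dpsi <- cfg$min_abs_dpsi %||% 0.1
  min_total_depth <- cfg$min_total_depth %||% 5L
  min_replicates <- cfg$min_replicates %||% 2L
  exonic_bp <- cfg$exonic_bp %||% 50L
  intronic_bp <- cfg$intronic_bp %||% 200L
  ri_bp <- cfg$ri_bp %||% 50L
  curve_windows <- cfg$curve_windows %||% c(50L, 250L, 500L, 1000L)
  log("thresholds: min_reads=%d max_fdr=%g min_abs_dpsi=%g", min_reads,
      max_fdr, min_abs_dpsi)
  log("site filters: min_total_depth=%d min_replicates=%d", min_total_depth,
      min_replicates)
  log("windows: exonic=%d intronic=%d ri=%d", exonic_bp, intronic_bp, ri_bp)
  events <- do.call(rbind, lapply(names(cfg$rmats), function(tp)
    read_rmats_jc(cfg$rmats[[tp]], tp)))
  log("read %d events from %d rMATS tables", NROW(events), length(cfg$rmats))
  flt <- filter_rmats(events, min_reads, max_fdr, min_abs_dpsi)
  log("rMATS filters kept %d / %d events", NROW(flt$kept), NROW(events))
  db <- load_db_sites(cfg$radar, cfg$darned)
  sites <- read_editing_table(unlist(cfg$edits),
                              sample_ids = unlist(cfg$edit_samples))
  n0 <- NROW(sites)
  sites <- filter_addressable(sites)
  sites <- filter_support(sites, min_total_depth, min_replicates, db)
  log("editing-site filters kept %d / %d sites", NROW(sites), n0)
  if (!NROW(flt$kept)) {
    warning("no events pass the rMATS filters; writing empty outputs")
    for (f in c("classification.tsv", "summary_event.tsv", "summary_gene.tsv",
                "curves.tsv"))
      writeLines(character(), file.path(out_dir, f))
    write_manifest(out_dir, cfg, c(cfg$rmats, cfg$edits, cfg$radar, cfg$darned))
    return(invisible(list(records = NULL)))
  }
  records <- classify_events(flt$kept, sites, db, exonic_bp, intronic_bp, ri_bp)
  write_classification(records, file.path(out_dir, "classification.tsv"))
  sum_ev <- summarize_fractions(records, "event")
  sum_gene <- summarize_fractions(records, "gene")
  write.table(sum_ev, file.path(out_dir, "summary_event.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sum_gene, file.path(out_dir, "summary_gene.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  curve_of <- function(ev, set) {
    if (!NROW(ev)) return(NULL)
    cv <- accumulation_curve(ev, sites, curve_windows, "event_windows")
    attr(cv, "set") <- set
    cv
  }
  curves <- Filter(Negate(is.null), list(
    curve_of(flt$kept, "significant"),
    curve_of(select_null_events(events, "nonsignificant", max_fdr), "nonsignificant"),
    curve_of(select_null_events(events, "low_dpsi", max_fdr, min_abs_dpsi),
             "low_dpsi")))
  if (length(curves)) write_curve(curves, file.path(out_dir, "curves.tsv"))
  write_manifest(out_dir, cfg, c(cfg$rmats, cfg$edits, cfg$radar, cfg$darned))
  log("classified %d events: %d editing-dependent", NROW(records),
      sum(records$tag == "editing-dependent"))
  invisible(list(records = records, summary_event = sum_ev,
                 summary_gene = sum_gene, curves = curves, sites = sites))
}

#' Run the DEU-window overlap analysis
#'
#' Config keys: `dexseq` (table path), `edits`/`edit_samples` (as in
#' [run_classify()]), optional `radar`/`darned`, `max_fdr` (default 0.05,
#' applied to the DEU table), `curve_windows` (default 50/250/500/1000) and
#' site-filter thresholds.
#'
#' @inheritParams run_classify
#' @export
run_deu_overlap <- function(config, out_dir) {
  cfg <- read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- log_open(out_dir)
  require_inputs(c(cfg$dexseq, cfg$edits, cfg$radar, cfg$darned))
  max_fdr <- cfg$max_fdr %||% 0.05
  curve_windows <- cfg$curve_windows %||% c(50L, 250L, 500L, 1000L)
  deu <- read_dexseq(cfg$dexseq,
                     do.call(dexseq_col_map, cfg$dexseq_col_map %||% list()))
  keep <- !is.na(deu$fdr) & deu$fdr < max_fdr
  log("DEU table: %d rows, %d with FDR < %g", nrow(deu), sum(keep), max_fdr)
  deu <- deu[keep, , drop = FALSE]
  if (!nrow(deu)) stop("no significant DEU features")
  db <- load_db_sites(cfg$radar, cfg$darned)
  sites <- read_editing_table(unlist(cfg$edits),
                              sample_ids = unlist(cfg$edit_samples))
  sites <- filter_addressable(sites)
  sites <- filter_support(sites, cfg$min_total_depth %||% 5L,
                          cfg$min_replicates %||% 2L, db)
  cv <- accumulation_curve(deu, sites, curve_windows, "deu_expand")
  attr(cv, "set") <- "significant_deu"
  write_curve(cv, file.path(out_dir, "curves.tsv"))
  write_manifest(out_dir, cfg, c(cfg$dexseq, cfg$edits, cfg$radar, cfg$darned))
  log("curve written for %d DEU features", cv$n_features[1])
  invisible(cv)
}

#' Run the iCLIP footprint / database-site overlap analysis
#'
#' Config keys: `clip` (footprint BED), `radar`/`darned` (database BEDs),
#' optional `curve_windows` (default 0/50/250/500/1000).
#'
#' @inheritParams run_classify
#' @export
run_clip_overlap <- function(config, out_dir) {
  cfg <- read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- log_open(out_dir)
  require_inputs(c(cfg$clip, cfg$radar, cfg$darned))
  footprints <- read_bed(cfg$clip)
  db <- load_db_sites(cfg$radar, cfg$darned)
  cv <- footprint_site_overlap(footprints, db,
                               cfg$curve_windows %||% c(0L, 50L, 250L, 500L, 1000L))
  attr(cv, "set") <- "db_sites"
  write_curve(cv, file.path(out_dir, "curves.tsv"))
  write_manifest(out_dir, cfg, c(cfg$clip, cfg$radar, cfg$darned))
  log("clip overlap: %.4f at w=%d, %.4f at w=%d",
      cv$fraction[1], cv$window_size[1],
      cv$fraction[nrow(cv)], cv$window_size[nrow(cv)])
  invisible(cv)
}
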