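# Stage orchestration: one reproducible run from junction tables (plus
# annotation, genome, counts, groups) to result TSVs and a summary report.

#' Pipeline configuration
#'
#' Paths plus the analysis thresholds; the defaults are the pipeline's
#' canonical operating values (summed-coverage filter 50, p < 0.05,
#' cryptic acceptors closer than 50 nt upstream, -100/+10 windows, 50 nt
#' A-run region, six-mers over 30 nt, top 30 events, preferred-set sizes
#' 350/348, 500 control introns).
#'
#' @param junction_files Named character vector: sample -> SJ table path.
#' @param gtf,fasta,counts,groups_file Input paths (`counts` and
#'   `groups_file` may be `NULL` to skip the expression stage).
#' @param out_dir Output directory.
#' @param group_wt,group_r,group_k Group labels: wild-type comparator and
#'   the two mutant groups.
#' @param min_total_reads,p_threshold,max_upstream,window_up,window_down,
#'   run_region,kmer_k,kmer_region,top_n,n_set_r,n_set_k,n_controls,seed
#'   Analysis parameters.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(junction_files, gtf, fasta, out_dir,
                            counts = NULL, groups_file = NULL,
                            group_wt = "WT", group_r = "R625H",
                            group_k = "K700E",
                            min_total_reads = 50, p_threshold = 0.05,
                            max_upstream = 50, window_up = 100L,
                            window_down = 10L, run_region = 50L,
                            kmer_k = 6L, kmer_region = 30L, top_n = 30L,
                            n_set_r = 350L, n_set_k = 348L,
                            n_controls = 500L, seed = 1L) {
  structure(list(
    junction_files = junction_files, gtf = gtf, fasta = fasta,
    counts = counts, groups_file = groups_file, out_dir = out_dir,
    group_wt = group_wt, group_r = group_r, group_k = group_k,
    min_total_reads = min_total_reads, p_threshold = p_threshold,
    max_upstream = max_upstream, window_up = as.integer(window_up),
    window_down = as.integer(window_down),
    run_region = as.integer(run_region), kmer_k = as.integer(kmer_k),
    kmer_region = as.integer(kmer_region), top_n = as.integer(top_n),
    n_set_r = as.integer(n_set_r), n_set_k = as.integer(n_set_k),
    n_controls = as.integer(n_controls), seed = as.integer(seed)),
    class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; `junction_files` is a
#' mapping sample -> path.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  y$junction_files <- unlist(y$junction_files)
  do.call(pipeline_config, y)
}

read_groups_file <- function(path) {
  if (!file.exists(path)) stop("groups file not found: ", path)
  g <- data.table::fread(path, header = TRUE)
  stopifnot(all(c("sample", "group") %in% names(g)))
  stats::setNames(g$group, g$sample)
}

read_count_matrix <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  m <- as.matrix(dt[, -1, with = FALSE])
  rownames(m) <- dt[[1]]
  m
}

#' Run the full cryptic 3'ss pipeline
#'
#' Stages, in order: junction reading and coverage filtering; junction
#' classification and canonical pairing; PSI and differential-usage tests
#' (mutant pooled vs wild type, and R vs K); significant-event selection
#' and ranking; preferred-set split and control-intron selection;
#' acceptor-context sequence statistics (composition, Fisher tracks,
#' A-run features and their R-vs-K comparison, six-mer enrichment);
#' expression normalization, differential expression, PCA and clustering
#' (when a count matrix is provided). All result tables and a JSON report
#' are written under `config$out_dir`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every intermediate object plus `report`.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "pipeline.log")
  logf <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    cat(msg, "\n", sep = "", file = log_path, append = TRUE)
    message(msg)
  }

  logf("stage call: reading inputs")
  jt <- read_junction_table(cfg$junction_files)
  ann <- read_annotation(cfg$gtf)
  genome <- read_genome(cfg$fasta)
  groups <- if (!is.null(cfg$groups_file)) read_groups_file(cfg$groups_file)
            else stop("groups file is required")
  missing_groups <- setdiff(jt$samples, names(groups))
  if (length(missing_groups) > 0L) {
    stop("samples without group assignment: ",
         paste(missing_groups, collapse = ", "))
  }

  logf("stage call: %d junctions before filtering", nrow(jt$junctions))
  jt <- filter_low_coverage(jt, cfg$min_total_reads)
  jt <- classify_junctions(jt, ann)
  events <- pair_with_canonical(jt)
  psi <- compute_psi(events, jt)
  logf("stage call: %d junctions kept, %d events", nrow(jt$junctions),
       nrow(events))

  logf("stage test: differential PSI")
  mut_groups <- c(cfg$group_r, cfg$group_k)
  groups_mw <- ifelse(groups %in% mut_groups, "MUT", groups)
  names(groups_mw) <- names(groups)
  res_mut_wt <- test_differential_psi(psi, groups_mw, "MUT", cfg$group_wt)
  res_rk <- test_differential_psi(psi, groups, cfg$group_r, cfg$group_k)

  logf("stage select")
  sig <- select_significant_events(res_mut_wt, events,
                                   p_max = cfg$p_threshold,
                                   max_upstream = cfg$max_upstream)
  top <- rank_top_events(sig, n = cfg$top_n)
  sig_rk <- select_significant_events(res_rk, events,
                                      p_max = cfg$p_threshold,
                                      max_upstream = cfg$max_upstream)
  sets <- split_preferred_sets(sig_rk, n_R = cfg$n_set_r, n_K = cfg$n_set_k,
                               p_max = cfg$p_threshold)
  controls <- select_control_introns(ann, events, jt, n = cfg$n_controls,
                                     seed = cfg$seed)
  logf("stage select: %d significant, %d R-preferred, %d K-preferred, %d controls",
       nrow(sig), length(sets$R_preferred), length(sets$K_preferred),
       nrow(controls))

  logf("stage motif")
  ev_sites <- events[events$side == "3ss" & events$direction == "upstream",
                     c("event_id", "chrom", "strand", "cryptic_pos",
                       "canonical_pos"), with = FALSE]
  site_tbl <- rbind(
    data.table::data.table(site_id = ev_sites$event_id, class = "cryptic",
                           chrom = ev_sites$chrom, strand = ev_sites$strand,
                           acceptor_pos = ev_sites$cryptic_pos),
    data.table::data.table(site_id = paste0(ev_sites$event_id, ":canon"),
                           class = "canonical", chrom = ev_sites$chrom,
                           strand = ev_sites$strand,
                           acceptor_pos = ev_sites$canonical_pos),
    if (nrow(controls) > 0L) data.table::data.table(
      site_id = paste0("ctrl:", controls$chrom, ":", controls$acceptor_pos),
      class = "control", chrom = controls$chrom, strand = controls$strand,
      acceptor_pos = controls$acceptor_pos))
  windows <- extract_windows(site_tbl, genome, up = cfg$window_up,
                             down = cfg$window_down)
  motif <- NULL
  run_cmp <- NULL
  if (any(windows$class == "cryptic") && any(windows$class == "control")) {
    prof_cry <- composition_profile(windows[windows$class == "cryptic"])
    prof_can <- composition_profile(windows[windows$class == "canonical"])
    prof_ctl <- composition_profile(windows[windows$class == "control"])
    fisher_cry <- fisher_position_enrichment(prof_cry, prof_ctl)
    fisher_can <- fisher_position_enrichment(prof_can, prof_ctl)
    kmers <- kmer_enrichment(windows[windows$class == "cryptic"],
                             windows[windows$class == "control"],
                             k = cfg$kmer_k,
                             region = c(-cfg$kmer_region, -1L))
    run_region <- c(-cfg$run_region, -1L)
    w_r <- windows[windows$site_id %in% sets$R_preferred]
    w_k <- windows[windows$site_id %in% sets$K_preferred]
    data.table::setattr(w_r, "up", cfg$window_up)
    data.table::setattr(w_r, "down", cfg$window_down)
    data.table::setattr(w_k, "up", cfg$window_up)
    data.table::setattr(w_k, "down", cfg$window_down)
    if (nrow(w_r) > 0L && nrow(w_k) > 0L) {
      rf_r <- polyA_run_features(w_r, run_region)
      rf_k <- polyA_run_features(w_k, run_region)
      run_cmp <- lapply(c("A", "AA", "AAA", "AAAA"), function(f)
        compare_run_frequencies(rf_r, rf_k, f))
    }
    motif <- list(prof_cry = prof_cry, prof_can = prof_can,
                  prof_ctl = prof_ctl, fisher_cry = fisher_cry,
                  fisher_can = fisher_can, kmers = kmers)
  }

  expression <- NULL
  if (!is.null(cfg$counts)) {
    logf("stage expression")
    counts <- read_count_matrix(cfg$counts)
    counts <- filter_low_depth_genes(counts, min_mean = 1)
    gl <- stats::setNames(ann$gene_lengths$length, ann$gene_lengths$gene_id)
    norm <- quantile_normalize(log2_transform(counts_to_rpkm(counts, gl)))
    de <- differential_expression(norm, groups_mw, "MUT", cfg$group_wt)
    pca_expr <- pca_samples(norm)
    complete <- psi$psi[stats::complete.cases(psi$psi), , drop = FALSE]
    pca_psi <- if (nrow(complete) > 1L) pca_samples(complete) else NULL
    hc_psi <- if (nrow(complete) > 1L) {
      hierarchical_cluster(zscore_rows(complete))
    } else NULL
    expression <- list(norm = norm, de = de, pca_expr = pca_expr,
                       pca_psi = pca_psi, hc_psi = hc_psi)
  }

  logf("stage report: writing outputs")
  out <- file.path(cfg$out_dir)
  write_events(events, res_mut_wt, file.path(out, "events.tsv"),
               file.path(out, "events.bed"))
  data.table::fwrite(res_rk, file.path(out, "results_r_vs_k.tsv"),
                     sep = "\t")
  data.table::fwrite(sig, file.path(out, "significant_events.tsv"),
                     sep = "\t")
  data.table::fwrite(top, file.path(out, "top_events.tsv"), sep = "\t")
  data.table::fwrite(distance_histogram(events),
                     file.path(out, "distance_histogram.tsv"), sep = "\t")
  data.table::fwrite(
    data.table::data.table(
      event_id = c(sets$R_preferred, sets$K_preferred),
      set = rep(c("R_preferred", "K_preferred"),
                c(length(sets$R_preferred), length(sets$K_preferred)))),
    file.path(out, "preferred_sets.tsv"), sep = "\t")
  data.table::fwrite(controls, file.path(out, "control_introns.tsv"),
                     sep = "\t")
  if (!is.null(motif)) {
    data.table::fwrite(motif$fisher_cry,
                       file.path(out, "fisher_track_cryptic.tsv"),
                       sep = "\t")
    data.table::fwrite(motif$fisher_can,
                       file.path(out, "fisher_track_canonical.tsv"),
                       sep = "\t")
    data.table::fwrite(motif$kmers, file.path(out, "kmer_enrichment.tsv"),
                       sep = "\t")
    data.table::fwrite(logo_matrix(motif$prof_cry),
                       file.path(out, "logo_cryptic.tsv"), sep = "\t")
    data.table::fwrite(logo_matrix(motif$prof_ctl),
                       file.path(out, "logo_control.tsv"), sep = "\t")
  }
  if (!is.null(run_cmp)) {
    data.table::fwrite(
      data.table::rbindlist(lapply(run_cmp, data.table::as.data.table)),
      file.path(out, "run_feature_tests.tsv"), sep = "\t")
  }
  if (!is.null(expression)) {
    data.table::fwrite(
      data.table::data.table(gene_id = rownames(expression$norm),
                             expression$norm),
      file.path(out, "normalized_expression.tsv"), sep = "\t")
    data.table::fwrite(expression$de,
                       file.path(out, "differential_expression.tsv"),
                       sep = "\t")
    if (!is.null(expression$pca_psi)) {
      sc <- expression$pca_psi$scores
      data.table::fwrite(
        data.table::data.table(sample = rownames(sc), sc),
        file.path(out, "pca_psi_scores.tsv"), sep = "\t")
    }
  }

  report <- build_report(events, sig, top, sets, controls, run_cmp,
                         expression, cfg)
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(
    inputs = list(junction_files = as.list(cfg$junction_files),
                  gtf = cfg$gtf, fasta = cfg$fasta, counts = cfg$counts,
                  groups = cfg$groups_file),
    config = unclass(cfg)[!(names(cfg) %in%
                              c("junction_files", "gtf", "fasta", "counts",
                                "groups_file", "out_dir"))],
    rows = list(junctions = nrow(jt$junctions), events = nrow(events),
                significant = nrow(sig), controls = nrow(controls)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  logf("done")
  invisible(list(jt = jt, ann = ann, genome = genome, groups = groups,
                 events = events, psi = psi, res_mut_wt = res_mut_wt,
                 res_rk = res_rk, sig = sig, top = top, sets = sets,
                 controls = controls, windows = windows, motif = motif,
                 run_cmp = run_cmp, expression = expression,
                 report = report))
}

build_report <- function(events, sig, top, sets, controls, run_cmp,
                         expression, cfg) {
  ev <- data.table::as.data.table(events)
  side_dir <- if (nrow(ev) > 0L) {
    counts <- ev[, .N, by = .(side, direction)]
    stats::setNames(as.list(counts$N),
                    paste(counts$side, counts$direction, sep = "_"))
  } else list()
  dh <- distance_histogram(events)
  list(
    n_events = nrow(ev),
    events_by_side_direction = side_dir,
    n_significant = nrow(sig),
    distance_histogram = list(distance = dh$distance, n = dh$n),
    top_events = if (nrow(top) > 0L) {
      list(event_id = top$event_id, dpsi = top$dpsi, p = top$p)
    } else list(),
    set_sizes = list(R_preferred = length(sets$R_preferred),
                     K_preferred = length(sets$K_preferred),
                     controls = nrow(controls)),
    run_feature_tests = if (!is.null(run_cmp)) {
      lapply(run_cmp, function(x) x[c("feature", "statistic", "p",
                                      "mean_a", "mean_b")])
    } else list(),
    de_summary = if (!is.null(expression)) {
      list(n_genes = nrow(expression$de),
           n_significant = sum(expression$de$significant))
    } else list(),
    pca_variance_fractions = if (!is.null(expression) &&
                                 !is.null(expression$pca_psi)) {
      expression$pca_psi$var_frac[seq_len(min(
        5L, length(expression$pca_psi$var_frac)))]
    } else numeric(0))
}
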