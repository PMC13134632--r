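test_that("configuration validation names the offending field", {
  expect_error(simulation_config(n_genes = 10), "n_genes")
  expect_error(simulation_config(intron_length_range = c(60L, 80L)),
               "intron_length_range")
  expect_error(simulation_config(nmd_efficiency = 1.2), "nmd_efficiency")
  expect_error(simulation_config(
    psi = list(R_preferred = c(WT = 2, K700E = 0.1, R625H = 0.1),
               K_preferred = c(WT = 0.1, K700E = 0.1, R625H = 0.1),
               shared = c(WT = 0.1, K700E = 0.1, R625H = 0.1),
               null = c(WT = 0.1, K700E = 0.1, R625H = 0.1))),
    "\\[0, 1\\]")
})

test_that("simulated genomes are deterministic and annotation-consistent", {
  cfg <- small_sim_config(seed = 7)
  s1 <- simulate_genome(cfg)
  s2 <- simulate_genome(cfg)
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(s1$truth$events, s2$truth$events)
  s3 <- simulate_genome(small_sim_config(seed = 8))
  expect_false(identical(as.character(s1$genome),
                         as.character(s3$genome)))
  # every intron boundary fits its chromosome
  lens <- setNames(Biostrings::width(s1$genome), names(s1$genome))
  expect_true(all(s1$truth$introns$intron_last <
                    lens[s1$truth$introns$chrom]))
})

test_that("planted cryptic acceptors have the promised local structure", {
  cfg <- small_sim_config(seed = 9)
  sim <- simulate_genome(cfg)
  ev <- sim$truth$events
  expect_true(all(ev$distance >= 10 & ev$distance <= 24))
  # cryptic acceptor strictly inside the intron, upstream of the canonical
  expect_true(all(ev$cryptic_pos > ev$intron_first &
                    ev$cryptic_pos < ev$intron_last))
  for (i in seq_len(nrow(ev))) {
    up <- if (ev$strand[i] == "+") {
      extract_sequence(sim$genome, ev$chrom[i], ev$cryptic_pos[i] - 11L,
                       ev$cryptic_pos[i], "+")
    } else {
      extract_sequence(sim$genome, ev$chrom[i], ev$cryptic_pos[i],
                       ev$cryptic_pos[i] + 11L, "-")
    }
    # window ends in AG ...
    expect_equal(substr(up, 11, 12), "AG")
    # ... and no spurious AG within the 8 nt upstream of it
    expect_false(grepl("AG", substr(up, 1, 10), fixed = TRUE))
  }
  # no AG between cryptic and canonical acceptors (transcript orientation)
  for (i in seq_len(min(nrow(ev), 50L))) {
    between <- if (ev$strand[i] == "+") {
      extract_sequence(sim$genome, ev$chrom[i], ev$cryptic_pos[i] + 1L,
                       ev$acceptor_pos[i], "+")
    } else {
      extract_sequence(sim$genome, ev$chrom[i], ev$acceptor_pos[i],
                       ev$cryptic_pos[i] - 1L, "-")
    }
    inner <- substr(between, 1, nchar(between) - 2L)
    expect_false(grepl("AG", inner, fixed = TRUE))
    expect_equal(substr(between, nchar(between) - 1L, nchar(between)),
                 "AG")
  }
})

test_that("canonical acceptors carry a pyrimidine-biased tract", {
  cfg <- small_sim_config(seed = 10)
  sim <- simulate_genome(cfg)
  ctrl <- sim$truth$introns[class == "none"][1:30]
  sites <- data.frame(site_id = paste0("c", 1:30), class = "control",
                      chrom = ctrl$chrom, strand = ctrl$strand,
                      acceptor_pos = ctrl$acceptor_pos)
  w <- extract_windows(sites, sim$genome)
  prof <- composition_profile(w)
  # T+C fraction over the 20 nt preceding the AG is strongly elevated
  py <- prof$freq["T", as.character(-22:-3)] +
    prof$freq["C", as.character(-22:-3)]
  expect_gt(mean(py), 0.8)
})

test_that("junction simulation respects PSI and the annotated flag", {
  cfg <- small_sim_config(seed = 11)
  sim <- simulate_genome(cfg)
  jt <- simulate_junction_tables(sim$truth, cfg)
  expect_setequal(unique(jt$junctions$annotated_src), c(0L, 1L))
  # annotated flag only on canonical junctions
  canon <- jt$junctions[annotated_src == 1L]
  key <- paste(canon$chrom, canon$intron_first, canon$intron_last)
  truth_key <- paste(sim$truth$introns$chrom,
                     sim$truth$introns$intron_first,
                     sim$truth$introns$intron_last)
  expect_true(all(key %in% truth_key))
  # determinism
  jt2 <- simulate_junction_tables(sim$truth, cfg)
  expect_identical(as.data.frame(jt$junctions),
                   as.data.frame(jt2$junctions))
})

test_that("degenerate PSI values produce the expected junction rows", {
  cfg <- small_sim_config(
    seed = 12,
    psi = list(R_preferred = c(WT = 0, K700E = 0, R625H = 1),
               K_preferred = c(WT = 0, K700E = 0, R625H = 0),
               shared = c(WT = 0, K700E = 0, R625H = 0),
               null = c(WT = 0, K700E = 0, R625H = 0)))
  sim <- simulate_genome(cfg)
  jt <- simulate_junction_tables(sim$truth, cfg)
  groups <- simulation_groups(cfg)
  r_samples <- names(groups)[groups == "R625H"]
  other_samples <- setdiff(names(groups), r_samples)
  ev_r <- sim$truth$events[class == "R_preferred"]
  cryj <- jt$junctions[annotated_src == 0L]
  # PSI = 0 everywhere else: every cryptic junction belongs to an
  # R_preferred intron
  cry_key <- paste(cryj$chrom, data.table::fifelse(cryj$strand == "+",
                                                   cryj$intron_last,
                                                   cryj$intron_first))
  expect_true(all(cry_key %in% paste(ev_r$chrom, ev_r$cryptic_pos)))
  # and its counts are zero outside the R group
  expect_true(all(as.matrix(cryj[, other_samples, with = FALSE]) == 0))
  # PSI = 1: canonical counts are zero in the R group for those introns
  canj <- jt$junctions[annotated_src == 1L]
  can_r <- canj[paste(chrom, intron_first, intron_last) %in%
                  paste(ev_r$chrom, ev_r$intron_first, ev_r$intron_last)]
  expect_true(all(as.matrix(can_r[, r_samples, with = FALSE]) == 0))
})

test_that("binomial junction sampling is centred on the planted PSI", {
  cfg <- small_sim_config(seed = 13)
  sim <- simulate_genome(cfg)
  jt <- simulate_junction_tables(sim$truth, cfg)
  psi_mat <- compute_psi(
    pair_with_canonical(classify_junctions(filter_low_coverage(jt, 50),
                                           sim$annotation)),
    filter_low_coverage(jt, 50))
  groups <- simulation_groups(cfg)
  r_cols <- names(groups)[groups == "R625H"]
  ev <- sim$truth$events
  r_events <- psi_mat$events$event_id[
    match(paste(ev[class == "R_preferred"]$chrom,
                ev[class == "R_preferred"]$cryptic_pos),
          paste(psi_mat$events$chrom, psi_mat$events$cryptic_pos))]
  r_events <- r_events[!is.na(r_events)]
  obs <- mean(psi_mat$psi[r_events, r_cols], na.rm = TRUE)
  n_cells <- length(r_events) * length(r_cols)
  se <- sqrt(0.4 * 0.6 / (100 * n_cells)) * 3 + 0.01
  expect_lt(abs(obs - 0.4), max(se, 0.02))
})

test_that("NMD coupling depresses expression of event genes", {
  cfg <- small_sim_config(seed = 14)
  sim <- simulate_genome(cfg)
  counts <- simulate_expression(sim$truth, cfg)
  groups <- simulation_groups(cfg)
  genes <- sim$truth$genes
  shared <- genes[class == "shared"]
  wt_cols <- names(groups)[groups == "WT"]
  mut_cols <- names(groups)[groups != "WT"]
  # expected multiplier 1 - 0.8 * 0.3 = 0.76 in mutants
  ratio <- rowMeans(counts[shared$gene_id, mut_cols, drop = FALSE]) /
    rowMeans(counts[shared$gene_id, wt_cols, drop = FALSE])
  expect_lt(median(ratio), 0.9)
  none <- genes[class == "none"]$gene_id[1:20]
  ratio0 <- rowMeans(counts[none, mut_cols, drop = FALSE]) /
    rowMeans(counts[none, wt_cols, drop = FALSE])
  expect_lt(abs(median(ratio0) - 1), 0.15)
  # zero NMD efficiency leaves group means at baseline
  cfg0 <- small_sim_config(seed = 14, nmd_efficiency = 0)
  counts0 <- simulate_expression(sim$truth, cfg0)
  ratio_off <- rowMeans(counts0[shared$gene_id, mut_cols, drop = FALSE]) /
    rowMeans(counts0[shared$gene_id, wt_cols, drop = FALSE])
  expect_lt(abs(median(ratio_off) - 1), 0.15)
})

test_that("written datasets are byte-identical under one seed", {
  cfg <- small_sim_config(seed = 15)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_dataset(cfg, dir = d1)
  simulate_dataset(cfg, dir = d2)
  files <- list.files(d1, recursive = TRUE)
  expect_gt(length(files), 5)
  for (f in files) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
})
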