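# Synthetic genomes, annotations, junction tables and count matrices with
# the statistical structure the analysis assumes, plus a ground-truth
# registry, so every stage is testable without any external download.
#
# Each gene: 3 exons / 2 introns on a random strand. Every canonical
# acceptor carries a >= 20 nt T/C-biased polypyrimidine tract and a
# branch-point adenosine upstream of it. Event genes additionally carry a
# cryptic AG planted 10-24 nt upstream (intron-ward) of the canonical AG
# in the last intron, with class-dependent poly-A run density within 50 nt
# upstream of the cryptic AG, no G at all between the cryptic and
# canonical AGs (a weak pyrimidine stretch), and no spurious AG within
# 8 nt upstream of the cryptic AG.

#' Simulation configuration
#'
#' Defaults are the study conditions every property test runs under:
#' a 1000-gene universe carrying 200 differential cryptic events
#' (70 R-preferred, 70 K-preferred, 60 shared), so that NMD-affected genes
#' remain a minority of the transcriptome as they are in real cohorts;
#' three groups (WT / K700E / R625H) of 5 samples, junction
#' depth ~ NegBin(mean 100, size 8), planted distances uniform on 10..24
#' nt, group PSI per class as listed, poly-A run density at 3x background
#' for R-preferred and 1.5x for K-preferred and shared events, and
#' NMD-coupled expression with efficiency 0.8.
#'
#' @param seed Integer seed; the same seed reproduces every output
#'   byte-for-byte.
#' @param n_genes Total genes (>= sum of event counts).
#' @param n_events Named integer vector with entries `R_preferred`,
#'   `K_preferred`, `shared`, `null`.
#' @param groups Named integer vector: group label -> samples per group.
#' @param psi List of per-class group PSI vectors.
#' @param distance_range Planted cryptic-to-canonical distances (nt).
#' @param depth_mean,depth_size Negative-binomial junction depth model.
#' @param polyA_multiplier Per-class A-run density multiplier relative to
#'   background within 50 nt upstream of the cryptic AG.
#' @param exon_length_range,intron_length_range,genes_per_chrom Geometry.
#' @param py_tract_length Canonical polypyrimidine tract length (nt).
#' @param background_base_probs Background base composition (A/C/G/T).
#' @param expr_baseline_meanlog,expr_baseline_sdlog Log-normal baseline
#'   expression model.
#' @param expr_size Negative-binomial size for expression counts.
#' @param nmd_efficiency Fraction of cryptic transcripts degraded (the
#'   group mean multiplier is `1 - nmd_efficiency * PSI`).
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(
    seed = 1L,
    n_genes = 1000L,
    n_events = c(R_preferred = 70L, K_preferred = 70L, shared = 60L,
                 null = 0L),
    groups = c(WT = 5L, K700E = 5L, R625H = 5L),
    psi = list(
      R_preferred = c(WT = 0.02, K700E = 0.15, R625H = 0.40),
      K_preferred = c(WT = 0.02, K700E = 0.40, R625H = 0.15),
      shared      = c(WT = 0.02, K700E = 0.30, R625H = 0.30),
      null        = c(WT = 0.02, K700E = 0.02, R625H = 0.02)),
    distance_range = c(10L, 24L),
    depth_mean = 100,
    depth_size = 8,
    polyA_multiplier = c(R_preferred = 3, K_preferred = 1.5, shared = 1.5,
                         null = 1),
    exon_length_range = c(100L, 200L),
    intron_length_range = c(200L, 350L),
    genes_per_chrom = 50L,
    py_tract_length = 25L,
    background_base_probs = c(A = 0.27, C = 0.20, G = 0.20, T = 0.33),
    expr_baseline_meanlog = log(300),
    expr_baseline_sdlog = 0.8,
    expr_size = 20,
    nmd_efficiency = 0.8) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_events = n_events, groups = groups, psi = psi,
              distance_range = as.integer(distance_range),
              depth_mean = depth_mean, depth_size = depth_size,
              polyA_multiplier = polyA_multiplier,
              exon_length_range = as.integer(exon_length_range),
              intron_length_range = as.integer(intron_length_range),
              genes_per_chrom = as.integer(genes_per_chrom),
              py_tract_length = as.integer(py_tract_length),
              background_base_probs = background_base_probs,
              expr_baseline_meanlog = expr_baseline_meanlog,
              expr_baseline_sdlog = expr_baseline_sdlog,
              expr_size = expr_size, nmd_efficiency = nmd_efficiency)
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  classes <- c("R_preferred", "K_preferred", "shared", "null")
  if (!all(classes %in% names(cfg$n_events))) {
    stop("n_events must name R_preferred, K_preferred, shared, null")
  }
  if (sum(cfg$n_events) > cfg$n_genes) {
    stop("n_genes is smaller than the number of planted events (n_events)")
  }
  if (!all(names(cfg$groups) %in% names(cfg$psi[[1]]))) {
    stop("psi must provide a value for every group")
  }
  for (cl in classes) {
    if (any(cfg$psi[[cl]] < 0 | cfg$psi[[cl]] > 1)) {
      stop("psi values must lie in [0, 1]")
    }
  }
  if (cfg$nmd_efficiency < 0 || cfg$nmd_efficiency > 1) {
    stop("nmd_efficiency must lie in [0, 1]")
  }
  if (cfg$distance_range[1] < 3L) stop("distance_range: minimum below 3")
  # the cryptic layout (distance + 50 nt planting region + donor margin)
  # must fit inside the shortest intron
  need <- cfg$distance_range[2] + 52L + 10L
  if (cfg$intron_length_range[1] < need) {
    stop(sprintf("intron_length_range: minimum %d too short for the cryptic layout (need >= %d)",
                 cfg$intron_length_range[1], need))
  }
  invisible(cfg)
}

.SIM_BASES <- c("A", "C", "G", "T")

sample_bases <- function(n, probs) {
  sample(.SIM_BASES, n, replace = TRUE, prob = probs)
}

# Insert extra maximal A-runs (length 2-4) into s[lo..hi] so that the
# run density is `mult` times the background rate expected from per-base
# A probability pA. mult = 1 inserts nothing.
plant_a_runs <- function(s, lo, hi, mult, pA) {
  n <- hi - lo + 1L
  base_rate <- n * pA^2 * (1 - pA)   # expected background runs of len >= 2
  lambda <- base_rate * max(mult - 1, 0)
  k <- stats::rpois(1L, lambda)
  for (j in seq_len(k)) {
    len <- sample(2:4, 1L, prob = c(0.45, 0.35, 0.2))
    # one guard base on each side keeps the inserted run maximal at its
    # intended length instead of merging with neighbouring adenines
    start <- lo + sample.int(n - len - 1L, 1L)
    s[start:(start + len - 1L)] <- "A"
    for (fl in c(start - 1L, start + len)) {
      if (s[fl] == "A") s[fl] <- sample(c("C", "T"), 1L)
    }
  }
  s
}

# Remove any AG dinucleotide whose A lies within `margin` nt upstream of
# the cryptic AG (positions cg-1, cg), to keep the planted acceptor
# unambiguous.
scrub_upstream_ag <- function(s, cg, margin = 8L) {
  for (i in seq.int(max(1L, cg - margin - 3L), cg - 3L)) {
    if (s[i] == "A" && s[i + 1L] == "G") s[i + 1L] <- "C"
  }
  s
}

# Build one intron in transcript orientation. `class` is "none" or an
# event class; `d` is the planted cryptic distance (ignored for "none").
make_intron <- function(L, class, d, cfg) {
  bg <- cfg$background_base_probs
  s <- sample_bases(L, bg)
  s[1:2] <- c("G", "T")                      # donor dinucleotide
  s[L - 1L] <- "A"; s[L] <- "G"              # canonical acceptor AG
  py_len <- cfg$py_tract_length
  py_lo <- L - 1L - py_len
  s[py_lo:(L - 2L)] <- sample_bases(py_len,
                                    c(A = 0.05, C = 0.35, G = 0.05, T = 0.55))
  s[py_lo - sample(3:8, 1L)] <- "A"          # branch-point adenosine
  if (class != "none") {
    cg <- L - d                              # cryptic boundary base (the G)
    s[cg - 1L] <- "A"; s[cg] <- "G"
    if (d > 2L) {
      # weak pyrimidine stretch, no G: no AG between cryptic and canonical
      s[(cg + 1L):(L - 2L)] <- sample(c("T", "C", "A"), d - 2L,
                                      replace = TRUE,
                                      prob = c(0.45, 0.3, 0.25))
    }
    reg_lo <- cg - 49L                       # region -50..-3 of the cryptic AG
    reg_hi <- cg - 2L
    s[reg_lo:reg_hi] <- sample_bases(reg_hi - reg_lo + 1L, bg)
    s <- plant_a_runs(s, reg_lo, reg_hi, cfg$polyA_multiplier[[class]],
                      bg[["A"]])
    s <- scrub_upstream_ag(s, cg)
  }
  s
}

#' Simulate a genome, annotation and ground-truth event registry
#'
#' @param config A [simulation_config()].
#' @return List with `genome` ([Biostrings::DNAStringSet]), `annotation`
#'   (`genome_annotation`), `exons` (the exon table behind the
#'   annotation), and `truth`: a list of data.tables `events` (planted
#'   cryptic acceptors with genomic coordinates, distances, class and
#'   per-group PSI), `introns` (every intron, event or not) and `genes`
#'   (class and baseline expression).
#' @export
simulate_genome <- function(config) {
  cfg <- validate_simulation_config(config)
  with_local_seed(cfg$seed, simulate_genome_impl(cfg))
}

simulate_genome_impl <- function(cfg) {
  n_genes <- cfg$n_genes
  classes <- rep("none", n_genes)
  ev_classes <- rep(names(cfg$n_events), times = cfg$n_events)
  classes[sample.int(n_genes, length(ev_classes))] <- sample(ev_classes)
  strands <- sample(c("+", "-"), n_genes, replace = TRUE)
  distances <- sample(seq.int(cfg$distance_range[1], cfg$distance_range[2]),
                      n_genes, replace = TRUE)
  baselines <- pmax(10, round(stats::rlnorm(n_genes,
                                            cfg$expr_baseline_meanlog,
                                            cfg$expr_baseline_sdlog)))
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))

  chrom_seqs <- list()
  chrom_parts <- list()
  chrom_offset <- 0L
  chrom_idx <- 1L
  spacer <- 100L

  # preallocated accumulators: 3 exons and 2 introns per gene
  ex_chrom <- character(3L * n_genes); ex_start <- integer(3L * n_genes)
  ex_end <- integer(3L * n_genes); ex_strand <- character(3L * n_genes)
  ex_gene <- character(3L * n_genes)
  in_chrom <- character(2L * n_genes); in_strand <- character(2L * n_genes)
  in_first <- integer(2L * n_genes); in_last <- integer(2L * n_genes)
  in_gene <- character(2L * n_genes); in_class <- character(2L * n_genes)
  in_cryptic <- rep(NA_integer_, 2L * n_genes)
  in_dist <- rep(NA_integer_, 2L * n_genes)

  for (g in seq_len(n_genes)) {
    class <- classes[g]
    d <- distances[g]
    ex_len <- sample(seq.int(cfg$exon_length_range[1],
                             cfg$exon_length_range[2]), 3L, replace = TRUE)
    in_len <- sample(seq.int(cfg$intron_length_range[1],
                             cfg$intron_length_range[2]), 2L, replace = TRUE)
    gene_seq <- c(sample_bases(ex_len[1], cfg$background_base_probs),
                  make_intron(in_len[1], "none", 0L, cfg),
                  sample_bases(ex_len[2], cfg$background_base_probs),
                  make_intron(in_len[2], class, d, cfg),
                  sample_bases(ex_len[3], cfg$background_base_probs))
    glen <- length(gene_seq)

    # transcript-coordinate intervals
    t_ex <- rbind(c(1L, ex_len[1]),
                  c(ex_len[1] + in_len[1] + 1L,
                    ex_len[1] + in_len[1] + ex_len[2]),
                  c(ex_len[1] + in_len[1] + ex_len[2] + in_len[2] + 1L, glen))
    t_in <- rbind(c(ex_len[1] + 1L, ex_len[1] + in_len[1]),
                  c(t_ex[2, 2] + 1L, t_ex[3, 1] - 1L))

    strand <- strands[g]
    offset <- chrom_offset + spacer
    chrom <- sprintf("chr%d", chrom_idx)
    if (strand == "+") {
      fwd <- gene_seq
      g_of <- function(t) offset + t
    } else {
      fwd <- rev(chartr("ACGT", "TGCA", gene_seq))
      g_of <- function(t) offset + glen - t + 1L
    }
    chrom_parts[[length(chrom_parts) + 1L]] <-
      c(sample_bases(spacer, cfg$background_base_probs), fwd)

    ei <- 3L * (g - 1L)
    for (k in 1:3) {
      iv <- sort(g_of(c(t_ex[k, 1], t_ex[k, 2])))
      ex_start[ei + k] <- iv[1]; ex_end[ei + k] <- iv[2]
    }
    ex_chrom[ei + 1:3] <- chrom; ex_strand[ei + 1:3] <- strand
    ex_gene[ei + 1:3] <- gene_ids[g]

    ii <- 2L * (g - 1L)
    for (k in 1:2) {
      iv <- sort(g_of(c(t_in[k, 1], t_in[k, 2])))
      in_first[ii + k] <- iv[1]; in_last[ii + k] <- iv[2]
      cls <- if (k == 2L) class else "none"
      in_class[ii + k] <- cls
      if (cls != "none") {
        acceptor <- if (strand == "+") iv[2] else iv[1]
        in_cryptic[ii + k] <- if (strand == "+") acceptor - d else
          acceptor + d
        in_dist[ii + k] <- d
      }
    }
    in_chrom[ii + 1:2] <- chrom; in_strand[ii + 1:2] <- strand
    in_gene[ii + 1:2] <- gene_ids[g]

    chrom_offset <- chrom_offset + spacer + glen
    if (g %% cfg$genes_per_chrom == 0L || g == n_genes) {
      chrom_parts[[length(chrom_parts) + 1L]] <-
        sample_bases(spacer, cfg$background_base_probs)
      chrom_seqs[[chrom]] <- paste(unlist(chrom_parts), collapse = "")
      chrom_parts <- list()
      chrom_offset <- 0L
      chrom_idx <- chrom_idx + 1L
    }
  }

  genome <- Biostrings::DNAStringSet(unlist(chrom_seqs))
  exons <- data.table::data.table(
    chrom = ex_chrom, start = ex_start, end = ex_end, strand = ex_strand,
    transcript_id = paste0(ex_gene, ".t1"), gene_id = ex_gene)
  introns <- data.table::data.table(
    gene_id = in_gene, chrom = in_chrom, strand = in_strand,
    intron_first = in_first, intron_last = in_last,
    donor_pos = data.table::fifelse(in_strand == "+", in_first, in_last),
    acceptor_pos = data.table::fifelse(in_strand == "+", in_last, in_first),
    cryptic_pos = in_cryptic, distance = in_dist, class = in_class)
  psi_cols <- do.call(rbind, lapply(introns$class, function(cl) {
    if (cl == "none") {
      stats::setNames(rep(0, length(cfg$groups)), names(cfg$groups))
    } else cfg$psi[[cl]][names(cfg$groups)]
  }))
  colnames(psi_cols) <- paste0("psi_", names(cfg$groups))
  introns <- cbind(introns, data.table::as.data.table(psi_cols))
  events <- introns[class != "none"]
  genes <- data.table::data.table(
    gene_id = gene_ids,
    class = classes, baseline = baselines)
  genes <- merge(genes,
                 events[, c("gene_id", colnames(psi_cols)), with = FALSE],
                 by = "gene_id", all.x = TRUE)
  for (pc in colnames(psi_cols)) {
    genes[is.na(get(pc)), (pc) := 0]
  }
  list(genome = genome,
       annotation = build_annotation(exons),
       exons = exons,
       truth = list(events = events, introns = introns, genes = genes))
}

#' Group assignment implied by a simulation configuration
#'
#' @param config A [simulation_config()].
#' @return Named character vector: sample id -> group label.
#' @export
simulation_groups <- function(config) {
  g <- rep(names(config$groups), times = config$groups)
  ids <- unlist(lapply(names(config$groups), function(x)
    paste0(x, "_", seq_len(config$groups[[x]]))))
  stats::setNames(g, ids)
}

#' Simulate per-sample splice-junction evidence
#'
#' Per intron and sample, total junction depth ~ NegBin(depth_mean,
#' depth_size); cryptic reads ~ Binomial(depth, group PSI); canonical
#' reads are the remainder. The canonical junction carries the annotated
#' flag, the cryptic junction does not; strand codes follow the gene
#' strand. Junctions with zero reads in every sample are not emitted,
#' mirroring aligner output.
#'
#' @param truth The `truth` element of [simulate_genome()] output (its
#'   `introns` table is used).
#' @param config The same [simulation_config()].
#' @return A `junction_table`.
#' @export
simulate_junction_tables <- function(truth, config) {
  cfg <- config
  with_local_seed(cfg$seed + 1L, simulate_junctions_impl(truth, cfg))
}

simulate_junctions_impl <- function(truth, cfg) {
  introns <- truth$introns
  groups <- simulation_groups(cfg)
  samples <- names(groups)
  nI <- nrow(introns); nS <- length(samples)
  depth <- matrix(stats::rnbinom(nI * nS, size = cfg$depth_size,
                                 mu = cfg$depth_mean), nI, nS)
  psi <- as.matrix(introns[, paste0("psi_", groups), with = FALSE])
  cryptic <- matrix(stats::rbinom(nI * nS, as.vector(depth), as.vector(psi)),
                    nI, nS)
  canonical <- depth - cryptic
  colnames(cryptic) <- colnames(canonical) <- samples

  canon_dt <- data.table::data.table(
    chrom = introns$chrom, intron_first = introns$intron_first,
    intron_last = introns$intron_last, strand = introns$strand,
    annotated_src = 1L)
  canon_dt <- cbind(canon_dt, data.table::as.data.table(canonical))

  has_event <- !is.na(introns$cryptic_pos)
  cry <- introns[has_event]
  cry_dt <- data.table::data.table(
    chrom = cry$chrom,
    intron_first = data.table::fifelse(cry$strand == "+", cry$intron_first,
                                       cry$cryptic_pos),
    intron_last = data.table::fifelse(cry$strand == "+", cry$cryptic_pos,
                                      cry$intron_last),
    strand = cry$strand,
    annotated_src = 0L)
  cry_dt <- cbind(cry_dt, data.table::as.data.table(
    cryptic[has_event, , drop = FALSE]))

  all_dt <- rbind(canon_dt, cry_dt)
  data.table::setcolorder(all_dt, c("chrom", "intron_first", "intron_last",
                                    "strand", samples, "annotated_src"))
  all_dt[, total := rowSums(.SD), .SDcols = samples]
  all_dt <- all_dt[total > 0]
  data.table::setkeyv(all_dt, c("chrom", "intron_first", "intron_last",
                                "strand"))
  new_junction_table(all_dt, samples)
}

#' Simulate an NMD-coupled gene-expression count matrix
#'
#' For a gene carrying a cryptic event, the group mean is
#' `baseline * (1 - nmd_efficiency * PSI_group)`; other genes keep their
#' baseline in every group. Counts are NegBin(size = expr_size) around the
#' mean.
#'
#' @param truth The `truth` element of [simulate_genome()] output.
#' @param config The same [simulation_config()].
#' @return Gene x sample integer matrix.
#' @export
simulate_expression <- function(truth, config) {
  cfg <- config
  with_local_seed(cfg$seed + 2L, {
    genes <- truth$genes
    groups <- simulation_groups(cfg)
    samples <- names(groups)
    psi <- as.matrix(genes[, paste0("psi_", groups), with = FALSE])
    mult <- 1 - cfg$nmd_efficiency * psi
    mu <- genes$baseline * mult
    counts <- matrix(stats::rnbinom(length(mu), size = cfg$expr_size,
                                    mu = as.vector(mu)),
                     nrow(genes), length(samples),
                     dimnames = list(genes$gene_id, samples))
    counts
  })
}

#' Simulate standalone cryptic-acceptor context windows
#'
#' Generates 110-nt windows (-100..+10 around a cryptic AG) with the same
#' poly-A planting machinery used inside [simulate_genome()], for
#' window-level studies of the run statistics without building a genome.
#'
#' @param n Number of windows.
#' @param class Event class controlling the poly-A multiplier
#'   (`"R_preferred"`, `"K_preferred"`, `"shared"`, `"null"`) or
#'   `"control"` for background-only windows.
#' @param config A [simulation_config()] (only the sequence parameters are
#'   used).
#' @param seed Seed for this draw.
#' @return A window table as produced by [extract_windows()].
#' @export
simulate_acceptor_windows <- function(n, class, config = simulation_config(),
                                      seed = 1L) {
  cfg <- config
  bg <- cfg$background_base_probs
  with_local_seed(seed, {
    seqs <- vapply(seq_len(n), function(i) {
      s <- sample_bases(110L, bg)
      s[99:100] <- c("A", "G")             # the acceptor AG at -2,-1
      if (class != "control") {
        s <- plant_a_runs(s, 51L, 98L, cfg$polyA_multiplier[[class]],
                          bg[["A"]])
      }
      s <- scrub_upstream_ag(s, 100L)
      paste(s, collapse = "")
    }, character(1))
    out <- data.table::data.table(
      site_id = sprintf("%s_w%04d", class, seq_len(n)),
      class = class, seq = seqs)
    data.table::setattr(out, "up", 100L)
    data.table::setattr(out, "down", 10L)
    out[]
  })
}

#' Write a simulated dataset to a directory
#'
#' Emits genome FASTA, annotation GTF, per-sample SJ tables, the count
#' matrix, group assignments, the truth registry and the configuration.
#'
#' @param sim Output of [simulate_genome()].
#' @param jt Output of [simulate_junction_tables()].
#' @param counts Output of [simulate_expression()].
#' @param config The [simulation_config()] used.
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_simulation <- function(sim, jt, counts, config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list()
  paths$fasta <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(sim$genome, paths$fasta)
  paths$gtf <- file.path(dir, "annotation.gtf")
  writeLines(sprintf(
    '%s\tsim\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    sim$exons$chrom, sim$exons$start, sim$exons$end, sim$exons$strand,
    sim$exons$gene_id, sim$exons$transcript_id), paths$gtf)
  sj_dir <- file.path(dir, "junctions")
  paths$junctions <- write_junction_table(jt, sj_dir)
  paths$counts <- file.path(dir, "counts.tsv")
  data.table::fwrite(data.table::data.table(gene_id = rownames(counts),
                                            counts),
                     paths$counts, sep = "\t")
  groups <- simulation_groups(config)
  paths$groups <- file.path(dir, "groups.tsv")
  data.table::fwrite(data.table::data.table(sample = names(groups),
                                            group = unname(groups)),
                     paths$groups, sep = "\t")
  paths$truth_events <- file.path(dir, "truth_events.tsv")
  data.table::fwrite(sim$truth$events, paths$truth_events, sep = "\t")
  paths$truth_introns <- file.path(dir, "truth_introns.tsv")
  data.table::fwrite(sim$truth$introns, paths$truth_introns, sep = "\t")
  paths$config <- file.path(dir, "config.yaml")
  cfg <- config
  cfg$psi <- lapply(cfg$psi, as.list)
  yaml::write_yaml(lapply(unclass(cfg), function(x)
    if (is.numeric(x) || is.character(x)) as.list(x) else x), paths$config)
  invisible(paths)
}

#' One-call synthetic dataset
#'
#' Runs [simulate_genome()], [simulate_junction_tables()] and
#' [simulate_expression()] under one configuration and optionally writes
#' everything to disk.
#'
#' @param config A [simulation_config()].
#' @param dir Optional output directory for [write_simulation()].
#' @return List with `sim`, `jt`, `counts`, `groups`, `config` and (when
#'   written) `paths`.
#' @export
simulate_dataset <- function(config = simulation_config(), dir = NULL) {
  sim <- simulate_genome(config)
  jt <- simulate_junction_tables(sim$truth, config)
  counts <- simulate_expression(sim$truth, config)
  out <- list(sim = sim, jt = jt, counts = counts,
              groups = simulation_groups(config), config = config)
  if (!is.null(dir)) {
    out$paths <- write_simulation(sim, jt, counts, config, dir)
  }
  out
}
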