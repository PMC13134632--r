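# Fixture builders shared across test files. Everything is generated in
# code; nothing is read from stored data.

# A compact simulation: same structure as the default conditions, smaller
# universe, for fast unit tests.
small_sim_config <- function(seed = 1L, ...) {
  simulation_config(seed = seed, n_genes = 80L,
                    n_events = c(R_preferred = 12L, K_preferred = 12L,
                                 shared = 8L, null = 0L),
                    genes_per_chrom = 20L, ...)
}

# Build a junction_table directly from per-sample count vectors.
# counts: named list sample -> integer vector (one entry per junction row).
make_jt <- function(chrom, intron_first, intron_last, strand, counts,
                    annotated_src = NULL) {
  dt <- data.table::data.table(chrom = chrom,
                               intron_first = as.integer(intron_first),
                               intron_last = as.integer(intron_last),
                               strand = strand)
  for (s in names(counts)) dt[[s]] <- as.integer(counts[[s]])
  dt$annotated_src <- if (is.null(annotated_src)) 0L else
    as.integer(annotated_src)
  dt$total <- rowSums(as.matrix(dt[, names(counts), with = FALSE]))
  data.table::setkeyv(dt, c("chrom", "intron_first", "intron_last",
                            "strand"))
  cryptic3ss:::new_junction_table(dt, names(counts))
}

# Annotation from a list of transcripts:
#   list(list(chrom=, strand=, exons=rbind(c(start,end), ...)), ...)
make_annotation <- function(transcripts) {
  rows <- lapply(seq_along(transcripts), function(i) {
    tx <- transcripts[[i]]
    data.table::data.table(chrom = tx$chrom,
                           start = tx$exons[, 1], end = tx$exons[, 2],
                           strand = tx$strand,
                           transcript_id = sprintf("tx%03d", i),
                           gene_id = if (!is.null(tx$gene_id)) tx$gene_id
                                     else sprintf("g%03d", i))
  })
  cryptic3ss:::build_annotation(data.table::rbindlist(rows))
}

# Write SJ.out.tab dialect rows; `rows` is a data.frame with chrom,
# intron_first, intron_last, strand_code, motif, annotated, unique_reads,
# multi_reads, overhang.
write_sj <- function(rows, path) {
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  path
}

# A window table in the layout extract_windows() produces.
make_windows <- function(seqs, class = "cryptic", up = 100L, down = 10L) {
  out <- data.table::data.table(
    site_id = sprintf("w%04d", seq_along(seqs)), class = class, seq = seqs)
  data.table::setattr(out, "up", as.integer(up))
  data.table::setattr(out, "down", as.integer(down))
  out
}

# Random small caller instance for fuzzing: annotation site sets plus a
# junction mix of fully annotated introns, one-end perturbations and
# random junctions. Returns the plain pieces both the oracle and the
# package path consume.
random_caller_instance <- function(seed) {
  set.seed(seed)
  n_tx <- sample(3:8, 1)
  chroms <- paste0("c", 1:2)
  txs <- lapply(seq_len(n_tx), function(i) {
    n_ex <- sample(2:4, 1)
    # exon/intron boundaries spaced widely enough to keep sites distinct
    starts <- cumsum(sample(60:200, 2 * n_ex - 1)) + sample(1:50, 1)
    exons <- cbind(starts[seq(1, 2 * n_ex - 1, by = 2)],
                   starts[seq(1, 2 * n_ex - 1, by = 2)] +
                     sample(30:80, n_ex, replace = TRUE))
    # keep exons non-overlapping: shift each exon after its predecessor
    for (k in seq_len(n_ex)[-1]) {
      if (exons[k, 1] <= exons[k - 1, 2]) {
        exons[k, ] <- exons[k, ] + exons[k - 1, 2] - exons[k, 1] + 40
      }
    }
    list(chrom = sample(chroms, 1), strand = sample(c("+", "-"), 1),
         exons = exons)
  })
  ann <- make_annotation(txs)
  introns <- ann$introns
  if (nrow(introns) == 0L) return(NULL)

  mk <- function(chrom, f, l, strand) {
    data.frame(chrom = chrom, intron_first = f, intron_last = l,
               strand = strand, stringsAsFactors = FALSE)
  }
  rows <- list()
  # annotated introns (canonical evidence)
  take <- introns[sample(nrow(introns), min(nrow(introns),
                                            sample(2:6, 1)))]
  for (i in seq_len(nrow(take))) {
    rows[[length(rows) + 1L]] <- mk(take$chrom[i], take$intron_first[i],
                                    take$intron_last[i], take$strand[i])
  }
  # perturbed introns: move one end off-annotation
  n_pert <- sample(1:6, 1)
  for (k in seq_len(n_pert)) {
    i <- sample(nrow(introns), 1)
    delta <- sample(c(-30:-5, 5:30), 1)
    if (runif(1) < 0.5) {
      rows[[length(rows) + 1L]] <- mk(introns$chrom[i],
                                      introns$intron_first[i] + delta,
                                      introns$intron_last[i],
                                      introns$strand[i])
    } else {
      rows[[length(rows) + 1L]] <- mk(introns$chrom[i],
                                      introns$intron_first[i],
                                      introns$intron_last[i] + delta,
                                      introns$strand[i])
    }
  }
  # fully random junctions
  for (k in seq_len(sample(0:4, 1))) {
    f <- sample(100:2000, 1)
    rows[[length(rows) + 1L]] <- mk(sample(chroms, 1), f,
                                    f + sample(50:400, 1),
                                    sample(c("+", "-", "*"), 1))
  }
  junc <- unique(do.call(rbind, rows))
  junc <- junc[junc$intron_first <= junc$intron_last, , drop = FALSE]
  junc$count_s1 <- sample(0:80, nrow(junc), replace = TRUE)
  junc$count_s2 <- sample(0:80, nrow(junc), replace = TRUE)
  list(ann = ann, junc = junc)
}

# Package-path event call on a random instance (shared by unit fuzz and
# the acceptance criterion).
package_call_events <- function(inst, min_total = 50) {
  jt <- make_jt(inst$junc$chrom, inst$junc$intron_first,
                inst$junc$intron_last, inst$junc$strand,
                list(s1 = inst$junc$count_s1, s2 = inst$junc$count_s2))
  jt <- filter_low_coverage(jt, min_total)
  jt <- classify_junctions(jt, inst$ann)
  pair_with_canonical(jt)
}

# Canonical comparable form for event sets from either route.
normalize_events <- function(ev) {
  if (is.null(ev) || nrow(ev) == 0L) return(NULL)
  ev <- as.data.frame(ev)[, c("chrom", "strand", "cryptic_first",
                              "cryptic_last", "canonical_first",
                              "canonical_last", "side", "direction",
                              "distance")]
  ev <- ev[order(ev$chrom, ev$strand, ev$cryptic_first, ev$cryptic_last), ]
  rownames(ev) <- NULL
  ev
}
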