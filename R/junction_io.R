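# Readers/writers for the external formats the pipeline touches and the
# coordinate conventions every other stage relies on.
#
# Conventions fixed here:
#   * splice-junction tables and GTF are 1-based inclusive; intron_first /
#     intron_last are the first and last intronic bases of a junction;
#   * BED export converts to 0-based half-open at the boundary;
#   * on the + strand the acceptor is intron_last, on the - strand it is
#     intron_first (the donor is the opposite end);
#   * strand codes 0/1/2 decode to "*", "+", "-".

.STRAND_DECODE <- c(`0` = "*", `1` = "+", `2` = "-")
.STRAND_ENCODE <- c(`*` = 0L, `+` = 1L, `-` = 2L)

#' Read per-sample splice-junction tables and merge them
#'
#' Reads one 9-column tab-delimited junction file per sample (the STAR
#' `SJ.out.tab` dialect) and merges junctions across samples on
#' (chrom, intron_first, intron_last, strand). Only uniquely-mapped read
#' counts (column 7) are used; the multi-mapped column is ignored. Samples
#' with no row for a junction get count 0.
#'
#' @param paths_by_sample Named character vector: sample id -> file path.
#' @return A `junction_table`: a list with `junctions` (a data.table with
#'   key columns, one count column per sample, `total` across samples and
#'   the source `annotated_src` flag) and `samples` (sample ids in input
#'   order).
#' @export
read_junction_table <- function(paths_by_sample) {
  if (length(paths_by_sample) == 0L) {
    return(new_junction_table(empty_junction_dt(character(0)), character(0)))
  }
  if (is.null(names(paths_by_sample)) || any(names(paths_by_sample) == "")) {
    stop("paths_by_sample must be a named vector (sample id -> path)")
  }
  samples <- names(paths_by_sample)
  if (anyDuplicated(samples)) stop("duplicate sample ids in paths_by_sample")

  per_sample <- lapply(samples, function(s) {
    path <- paths_by_sample[[s]]
    dt <- parse_sj_file(path)
    dt[, sample_id := s]
    dt
  })
  long <- data.table::rbindlist(per_sample)
  if (nrow(long) == 0L) {
    return(new_junction_table(empty_junction_dt(samples), samples))
  }

  wide <- data.table::dcast(
    long, chrom + intron_first + intron_last + strand ~ sample_id,
    value.var = "unique_reads", fill = 0L
  )
  # dcast orders value columns alphabetically; restore input sample order
  data.table::setcolorder(wide, c("chrom", "intron_first", "intron_last",
                                  "strand", samples))
  ann <- long[, .(annotated_src = max(annotated_src)),
              by = .(chrom, intron_first, intron_last, strand)]
  wide <- merge(wide, ann,
                by = c("chrom", "intron_first", "intron_last", "strand"),
                sort = TRUE)
  wide[, total := rowSums(.SD), .SDcols = samples]
  data.table::setkeyv(wide, c("chrom", "intron_first", "intron_last", "strand"))
  new_junction_table(wide, samples)
}

parse_sj_file <- function(path) {
  if (!file.exists(path)) stop("junction file not found: ", path)
  raw <- readLines(path)
  if (length(raw) == 0L) {
    return(data.table::data.table(chrom = character(0),
                                  intron_first = integer(0),
                                  intron_last = integer(0),
                                  strand = character(0),
                                  annotated_src = integer(0),
                                  unique_reads = integer(0)))
  }
  fields <- strsplit(raw, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    bad <- which(nf != 9L)[1L]
    stop(sprintf("malformed junction row in %s at line %d: expected 9 columns, got %d",
                 path, bad, nf[bad]))
  }
  m <- matrix(unlist(fields), ncol = 9L, byrow = TRUE)
  ints <- suppressWarnings(apply(m[, c(2, 3, 4, 6, 7), drop = FALSE], 2L,
                                 as.integer))
  if (!is.matrix(ints)) ints <- matrix(ints, ncol = 5L)
  if (anyNA(ints)) {
    bad <- which(apply(ints, 1L, anyNA))[1L]
    stop(sprintf("malformed junction row in %s at line %d: non-integer field",
                 path, bad))
  }
  dt <- data.table::data.table(
    chrom = m[, 1L],
    intron_first = ints[, 1L],
    intron_last = ints[, 2L],
    strand = unname(.STRAND_DECODE[as.character(ints[, 3L])]),
    annotated_src = ints[, 4L],
    unique_reads = ints[, 5L]
  )
  if (anyNA(dt$strand)) {
    bad <- which(is.na(dt$strand))[1L]
    stop(sprintf("bad strand code in %s at line %d", path, bad))
  }
  if (any(dt$intron_first < 1L) || any(dt$intron_last < dt$intron_first)) {
    bad <- which(dt$intron_first < 1L | dt$intron_last < dt$intron_first)[1L]
    stop(sprintf("bad intron coordinates in %s at line %d", path, bad))
  }
  if (any(dt$unique_reads < 0L)) {
    stop(sprintf("negative read count in %s", path))
  }
  key <- paste(dt$chrom, dt$intron_first, dt$intron_last, dt$strand)
  if (anyDuplicated(key)) {
    bad <- which(duplicated(key))[1L]
    stop(sprintf("duplicate junction in %s at line %d", path, bad))
  }
  dt
}

empty_junction_dt <- function(samples) {
  dt <- data.table::data.table(chrom = character(0),
                               intron_first = integer(0),
                               intron_last = integer(0),
                               strand = character(0))
  for (s in samples) dt[, (s) := integer(0)]
  dt[, annotated_src := integer(0)]
  dt[, total := numeric(0)]
  dt
}

new_junction_table <- function(junctions, samples) {
  structure(list(junctions = junctions, samples = samples),
            class = "junction_table")
}

#' @export
print.junction_table <- function(x, ...) {
  cat(sprintf("junction_table: %d junctions x %d samples\n",
              nrow(x$junctions), length(x$samples)))
  invisible(x)
}

#' Write a junction table back to per-sample 9-column files
#'
#' Inverse of [read_junction_table()]: one file per sample, rows only for
#' junctions with a nonzero count in that sample. Ignored dialect columns
#' (motif, multi-mapped reads, overhang) are written as 0.
#'
#' @param jt A `junction_table`.
#' @param dir Output directory; files are named `<sample>.SJ.out.tab`.
#' @return Named vector of written paths, invisibly.
#' @export
write_junction_table <- function(jt, dir) {
  stopifnot(inherits(jt, "junction_table"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (s in jt$samples) {
    dt <- jt$junctions[jt$junctions[[s]] > 0L]
    out <- data.table::data.table(
      chrom = dt$chrom,
      intron_first = dt$intron_first,
      intron_last = dt$intron_last,
      strand_code = unname(.STRAND_ENCODE[dt$strand]),
      motif = 0L,
      annotated = dt$annotated_src,
      unique_reads = dt[[s]],
      multi_reads = 0L,
      overhang = 0L
    )
    path <- file.path(dir, paste0(s, ".SJ.out.tab"))
    data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
    paths[s] <- path
  }
  invisible(paths)
}

#' Read a gene annotation from GTF
#'
#' Parses exon features (1-based inclusive), derives introns between
#' consecutive exons of each transcript, and the annotated donor and
#' acceptor site sets used for junction classification. On the + strand an
#' intron's donor is its first base and its acceptor its last base; the -
#' strand flips this. Gene length is the length of the union of the gene's
#' exons.
#'
#' @param gtf_path Path to a GTF file with exon features carrying
#'   `transcript_id` (and ideally `gene_id`) attributes.
#' @return A `genome_annotation` object: list with `exons`, `introns`,
#'   `donors`, `acceptors`, `gene_lengths` data.tables.
#' @export
read_annotation <- function(gtf_path) {
  if (!file.exists(gtf_path)) stop("GTF not found: ", gtf_path)
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) stop("no exon features in ", gtf_path)
  gene_id <- if (!is.null(gr$gene_id)) gr$gene_id else gr$transcript_id
  exon_df <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    transcript_id = gr$transcript_id,
    gene_id = gene_id
  )
  build_annotation(exon_df)
}

# Shared builder so the simulator and the GTF reader derive sites the same way.
build_annotation <- function(exon_df) {
  ex <- data.table::as.data.table(exon_df)
  stopifnot(all(c("chrom", "start", "end", "strand", "transcript_id",
                  "gene_id") %in% names(ex)))
  if (any(!ex$strand %in% c("+", "-"))) {
    stop("exon features must be stranded (+ or -)")
  }
  data.table::setorder(ex, transcript_id, start)
  ex[, idx := seq_len(.N), by = transcript_id]
  ov <- ex[, .(bad = .N > 1L && any(start[-1L] <= end[-.N])), by = transcript_id]
  if (any(ov$bad)) {
    stop("overlapping exons within transcript: ",
         paste(ov$transcript_id[ov$bad], collapse = ", "))
  }
  introns <- ex[, if (.N > 1L) .(
    chrom = chrom[1L], strand = strand[1L], gene_id = gene_id[1L],
    intron_first = end[-.N] + 1L, intron_last = start[-1L] - 1L
  ), by = transcript_id]
  if (nrow(introns) > 0L) {
    if (any(introns$intron_last < introns$intron_first)) {
      stop("adjacent or overlapping exons leave no intron between them")
    }
    introns[, `:=`(
      donor_pos = ifelse(strand == "+", intron_first, intron_last),
      acceptor_pos = ifelse(strand == "+", intron_last, intron_first)
    )]
    donors <- unique(introns[, .(chrom, strand, pos = donor_pos)])
    acceptors <- unique(introns[, .(chrom, strand, pos = acceptor_pos)])
    introns <- unique(introns[, .(chrom, strand, intron_first, intron_last,
                                  donor_pos, acceptor_pos, gene_id,
                                  transcript_id)])
  } else {
    introns <- data.table::data.table(
      chrom = character(0), strand = character(0), intron_first = integer(0),
      intron_last = integer(0), donor_pos = integer(0),
      acceptor_pos = integer(0), gene_id = character(0),
      transcript_id = character(0))
    donors <- data.table::data.table(chrom = character(0),
                                     strand = character(0), pos = integer(0))
    acceptors <- data.table::copy(donors)
  }
  red <- IRanges::reduce(S4Vectors::splitAsList(
    IRanges::IRanges(ex$start, ex$end), ex$gene_id))
  gene_lengths <- data.table::data.table(
    gene_id = names(red),
    length = sum(IRanges::width(red)))
  structure(list(exons = ex[, .(chrom, start, end, strand, transcript_id,
                                gene_id)],
                 introns = introns, donors = donors, acceptors = acceptors,
                 gene_lengths = gene_lengths),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %d exons, %d introns, %d genes\n",
              nrow(x$exons), nrow(x$introns), nrow(x$gene_lengths)))
  invisible(x)
}

#' Read a genome FASTA
#'
#' Sequences are uppercased on read; names are truncated at the first
#' whitespace.
#'
#' @param fasta_path Path to an (uncompressed or gzipped) FASTA file.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_genome <- function(fasta_path) {
  if (!file.exists(fasta_path)) stop("FASTA not found: ", fasta_path)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  out <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Extract a genomic subsequence in transcript orientation
#'
#' 1-based inclusive coordinates. `strand = "-"` returns the reverse
#' complement of the forward slice. Out-of-bounds requests are an error,
#' never silently clipped.
#'
#' @param genome A [Biostrings::DNAStringSet] (see [read_genome()]).
#' @param chrom,start,end Chromosome name and 1-based inclusive interval.
#' @param strand `"+"` or `"-"`.
#' @return Character scalar of length `end - start + 1`.
#' @export
extract_sequence <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  if (!strand %in% c("+", "-")) stop("strand must be + or -")
  len <- length(genome[[chrom]])
  if (start < 1L || end > len || start > end) {
    stop(sprintf("interval [%d,%d] out of bounds for %s (length %d)",
                 start, end, chrom, len))
  }
  s <- Biostrings::subseq(genome[[chrom]], start, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Write called events with their test results to TSV and BED6
#'
#' The TSV carries one row per event (coordinates, side, direction,
#' distance, group mean PSI, delta-PSI, p, q). The BED6 file marks each
#' cryptic acceptor base in 0-based half-open coordinates with
#' `score = round(1000 * |delta PSI|)`.
#'
#' @param events Event table from [pair_with_canonical()].
#' @param results Test results from [test_differential_psi()] (joined on
#'   `event_id`); may be `NULL` for annotation-only export.
#' @param tsv_path,bed_path Output paths.
#' @return Invisibly, the joined table that was written.
#' @export
write_events <- function(events, results, tsv_path, bed_path) {
  ev <- data.table::as.data.table(events)
  if (!is.null(results) && nrow(ev) > 0L) {
    ev <- merge(ev, data.table::as.data.table(results), by = "event_id",
                all.x = TRUE, sort = FALSE)
  } else if (!is.null(results)) {
    res <- data.table::as.data.table(results)
    for (cn in setdiff(names(res), "event_id")) ev[, (cn) := numeric(0)]
  }
  data.table::setorder(ev, chrom, cryptic_pos)
  data.table::fwrite(ev, tsv_path, sep = "\t")
  if (nrow(ev) > 0L) {
    score <- if ("dpsi" %in% names(ev)) {
      pmin(1000L, pmax(0L, as.integer(round(1000 * abs(ev$dpsi)))))
    } else rep(0L, nrow(ev))
    score[is.na(score)] <- 0L
    bed <- data.table::data.table(
      chrom = ev$chrom,
      start = ev$cryptic_pos - 1L,   # 0-based half-open at the boundary
      end = ev$cryptic_pos,
      name = ev$event_id,
      score = score,
      strand = ev$strand
    )
    data.table::fwrite(bed, bed_path, sep = "\t", col.names = FALSE)
  } else {
    file.create(bed_path)
  }
  invisible(ev)
}
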