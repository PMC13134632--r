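# Branch-point-context statistics around acceptor AG sites: window
# extraction, per-position composition with Fisher enrichment against
# control introns, consecutive-A run features with paired nonparametric
# group comparison, and six-mer enrichment.
#
# Window layout: 110 nt in transcript orientation, positions -100..-1
# (intronic; -2,-1 are the acceptor AG, so -1 is the acceptor boundary
# base) followed by +1..+10 (exonic).

.BASES <- c("A", "C", "G", "T")

# position label -> string index within a window
pos_to_index <- function(pos, up = 100L) {
  ifelse(pos < 0L, pos + up + 1L, up + pos)
}

#' Extract acceptor-context sequence windows
#'
#' For each site, extracts `up` nt upstream through `down` nt downstream of
#' the acceptor boundary base in transcript orientation: a + strand
#' acceptor at E yields the forward slice `[E-up+1, E+down]`; a - strand
#' acceptor at S yields the reverse complement of `[S-down, S+up-1]`.
#' Windows that would run off the chromosome, and windows containing N, are
#' dropped with a message.
#'
#' @param sites data.frame with `site_id`, `class`, `chrom`, `strand`,
#'   `acceptor_pos` columns.
#' @param genome A [Biostrings::DNAStringSet].
#' @param up,down Window extent (defaults 100 and 10).
#' @return A data.table (`site_id`, `class`, `seq`) with attributes `up`,
#'   `down`.
#' @export
extract_windows <- function(sites, genome, up = 100L, down = 10L) {
  st <- data.table::as.data.table(sites)
  stopifnot(all(c("site_id", "class", "chrom", "strand", "acceptor_pos")
                %in% names(st)))
  n0 <- nrow(st)
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  st <- st[chrom %in% names(genome)]
  st[, `:=`(
    start = data.table::fifelse(strand == "+", acceptor_pos - up + 1L,
                                acceptor_pos - down),
    end = data.table::fifelse(strand == "+", acceptor_pos + down,
                              acceptor_pos + up - 1L))]
  st <- st[start >= 1L & end <= lens[chrom]]
  if (nrow(st) < n0) {
    message(n0 - nrow(st), " window(s) dropped: outside chromosome bounds")
  }
  if (nrow(st) == 0L) {
    out <- data.table::data.table(site_id = character(0),
                                  class = character(0), seq = character(0))
    data.table::setattr(out, "up", as.integer(up))
    data.table::setattr(out, "down", as.integer(down))
    return(out)
  }
  seqs <- vapply(seq_len(nrow(st)), function(i) {
    extract_sequence(genome, st$chrom[i], st$start[i], st$end[i],
                     st$strand[i])
  }, character(1))
  has_n <- grepl("N", seqs, fixed = TRUE)
  if (any(has_n)) {
    message(sum(has_n), " window(s) dropped: contain N")
  }
  out <- data.table::data.table(site_id = st$site_id, class = st$class,
                                seq = seqs)[!has_n]
  data.table::setattr(out, "up", as.integer(up))
  data.table::setattr(out, "down", as.integer(down))
  out[]
}

windows_to_matrix <- function(windows) {
  if (nrow(windows) == 0L) stop("no windows")
  w <- nchar(windows$seq[1L])
  stopifnot(all(nchar(windows$seq) == w))
  matrix(unlist(strsplit(windows$seq, "", fixed = TRUE), use.names = FALSE),
         nrow = nrow(windows), ncol = w, byrow = TRUE)
}

window_positions <- function(windows) {
  up <- attr(windows, "up"); down <- attr(windows, "down")
  if (is.null(up)) { up <- 100L; down <- 10L }
  c(seq.int(-up, -1L), seq.int(1L, down))
}

#' Per-position nucleotide composition of a window set
#'
#' @param windows Output of [extract_windows()].
#' @return A `composition_profile`: list with `counts` and `freq`
#'   (4 x width matrices, rows A/C/G/T, columns labelled by position),
#'   `n` (number of windows) and `positions`.
#' @export
composition_profile <- function(windows) {
  m <- windows_to_matrix(windows)
  pos <- window_positions(windows)
  counts <- vapply(seq_len(ncol(m)), function(j) {
    tab <- table(factor(m[, j], levels = .BASES))
    as.integer(tab)
  }, integer(4))
  dimnames(counts) <- list(.BASES, as.character(pos))
  freq <- sweep(counts, 2L, pmax(colSums(counts), 1L), "/")
  structure(list(counts = counts, freq = freq, n = nrow(m), positions = pos),
            class = "composition_profile")
}

#' Per-position, per-base Fisher enrichment of one profile against another
#'
#' At each position and base b, a two-sided Fisher exact test on the 2x2
#' table \[\[target b, target not-b\], \[control b, control not-b\]\].
#' Positions with zero contributing windows in either profile get missing
#' p. P-values are reported raw (no multiple-testing correction), matching
#' the -log10 p track convention.
#'
#' @param target,control `composition_profile`s over the same layout.
#' @return data.table: `position`, `base`, `target_freq`, `control_freq`,
#'   `p`, `neglog10_p`.
#' @export
fisher_position_enrichment <- function(target, control) {
  stopifnot(inherits(target, "composition_profile"),
            inherits(control, "composition_profile"))
  if (!identical(target$positions, control$positions)) {
    stop("profiles have different position layouts")
  }
  pos <- target$positions
  grid <- data.table::CJ(position = pos, base = .BASES, sorted = FALSE)
  tc <- colSums(target$counts)
  cc <- colSums(control$counts)
  p <- mapply(function(position, base) {
    j <- as.character(position)
    if (tc[j] == 0L || cc[j] == 0L) return(NA_real_)
    tb <- target$counts[base, j]
    cb <- control$counts[base, j]
    stats::fisher.test(matrix(c(tb, tc[j] - tb, cb, cc[j] - cb), nrow = 2L,
                              byrow = TRUE))$p.value
  }, grid$position, grid$base)
  grid[, target_freq := mapply(function(position, base)
    target$freq[base, as.character(position)], position, base)]
  grid[, control_freq := mapply(function(position, base)
    control$freq[base, as.character(position)], position, base)]
  grid[, p := pmin(p, 1)]
  grid[, neglog10_p := -log10(p)]
  grid[]
}

# Maximal A-run class counts for one region string.
# A maximal run of length L contributes to: A (L==1), AA (L==2),
# AAA (L==3), AAAA (L>=4).
count_a_runs <- function(chars) {
  r <- rle(chars == "A")
  lens <- r$lengths[r$values]
  c(A = sum(lens == 1L), AA = sum(lens == 2L), AAA = sum(lens == 3L),
    AAAA = sum(lens >= 4L))
}

#' Consecutive-adenine run features in an upstream region
#'
#' Scans each window's stated region (positions relative to the acceptor
#' boundary base; default -50..-1) for maximal runs of A and counts them by
#' class: `A` = isolated A, `AA`/`AAA` = runs of exactly 2/3, `AAAA` = runs
#' of length >= 4. Also records, per position, an indicator of a run of
#' each class starting there, which is what the paired group comparison
#' uses.
#'
#' @param windows Output of [extract_windows()].
#' @param region Length-2 integer vector of position labels, within
#'   -up..-1.
#' @return A `run_feature_matrix`: list with `features` (windows x 4 count
#'   matrix), `tracks` (list of 4 windows x region indicator matrices),
#'   `means` (per-class mean count per window), `region`, `site_ids`.
#' @export
polyA_run_features <- function(windows, region = c(-50L, -1L)) {
  up <- attr(windows, "up"); if (is.null(up)) up <- 100L
  region <- as.integer(region)
  if (length(region) != 2L || region[1L] > region[2L] ||
      region[1L] < -up || region[2L] > -1L) {
    stop("region must lie within -up..-1")
  }
  m <- windows_to_matrix(windows)
  idx <- pos_to_index(seq.int(region[1L], region[2L]), up)
  sub <- m[, idx, drop = FALSE]
  n <- nrow(sub); w <- ncol(sub)
  feats <- matrix(0L, n, 4L, dimnames = list(windows$site_id,
                                             c("A", "AA", "AAA", "AAAA")))
  tracks <- lapply(1:4, function(i) matrix(0L, n, w))
  names(tracks) <- c("A", "AA", "AAA", "AAAA")
  for (i in seq_len(n)) {
    r <- rle(sub[i, ] == "A")
    if (!any(r$values)) next
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    lens <- r$lengths[r$values]
    starts <- starts[r$values]
    cls <- pmin(lens, 4L)
    feats[i, ] <- tabulate(cls, 4L)
    for (k in seq_along(lens)) {
      tracks[[cls[k]]][i, starts[k]] <- 1L
    }
  }
  pos_labels <- seq.int(region[1L], region[2L])
  for (k in 1:4) colnames(tracks[[k]]) <- as.character(pos_labels)
  structure(list(features = feats, tracks = tracks,
                 means = colMeans(feats), region = region,
                 site_ids = windows$site_id),
            class = "run_feature_matrix")
}

#' Compare A-run frequencies between two groups of windows
#'
#' Wilcoxon signed-rank test (two-sided, continuity-corrected normal
#' approximation above 25 informative pairs, exact below) on
#' position-paired differences between the two groups' mean
#' run-start-frequency tracks for one run class. Zero differences are
#' dropped (standard signed-rank convention); if every difference is zero,
#' p = 1.
#'
#' @param group_a,group_b `run_feature_matrix` objects over the same region.
#' @param feature One of `"A"`, `"AA"`, `"AAA"`, `"AAAA"`.
#' @return List: `feature`, `statistic` (V), `p`, `n_pairs` (informative),
#'   `mean_a`, `mean_b`.
#' @export
compare_run_frequencies <- function(group_a, group_b, feature = "AAAA") {
  stopifnot(inherits(group_a, "run_feature_matrix"),
            inherits(group_b, "run_feature_matrix"),
            feature %in% c("A", "AA", "AAA", "AAAA"))
  if (!identical(group_a$region, group_b$region)) {
    stop("run feature matrices cover different regions")
  }
  fa <- colMeans(group_a$tracks[[feature]])
  fb <- colMeans(group_b$tracks[[feature]])
  d <- fa - fb
  n_inf <- sum(d != 0)
  if (n_inf == 0L) {
    return(list(feature = feature, statistic = 0, p = 1, n_pairs = 0L,
                mean_a = unname(group_a$means[feature]),
                mean_b = unname(group_b$means[feature])))
  }
  ht <- suppressWarnings(stats::wilcox.test(
    fa, fb, paired = TRUE, exact = n_inf <= 25L, correct = TRUE))
  list(feature = feature, statistic = unname(ht$statistic), p = ht$p.value,
       n_pairs = n_inf,
       mean_a = unname(group_a$means[feature]),
       mean_b = unname(group_b$means[feature]))
}

#' Six-mer (k-mer) enrichment in the region upstream of the acceptor AG
#'
#' Counts overlapping k-mers in the stated region of each window set,
#' computes per-k-mer frequencies (count / total k-mers), a two-sided
#' Fisher exact test of target vs control occurrence, and ranks k-mers by
#' target frequency.
#'
#' @param target_windows,control_windows Outputs of [extract_windows()].
#' @param k K-mer length (default 6).
#' @param region Position labels of the scanned region (default -30..-1).
#' @return data.table: `kmer`, counts, frequencies, `p`, `rank`.
#' @export
kmer_enrichment <- function(target_windows, control_windows, k = 6L,
                            region = c(-30L, -1L)) {
  region <- as.integer(region)
  width <- region[2L] - region[1L] + 1L
  if (k > width) stop("k exceeds the region length")
  count_kmers <- function(windows) {
    up <- attr(windows, "up"); if (is.null(up)) up <- 100L
    i1 <- pos_to_index(region[1L], up); i2 <- pos_to_index(region[2L], up)
    regs <- substr(windows$seq, i1, i2)
    starts <- seq_len(width - k + 1L)
    kmers <- unlist(lapply(regs, function(s) substring(s, starts,
                                                       starts + k - 1L)))
    table(kmers)
  }
  tt <- count_kmers(target_windows)
  ct <- count_kmers(control_windows)
  t_total <- sum(tt); c_total <- sum(ct)
  all_k <- sort(union(names(tt), names(ct)))
  dt <- data.table::data.table(
    kmer = all_k,
    target_count = as.integer(tt[all_k]),
    control_count = as.integer(ct[all_k]))
  dt[is.na(target_count), target_count := 0L]
  dt[is.na(control_count), control_count := 0L]
  dt[, `:=`(target_freq = target_count / t_total,
            control_freq = control_count / c_total)]
  dt[, p := mapply(function(a, b) {
    stats::fisher.test(matrix(c(a, t_total - a, b, c_total - b), nrow = 2L,
                              byrow = TRUE))$p.value
  }, target_count, control_count)]
  data.table::setorder(dt, -target_freq, kmer)
  dt[, rank := seq_len(.N)]
  dt[]
}

#' Frequency matrix for sequence-logo rendering
#'
#' Serializable per-position base-frequency table (positions x A/C/G/T),
#' consumable by any logo plotter.
#'
#' @param profile A `composition_profile`.
#' @return data.table with `position` and one column per base.
#' @export
logo_matrix <- function(profile) {
  stopifnot(inherits(profile, "composition_profile"))
  dt <- data.table::data.table(position = profile$positions)
  for (b in .BASES) dt[, (b) := profile$freq[b, ]]
  dt[]
}
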