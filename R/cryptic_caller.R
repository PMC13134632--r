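# Cryptic splice-site identification: coverage filtering, one-end-annotated
# classification, canonical pairing by the minimum-distance rule, 3'/5' and
# upstream/downstream assignment, and per-sample PSI.

#' Filter junctions on summed coverage
#'
#' Drops junctions whose unique-read total across all samples is below
#' `min_total` (default 50). Totals exactly at the threshold are retained.
#'
#' @param jt A `junction_table`.
#' @param min_total Minimum summed coverage (inclusive).
#' @return The filtered `junction_table`.
#' @export
filter_low_coverage <- function(jt, min_total = 50) {
  stopifnot(inherits(jt, "junction_table"))
  if (min_total < 0) stop("min_total must be non-negative")
  new_junction_table(jt$junctions[jt$junctions$total >= min_total],
                     jt$samples)
}

#' Classify junctions by annotation status of their two ends
#'
#' Each stranded junction is labelled by membership of its donor and
#' acceptor boundary bases in the annotation's strand-matched site sets:
#' `both_annotated`, `novel_acceptor` (donor known, acceptor novel - the
#' candidate cryptic 3'ss), `novel_donor` (candidate cryptic 5'ss), or
#' `neither`. Junctions with undefined strand are labelled `unstranded` and
#' excluded from pairing.
#'
#' @param jt A `junction_table` (typically after [filter_low_coverage()]).
#' @param ann A `genome_annotation`.
#' @return The `junction_table` with `donor_pos`, `acceptor_pos`,
#'   `donor_annotated`, `acceptor_annotated` and `class` columns added.
#' @export
classify_junctions <- function(jt, ann) {
  stopifnot(inherits(jt, "junction_table"), inherits(ann, "genome_annotation"))
  dt <- data.table::copy(jt$junctions)
  if (nrow(dt) == 0L) {
    dt[, `:=`(donor_pos = integer(0), acceptor_pos = integer(0),
              donor_annotated = logical(0), acceptor_annotated = logical(0),
              class = character(0))]
    return(new_junction_table(dt, jt$samples))
  }
  dt[, donor_pos := data.table::fifelse(strand == "+", intron_first,
                                        intron_last)]
  dt[, acceptor_pos := data.table::fifelse(strand == "+", intron_last,
                                           intron_first)]
  dkey <- paste(ann$donors$chrom, ann$donors$strand, ann$donors$pos)
  akey <- paste(ann$acceptors$chrom, ann$acceptors$strand, ann$acceptors$pos)
  dt[, donor_annotated := paste(chrom, strand, donor_pos) %chin% dkey]
  dt[, acceptor_annotated := paste(chrom, strand, acceptor_pos) %chin% akey]
  dt[, class := data.table::fcase(
    strand == "*", "unstranded",
    donor_annotated & acceptor_annotated, "both_annotated",
    donor_annotated & !acceptor_annotated, "novel_acceptor",
    !donor_annotated & acceptor_annotated, "novel_donor",
    default = "neither"
  )]
  dt[strand == "*", `:=`(donor_pos = NA_integer_, acceptor_pos = NA_integer_,
                         donor_annotated = NA, acceptor_annotated = NA)]
  new_junction_table(dt, jt$samples)
}

#' Pair one-end-annotated junctions with their canonical junction
#'
#' For each one-end-annotated ("novel") junction, the candidate canonical
#' junctions are the fully annotated junctions in the same table that share
#' the novel junction's annotated end. The distance is the absolute
#' difference between the novel end and the candidate's corresponding
#' canonical end; the candidate at minimum distance is chosen (ties broken
#' toward larger candidate total coverage, then smaller genomic
#' coordinate). Side is `3ss` when the novel end is an acceptor, `5ss` when
#' it is a donor; direction is `upstream` when the novel site lies 5'-ward
#' of the canonical site in transcript orientation.
#'
#' @param jt A classified `junction_table` (see [classify_junctions()]).
#' @return A data.table of cryptic events (one per paired novel junction).
#' @export
pair_with_canonical <- function(jt) {
  stopifnot(inherits(jt, "junction_table"))
  dt <- jt$junctions
  if (!"class" %in% names(dt)) stop("run classify_junctions() first")
  empty <- data.table::data.table(
    event_id = character(0), chrom = character(0), strand = character(0),
    side = character(0), direction = character(0),
    cryptic_pos = integer(0), canonical_pos = integer(0),
    shared_pos = integer(0), distance = integer(0),
    cryptic_first = integer(0), cryptic_last = integer(0),
    canonical_first = integer(0), canonical_last = integer(0))
  novel <- dt[dt$class %in% c("novel_acceptor", "novel_donor")]
  canon <- dt[dt$class == "both_annotated",
              .(chrom, strand, intron_first, intron_last,
                donor_pos, acceptor_pos, total)]
  if (nrow(novel) == 0L || nrow(canon) == 0L) {
    if (nrow(novel) > 0L) {
      message(nrow(novel), " novel junction(s) dropped: no canonical partner")
    }
    return(empty)
  }
  pair_side <- function(side) {
    if (side == "3ss") {
      nv <- novel[novel$class == "novel_acceptor",
                  .(chrom, strand, intron_first, intron_last,
                    shared_pos = donor_pos, novel_pos = acceptor_pos)]
      cd <- canon[, .(chrom, strand, shared_pos = donor_pos,
                      canon_pos = acceptor_pos,
                      canonical_first = intron_first,
                      canonical_last = intron_last, canon_total = total)]
    } else {
      nv <- novel[novel$class == "novel_donor",
                  .(chrom, strand, intron_first, intron_last,
                    shared_pos = acceptor_pos, novel_pos = donor_pos)]
      cd <- canon[, .(chrom, strand, shared_pos = acceptor_pos,
                      canon_pos = donor_pos,
                      canonical_first = intron_first,
                      canonical_last = intron_last, canon_total = total)]
    }
    if (nrow(nv) == 0L) return(NULL)
    cand <- merge(nv, cd, by = c("chrom", "strand", "shared_pos"),
                  allow.cartesian = TRUE)
    if (nrow(cand) == 0L) return(NULL)
    cand[, distance := abs(novel_pos - canon_pos)]
    # min distance; ties -> larger canonical coverage, then smaller coordinate
    data.table::setorder(cand, chrom, strand, intron_first, intron_last,
                         distance, -canon_total, canonical_first,
                         canonical_last)
    best <- cand[, .SD[1L],
                 by = .(chrom, strand, intron_first, intron_last)]
    best[, side := side]
    best
  }
  best <- data.table::rbindlist(
    Filter(Negate(is.null), list(pair_side("3ss"), pair_side("5ss"))))
  n_dropped <- sum(novel$class == "novel_acceptor") +
    sum(novel$class == "novel_donor") - nrow(best)
  if (n_dropped > 0L) {
    message(n_dropped, " novel junction(s) dropped: no canonical partner")
  }
  if (nrow(best) == 0L) return(empty)
  # transcript orientation: 5'-ward means smaller coordinate on +, larger on -
  best[, direction := data.table::fifelse(
    (strand == "+") == (novel_pos < canon_pos), "upstream", "downstream")]
  best[, event_id := paste0(chrom, ":", intron_first, "-", intron_last,
                            "(", strand, ")")]
  out <- best[, .(event_id, chrom, strand, side, direction,
                  cryptic_pos = novel_pos, canonical_pos = canon_pos,
                  shared_pos, distance,
                  cryptic_first = intron_first, cryptic_last = intron_last,
                  canonical_first, canonical_last)]
  data.table::setorder(out, chrom, cryptic_first, cryptic_last, strand)
  out[]
}

#' Per-sample percent-spliced-in for cryptic events
#'
#' `PSI = cryptic / (cryptic + canonical)` from raw unique-read counts of
#' the event's cryptic junction and its single paired canonical junction;
#' `NA` where the denominator is 0.
#'
#' @param events Event table from [pair_with_canonical()].
#' @param jt The same filtered `junction_table` the events were called from.
#' @return A `psi_matrix`: list with `psi`, `cryptic`, `canonical`
#'   (event x sample matrices) and the `events` table.
#' @export
compute_psi <- function(events, jt) {
  stopifnot(inherits(jt, "junction_table"))
  ev <- data.table::as.data.table(events)
  samples <- jt$samples
  get_counts <- function(first_col, last_col) {
    keys <- ev[, .(chrom, intron_first = get(first_col),
                   intron_last = get(last_col), strand)]
    m <- jt$junctions[keys, on = c("chrom", "intron_first", "intron_last",
                                   "strand"), mget(samples)]
    m <- as.matrix(m)
    if (anyNA(m)) stop("event junction missing from the junction table")
    rownames(m) <- ev$event_id
    storage.mode(m) <- "numeric"
    m
  }
  if (nrow(ev) == 0L) {
    z <- matrix(numeric(0), nrow = 0L, ncol = length(samples),
                dimnames = list(NULL, samples))
    return(structure(list(psi = z, cryptic = z, canonical = z, events = ev),
                     class = "psi_matrix"))
  }
  cr <- get_counts("cryptic_first", "cryptic_last")
  ca <- get_counts("canonical_first", "canonical_last")
  denom <- cr + ca
  psi <- cr / denom
  psi[denom == 0] <- NA_real_
  structure(list(psi = psi, cryptic = cr, canonical = ca, events = ev),
            class = "psi_matrix")
}

#' @export
print.psi_matrix <- function(x, ...) {
  cat(sprintf("psi_matrix: %d events x %d samples (%d missing cells)\n",
              nrow(x$psi), ncol(x$psi), sum(is.na(x$psi))))
  invisible(x)
}

#' Distance histogram of upstream cryptic 3'ss events
#'
#' Counts upstream 3'ss events per cryptic-to-canonical distance, the
#' summary used to inspect where cryptic acceptors localize relative to
#' their canonical acceptors.
#'
#' @param events Event table from [pair_with_canonical()].
#' @return data.table with `distance` and `n`, sorted by distance.
#' @export
distance_histogram <- function(events) {
  ev <- data.table::as.data.table(events)
  ev <- ev[ev$side == "3ss" & ev$direction == "upstream"]
  if (nrow(ev) == 0L) {
    return(data.table::data.table(distance = integer(0), n = integer(0)))
  }
  out <- ev[, .(n = .N), by = distance]
  data.table::setorder(out, distance)
  out[]
}
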