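# Differential cryptic-3'ss usage: t-tests on PSI, BH correction, event
# selection/ranking, control-intron selection and matrix preparation for
# clustering / PCA.

# t-test wrapper that survives the degenerate zero-variance cases:
# both groups constant and equal -> p = 1; constant but different -> the
# smallest representable p (usage differs with certainty under the model).
welch_p <- function(x, y, var_equal = FALSE) {
  vx <- stats::var(x)
  vy <- stats::var(y)
  if (isTRUE(all.equal(vx, 0)) && isTRUE(all.equal(vy, 0))) {
    d <- mean(x) - mean(y)
    if (isTRUE(all.equal(d, 0))) {
      return(list(t = 0, p = 1))
    }
    return(list(t = sign(d) * Inf, p = .Machine$double.xmin))
  }
  ht <- stats::t.test(x, y, var.equal = var_equal)
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' Test differential PSI between two sample groups
#'
#' Two-sided t-test per event on PSI values (Welch by default), with
#' `dpsi = mean(group_a) - mean(group_b)`. Events with fewer than two
#' usable (non-missing) PSI values in either group are reported with
#' missing p rather than dropped silently.
#'
#' @param psi A `psi_matrix` (or a plain event x sample matrix).
#' @param groups Named character vector: sample -> group label.
#' @param group_a,group_b The two group labels to compare (`dpsi` is a - b).
#' @param var_equal Use the pooled-variance (Student) test instead of Welch.
#' @return data.table: `event_id`, `mean_a`, `mean_b`, `dpsi`, `t`, `p`,
#'   `q` (BH across tested events), `n_a`, `n_b`, `tested`.
#' @export
test_differential_psi <- function(psi, groups, group_a, group_b,
                                  var_equal = FALSE) {
  m <- if (inherits(psi, "psi_matrix")) psi$psi else as.matrix(psi)
  if (is.null(rownames(m))) rownames(m) <- as.character(seq_len(nrow(m)))
  sa <- names(groups)[groups == group_a]
  sb <- names(groups)[groups == group_b]
  sa <- intersect(sa, colnames(m))
  sb <- intersect(sb, colnames(m))
  if (length(sa) == 0L || length(sb) == 0L) {
    stop("no samples found for one of the groups")
  }
  n <- nrow(m)
  res <- data.table::data.table(
    event_id = rownames(m),
    mean_a = NA_real_, mean_b = NA_real_, dpsi = NA_real_,
    t = NA_real_, p = NA_real_, q = NA_real_,
    n_a = 0L, n_b = 0L, tested = FALSE)
  for (i in seq_len(n)) {
    x <- m[i, sa]; x <- x[!is.na(x)]
    y <- m[i, sb]; y <- y[!is.na(y)]
    data.table::set(res, i, c("n_a", "n_b"),
                    list(length(x), length(y)))
    if (length(x) > 0L) data.table::set(res, i, "mean_a", mean(x))
    if (length(y) > 0L) data.table::set(res, i, "mean_b", mean(y))
    if (length(x) >= 2L && length(y) >= 2L) {
      ht <- welch_p(x, y, var_equal = var_equal)
      data.table::set(res, i, c("dpsi", "t", "p", "tested"),
                      list(mean(x) - mean(y), ht$t, ht$p, TRUE))
    }
  }
  res[tested == TRUE, q := bh_adjust(p)]
  res[]
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotone enforcement (delegates to
#' [stats::p.adjust()]); input p-values must lie in \[0, 1\].
#'
#' @param p Numeric vector of p-values (NA allowed, preserved).
#' @return Vector of q-values.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Select differentially used cryptic 3'ss events
#'
#' Keeps events with `p < p_max` that are upstream cryptic 3'ss located
#' closer than `max_upstream` nt to their canonical acceptor (both
#' inequalities strict).
#'
#' @param results Output of [test_differential_psi()].
#' @param events Event table from [pair_with_canonical()].
#' @param p_max P-value cutoff (strict).
#' @param max_upstream Distance cutoff in nt (strict).
#' @return The selected events joined with their test columns, sorted by
#'   `event_id`.
#' @export
select_significant_events <- function(results, events, p_max = 0.05,
                                      max_upstream = 50) {
  res <- data.table::as.data.table(results)
  ev <- data.table::as.data.table(events)
  j <- merge(ev, res, by = "event_id")
  j <- j[!is.na(p) & p < p_max & side == "3ss" & direction == "upstream" &
           distance < max_upstream]
  data.table::setorder(j, event_id)
  j[]
}

#' Rank events by absolute delta-PSI
#'
#' Descending `|dpsi|`; ties broken by ascending p then event id.
#'
#' @param results A results (or selected-events) table with `dpsi`, `p`.
#' @param n Number of top events to return.
#' @return The top `n` rows in rank order.
#' @export
rank_top_events <- function(results, n = 30) {
  res <- data.table::as.data.table(results)
  res <- res[!is.na(dpsi)]
  o <- order(-abs(res$dpsi), res$p, res$event_id)
  res[o][seq_len(min(n, nrow(res)))]
}

#' Split significant events into mutation-preferred sets
#'
#' From a test of group R against group K (`dpsi = mean(R) - mean(K)`),
#' the R-preferred set is the top `n_R` significant events with positive
#' `dpsi`, the K-preferred set the top `n_K` with negative `dpsi` (ranked
#' by `|dpsi|`).
#'
#' @param results_rk Output of [test_differential_psi()] for R vs K.
#' @param n_R,n_K Set sizes.
#' @param p_max Significance cutoff (strict).
#' @return List with `R_preferred` and `K_preferred` event-id vectors and
#'   the selection parameters.
#' @export
split_preferred_sets <- function(results_rk, n_R = 350, n_K = 348,
                                 p_max = 0.05) {
  res <- data.table::as.data.table(results_rk)
  sig <- res[!is.na(p) & p < p_max]
  rp <- sig[dpsi > 0][order(-abs(dpsi), p, event_id)]
  kp <- sig[dpsi < 0][order(-abs(dpsi), p, event_id)]
  list(R_preferred = rp$event_id[seq_len(min(n_R, nrow(rp)))],
       K_preferred = kp$event_id[seq_len(min(n_K, nrow(kp)))],
       params = list(n_R = n_R, n_K = n_K, p_max = p_max))
}

#' Select control introns without cryptic 3'ss usage
#'
#' Draws a seeded uniform random sample of annotated introns that carry
#' canonical junction coverage in the table but no detected novel junction
#' (no cryptic event paired to their acceptor), i.e. introns whose
#' differential-usage p would be 1 because no cryptic read exists in any
#' sample.
#'
#' @param ann A `genome_annotation`.
#' @param events All called events (pre-significance filtering).
#' @param jt The filtered, classified `junction_table`.
#' @param n Number of control introns to sample.
#' @param seed Integer seed for the draw.
#' @return data.table of sampled introns (subset of `ann$introns`); warns
#'   and returns all eligible introns if fewer than `n` exist.
#' @export
select_control_introns <- function(ann, events, jt, n = 500, seed = 1L) {
  stopifnot(inherits(ann, "genome_annotation"), inherits(jt, "junction_table"))
  ev <- data.table::as.data.table(events)
  introns <- data.table::copy(ann$introns)
  covered <- jt$junctions[jt$junctions$total > 0,
                          .(chrom, intron_first, intron_last, strand)]
  introns <- introns[covered, on = c("chrom", "intron_first", "intron_last",
                                     "strand"), nomatch = NULL]
  if (nrow(ev) > 0L) {
    used <- unique(ev[, .(chrom, strand, acceptor_pos = canonical_pos)])
    introns <- introns[!used, on = c("chrom", "strand", "acceptor_pos")]
  }
  if (nrow(introns) == 0L) {
    warning("no eligible control introns")
    return(introns)
  }
  data.table::setorder(introns, chrom, intron_first, intron_last, strand)
  if (nrow(introns) < n) {
    warning(sprintf("only %d eligible control introns (requested %d)",
                    nrow(introns), n))
    return(introns)
  }
  idx <- with_local_seed(seed, sample.int(nrow(introns), n))
  out <- introns[sort(idx)]
  out[]
}

# Run code under a temporary RNG state so callers' streams are untouched.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Row-wise z-score
#'
#' Each row is centred to mean 0 and scaled to sample (n-1) standard
#' deviation 1; constant rows (or single-column input) map to all zeros.
#'
#' @param m Numeric matrix.
#' @return Matrix of the same shape.
#' @export
zscore_rows <- function(m) {
  m <- as.matrix(m)
  mu <- rowMeans(m)
  s <- apply(m, 1L, stats::sd)
  z <- (m - mu) / ifelse(s > 0, s, 1)
  z[s == 0 | is.na(s), ] <- 0
  z
}
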