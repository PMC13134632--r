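# Independent oracles used to validate the statistical kernels and the
# cryptic-site caller. These re-derive every quantity from first
# principles (enumeration, closed forms) and never call the code paths
# they check.

# Benjamini-Hochberg by the step-up definition: q_(i) = min_{j >= i} m p_(j)/j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Welch two-sided t-test from the textbook formulas
oracle_welch_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  t_stat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  2 * pt(-abs(t_stat), df)
}

# Two-sided Fisher exact p for table [[a, b], [c, d]] by exhaustive
# enumeration of the hypergeometric support (sum of outcomes at most as
# probable as the observed one).
oracle_fisher_two_sided <- function(a, b, c, d) {
  m <- a + b            # row 1 total
  n <- c + d            # row 2 total
  k <- a + c            # column 1 total
  support <- max(0L, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact two-sided signed-rank p by enumeration of all 2^n sign
# assignments (tie-free |d| assumed; zero differences must be removed by
# the caller first).
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n <= 12, !anyDuplicated(abs(d)))
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  mu <- n * (n + 1) / 4
  if (v_obs > mu) {
    p <- 2 * mean(v_all >= v_obs)
  } else if (v_obs < mu) {
    p <- 2 * mean(v_all <= v_obs)
  } else {
    p <- 1
  }
  min(p, 1)
}

# Brute-force cryptic caller implementing the identification rules
# verbatim on a plain junction data.frame:
#  * drop junctions with summed coverage < min_total;
#  * a junction is "novel" if exactly one end (donor or acceptor,
#    strand-aware) is in the annotated site sets;
#  * its canonical partners are junctions with BOTH ends annotated that
#    share the novel junction's annotated end;
#  * distance = |novel end - canonical end|, minimum over partners; ties
#    broken toward the partner with larger total, then smaller
#    intron_first, then smaller intron_last;
#  * side = 3ss when the acceptor is the novel end; direction = upstream
#    when the novel site lies 5'-ward of the canonical site in transcript
#    orientation.
# `donors` / `acceptors` are data.frames with chrom, strand, pos.
oracle_call_events <- function(junc, donors, acceptors, min_total = 50) {
  junc <- junc[rowSums(junc[, grep("^count_", names(junc)), drop = FALSE]) >=
                 min_total, , drop = FALSE]
  if (nrow(junc) == 0L) return(NULL)
  junc$total <- rowSums(junc[, grep("^count_", names(junc)), drop = FALSE])
  dset <- paste(donors$chrom, donors$strand, donors$pos)
  aset <- paste(acceptors$chrom, acceptors$strand, acceptors$pos)
  jd <- ifelse(junc$strand == "+", junc$intron_first, junc$intron_last)
  ja <- ifelse(junc$strand == "+", junc$intron_last, junc$intron_first)
  d_ann <- paste(junc$chrom, junc$strand, jd) %in% dset
  a_ann <- paste(junc$chrom, junc$strand, ja) %in% aset
  stranded <- junc$strand %in% c("+", "-")
  both <- which(stranded & d_ann & a_ann)
  out <- list()
  for (i in which(stranded & xor(d_ann, a_ann))) {
    novel_is_acceptor <- d_ann[i]
    if (novel_is_acceptor) {
      shared_i <- jd[i]; novel_i <- ja[i]
      cand <- both[jd[both] == shared_i & junc$chrom[both] == junc$chrom[i] &
                     junc$strand[both] == junc$strand[i]]
      cand_end <- ja[cand]
    } else {
      shared_i <- ja[i]; novel_i <- jd[i]
      cand <- both[ja[both] == shared_i & junc$chrom[both] == junc$chrom[i] &
                     junc$strand[both] == junc$strand[i]]
      cand_end <- jd[cand]
    }
    if (length(cand) == 0L) next
    dist <- abs(novel_i - cand_end)
    ord <- order(dist, -junc$total[cand], junc$intron_first[cand],
                 junc$intron_last[cand])
    j <- cand[ord[1]]
    canon_end <- cand_end[ord[1]]
    upstream <- (junc$strand[i] == "+") == (novel_i < canon_end)
    out[[length(out) + 1L]] <- data.frame(
      chrom = junc$chrom[i], strand = junc$strand[i],
      cryptic_first = junc$intron_first[i],
      cryptic_last = junc$intron_last[i],
      canonical_first = junc$intron_first[j],
      canonical_last = junc$intron_last[j],
      side = if (novel_is_acceptor) "3ss" else "5ss",
      direction = if (upstream) "upstream" else "downstream",
      distance = min(dist),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(NULL)
  do.call(rbind, out)
}
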