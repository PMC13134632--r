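rand_seq <- function(n, probs = c(0.25, 0.25, 0.25, 0.25)) {
  paste(sample(c("A", "C", "G", "T"), n, TRUE, prob = probs),
        collapse = "")
}

test_that("window extraction returns the -100..+10 slice per strand", {
  set.seed(30)
  chrom_seq <- rand_seq(400)
  genome <- Biostrings::DNAStringSet(c(chr1 = chrom_seq))
  # + strand acceptor at 250: forward slice [151, 260]
  sites <- data.frame(site_id = "s1", class = "cryptic", chrom = "chr1",
                      strand = "+", acceptor_pos = 250L)
  w <- extract_windows(sites, genome)
  expect_equal(nchar(w$seq), 110L)
  expect_equal(w$seq, substr(chrom_seq, 151, 260))

  # the same context mirrored onto the - strand of a reverse-complement
  # chromosome yields the identical labeled window
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(chrom_seq)))
  genome_rc <- Biostrings::DNAStringSet(c(chr1 = rc))
  sites_m <- data.frame(site_id = "s1", class = "cryptic", chrom = "chr1",
                        strand = "-", acceptor_pos = 400L - 250L + 1L)
  w_m <- extract_windows(sites_m, genome_rc)
  expect_identical(w_m$seq, w$seq)

  # too close to the chromosome start: dropped with a message
  sites_edge <- data.frame(site_id = "s2", class = "cryptic",
                           chrom = "chr1", strand = "+",
                           acceptor_pos = 50L)
  expect_message(w_e <- extract_windows(sites_edge, genome), "dropped")
  expect_equal(nrow(w_e), 0L)
})

test_that("windows containing N are excluded", {
  genome <- Biostrings::DNAStringSet(c(chr1 = paste0(
    strrep("A", 150), "N", strrep("T", 150))))
  sites <- data.frame(site_id = c("a", "b"), class = "x", chrom = "chr1",
                      strand = "+", acceptor_pos = c(155L, 290L))
  expect_message(w <- extract_windows(sites, genome), "contain N")
  expect_equal(w$site_id, "b")
})

test_that("composition profile counts every window at every position", {
  w <- make_windows(c(strrep("A", 110), strrep("T", 110)))
  prof <- composition_profile(w)
  expect_equal(unname(prof$freq["A", ]), rep(0.5, 110))
  expect_equal(unname(prof$freq["T", ]), rep(0.5, 110))
  expect_equal(unname(colSums(prof$counts)), rep(2L, 110))
  expect_equal(prof$positions[c(1, 100, 101, 110)], c(-100L, -1L, 1L, 10L))

  set.seed(31)
  w100 <- make_windows(replicate(100, rand_seq(110)))
  p100 <- composition_profile(w100)
  expect_equal(unname(colSums(p100$counts)), rep(100L, 110))
  expect_equal(unname(colSums(p100$freq)), rep(1, 110))
})

test_that("per-position Fisher enrichment matches exact enumeration", {
  w_t <- make_windows(rep(strrep("A", 110), 10))
  w_c <- make_windows(rep(strrep("T", 110), 10))
  fp <- fisher_position_enrichment(composition_profile(w_t),
                                   composition_profile(w_c))
  a_at_m50 <- fp[position == -50 & base == "A"]
  expect_equal(a_at_m50$p, oracle_fisher_two_sided(10, 0, 0, 10),
               tolerance = 1e-12)
  expect_equal(a_at_m50$p, 2 / choose(20, 10), tolerance = 1e-9)
  # identical profiles: p = 1 everywhere
  fp_same <- fisher_position_enrichment(composition_profile(w_t),
                                        composition_profile(w_t))
  expect_true(all(fp_same$p == 1))
  # symmetry under swapping target and control
  fp_swap <- fisher_position_enrichment(composition_profile(w_c),
                                        composition_profile(w_t))
  expect_equal(fp_swap[position == -50 & base == "A"]$p, a_at_m50$p)
})

test_that("Fisher p matches enumeration for all tables with margins <= 12", {
  # moderate margin cap keeps the sweep quick; the acceptance suite covers
  # margins up to 30
  for (m in c(5L, 9L, 12L)) {
    for (a in 0:m) {
      for (c_ in 0:m) {
        p_pkg <- fisher.test(matrix(c(a, m - a, c_, m - c_), 2,
                                    byrow = TRUE))$p.value
        expect_equal(p_pkg, oracle_fisher_two_sided(a, m - a, c_, m - c_),
                     tolerance = 1e-9,
                     info = sprintf("a=%d c=%d m=%d", a, c_, m))
      }
    }
  }
})

test_that("maximal A-run counting by class", {
  pad <- function(region) {
    # place `region` at -50..-1 of a 110-nt window
    paste0(strrep("C", 50), region, strrep("C", 10))
  }
  w <- make_windows(pad(paste0("CAAAT", strrep("C", 45))))
  rf <- polyA_run_features(w)
  expect_equal(unname(rf$features[1, ]), c(0, 0, 1, 0))

  w_t <- make_windows(pad(strrep("T", 50)))
  expect_equal(unname(polyA_run_features(w_t)$features[1, ]), c(0, 0, 0, 0))

  w_6 <- make_windows(pad(paste0("AAAAAA", "T", "AA", "T", "A",
                                 strrep("C", 39))))
  expect_equal(unname(polyA_run_features(w_6)$features[1, ]), c(1, 1, 0, 1))
})

test_that("run features ignore sequence outside the stated region", {
  set.seed(32)
  inside <- paste0("CC", strrep("A", 3), strrep("C", 45))
  w1 <- make_windows(paste0(strrep("A", 50), inside, strrep("T", 10)))
  w2 <- make_windows(paste0(strrep("G", 50), inside, strrep("C", 10)))
  expect_equal(polyA_run_features(w1)$features[1, ],
               polyA_run_features(w2)$features[1, ])
  expect_error(polyA_run_features(w1, region = c(-120, -1)), "region")
  expect_error(polyA_run_features(w1, region = c(-50, 5)), "region")
})

test_that("signed-rank comparison matches exact enumeration on small n", {
  # three informative pairs, all positive differences: two-sided p = 0.25
  mk_rf <- function(track_vals) {
    # single-window run_feature_matrix with a chosen AAAA start track
    n <- length(track_vals)
    tr <- lapply(1:4, function(i) matrix(0, 1, n))
    names(tr) <- c("A", "AA", "AAA", "AAAA")
    tr$AAAA <- matrix(track_vals, 1, n)
    structure(list(features = matrix(0, 1, 4,
                                     dimnames = list(NULL,
                                                     names(tr))),
                   tracks = tr,
                   means = setNames(numeric(4), names(tr)),
                   region = c(-3L, -1L), site_ids = "w1"),
              class = "run_feature_matrix")
  }
  a <- mk_rf(c(0.9, 0.8, 0.7))
  b <- mk_rf(c(0.1, 0.3, 0.5))
  got <- compare_run_frequencies(a, b, "AAAA")
  expect_equal(got$p, 0.25)
  expect_equal(got$p, oracle_signed_rank_p(c(0.8, 0.5, 0.2)))
  # identical tracks: p = 1
  same <- compare_run_frequencies(a, a, "AAAA")
  expect_equal(same$p, 1)
  expect_equal(same$n_pairs, 0L)
})

test_that("signed-rank implementation equals enumeration for n <= 12", {
  set.seed(33)
  for (i in 1:40) {
    n <- sample(3:12, 1)
    d <- round(runif(n, -1, 1), 7)
    d <- d[d != 0]
    if (anyDuplicated(abs(d)) || length(d) < 3) next
    p_pkg <- wilcox.test(d, exact = TRUE, correct = TRUE)$p.value
    expect_equal(p_pkg, oracle_signed_rank_p(d), tolerance = 1e-12)
  }
})

test_that("planted run-density differences are detected between groups", {
  cfg <- simulation_config()
  w_r <- simulate_acceptor_windows(300, "R_preferred", cfg, seed = 61)
  w_k <- simulate_acceptor_windows(300, "K_preferred", cfg, seed = 62)
  rf_r <- polyA_run_features(w_r)
  rf_k <- polyA_run_features(w_k)
  for (f in c("AA", "AAA", "AAAA")) {
    cmp <- compare_run_frequencies(rf_r, rf_k, f)
    expect_lt(cmp$p, 0.05)
    expect_gt(cmp$mean_a, cmp$mean_b)
  }
})

test_that("k-mer enrichment ranks and tests against the control set", {
  w_t <- make_windows(rep(strrep("T", 110), 5))
  km <- kmer_enrichment(w_t, w_t)
  expect_equal(km$kmer[km$rank == 1], "TTTTTT")
  expect_equal(km$target_freq[1], 1)
  expect_error(kmer_enrichment(w_t, w_t, k = 31, region = c(-30, -1)),
               "region")

  set.seed(34)
  w_a <- make_windows(replicate(120, paste0(
    rand_seq(70), "AAAAAA", rand_seq(24), "AG", rand_seq(8))))
  w_py <- make_windows(replicate(120, paste0(
    rand_seq(70), rand_seq(30, probs = c(0.05, 0.4, 0.05, 0.5)),
    rand_seq(10))))
  km2 <- kmer_enrichment(w_a, w_py)
  row_a6 <- km2[kmer == "AAAAAA"]
  expect_lt(row_a6$p, 0.05)
  expect_gt(row_a6$target_freq, row_a6$control_freq)
  expect_false(anyDuplicated(km2$rank) > 0)
})

test_that("logo matrix serializes frequencies that sum to one", {
  w <- make_windows(strrep("G", 110))
  lm1 <- logo_matrix(composition_profile(w))
  expect_equal(lm1$G, rep(1, 110))
  expect_equal(lm1$A + lm1$C + lm1$G + lm1$T, rep(1, 110))

  set.seed(35)
  w_u <- make_windows(replicate(400, rand_seq(110)))
  lmu <- logo_matrix(composition_profile(w_u))
  expect_true(all(abs(as.matrix(lmu[, -1]) - 0.25) < 0.12))
})
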