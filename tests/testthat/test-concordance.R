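test_that("sov_score matches hand-computed and printed examples", {
  # identical intervals
  for (v in c("half_capped", "as_printed")) {
    s <- sov_score(100, 200, 100, 200, v)
    expect_equal(s$minov, 100); expect_equal(s$maxov, 100)
    expect_equal(s$delta, 0);   expect_equal(s$sov, 1)
  }
  # the LOR1-int pair (RepBase vs HERVd coordinates)
  hc <- sov_score(48138333, 48140169, 48138680, 48141264, "half_capped")
  expect_equal(hc$minov, 1489)
  expect_equal(hc$maxov, 2931)
  expect_equal(hc$delta, 918)           # min(1442, 1489, 918, 1292)
  expect_equal(hc$sov, 2407 / 2931)     # ~0.8212
  ap <- sov_score(48138333, 48140169, 48138680, 48141264, "as_printed")
  expect_equal(ap$delta, 1442)
  expect_equal(ap$sov, 1)
  # one interval engulfing a short overlap
  for (v in c("half_capped", "as_printed"))
    expect_equal(sov_score(0, 100, 50, 400, v)$sov, 0.25)
  # non-overlapping input is a caller error
  expect_error(sov_score(0, 100, 100, 200), "overlapping")
})

test_that("sov_score is symmetric and bounded on random overlapping pairs", {
  set.seed(99)
  n <- 500
  sa <- sample.int(5000, n); ea <- sa + sample.int(800, n)
  # force overlap: b starts inside a
  sb <- sa + floor(runif(n) * pmax(ea - sa - 1L, 1L))
  eb <- sb + sample.int(800, n)
  for (v in c("half_capped", "as_printed")) {
    ab <- sov_score(sa, ea, sb, eb, v)
    ba <- sov_score(sb, eb, sa, ea, v)
    expect_equal(ab, ba)
    expect_true(all(ab$sov > 0 & ab$sov <= 1))
    expect_true(all(ab$minov <= pmin(ea - sa, eb - sb)))
    expect_true(all(ab$maxov >= pmax(ea - sa, eb - sb)))
  }
})

test_that("containment closed forms hold on a small sweep", {
  # a inside b starting at 0: sov = 1 iff len_a >= len_b/2 (as_printed)
  # and iff len_a >= 2/3 len_b (half_capped)
  for (lb in c(7, 30, 60)) {
    la <- seq_len(lb)
    ap <- sov_score(rep(0, lb), la, 0, lb, "as_printed")$sov
    hc <- sov_score(rep(0, lb), la, 0, lb, "half_capped")$sov
    expect_equal(ap == 1, la >= lb / 2)
    expect_equal(hc == 1, la >= (2 / 3) * lb)
  }
})

test_that("find_overlaps applies half-open semantics and finds 1 bp overlaps", {
  A <- mk_set(0, 100, source = "A")
  B <- mk_set(100, 200, source = "B")
  expect_equal(nrow(find_overlaps(A, B)), 0L)   # touching is not overlap
  B2 <- mk_set(99, 200, source = "B")
  p <- find_overlaps(A, B2)
  expect_equal(nrow(p), 1L)
  expect_equal(sov_score(p$start_a, p$end_a, p$start_b, p$end_b)$minov, 1)
  # different chromosomes never overlap
  B3 <- mk_set(0, 100, chrom = "chr2", source = "B")
  expect_equal(nrow(find_overlaps(A, B3)), 0L)
  # build mismatch is an error
  Bx <- mk_set(0, 100, source = "B", build = "otherbuild")
  expect_error(find_overlaps(A, Bx), "genome build mismatch")
})

test_that("find_overlaps equals the brute-force all-pairs oracle", {
  for (seed in 1:10) {
    A <- random_set(60, seed, source = "A")
    B <- random_set(60, seed + 1000, source = "B")
    expect_equal(pair_keys(find_overlaps(A, B)),
                 brute_force_overlaps(A, B))
  }
})

test_that("is_match combines the Sov and 5%-shift criteria", {
  cfg <- sov_config()
  expect_true(is_match(100, 100, 100, 1, cfg))        # identical intervals
  # a 300 bp fragment inside a 1000 bp merged record: Sov < 1 but the
  # overlap covers 100% >= 95% of the fragment
  sc <- sov_score(0, 300, 0, 1000)
  expect_lt(sc$sov, 1)
  expect_true(is_match(sc$minov, 300, 1000, sc$sov, cfg))
  # overlap below 95% of the smaller record and Sov < 1: no match
  sc2 <- sov_score(0, 100, 50, 400)
  expect_false(is_match(sc2$minov, 100, 350, sc2$sov, cfg))
  # secondary criterion can be disabled
  cfg_off <- sov_config(use_secondary_criterion = FALSE)
  expect_false(is_match(sc$minov, 300, 1000, sc$sov, cfg_off))
})

test_that("pairwise_matched reproduces the merged-vs-fragments scenario", {
  A <- mk_set(0, 1000, source = "A")                       # merged record
  B <- mk_set(c(0, 350, 700), c(300, 650, 1000), source = "B")  # fragments
  m <- pairwise_matched(A, B, sov_config())
  expect_equal(m$n_A_matched, 1L)
  expect_equal(m$n_B_matched, 3L)
  expect_equal(m$bp_A_matched, 1000L)
  expect_equal(m$bp_B_matched, 900L)
  # Sov alone never reaches 1 for 300/1000 fragments
  off <- sov_config(use_secondary_criterion = FALSE)
  m2 <- pairwise_matched(A, B, off)
  expect_equal(m2$n_A_matched, 0L)
  expect_equal(m2$n_B_matched, 0L)
  # disjoint sets give all-zero results
  C <- mk_set(5000, 6000, source = "C")
  m3 <- pairwise_matched(A, C, sov_config())
  expect_equal(unlist(m3), c(n_A_matched = 0L, bp_A_matched = 0L,
                             n_B_matched = 0L, bp_B_matched = 0L))
})

test_that("three_way decomposes trivially concordant and missing sources", {
  A <- mk_set(100, 600, source = "A")
  B <- mk_set(100, 600, source = "B")
  C <- mk_set(100, 600, source = "C")
  r <- three_way(A, B, C)
  expect_equal(r$per_source$n_shared_all, rep(1L, 3))
  expect_equal(r$per_source$n_unique, rep(0L, 3))
  # same record absent from the third source
  C0 <- mk_set(integer(), integer(), source = "C")
  r2 <- three_way(A, B, C0)
  ps <- r2$per_source
  expect_equal(ps$n_shared_all[ps$source == "A"], 0L)
  expect_equal(ps$n_unique[ps$source == "A"], 0L)   # matched in B
  expect_equal(ps$n_one_other[ps$source == "A"], 1L)
})

test_that("three_way conserves records per source on noisy simulations", {
  sim <- cached_sim("small_noisy",
                    sim_params(seed = 21,
                               n_elements = c(ERV1 = 300, ERV2 = 50,
                                              ERV3 = 500, Gypsy = 50,
                                              Unclassified = 50)))
  r <- three_way(sim$sources$M, sim$sources$F1, sim$sources$F2)
  ps <- r$per_source
  for (i in seq_len(nrow(ps))) {
    expect_equal(ps$n_shared_all[i] + ps$n_unique[i] + ps$n_one_other[i],
                 ps$n_total[i])
    expect_true(all(ps$n_shared_all[i] <=
                      r$pairwise$n_matched[r$pairwise$source == ps$source[i]]))
  }
  expect_equal(sort(unique(r$by_superfamily$source)), sort(ps$source))
  # superfamily rows add up to the whole-source decomposition
  agg <- r$by_superfamily[, .(n = sum(n_total), sh = sum(n_shared_all),
                              un = sum(n_unique)), by = source]
  expect_equal(agg$n, ps$n_total[match(agg$source, ps$source)])
  expect_equal(agg$sh, ps$n_shared_all[match(agg$source, ps$source)])
  expect_equal(agg$un, ps$n_unique[match(agg$source, ps$source)])
})

test_that("lowering shift_fraction never decreases matched counts", {
  sim <- cached_sim("small_noisy",
                    sim_params(seed = 21,
                               n_elements = c(ERV1 = 300, ERV2 = 50,
                                              ERV3 = 500, Gypsy = 50,
                                              Unclassified = 50)))
  A <- sim$sources$M; B <- sim$sources$F1
  prev <- -1L
  for (sf in c(0.99, 0.95, 0.8, 0.5)) {
    m <- pairwise_matched(A, B, sov_config(shift_fraction = sf))
    expect_gte(m$n_A_matched, prev)
    prev <- m$n_A_matched
  }
})

test_that("score_overlaps flags cross-superfamily matches as a diagnostic", {
  A <- mk_set(0, 500, source = "A", superfamily = "ERV1")
  B <- mk_set(0, 500, source = "B", superfamily = "ERV3")
  sp <- score_overlaps(find_overlaps(A, B))
  expect_true(sp$matched)            # matching ignores superfamily
  expect_true(sp$cross_superfamily)  # but the discrepancy is reported
})
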