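# Max-gap single-linkage breakpoint clustering.

test_that("published cluster rows reconstruct to the printed structure", {
  rows <- published_breakpoint_clusters()
  bp <- reconstruct_breakpoints(rows)
  expect_equal(nrow(bp), 63)  # all listed members

  clustered <- cluster_breakpoints(bp, max_gap = 2000)
  rep <- cluster_summary(clustered)
  expect_equal(nrow(rep), 17)                       # 12 clusters + 5 pairs
  expect_equal(sum(rep$n_members >= 3), 12)
  expect_equal(sum(rep$n_members == 2), 5)

  # spans recomputed from positions match gap sums of the printed rows
  by_anchor <- rep[order(rep$anchor), ]
  expect_equal(by_anchor$span[by_anchor$anchor == 54520243], 2118)  # A
  expect_equal(by_anchor$span[by_anchor$anchor == 54558285], 2497)  # B
  expect_equal(by_anchor$span[by_anchor$anchor == 54697888], 127)   # D
  expect_equal(by_anchor$span[by_anchor$anchor == 54668755], 61)    # C
  expect_equal(min(by_anchor$span[by_anchor$n_members >= 3]), 127)
  # every breakend is accounted for
  expect_equal(sum(rep$n_members), 63)
  expect_equal(clustered_fraction(clustered), 1)
})

test_that("the max-gap boundary is inclusive", {
  two <- tibble::tibble(chrom = "c", pos = c(1000, 3001))
  apart <- cluster_breakpoints(two, max_gap = 2000)
  expect_true(all(is.na(apart$cluster)))            # 2001 apart: singletons
  touching <- cluster_breakpoints(
    tibble::tibble(chrom = "c", pos = c(1000, 3000)), max_gap = 2000)
  expect_true(all(!is.na(touching$cluster)))        # exactly 2000: joined
})

test_that("single-linkage equals brute-force transitive closure", {
  withr::local_seed(17)
  for (rep_i in 1:5) {
    n <- 200
    bp <- tibble::tibble(
      chrom = sample(c("c1", "c2"), n, replace = TRUE),
      pos = sample.int(5e5, n))
    for (gap in c(500, 2000, 10000)) {
      got <- package_cluster_partition(cluster_breakpoints(bp, gap))
      want <- oracle_cluster_partition(bp, gap)
      expect_identical(got, want)
    }
  }
})

test_that("clusters and singletons partition the input exactly", {
  withr::local_seed(18)
  bp <- tibble::tibble(chrom = "c1", pos = sample.int(2e5, 300))
  cl <- cluster_breakpoints(bp, 1500)
  rep <- cluster_summary(cl)
  n_singletons <- sum(is.na(cl$cluster))
  expect_equal(sum(rep$n_members) + n_singletons, nrow(bp))
  # clustered_fraction numerator + singletons = total
  expect_equal(clustered_fraction(cl) * nrow(bp) + n_singletons, nrow(bp))
})

test_that("increasing max_gap never increases the number of groups", {
  withr::local_seed(19)
  bp <- tibble::tibble(chrom = "c1", pos = sample.int(1e5, 150))
  gaps <- c(100, 500, 1000, 5000, 20000)
  n_groups <- vapply(gaps, function(g) {
    cl <- cluster_breakpoints(bp, g)
    nrow(cluster_summary(cl)) + sum(is.na(cl$cluster))
  }, numeric(1))
  expect_true(all(diff(n_groups) <= 0))
})

test_that("new breakends join existing clusters or form new ones", {
  rows <- published_breakpoint_clusters()
  ref <- cluster_summary(cluster_breakpoints(reconstruct_breakpoints(rows),
                                             max_gap = 2000))
  new_rows <- published_new_breakpoints()
  new_bp <- reconstruct_breakpoints(new_rows)
  res <- assign_new_breakpoints(ref, new_bp, max_gap = 2000)

  # the six later-passage breakpoints published as additions to existing
  # clusters are assigned, each to one distinct cluster per published row
  pub_existing <- new_bp[new_bp$source_cluster %in% c("B", "J", "O", "Q"), ]
  expect_true(all(pub_existing$label %in% res$assigned$label))
  expect_equal(length(unique(
    res$assigned$cluster[res$assigned$label %in% pub_existing$label])), 4)

  # remote groups (T, U, R) become new clusters; the published group "S"
  # falls inside an existing cluster's span and is absorbed by the distance
  # rule, so 9 of the 11 published new-cluster members re-cluster here
  new_members <- unlist(res$new_clusters$members)
  for (lab in unlist(new_bp$label[new_bp$source_cluster %in%
                                    c("R", "T", "U")])) {
    expect_true(grepl(lab, paste(new_members, collapse = " ")))
  }
  expect_equal(nrow(res$new_clusters), 3)
  expect_equal(sum(res$new_clusters$n_members), 9)
  expect_equal(nrow(res$new_singletons), 0)
  # all 17 published later-passage breakpoints are accounted for
  expect_equal(nrow(res$assigned) + sum(res$new_clusters$n_members), 17)

  # a single new breakend just beyond a cluster's last member extends it
  q_anchor <- 55278611
  probe <- tibble::tibble(chrom = "chr7", pos = q_anchor + 1481 + 100,
                          label = "probe")
  ext <- assign_new_breakpoints(ref, probe, max_gap = 2000)
  expect_equal(nrow(ext$assigned), 1)
  q_id <- ref$cluster[ref$anchor == q_anchor]
  expect_equal(ext$assigned$cluster, q_id)

  none <- assign_new_breakpoints(ref, probe[0, ], max_gap = 2000)
  expect_equal(nrow(none$assigned), 0)
})

test_that("assignments on simulated passages recover planted membership", {
  sim <- simulate_amplicon(small_sim_config(seed = 81))
  p4 <- simulate_passage(sim, loss_prob = 0, new_break_rate = 0.5)
  ref_bp <- junction_breakends(junction_table(
    sim$junctions$id, sim$junctions$chrom1, sim$junctions$pos1,
    sim$junctions$orient1, sim$junctions$chrom2, sim$junctions$pos2,
    sim$junctions$orient2))
  ref <- cluster_summary(cluster_breakpoints(ref_bp, max_gap = 2000))
  new_jx <- p4$junctions[p4$junctions$fate == "new", ]
  expect_gt(nrow(new_jx), 0)
  new_bp <- junction_breakends(junction_table(
    new_jx$id, new_jx$chrom1, new_jx$pos1, new_jx$orient1,
    new_jx$chrom2, new_jx$pos2, new_jx$orient2))
  res <- assign_new_breakpoints(ref, new_bp, max_gap = 2000)
  # every new breakend assigned to a cluster truly lies within reach of it
  if (nrow(res$assigned) > 0) {
    for (i in seq_len(nrow(res$assigned))) {
      cl <- ref[ref$cluster == res$assigned$cluster[i], ]
      expect_lte(max(cl$anchor - res$assigned$pos[i],
                     res$assigned$pos[i] - (cl$anchor + cl$span)),
                 2000)
    }
  }
  # and the partition of new breakends is complete
  expect_equal(nrow(res$assigned) + sum(res$new_clusters$n_members) +
                 nrow(res$new_singletons), nrow(new_bp))
})
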