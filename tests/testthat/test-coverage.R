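# Binned coverage, segmentation, amplified-interval arithmetic.

test_that("constant depth bins to its value; empty regions are NA in log2", {
  trk <- depth_track(tibble::tibble(chrom = "c1", start = 1, end = 9000,
                                    depth = 4))
  bins <- bin_depth(trk, 3000)
  expect_equal(bins$depth, rep(4, 3))
  expect_equal(bins$log2_depth, rep(2, 3))

  trk0 <- depth_track(tibble::tibble(chrom = "c1", start = 6001, end = 9000,
                                     depth = 2))
  bins0 <- bin_depth(trk0, 3000)
  expect_equal(bins0$depth[1:2], c(0, 0))
  expect_true(all(is.na(bins0$log2_depth[1:2])))
  expect_equal(bins0$depth[3], 2)
})

test_that("binning averages partial overlaps exactly", {
  trk <- depth_track(tibble::tibble(chrom = "c1",
                                    start = c(1, 1501), end = c(1500, 3000),
                                    depth = c(2, 6)))
  bins <- bin_depth(trk, 3000)
  expect_equal(bins$depth, 4)  # (1500*2 + 1500*6) / 3000
})

test_that("a planted high-copy segment is called within one bin", {
  sim <- simulate_amplicon(small_sim_config(seed = 41))
  obs <- sim_observables(sim, depth_per_copy = 3, baseline = 3,
                         noise = TRUE)
  bins <- bin_depth(obs$depth, 3000, c(cA = 2e5))
  segs <- call_amplified_segments(bins, baseline = 3, min_fold = 3)
  expect_gt(nrow(segs), 0)
  # every truth amplified interval is covered by a called segment
  for (i in seq_len(nrow(obs$amplified))) {
    tr <- obs$amplified[i, ]
    if (tr$end - tr$start < 6000) next  # below calling resolution
    hit <- segs$chrom == tr$chrom & segs$start <= tr$start + 3000 &
      segs$end >= tr$end - 3000
    expect_true(any(hit))
  }
})

test_that("flat tracks yield no segments and close runs merge", {
  trk <- depth_track(tibble::tibble(chrom = "c1", start = 1, end = 60000,
                                    depth = 4))
  bins <- bin_depth(trk, 3000)
  expect_equal(nrow(call_amplified_segments(bins, baseline = 4)), 0)
  expect_error(call_amplified_segments(bins, baseline = 4, min_fold = 1),
               "min_fold")

  # two hot runs separated by 2 cold bins merge at merge_gap = 2
  d <- rep(4, 20); d[5:7] <- 40; d[10:12] <- 40
  bins2 <- tibble::tibble(chrom = "c1",
                          start = (0:19) * 3000 + 1, end = (1:20) * 3000,
                          depth = d, log2_depth = log2(d))
  merged <- call_amplified_segments(bins2, baseline = 4, merge_gap = 2)
  expect_equal(nrow(merged), 1)
  split <- call_amplified_segments(bins2, baseline = 4, merge_gap = 1)
  expect_equal(nrow(split), 2)
})

test_that("amplified length summary reproduces printed region totals", {
  segs <- published_amplified_segments()
  tot <- amplified_length_summary(segs)
  expect_equal(tot$total_bp[tot$chrom == "chr7"], 940e3)  # ~940 kb
  expect_equal(tot$total_bp[tot$chrom == "chr8"], 4.70e6) # ~4.7 Mb
  expect_equal(nrow(amplified_length_summary(segs[0, ])), 0)
})

test_that("amplified comparison obeys set identities", {
  a <- published_amplified_segments()
  same <- compare_amplified_segments(a, a)
  expect_true(all(same$summary$fraction_lost == 0))

  none <- compare_amplified_segments(a, a[0, ])
  expect_true(all(none$summary$fraction_lost == 1))

  withr::local_seed(8)
  for (rep in 1:20) {
    mk <- function() {
      s <- sort(sample.int(1e5, 6))
      tibble::tibble(chrom = "c", start = s[c(1, 3, 5)] ,
                     end = s[c(1, 3, 5)] + sample.int(5000, 3))
    }
    x <- mk(); y <- mk()
    cmp <- compare_amplified_segments(x, y)
    # |retained| + |lost| = |A| exactly
    expect_equal(cmp$summary$bp_retained + cmp$summary$bp_lost,
                 cmp$summary$bp_a)
  }
})

test_that("segmentation is idempotent on a rebuilt track", {
  sim <- simulate_amplicon(small_sim_config(seed = 42))
  obs <- sim_observables(sim, noise = FALSE)
  bins <- bin_depth(obs$depth, 3000, c(cA = 2e5))
  segs <- call_amplified_segments(bins, baseline = 3)
  trk2 <- segments_to_track(segs, baseline = 3, c(cA = 2e5))
  segs2 <- call_amplified_segments(bin_depth(trk2, 3000, c(cA = 2e5)),
                                   baseline = 3)
  expect_equal(segs2[c("chrom", "start", "end")],
               segs[c("chrom", "start", "end")])
})

test_that("passage loss measured on noiseless tracks matches truth", {
  sim <- simulate_amplicon(small_sim_config(seed = 43))
  p4 <- simulate_passage(sim, loss_prob = 0.5, new_break_rate = 0)
  o2 <- sim_observables(sim, noise = FALSE)
  o4 <- sim_observables(p4, noise = FALSE)
  cmp <- compare_amplified_segments(o2$amplified, o4$amplified)
  frag <- p4$fragments[p4$fragments$fate %in% c("lost", "retained"), ]
  truth_lost <- sum((frag$end - frag$start + 1)[frag$fate == "lost"])
  truth_all <- sum(frag$end - frag$start + 1)
  expect_equal(sum(cmp$summary$bp_lost) / sum(cmp$summary$bp_a),
               truth_lost / truth_all)
})
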