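# Generator: determinism, base composition, join statistics, passage fates.

test_that("genome simulation is deterministic and hits the GC target", {
  g1 <- simulate_genome(c(c1 = 10000), 0.5, seed = 1)
  g2 <- simulate_genome(c(c1 = 10000), 0.5, seed = 1)
  expect_identical(g1, g2)

  g <- simulate_genome(c(c1 = 1e6), 0.5, seed = 2)
  gc <- mean(strsplit(g[["c1"]], "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 0.5), 0.003)   # ~6 sigma for a 1 Mb binomial

  expect_error(simulate_genome(c(c1 = 10000), 1.0, seed = 1), "gc_fraction")
  expect_error(simulate_genome(c(c1 = 500), 0.5, seed = 1), "1 kb")
})

test_that("the same seed reproduces the whole simulation bit-for-bit", {
  s1 <- simulate_amplicon(small_sim_config(seed = 4))
  s2 <- simulate_amplicon(small_sim_config(seed = 4))
  expect_identical(s1$genome, s2$genome)
  expect_equal(as.data.frame(s1$fragments), as.data.frame(s2$fragments))
  expect_equal(as.data.frame(s1$junctions), as.data.frame(s2$junctions))
})

test_that("every emitted junction's microhomology is recomputable", {
  for (sd in c(21, 22, 23)) {
    sim <- simulate_amplicon(small_sim_config(seed = sd))
    obs <- sim_observables(sim, noise = FALSE)
    ch <- characterize_junctions(obs$junctions, sim$genome)
    expect_equal(ch$mh_len, sim$junctions$mh_len)
    expect_equal(ch$inserted_seq, sim$junctions$inserted_seq)
  }
})

test_that("p_insertion = 1 gives every join an insert and zero mh", {
  sim <- simulate_amplicon(small_sim_config(seed = 7, p_insertion = 1))
  expect_true(all(nchar(sim$junctions$inserted_seq) > 0))
  expect_true(all(sim$junctions$mh_len == 0))
})

test_that("with no bias the mh>=1 fraction matches the 43.75% null", {
  # many singleton breaks, no clusters, beta = 0: realized joins are a
  # draw from the random-joining null
  cfg <- sim_config(
    chrom_lengths = c(cA = 3e6),
    source_regions = tibble::tibble(chrom = "cA", start = 1000,
                                    end = 2999000),
    n_clusters = 0, singletons_per_region = 2000,
    mh_bias = 0, p_insertion = 0, p_fragment_drop = 0, seed = 31)
  sim <- simulate_amplicon(cfg)
  expect_gt(nrow(sim$junctions), 1500)
  frac <- mean(sim$junctions$mh_len >= 1)
  expect_lt(abs(frac - 0.4375), 0.04)  # ~3.2 sigma at n ~ 2000
})

test_that("mh bias enriches microhomology with power >= 0.9 at n = 100", {
  reject <- logical(15)
  for (i in seq_along(reject)) {
    cfg <- sim_config(
      chrom_lengths = c(cA = 2e6),
      source_regions = tibble::tibble(chrom = "cA", start = 1000,
                                      end = 1999000),
      n_clusters = 0, singletons_per_region = 100,
      mh_bias = 2, p_insertion = 0, p_fragment_drop = 0, seed = 400 + i)
    sim <- simulate_amplicon(cfg)
    mh <- sim$junctions$mh_len[seq_len(min(100, nrow(sim$junctions)))]
    reject[i] <- mh_enrichment_test(mh)$p.value < 0.05
  }
  expect_gte(mean(reject), 0.9)
})

test_that("passage transition edge cases and loss calibration behave", {
  sim <- simulate_amplicon(small_sim_config(seed = 9))

  frozen <- simulate_passage(sim, loss_prob = 0, new_break_rate = 0)
  expect_setequal(frozen$junctions$id, sim$junctions$id)
  expect_true(all(frozen$junctions$fate == "retained"))

  wiped <- simulate_passage(sim, loss_prob = 1)
  expect_true(wiped$empty)
  expect_true(all(wiped$lost_junctions$fate == "lost"))
  expect_equal(nrow(wiped$junctions), 0)
})

test_that("fragment loss matches the configured probability", {
  # ~1000 fragments via dense singleton breaks; beta 0 keeps joining cheap
  cfg <- sim_config(
    chrom_lengths = c(cA = 3e6),
    source_regions = tibble::tibble(chrom = "cA", start = 1000,
                                    end = 2999000),
    n_clusters = 0, singletons_per_region = 1000,
    mh_bias = 0, p_fragment_drop = 0, seed = 77,
    passage_loss_prob = 0.4, passage_new_break_rate = 0)
  sim <- simulate_amplicon(cfg)
  p4 <- simulate_passage(sim)
  considered <- p4$fragments[p4$fragments$fate %in% c("lost", "retained"), ]
  expect_gt(nrow(considered), 900)
  lost_frac <- mean(considered$fate == "lost")
  expect_lt(abs(lost_frac - 0.4), 0.05)  # ~3 sigma binomial at n ~ 1000
})

test_that("noiseless depth equals baseline + copy_number x depth_per_copy", {
  sim <- simulate_amplicon(small_sim_config(seed = 13))
  obs <- sim_observables(sim, depth_per_copy = 2, baseline = 3,
                         noise = FALSE)
  frag <- sim$fragments[!sim$fragments$dropped, ]
  mid <- floor((frag$start[1] + frag$end[1]) / 2)
  expect_equal(depth_at(obs$depth, frag$chrom[1], mid),
               3 + frag$copy_number[1] * 2)
  # a position outside any source region sits at baseline
  expect_equal(depth_at(obs$depth, "cA", 5000), 3)
  expect_error(sim_observables(sim, depth_per_copy = 0), "depth_per_copy")
})

test_that("read support scales linearly with copy number", {
  slopes <- vapply(c(51, 52, 53), function(sd) {
    sim <- simulate_amplicon(small_sim_config(seed = sd))
    obs <- sim_observables(sim, support_per_copy = 2, noise = TRUE)
    cn <- setNames(sim$fragments$copy_number, sim$fragments$frag_id)
    jx_cn <- (cn[sim$junctions$frag_a] + cn[sim$junctions$frag_b]) / 2
    unname(coef(lm(obs$junctions$support ~ 0 + jx_cn))[1])
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 2), 0.25)
})
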