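# Arm links, contig assembly, coordinated pairs.

test_that("facing breakends link with the published fragment arithmetic", {
  # the two arms bounding the 61 bp contig fragment: lower breakend retains
  # rightwards, higher retains leftwards
  jx <- junction_table(
    id = c("j11", "j16"),
    chrom1 = "chr7", pos1 = c(54668755, 54668816),
    orient1 = c("-", "+"),
    chrom2 = "chr7", pos2 = c(60000000, 61000000), orient2 = c("+", "-"),
    support = 5)
  links <- build_arm_links(jx, max_link = 5000)
  expect_equal(nrow(links), 1)
  expect_equal(links$frag_len, 61)
  expect_equal(links$id_low, "j11")
  expect_equal(links$id_high, "j16")

  # two same-orientation arms 50 bp apart are incompatible
  same <- junction_table(
    id = c("a", "b"),
    chrom1 = "chr7", pos1 = c(1000, 1050), orient1 = c("+", "+"),
    chrom2 = "chr7", pos2 = c(5e6, 6e6), orient2 = c("-", "-"), support = 5)
  expect_equal(nrow(build_arm_links(same, max_link = 5000)), 0)
})

test_that("simulated link sets contain the truth adjacency", {
  sim <- simulate_amplicon(small_sim_config(seed = 91))
  obs <- sim_observables(sim, noise = FALSE)
  links <- build_arm_links(obs$junctions, max_link = Inf)
  # every fragment bounded by two junctions must appear as a link
  frag <- sim$fragments[!sim$fragments$dropped, ]
  jx <- sim$junctions
  for (i in seq_len(nrow(frag))) {
    ja <- jx$id[(jx$frag_a == frag$frag_id[i] & jx$end_a == "L") |
                  (jx$frag_b == frag$frag_id[i] & jx$end_b == "L")]
    jb <- jx$id[(jx$frag_a == frag$frag_id[i] & jx$end_a == "R") |
                  (jx$frag_b == frag$frag_id[i] & jx$end_b == "R")]
    if (length(ja) == 1 && length(jb) == 1 && ja != jb) {
      hit <- (links$id_low %in% c(ja, jb)) & (links$id_high %in% c(ja, jb)) &
        links$start == frag$start[i] & links$end == frag$end[i]
      expect_true(any(hit))
    }
  }
})

test_that("assembly recovers planted chains exactly across 50 seeds", {
  exact <- logical(50)
  for (i in seq_along(exact)) {
    cfg <- small_sim_config(seed = 1000 + i)
    sim <- simulate_amplicon(cfg)
    obs <- sim_observables(sim, noise = FALSE)
    contigs <- assemble_contigs(build_arm_links(obs$junctions,
                                                max_link = Inf),
                                obs$junctions)
    truth <- truth_contigs(sim)
    # contigs are chains of two or more junctions; a lone self-closed
    # fragment has one junction and no internal fragment to link through
    truth <- truth[lengths(truth$junction_ids) >= 2, ]
    got <- sort(vapply(seq_len(nrow(contigs)), function(r) {
      canon_chain(contigs$junction_ids[[r]], contigs$circular[r])
    }, character(1)))
    want <- sort(vapply(seq_len(nrow(truth)), function(r) {
      canon_chain(truth$junction_ids[[r]], truth$circular[r])
    }, character(1)))
    exact[i] <- identical(got, want)
  }
  expect_equal(mean(exact), 1.0)
})

test_that("circular amplicons are flagged and counted correctly", {
  # a planted circle: junction count equals fragment count
  cfg <- small_sim_config(seed = 1101, n_clusters = 2,
                          singletons_per_region = 0)
  sim <- simulate_amplicon(cfg)
  obs <- sim_observables(sim, noise = FALSE)
  contigs <- assemble_contigs(build_arm_links(obs$junctions,
                                              max_link = Inf),
                              obs$junctions)
  circ <- contigs[contigs$circular, ]
  expect_gt(nrow(circ), 0)
  for (r in seq_len(nrow(circ))) {
    expect_equal(length(circ$junction_ids[[r]]),
                 length(circ$frag_lengths[[r]]))
  }
  expect_equal(nrow(assemble_contigs(build_arm_links(obs$junctions[0, ],
                                                     5000),
                                     obs$junctions)), 0)
})

test_that("assembly is deterministic under input permutation", {
  sim <- simulate_amplicon(small_sim_config(seed = 93))
  obs <- sim_observables(sim, noise = FALSE)
  links <- build_arm_links(obs$junctions, max_link = Inf)
  c1 <- assemble_contigs(links, obs$junctions)
  perm <- obs$junctions[rev(seq_len(nrow(obs$junctions))), ]
  c2 <- assemble_contigs(build_arm_links(perm, max_link = Inf), perm)
  key <- function(ct) sort(vapply(seq_len(nrow(ct)), function(r) {
    canon_chain(ct$junction_ids[[r]], ct$circular[r])
  }, character(1)))
  expect_identical(key(c1), key(c2))
})

test_that("emitted fragment lengths equal breakend arithmetic globally", {
  sim <- simulate_amplicon(small_sim_config(seed = 94))
  obs <- sim_observables(sim, noise = FALSE)
  links <- build_arm_links(obs$junctions, max_link = Inf)
  expect_true(all(links$frag_len == links$end - links$start))
  contigs <- assemble_contigs(links, obs$junctions)
  expect_true(all(unlist(contigs$frag_lengths) >= 0))
})

test_that("replaying the published contig table gives the printed summary", {
  pub <- published_contigs()
  s <- contig_summary(pub)
  expect_equal(s$stats$frac_blunt, 0.5)        # 28 of 56 printed values
  # "higher than 2 bp in only 10% of cases": 6/56 = 10.7%, printed as 10%
  expect_gte(s$stats$frac_mh_gt2, 0.10)
  expect_lt(s$stats$frac_mh_gt2, 0.11)
  # the long mixed contig holds four large segments above 10 kb
  c18 <- pub[pub$contig == "18", ]
  expect_equal(sum(c18$frag_lengths[[1]] > 1e4), 4)
})

test_that("coordinated junction pairs are detected by their geometry", {
  # arms co-located at two loci 500 kb apart
  jx <- junction_table(
    id = c("p1", "p2", "lonely"),
    chrom1 = "c1", pos1 = c(1000000, 1000126, 3000000),
    orient1 = c("+", "+", "+"),
    chrom2 = "c1", pos2 = c(1500000, 1500082, 7000000),
    orient2 = c("-", "-", "-"),
    support = 5)
  pairs <- find_coordinated_pairs(jx, max_intra = 2000, min_inter = 1e5)
  expect_equal(nrow(pairs), 1)
  expect_setequal(c(pairs$id1, pairs$id2), c("p1", "p2"))
  expect_equal(pairs$d_x, 126)
  expect_equal(pairs$d_y, 82)
  expect_equal(pairs$separation, 5e5)

  # co-location at only one end is not enough
  one_end <- junction_table(
    id = c("q1", "q2"),
    chrom1 = "c1", pos1 = c(1000000, 1000100), orient1 = "+",
    chrom2 = "c1", pos2 = c(1500000, 2500000), orient2 = "-",
    support = 5)
  expect_equal(nrow(find_coordinated_pairs(one_end)), 0)
})

test_that("planted coordinated pairs are recovered without false calls", {
  withr::local_seed(55)
  base <- junction_table(
    id = paste0("bg", 1:10),
    chrom1 = "c1", pos1 = sort(sample.int(9e6, 10)), orient1 = "+",
    chrom2 = "c1", pos2 = 1e7 + sort(sample.int(9e6, 10)) * 3, orient2 = "-",
    support = 5)
  planted <- junction_table(
    id = c("t1", "t2"),
    chrom1 = "c1", pos1 = c(41000000, 41000300), orient1 = "+",
    chrom2 = "c1", pos2 = c(43000000, 43000450), orient2 = "-",
    support = 5)
  pairs <- find_coordinated_pairs(dplyr::bind_rows(base, planted),
                                  max_intra = 2000, min_inter = 1e5)
  expect_true(any(pairs$id1 == "t1" & pairs$id2 == "t2"))
  # background arms are far apart, so the planted pair is the only call
  expect_equal(nrow(pairs), 1)
})
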