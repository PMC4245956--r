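# End-to-end orchestration and fixture generation.

PIPELINE_KEYS <- c("reference", "junctions", "samples", "depth", "amplified",
                   "out_dir", "bin_size", "min_fold", "merge_gap", "min_len",
                   "baseline", "min_support", "max_gap", "max_link", "tol",
                   "max_intra", "min_inter", "composition", "seed")

#' Assemble a pipeline configuration
#'
#' Validates paths and parameters for [run_pipeline()]. Unknown keys are
#' rejected so typos cannot silently disable a stage.
#'
#' @param reference path to the reference FASTA.
#' @param junctions character vector of one or two junction TSV paths (two
#'   = earlier and later passage).
#' @param samples sample names, parallel to `junctions`.
#' @param depth optional bedGraph path (one per sample or a single shared
#'   track); required unless `amplified` is given.
#' @param amplified optional BED of amplified regions; called from `depth`
#'   when absent.
#' @param out_dir output directory.
#' @param bin_size,min_fold,merge_gap,min_len,baseline coverage parameters
#'   (see [bin_depth()], [call_amplified_segments()]).
#' @param min_support junction support filter (see [filter_junctions()]).
#' @param max_gap clustering gap, bp.
#' @param max_link contig linking pass, bp.
#' @param tol junction matching tolerance, bp.
#' @param max_intra,min_inter coordinated-pair thresholds, bp.
#' @param composition optional base composition for the null model.
#' @param seed integer seed.
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(reference, junctions, samples = NULL,
                            depth = NULL, amplified = NULL,
                            out_dir = "amprearr_out", bin_size = 3000,
                            min_fold = 3, merge_gap = 2, min_len = 2,
                            baseline = NULL, min_support = 3,
                            max_gap = 2000, max_link = 5000, tol = 0,
                            max_intra = 2000, min_inter = 1e5,
                            composition = NULL, seed = 1) {
  cfg <- list(reference = reference, junctions = junctions,
              samples = samples %||% paste0("s", seq_along(junctions)),
              depth = depth, amplified = amplified, out_dir = out_dir,
              bin_size = bin_size, min_fold = min_fold,
              merge_gap = merge_gap, min_len = min_len, baseline = baseline,
              min_support = min_support, max_gap = max_gap,
              max_link = max_link, tol = tol, max_intra = max_intra,
              min_inter = min_inter, composition = composition, seed = seed)
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  unknown <- setdiff(names(cfg), PIPELINE_KEYS)
  if (length(unknown) > 0) {
    abort(paste0("unknown pipeline config keys: ",
                 paste(unknown, collapse = ", ")))
  }
  if (is.null(cfg$reference)) abort("config requires a reference FASTA path")
  if (length(cfg$junctions) < 1 || length(cfg$junctions) > 2) {
    abort("config requires one or two junction tables")
  }
  if (length(cfg$samples) != length(cfg$junctions)) {
    abort("samples must parallel the junction tables")
  }
  if (is.null(cfg$depth) && is.null(cfg$amplified)) {
    abort("config requires depth tracks or an amplified-region BED")
  }
  structure(cfg, class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ",
                 conditionMessage(e)))
  })
}

#' Run the full junction-characterization pipeline
#'
#' Stages: read inputs, call amplified segments from depth (unless
#' supplied), filter junctions by support and amplified overlap,
#' characterize seams (microhomology, insertions), test microhomology
#' enrichment against the random-joining null, cluster breakpoints, build
#' arm links and assemble contigs, detect coordinated pairs, and (with two
#' samples) compare the junction sets and amplified intervals across
#' passages. All tables are written as TSV/BED into `out_dir` together with
#' the resolved configuration; reruns with the same config and seed are
#' byte-identical.
#'
#' @param config a `pipeline_config` (or a path to a YAML file holding
#'   one).
#' @param quiet suppress progress messages.
#' @return invisibly, a list with all stage results (`amplified`, `bins`,
#'   per-sample `junctions`, `enrichment`, `clusters`, `contigs`, `pairs`,
#'   `comparison`, `summary`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) {
    raw <- yaml::read_yaml(config)
    unknown <- setdiff(names(raw), PIPELINE_KEYS)
    if (length(unknown) > 0) {
      abort(paste0("unknown pipeline config keys: ",
                   paste(unknown, collapse = ", ")))
    }
    for (k in c("junctions", "samples", "depth")) {
      if (!is.null(raw[[k]])) raw[[k]] <- unlist(raw[[k]])
    }
    cfg <- do.call(pipeline_config, raw)  # fills defaults
  } else {
    cfg <- validate_pipeline_config(config)
  }
  say <- function(...) if (!quiet) message(...)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(cfg[!vapply(cfg, is.null, logical(1))],
                   file.path(cfg$out_dir, "config_used.yaml"))

  genome <- stage("reference", read_genome(cfg$reference))
  say("reference: ", length(genome), " contig(s)")

  bins <- NULL
  amplified <- NULL
  if (!is.null(cfg$depth)) {
    track <- stage("depth", read_depth_track(cfg$depth[[1]]))
    bins <- bin_depth(track, cfg$bin_size,
                      setNames(nchar(genome), names(genome)))
    baseline <- cfg$baseline %||% estimate_baseline(bins)
    amplified <- stage("amplified", call_amplified_segments(
      bins, baseline, cfg$min_fold, cfg$merge_gap, cfg$min_len))
    say("amplified: ", nrow(amplified), " segment(s), baseline ", baseline)
    readr::write_tsv(bins, file.path(cfg$out_dir, "coverage_bins.tsv"),
                     progress = FALSE)
  }
  if (!is.null(cfg$amplified)) {
    amplified <- stage("amplified", read_bed(cfg$amplified))
  }
  write_bed(amplified, file.path(cfg$out_dir, "amplified.bed"))

  per_sample <- list()
  for (i in seq_along(cfg$junctions)) {
    sm <- cfg$samples[i]
    jx <- stage("junctions", read_junctions(cfg$junctions[[i]]))
    say(sm, ": ", nrow(jx), " raw junction(s)")
    jx <- filter_junctions(jx, amplified, cfg$min_support)
    jx <- stage("characterize", characterize_junctions(jx, genome))
    say(sm, ": ", nrow(jx), " filtered/characterized junction(s)")
    readr::write_tsv(
      select(jx, -dplyr::any_of("span_seq")),
      file.path(cfg$out_dir, paste0("junctions_", sm, ".tsv")),
      progress = FALSE)
    per_sample[[sm]] <- jx
  }
  all_jx <- bind_rows(per_sample) %>% distinct(.data$id, .keep_all = TRUE)

  insfree <- all_jx$mh_len[all_jx$insertion_len == 0]
  enr <- stage("enrichment", mh_enrichment_test(insfree, cfg$composition))
  readr::write_tsv(tidy(enr), file.path(cfg$out_dir, "mh_table.tsv"),
                   progress = FALSE)
  say(sprintf("microhomology: %.1f%% vs %.2f%% expected (p = %.3g)",
              100 * enr$estimate, 100 * enr$null_p, enr$p.value))

  clustered <- stage("cluster", cluster_breakpoints(
    junction_breakends(all_jx), cfg$max_gap))
  clusters <- cluster_summary(clustered)
  readr::write_tsv(select(clusters, -"positions", -"gaps"),
                   file.path(cfg$out_dir, "clusters.tsv"), progress = FALSE)
  say("clusters: ", nrow(clusters), " (",
      round(100 * clustered_fraction(clustered)), "% of breakends clustered)")

  links <- stage("contigs", build_arm_links(all_jx, cfg$max_link))
  contigs <- assemble_contigs(links, all_jx)
  csum <- contig_summary(contigs)
  readr::write_tsv(csum$table, file.path(cfg$out_dir, "contigs.tsv"),
                   progress = FALSE)
  say("contigs: ", nrow(contigs))

  pairs <- stage("pairs", find_coordinated_pairs(all_jx, cfg$max_intra,
                                                 cfg$min_inter))
  readr::write_tsv(pairs, file.path(cfg$out_dir, "coordinated_pairs.tsv"),
                   progress = FALSE)

  comparison <- NULL
  if (length(per_sample) == 2) {
    cmp <- stage("compare", match_junctions(per_sample[[1]],
                                            per_sample[[2]], cfg$tol))
    comparison <- comparison_summary(cmp, per_sample[[1]], per_sample[[2]])
    readr::write_tsv(tidy(cmp), file.path(cfg$out_dir, "junction_fates.tsv"),
                     progress = FALSE)
    say("compare: ", cmp$counts$shared, " shared, ", cmp$counts$lost,
        " lost, ", cmp$counts$gained, " gained")
  }

  summary_tbl <- tibble(
    stat = c("n_junctions", "n_clusters", "clustered_fraction", "n_contigs",
             "n_coordinated_pairs", "frac_mh_insfree", "enrichment_p"),
    value = c(nrow(all_jx), nrow(clusters),
              clustered_fraction(clustered), nrow(contigs), nrow(pairs),
              enr$estimate, enr$p.value))
  readr::write_tsv(summary_tbl, file.path(cfg$out_dir, "summary.tsv"),
                   progress = FALSE)

  invisible(list(amplified = amplified, bins = bins, junctions = per_sample,
                 enrichment = enr, clustered = clustered,
                 clusters = clusters, links = links, contigs = contigs,
                 pairs = pairs, comparison = comparison,
                 summary = summary_tbl))
}

#' Write a deterministic miniature two-passage dataset
#'
#' Simulates a small two-chromosome amplicon (dmin state), applies the
#' passage transition (hsr state), and writes every pipeline input format:
#' reference FASTA, per-passage junction TSVs, bedGraph depth tracks,
#' amplified-region BEDs, and truth tables. Also returns the paths of the
#' packaged published worked-example tables.
#'
#' @param dir output directory.
#' @param seed integer seed; the same seed reproduces the dataset
#'   byte-for-byte.
#' @return invisibly, a named list of file paths plus the two `amplicon_sim`
#'   truth objects.
#' @export
make_fixtures <- function(dir = tempfile("amprearr_fix"), seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- sim_config(seed = seed)
  sim2 <- simulate_amplicon(cfg)
  sim4 <- simulate_passage(sim2)
  obs2 <- sim_observables(sim2, sample_name = "p2", seed = cfg$seed + 10L)
  obs4 <- sim_observables(sim4, sample_name = "p4", seed = cfg$seed + 11L)
  paths <- list(
    reference = file.path(dir, "reference.fa"),
    junctions_p2 = file.path(dir, "junctions_p2.tsv"),
    junctions_p4 = file.path(dir, "junctions_p4.tsv"),
    depth_p2 = file.path(dir, "depth_p2.bedGraph"),
    depth_p4 = file.path(dir, "depth_p4.bedGraph"),
    amplified_p2 = file.path(dir, "amplified_p2.bed"),
    amplified_p4 = file.path(dir, "amplified_p4.bed"),
    truth_fragments_p2 = file.path(dir, "truth_fragments_p2.tsv"),
    truth_fragments_p4 = file.path(dir, "truth_fragments_p4.tsv"),
    truth_junctions_p2 = file.path(dir, "truth_junctions_p2.tsv"),
    truth_junctions_p4 = file.path(dir, "truth_junctions_p4.tsv"))
  write_genome(sim2$genome, paths$reference)
  write_junctions(obs2$junctions, paths$junctions_p2)
  write_junctions(obs4$junctions, paths$junctions_p4)
  write_depth_track(obs2$depth, paths$depth_p2)
  write_depth_track(obs4$depth, paths$depth_p4)
  write_bed(obs2$amplified, paths$amplified_p2)
  write_bed(obs4$amplified, paths$amplified_p4)
  readr::write_tsv(sim2$fragments, paths$truth_fragments_p2, progress = FALSE)
  readr::write_tsv(sim4$fragments, paths$truth_fragments_p4, progress = FALSE)
  readr::write_tsv(sim2$junctions, paths$truth_junctions_p2, progress = FALSE)
  readr::write_tsv(bind_rows(sim4$junctions, sim4$lost_junctions),
                   paths$truth_junctions_p4, progress = FALSE)
  paths$published_clusters <- pkg_extdata("oda14p2_chr7_clusters.tsv")
  paths$published_new_breakpoints <-
    pkg_extdata("oda14p4_chr7_new_breakpoints.tsv")
  paths$published_contigs <- pkg_extdata("oda14_contigs.tsv")
  paths$published_amplified <- pkg_extdata("oda14p2_amplified_segments.tsv")
  invisible(c(paths, list(sim_p2 = sim2, sim_p4 = sim4)))
}
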