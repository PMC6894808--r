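#' Run the full pipeline
#'
#' Computational twin of the wet protocol: synthesise the phased genome,
#' simulate the selection experiment, genotype and map the surviving
#' clones, simulate and segment their array profiles, and write all
#' stage outputs plus a run manifest. The run is a pure function of
#' (config, seed): manifests and outputs are byte-identical across
#' reruns.
#'
#' Outputs written to `out_dir`: `clones.tsv` (one row per surviving
#' clone with bands, class, inferred point and truth), `panel.tsv`
#' (SNP x clone call matrix of the positive clones), `crossover_points.tsv`,
#' `segments.bed` (array segmentation of mapped crossover clones, BED
#' 0-based half-open), `truth.bed` (true breakpoints), `summary.json`
#' and `manifest.json`.
#'
#' @param run_config Named list (or YAML path) with fields `preset`,
#'   `dsb_label`, `snp_density`, `seed`, `panel_k`, `array` (list:
#'   `noise_sd_baf`, `noise_sd_lrr`, `window`, `max_clones`) and `config`
#'   (overrides for [experiment_config()]).
#' @param out_dir Output directory (created).
#' @return The run manifest (invisibly a list, also written as JSON).
#' @export
run_pipeline <- function(run_config, out_dir) {
  rc <- if (is.character(run_config)) yaml::read_yaml(run_config)
        else run_config
  defaults <- list(preset = "chr19_aavs1", dsb_label = "9M",
                   snp_density = 1 / 5000, seed = 1, panel_k = 3,
                   array = list(noise_sd_baf = 0.05, noise_sd_lrr = 0.15,
                                window = 25, max_clones = 10),
                   config = list())
  rc <- utils::modifyList(defaults, rc)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  genome <- stage("synth", make_genome(rc$preset, rc$snp_density, rc$seed))
  cfg <- stage("config", make_cohort_config(
    rc$preset, utils::modifyList(rc$config, list(seed = rc$seed))))
  cohort <- stage("simulate", simulate_experiment(genome, rc$dsb_label, cfg))
  chrom <- cohort$chrom
  panel <- panel_positions(genome, chrom)
  mapped <- stage("map", map_cohort(cohort, panel, k = rc$panel_k))

  # per-clone smoothed panel matrix for the positive clones (Fig-2C-style)
  set.seed(substream_seed(cfg$seed, "genotype"))
  pos_idx <- which(vapply(cohort$clones, `[[`, TRUE, "positive"))
  calls_list <- lapply(cohort$clones, function(cl)
    smooth_panel(genotype_panel(cl$daughter, panel, cfg$genotype_error),
                 rc$panel_k))
  panel_mat <- if (length(pos_idx)) {
    m <- vapply(calls_list[pos_idx], function(cc)
      ifelse(cc$call == "het", "het", "LOH"), character(length(panel)))
    m <- matrix(m, nrow = length(panel),
                dimnames = list(NULL,
                  vapply(cohort$clones[pos_idx], `[[`, "", "id")))
    data.frame(pos = panel, m, check.names = FALSE)
  } else data.frame(pos = numeric(0))

  # array profiles + segmentation for mapped crossover clones
  arr <- rc$array
  xo_idx <- which(!is.na(mapped$point))[
    seq_len(min(arr$max_clones, sum(!is.na(mapped$point))))]
  set.seed(substream_seed(cfg$seed, "array"))
  segs <- do.call(rbind, lapply(xo_idx, function(i) {
    prof <- simulate_baf_lrr(cohort$clones[[i]]$daughter, panel,
                             arr$noise_sd_baf, arr$noise_sd_lrr)
    sg <- segment_loh(prof, arr$window)
    data.frame(chrom = chrom, start = sg$start, end = sg$end,
               class = paste0(mapped$id[i], ":", sg$class),
               stringsAsFactors = FALSE)
  }))

  clones_path <- file.path(out_dir, "clones.tsv")
  utils::write.table(mapped, clones_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  panel_path <- file.path(out_dir, "panel.tsv")
  utils::write.table(panel_mat, panel_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  xo_path <- file.path(out_dir, "crossover_points.tsv")
  xo_tab <- mapped[!is.na(mapped$point),
                   c("id", "point", "side", "distance_bp"), drop = FALSE]
  utils::write.table(xo_tab, xo_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  seg_path <- file.path(out_dir, "segments.bed")
  write_loh_bed(if (is.null(segs)) empty_tracts() else segs, seg_path)
  truth_path <- file.path(out_dir, "truth.bed")
  tb <- mapped[!is.na(mapped$true_breakpoint), , drop = FALSE]
  write_loh_bed(if (nrow(tb)) data.frame(chrom = chrom,
                                         start = tb$true_breakpoint,
                                         end = tb$true_breakpoint,
                                         class = tb$id)
                else empty_tracts(), truth_path)

  ct <- cohort$counters
  summary <- list(
    preset = rc$preset, dsb_label = rc$dsb_label, seed = rc$seed,
    counters = ct,
    class_counts = as.list(table(mapped$class)),
    per_side = if (nrow(mapped)) summarize_safe(mapped, ct$n_cells) else NULL)
  sum_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, sum_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")

  # counter algebra must hold on every run
  stopifnot(ct$n_survivors >= ct$n_positive,
            ct$n_positive >= sum(mapped$class == "crossover"))

  outputs <- c(clones_path, panel_path, xo_path, seg_path, truth_path,
               sum_path)
  manifest <- list(
    config = rc, seed = rc$seed, counters = ct,
    digests = as.list(tools::md5sum(outputs)))
  names(manifest$digests) <- basename(outputs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

empty_tracts <- function() {
  data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
             class = character(0))
}

summarize_safe <- function(mapped, n_cells) {
  s <- summarize_cohort(mapped, n_cells)
  list(counts = as.list(s$counts),
       centromeric = s$per_side$centromeric,
       telomeric = s$per_side$telomeric,
       n_spanning = s$n_spanning,
       efficiency = s$efficiency)
}

#' Human-readable replay report
#'
#' Renders class counts, the per-side distance table, panel dimensions
#' and, for the chr6p design, the per-locus HLA genotype table of mapped
#' crossover clones.
#'
#' @param out_dir A directory written by [run_pipeline()].
#' @param genome Optional [phased_genome()]; needed for the HLA table.
#' @param cohort Optional cohort (same run) for the HLA table.
#' @return Character vector of report lines (also printed).
#' @export
replay_report <- function(out_dir, genome = NULL, cohort = NULL) {
  summary <- jsonlite::read_json(file.path(out_dir, "summary.json"))
  lines <- c(sprintf("LOH induction replay: preset %s, DSB %s, seed %s",
                     summary$preset, summary$dsb_label, summary$seed),
             sprintf("cells %s | survivors %s | positive %s",
                     summary$counters$n_cells, summary$counters$n_survivors,
                     summary$counters$n_positive))
  if (length(summary$class_counts)) {
    lines <- c(lines, "clone classes:",
               vapply(names(summary$class_counts), function(nm)
                 sprintf("  %-22s %s", nm, summary$class_counts[[nm]]), ""))
  } else lines <- c(lines, "no positive clones; no panel to report")
  ps <- summary$per_side
  if (!is.null(ps)) {
    for (s in c("centromeric", "telomeric")) {
      v <- ps[[s]]
      if (!is.null(v) && v$n > 0)
        lines <- c(lines, sprintf(
          "  %s crossovers: n=%s mean %.1f kb median %.1f kb",
          s, v$n, as.numeric(v$mean_kb), as.numeric(v$median_kb)))
    }
  }
  panel <- utils::read.table(file.path(out_dir, "panel.tsv"), header = TRUE,
                             sep = "\t", check.names = FALSE, nrows = 1)
  lines <- c(lines, sprintf("panel matrix: %d SNPs x %d positive clones",
                            if (ncol(panel) > 1 || nrow(panel) > 0)
                              length(utils::count.fields(
                                file.path(out_dir, "panel.tsv"))) - 1 else 0,
                            max(0, ncol(panel) - 1)))
  if (!is.null(genome) && !is.null(cohort)) {
    hla <- genome_feature(genome, "hla_locus")
    if (nrow(hla)) {
      pos_clones <- Filter(function(cl) cl$positive, cohort$clones)
      if (length(pos_clones)) {
        rep1 <- hla_report(pos_clones[[1]]$daughter, hla)
        lines <- c(lines, sprintf("HLA genotypes (clone %s):",
                                  pos_clones[[1]]$id),
                   vapply(seq_len(nrow(rep1)), function(i)
                     sprintf("  %-5s %s/%s %s", rep1$locus[i],
                             rep1$allele1[i], rep1$allele2[i],
                             ifelse(rep1$homozygous[i], "homozygous",
                                    "heterozygous")), ""))
      }
    }
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
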