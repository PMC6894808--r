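#' Genome presets
#'
#' Geometry for the two experimental designs and a toy chromosome.
#' `chr19_aavs1`: a 58.6 Mb q-arm design with the selection cassette at a
#' safe-harbor-like site (55.1 Mb) and three allele-specific DSB sites 9,
#' 14 and 19 Mb telomeric of the centromere edge, all centromeric to the
#' cassette. `chr6p_hla`: a p-arm design with the cassette near the p
#' telomere (0.2 Mb), the DSB between the HLA class I and class III
#' blocks (31.4 Mb), and HLA-like loci ordered telomere to centromere as
#' A, C, B (class I), a class III locus, then DRB1 and DQB1 (class II).
#' Absolute coordinates approximate the human reference and are
#' conventional; only the relative geometry matters to the model.
#'
#' The cassette carrier and DSB target haplotypes are fixed to hapA and
#' hapB respectively and recorded in the feature table.
#'
#' @param name One of `"chr19_aavs1"`, `"chr6p_hla"`, `"toy"`.
#' @return List with `spec` ([chromosome_spec()]) and `features`.
#' @export
genome_preset <- function(name = c("chr19_aavs1", "chr6p_hla", "toy")) {
  name <- match.arg(name)
  feat <- function(kind, chrom, pos, hap = NA, label = NA,
                   hapA_label = NA, hapB_label = NA) {
    data.frame(kind = kind, chrom = chrom, pos = pos, hap = hap,
               label = label, hapA_label = hapA_label,
               hapB_label = hapB_label, stringsAsFactors = FALSE)
  }
  if (name == "chr19_aavs1") {
    spec <- chromosome_spec("chr19", 58.6e6, 24.5e6, 27.0e6)
    features <- rbind(
      feat("cassette_site", "chr19", 55.1e6, hap = "hapA", label = "AAVS1"),
      feat("dsb_site", "chr19", 27.0e6 + 9e6, hap = "hapB", label = "9M"),
      feat("dsb_site", "chr19", 27.0e6 + 14e6, hap = "hapB", label = "14M"),
      feat("dsb_site", "chr19", 27.0e6 + 19e6, hap = "hapB", label = "19M"))
  } else if (name == "chr6p_hla") {
    spec <- chromosome_spec("chr6", 170.8e6, 59.0e6, 60.5e6)
    features <- rbind(
      feat("cassette_site", "chr6", 0.2e6, hap = "hapA", label = "telHLA"),
      feat("dsb_site", "chr6", 31.4e6, hap = "hapB", label = "HLA-I-III"),
      make_hla_haplotypes())
  } else {
    spec <- chromosome_spec("toy", 1e6, 4.5e5, 4.6e5)
    features <- rbind(
      feat("cassette_site", "toy", 9e5, hap = "hapA", label = "cassette"),
      feat("dsb_site", "toy", 7e5, hap = "hapB", label = "D1"))
  }
  list(name = name, spec = spec, features = features)
}

#' HLA-like locus annotations for the chr6p preset
#'
#' Each locus carries two haplotype labels (per hapA/hapB). The class I
#' loci (A, C, B) lie telomeric to the DSB at 31.4 Mb, the class III
#' locus and the class II loci (DRB1, DQB1) centromeric to it. Default A
#' locus labels are A2 (hapA, the cassette-carrier haplotype whose distal
#' tract is duplicated in positive clones) and A32 (hapB).
#'
#' @param labels Optional named list overriding per-locus label pairs,
#'   e.g. `list(A = c("A24", "A2"))` giving `(hapA_label, hapB_label)`.
#' @return Feature data.frame of `hla_locus` rows.
#' @export
make_hla_haplotypes <- function(labels = list()) {
  def <- list(A = c("A2", "A32"), C = c("Cw5", "Cw7"), B = c("B44", "B40"),
              C4A = c("C4A3", "C4A2"), DRB1 = c("DRB1*04", "DRB1*15"),
              DQB1 = c("DQB1*03", "DQB1*06"))
  pos <- c(A = 29.94e6, C = 31.27e6, B = 31.32e6, C4A = 31.95e6,
           DRB1 = 32.58e6, DQB1 = 32.66e6)
  for (nm in names(labels)) {
    if (!nm %in% names(def)) stop("unknown HLA locus ", nm)
    def[[nm]] <- labels[[nm]]
  }
  do.call(rbind, lapply(names(def), function(nm) {
    data.frame(kind = "hla_locus", chrom = "chr6", pos = pos[[nm]],
               hap = NA, label = nm, hapA_label = def[[nm]][1],
               hapB_label = def[[nm]][2], stringsAsFactors = FALSE)
  }))
}

#' Generate a synthetic phased genome
#'
#' Heterozygous SNP positions are drawn as a Poisson process at the given
#' density outside the centromere; alleles are random distinct bases.
#' Deterministic given `seed`. Stands in for a dbSNP-derived het panel.
#'
#' @param preset A preset name (see [genome_preset()]) or a list with
#'   `spec` and `features`.
#' @param snp_density Het SNPs per bp (default one per 5 kb).
#' @param seed Integer seed.
#' @return A [phased_genome()].
#' @export
make_genome <- function(preset = "chr19_aavs1", snp_density = 1 / 5000,
                        seed = 1) {
  stopifnot(snp_density > 0)
  p <- if (is.character(preset)) genome_preset(preset) else preset
  spec <- p$spec
  set.seed(substream_seed(seed, paste0("genome_", spec$name)))
  arms <- rbind(c(1, spec$cen_start - 1), c(spec$cen_end + 1, spec$length))
  pos <- unlist(lapply(seq_len(nrow(arms)), function(i) {
    len <- arms[i, 2] - arms[i, 1] + 1
    n <- stats::rpois(1, snp_density * len)
    unique(floor(stats::runif(n, arms[i, 1], arms[i, 2] + 1)))
  }))
  pos <- sort(unique(pos))
  pos <- setdiff(pos, p$features$pos)
  bases <- c("A", "C", "G", "T")
  a <- sample(bases, length(pos), replace = TRUE)
  shift <- sample(1:3, length(pos), replace = TRUE)
  b <- bases[(match(a, bases) - 1 + shift) %% 4 + 1]
  snps <- data.frame(chrom = spec$name, pos = pos, allele_hapA = a,
                     allele_hapB = b, stringsAsFactors = FALSE)
  phased_genome(list(spec), snps, p$features)
}

#' Cohort configuration with preset-aware defaults
#'
#' Returns an [experiment_config()] with the study-condition defaults,
#' with named overrides applied. Unknown keys are an error.
#'
#' @param preset Preset name (recorded; defaults are shared).
#' @param overrides Named list of [experiment_config()] fields.
#' @return An `experiment_config`.
#' @export
make_cohort_config <- function(preset = "chr19_aavs1", overrides = list()) {
  base <- experiment_config()
  unknown <- setdiff(names(overrides), names(base))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  args <- utils::modifyList(unclass(base), overrides)
  do.call(experiment_config, args)
}

#' Write an experiment config to YAML
#' @param cfg An [experiment_config()].
#' @param path Output path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Read an experiment config from YAML
#' @param path Path written by [write_config()].
#' @return An `experiment_config`.
#' @export
read_config <- function(path) {
  do.call(experiment_config, yaml::read_yaml(path))
}
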