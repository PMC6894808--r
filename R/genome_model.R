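#' Chromosome specification
#'
#' A chromosome is described by its name, length and centromere interval.
#' Positions below the centromere lie on the p arm, positions above it on
#' the q arm; "telomeric" means decreasing coordinate on p and increasing
#' coordinate on q. Positions inside the centromere are pericentric and are
#' excluded from all arm-aware logic.
#'
#' @param name Chromosome name, e.g. `"chr19"`.
#' @param length Chromosome length in bp.
#' @param cen_start,cen_end Closed centromere interval in bp,
#'   `0 < cen_start <= cen_end < length`.
#' @return An object of class `chrom_spec`.
#' @export
chromosome_spec <- function(name, length, cen_start, cen_end) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(length), length > 0,
            cen_start > 0, cen_start <= cen_end, cen_end < length)
  structure(list(name = name, length = as.numeric(length),
                 cen_start = as.numeric(cen_start),
                 cen_end = as.numeric(cen_end)),
            class = "chrom_spec")
}

#' Arm direction at a position
#'
#' Returns the sign of the telomeric direction at `pos`: `+1` on the q arm
#' (telomeric = larger coordinate) and `-1` on the p arm (telomeric =
#' smaller coordinate). All "telomeric of X" / "centromeric of X"
#' comparisons in the package are defined through this sign.
#'
#' @param spec A [chromosome_spec()].
#' @param pos Position in bp (vectorised).
#' @return Integer vector of `+1` / `-1`.
#' @export
arm_direction <- function(spec, pos) {
  stopifnot(inherits(spec, "chrom_spec"))
  if (any(pos < 1 | pos > spec$length))
    stop("position outside chromosome ", spec$name)
  if (any(pos >= spec$cen_start & pos <= spec$cen_end))
    stop("pericentric position has no arm direction")
  ifelse(pos > spec$cen_end, 1L, -1L)
}

#' Phased genome container
#'
#' Bundles chromosome specs, phased heterozygous SNPs and feature
#' annotations (cassette insertion site, DSB/guide sites, HLA-like loci).
#' Only heterozygous loci are stored: LOH is only observable at sites that
#' were heterozygous to begin with. Haplotype labels `hapA`/`hapB` are
#' fixed by VCF phase order (hapA = left of `|`) and give the stable frame
#' that the cassette carrier and the DSB target refer to.
#'
#' @param specs A list of [chromosome_spec()] objects (named by chromosome).
#' @param snps data.frame with columns `chrom`, `pos` (1-based bp),
#'   `allele_hapA`, `allele_hapB`; heterozygous, sorted, unique positions.
#' @param features data.frame with columns `kind` (one of `cassette_site`,
#'   `dsb_site`, `hla_locus`), `chrom`, `pos`, and payload columns:
#'   `hap` (cassette carrier or DSB target haplotype), `label`
#'   (DSB label such as `"9M"` or HLA locus name), `hapA_label`,
#'   `hapB_label` (HLA haplotype names).
#' @return An object of class `phased_genome`.
#' @export
phased_genome <- function(specs, snps, features = empty_features()) {
  if (inherits(specs, "chrom_spec")) specs <- list(specs)
  names(specs) <- vapply(specs, `[[`, "", "name")
  snps <- snps[order(snps$chrom, snps$pos), , drop = FALSE]
  rownames(snps) <- NULL
  g <- structure(list(specs = specs, snps = snps, features = features),
                 class = "phased_genome")
  validate_phased_genome(g)
  g
}

empty_features <- function() {
  data.frame(kind = character(0), chrom = character(0), pos = numeric(0),
              hap = character(0), label = character(0),
              hapA_label = character(0), hapB_label = character(0),
              stringsAsFactors = FALSE)
}

validate_phased_genome <- function(g) {
  sn <- names(g$specs)
  if (nrow(g$snps)) {
    if (!all(g$snps$chrom %in% sn))
      stop("SNP references undeclared chromosome")
    if (any(g$snps$allele_hapA == g$snps$allele_hapB))
      stop("homozygous locus in het SNP table")
    lens <- vapply(g$specs, `[[`, 0, "length")[g$snps$chrom]
    if (any(g$snps$pos < 1 | g$snps$pos > lens))
      stop("SNP position outside chromosome bounds")
    if (anyDuplicated(g$snps[c("chrom", "pos")]))
      stop("duplicate SNP positions")
  }
  f <- g$features
  if (nrow(f)) {
    if (!all(f$chrom %in% sn))
      stop("feature references undeclared chromosome")
    for (ch in unique(f$chrom)) {
      fc <- f[f$chrom == ch, ]
      cas <- fc[fc$kind == "cassette_site", ]
      if (nrow(cas) > 1) stop("more than one cassette_site on ", ch)
      if (nrow(cas) == 1) {
        spec <- g$specs[[ch]]
        for (dp in fc$pos[fc$kind == "dsb_site"]) {
          # DSB must sit between centromere and cassette on the same arm
          if (arm_direction(spec, dp) != arm_direction(spec, cas$pos) ||
              abs_telomeric_offset(spec, dp) >= abs_telomeric_offset(spec, cas$pos))
            stop("dsb_site must lie between centromere and cassette on ", ch)
        }
      }
    }
  }
  invisible(g)
}

# distance from the centromere edge along the arm (arm-aware)
abs_telomeric_offset <- function(spec, pos) {
  d <- arm_direction(spec, pos)
  ifelse(d > 0, pos - spec$cen_end, spec$cen_start - pos)
}

#' Select feature annotations from a genome
#'
#' @param g A [phased_genome()].
#' @param kind Feature kind (`cassette_site`, `dsb_site`, `hla_locus`).
#' @param chrom,label Optional filters.
#' @return The matching feature rows.
#' @export
genome_feature <- function(g, kind, chrom = NULL, label = NULL) {
  f <- g$features[g$features$kind == kind, , drop = FALSE]
  if (!is.null(chrom)) f <- f[f$chrom == chrom, , drop = FALSE]
  if (!is.null(label)) f <- f[f$label == label, , drop = FALSE]
  f
}

#' Load phased heterozygous SNPs from a VCF
#'
#' Reads phased genotypes for one sample and keeps heterozygous records
#' only; unphased or homozygous records are skipped and counted. Multiple
#' chromosomes are supported; contigs must be declared in the VCF header.
#'
#' @param vcf_path Path to a VCF 4.x file (optionally gzipped).
#' @param sample Sample name present in the VCF.
#' @return A list with `snps` (data.frame as in [phased_genome()]) and
#'   `n_skipped` (records dropped as unphased/homozygous/non-SNP).
#' @export
load_phased_snps <- function(vcf_path, sample) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (!sample %in% colnames(gt))
    stop("sample '", sample, "' not found in ", vcf_path)
  meta <- vcfR::queryMETA(v, element = "contig")
  contigs <- unique(sub(".*ID=([^,]+).*", "\\1", unlist(meta)))
  chrom <- vcfR::getCHROM(v)
  if (length(contigs) && !all(chrom %in% contigs))
    stop("VCF record contig not declared in header")
  pos <- vcfR::getPOS(v)
  ref <- vcfR::getREF(v)
  alt <- vcfR::getALT(v)
  g <- gt[, sample]
  phased <- grepl("^[0-9]+\\|[0-9]+$", g)
  parts <- matrix(NA_integer_, nrow = length(g), ncol = 2)
  parts[phased, ] <- t(vapply(strsplit(g[phased], "|", fixed = TRUE),
                              as.integer, integer(2)))
  het <- phased & parts[, 1] != parts[, 2]
  alleles <- function(i, k) {
    idx <- parts[i, k]
    vapply(seq_along(i), function(j) {
      if (idx[j] == 0L) ref[i[j]]
      else strsplit(alt[i[j]], ",", fixed = TRUE)[[1]][idx[j]]
    }, "")
  }
  keep <- which(het)
  a <- if (length(keep)) alleles(keep, 1) else character(0)
  b <- if (length(keep)) alleles(keep, 2) else character(0)
  snp_ok <- nchar(a) == 1 & nchar(b) == 1
  keep <- keep[snp_ok]
  snps <- data.frame(chrom = chrom[keep], pos = pos[keep],
                     allele_hapA = a[snp_ok], allele_hapB = b[snp_ok],
                     stringsAsFactors = FALSE)
  snps <- unique(snps[order(snps$chrom, snps$pos), ])
  rownames(snps) <- NULL
  list(snps = snps, n_skipped = length(g) - nrow(snps))
}

#' Write phased heterozygous SNPs to VCF
#'
#' Inverse of [load_phased_snps()]: emits one phased het record per locus
#' (`GT 0|1`, REF = hapA allele, ALT = hapB allele) for a single sample.
#'
#' @param genome A [phased_genome()] (or a list with `specs` and `snps`).
#' @param path Output path; `vcfR` writes gzip-compressed VCF.
#' @param sample Sample name to write.
#' @export
write_phased_vcf <- function(genome, path, sample = "SYNTH") {
  snps <- genome$snps
  contigs <- vapply(genome$specs, function(s)
    sprintf("##contig=<ID=%s,length=%d>", s$name, as.integer(s$length)), "")
  meta <- c("##fileformat=VCFv4.2",
            contigs,
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  fix <- cbind(CHROM = snps$chrom, POS = as.character(as.integer(snps$pos)),
               ID = rep(".", nrow(snps)), REF = snps$allele_hapA,
               ALT = snps$allele_hapB, QUAL = rep(".", nrow(snps)),
               FILTER = rep("PASS", nrow(snps)), INFO = rep(".", nrow(snps)))
  gtm <- cbind(FORMAT = rep("GT", nrow(snps)), rep("0|1", nrow(snps)))
  colnames(gtm) <- c("FORMAT", sample)
  v <- new("vcfR", meta = meta, fix = fix, gt = gtm)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}

#' Write LOH tracts as BED
#'
#' Internal 1-based closed intervals are converted losslessly to BED
#' (0-based, half-open); the tract class goes in column 4.
#'
#' @param tracts data.frame with columns `chrom`, `start`, `end` (1-based
#'   closed) and `class`.
#' @param path Output BED path.
#' @export
write_loh_bed <- function(tracts, path) {
  if (nrow(tracts) == 0) {
    file.create(path)
    return(invisible(path))
  }
  if (any(tracts$end < tracts$start)) stop("inverted interval in tracts")
  gr <- GenomicRanges::GRanges(
    seqnames = tracts$chrom,
    ranges = IRanges::IRanges(start = tracts$start, end = tracts$end),
    name = tracts$class)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a BED file back into 1-based closed tracts
#'
#' @param path BED path written by [write_loh_bed()].
#' @return data.frame with columns `chrom`, `start`, `end`, `class`.
#' @export
read_loh_bed <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), class = character(0)))
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             class = gr$name, stringsAsFactors = FALSE)
}
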