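#' Genotype a daughter cell on a SNP panel
#'
#' The call at a position is `het` when the daughter's two chromatids
#' carry different source haplotypes there, `homA`/`homB` otherwise
#' (resolved against phase metadata: which haplotype's material is
#' present). A position deleted on one chromatid is hemizygous and reports
#' the remaining haplotype as a hom call; deleted on both, `missing`.
#' Each call is independently corrupted (het to a random hom, hom to het)
#' with probability `genotype_error`.
#'
#' @param daughter A `daughter_genome`.
#' @param positions SNP positions (subset of the genome's het loci).
#' @param genotype_error Per-call flip probability.
#' @return data.frame with columns `pos` and `call`
#'   (`het`/`homA`/`homB`/`missing`), ordered by position.
#' @export
genotype_panel <- function(daughter, positions, genotype_error = 0) {
  positions <- sort(positions)
  ch1 <- daughter$chromatids[[1]]; ch2 <- daughter$chromatids[[2]]
  h1 <- hap_at(ch1, positions); h2 <- hap_at(ch2, positions)
  d1 <- is_deleted_at(ch1, positions); d2 <- is_deleted_at(ch2, positions)
  call <- ifelse(d1 & d2, "missing",
          ifelse(d1, paste0("hom", c("A", "B"))[h2],
          ifelse(d2, paste0("hom", c("A", "B"))[h1],
          ifelse(h1 != h2, "het", paste0("hom", c("A", "B"))[h1]))))
  if (genotype_error > 0) {
    flip <- stats::runif(length(call)) < genotype_error & call != "missing"
    if (any(flip)) {
      is_het <- call == "het"
      to_hom <- flip & is_het
      call[to_hom] <- sample(c("homA", "homB"), sum(to_hom), replace = TRUE)
      call[flip & !is_het] <- "het"
    }
  }
  data.frame(pos = positions, call = call, stringsAsFactors = FALSE)
}

#' Smooth a genotype panel
#'
#' Error tolerance for breakpoint calling: a run of discordant calls
#' shorter than `k`, flanked on both sides by runs of at least `k`
#' concordant calls of the same value, is flipped to the flanking value.
#' `k = 1` is the identity; a single clean transition is never altered.
#'
#' @param calls data.frame from [genotype_panel()].
#' @param k Odd window parameter, `>= 1`.
#' @return The smoothed calls.
#' @export
smooth_panel <- function(calls, k = 3) {
  stopifnot(k >= 1, k %% 2 == 1)
  if (k == 1 || nrow(calls) == 0) return(calls)
  r <- rle(calls$call)
  nr <- length(r$lengths)
  if (nr >= 3) {
    vals <- r$values
    for (i in 2:(nr - 1)) {
      if (r$lengths[i] < k &&
          vals[i - 1] == vals[i + 1] &&
          r$lengths[i - 1] >= k && r$lengths[i + 1] >= k)
        r$values[i] <- vals[i - 1]
    }
  }
  calls$call <- inverse.rle(r)
  calls
}

panel_state <- function(call) ifelse(call == "het", "het",
                                     ifelse(call == "missing", NA, "hom"))

#' Infer a crossover point by the equidistance (midpoint) rule
#'
#' Orders the (smoothed) panel in the telomeric direction of the arm
#' bearing the DSB and requires exactly one het-to-hom transition, with
#' homozygosity extending to the most telomeric SNP. The crossover point
#' is the position equidistant from the last heterozygous and the first
#' LOH SNP, rounded half toward the centromere. The side of the DSB is
#' called only when the bounding SNP interval lies wholly on one side of
#' the DSB; an interval straddling the DSB is reported as `"spanning"`
#' (below marker resolution) and excluded from per-side summaries.
#'
#' @param calls Smoothed calls spanning the cassette arm.
#' @param spec The [chromosome_spec()].
#' @param dsb_pos DSB position in bp.
#' @return A list of class `crossover_point` with `status` one of
#'   `crossover`, `no_loh`, `whole_chromosome`, `complex`; for
#'   `crossover`: `point`, `bounding` (c(last_het, first_loh)), `side`
#'   (`centromeric`/`telomeric`/`spanning`), `distance` in bp.
#' @export
infer_crossover_point <- function(calls, spec, dsb_pos) {
  dir <- arm_direction(spec, dsb_pos)
  ord <- order(calls$pos, decreasing = dir < 0)
  calls <- calls[ord, , drop = FALSE]
  st <- panel_state(calls$call)
  keep <- !is.na(st)
  st <- st[keep]; pos <- calls$pos[keep]
  res <- function(status, ...) {
    structure(c(list(chrom = spec$name, status = status), list(...)),
              class = "crossover_point")
  }
  if (length(st) == 0) return(res("complex"))
  r <- rle(st)
  if (length(r$values) == 1) {
    if (r$values == "het") return(res("no_loh"))
    return(res("whole_chromosome"))
  }
  if (length(r$values) != 2 || r$values[1] != "het")
    return(res("complex"))
  last_het <- pos[r$lengths[1]]
  first_loh <- pos[r$lengths[1] + 1]
  m <- (last_het + first_loh) / 2
  # round half toward the centromere (down on q arm, up on p arm)
  point <- if (dir > 0) floor(m) else ceiling(m)
  lo <- min(last_het, first_loh); hi <- max(last_het, first_loh)
  side <- if (lo < dsb_pos && dsb_pos < hi) "spanning"
          else if ((point - dsb_pos) * dir < 0) "centromeric"
          else "telomeric"
  res("crossover", point = point, bounding = c(last_het, first_loh),
      side = side, distance = abs(point - dsb_pos))
}

#' Classify a screened clone
#'
#' The wildtype competitive-PCR band overrides the panel: such clones are
#' aberrant duplications (amplification without crossover). Otherwise an
#' all-homozygous panel is whole-chromosome LOH (uniparental disomy or a
#' centromere-proximal event; the two are not distinguishable from the
#' panel and are deliberately merged), a single telomeric-extending
#' het-to-hom transition is a crossover, and anything else is `no_loh`.
#'
#' @param bands Output of [competitive_pcr()].
#' @param calls Smoothed panel calls.
#' @param spec The [chromosome_spec()].
#' @param dsb_pos DSB position in bp.
#' @return One of `"crossover"`, `"whole_chromosome_loh"`,
#'   `"aberrant_duplication"`, `"no_loh"`.
#' @export
classify_clone <- function(bands, calls, spec, dsb_pos) {
  if ("wildtype" %in% bands) return("aberrant_duplication")
  cp <- infer_crossover_point(calls, spec, dsb_pos)
  switch(cp$status,
         whole_chromosome = "whole_chromosome_loh",
         crossover = "crossover",
         "no_loh")
}

#' Map all positive clones of a cohort
#'
#' Genotypes every selected clone on the panel, smooths, infers crossover
#' points and classifies. Genotyping noise draws from the cohort seed's
#' `"genotype"` substream.
#'
#' @param cohort A [simulate_experiment()] cohort.
#' @param panel_positions Panel SNP positions (cassette arm).
#' @param genotype_error Per-call flip probability (defaults to the
#'   cohort's configured value).
#' @param k Smoothing parameter for [smooth_panel()].
#' @return data.frame with one row per surviving clone: `id`, `bands`,
#'   `class`, `point`, `side`, `distance_bp`, truth columns.
#' @export
map_cohort <- function(cohort, panel_positions,
                       genotype_error = cohort$cfg$genotype_error, k = 3) {
  set.seed(substream_seed(cohort$cfg$seed, "genotype"))
  spec <- cohort$spec
  if (length(cohort$clones) == 0)
    return(data.frame(id = character(0), bands = character(0),
                      class = character(0), point = numeric(0),
                      side = character(0), distance_bp = numeric(0),
                      true_kind = character(0), true_breakpoint = numeric(0),
                      true_side = character(0), true_upd = logical(0),
                      true_amplification = logical(0)))
  rows <- lapply(cohort$clones, function(cl) {
    calls <- genotype_panel(cl$daughter, panel_positions, genotype_error)
    calls <- smooth_panel(calls, k)
    cls <- classify_clone(cl$bands, calls, spec, cohort$dsb$pos)
    cp <- infer_crossover_point(calls, spec, cohort$dsb$pos)
    data.frame(id = cl$id,
               bands = paste(cl$bands, collapse = "+"),
               class = cls,
               point = if (cp$status == "crossover") cp$point else NA,
               side = if (cp$status == "crossover") cp$side else NA,
               distance_bp = if (cp$status == "crossover") cp$distance else NA,
               true_kind = paste(unique(cl$truth$kinds), collapse = "+"),
               true_breakpoint = cl$truth$breakpoint,
               true_side = cl$truth$side,
               true_upd = cl$truth$upd,
               true_amplification = cl$truth$amplification,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Summarise a mapped cohort
#'
#' Counts clones per class and, for crossover clones with a resolved
#' side, reports per-side clone counts and mean/median crossover-to-DSB
#' distances (kb). Efficiency is positive clones over cells screened.
#'
#' @param clone_table Output of [map_cohort()].
#' @param n_screened Number of cells screened (for the efficiency).
#' @return A list of class `cohort_summary`.
#' @export
summarize_cohort <- function(clone_table, n_screened = NA) {
  if (is.null(clone_table) || nrow(clone_table) == 0)
    stop("empty clone table")
  classes <- c("crossover", "whole_chromosome_loh", "aberrant_duplication",
               "no_loh")
  counts <- vapply(classes, function(cl) sum(clone_table$class == cl), 0L)
  xo <- clone_table[clone_table$class == "crossover" &
                    clone_table$side %in% c("centromeric", "telomeric"), ]
  per_side <- lapply(c(centromeric = "centromeric", telomeric = "telomeric"),
    function(s) {
      d <- xo$distance_bp[xo$side == s]
      list(n = length(d),
           mean_kb = if (length(d)) mean(d) / 1000 else NA,
           median_kb = if (length(d)) stats::median(d) / 1000 else NA)
    })
  structure(list(counts = counts, per_side = per_side,
                 n_spanning = sum(clone_table$class == "crossover" &
                                  clone_table$side == "spanning", na.rm = TRUE),
                 n_clones = nrow(clone_table),
                 efficiency = if (is.na(n_screened)) NA
                              else nrow(clone_table) / n_screened),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Clone classes:\n")
  for (nm in names(x$counts)) cat(sprintf("  %-22s %d\n", nm, x$counts[[nm]]))
  for (s in names(x$per_side)) {
    ps <- x$per_side[[s]]
    cat(sprintf("  %s crossovers: n=%d mean=%.1f kb median=%.1f kb\n",
                s, ps$n, ps$mean_kb, ps$median_kb))
  }
  invisible(x)
}

#' HLA genotype report for a daughter cell
#'
#' For each annotated HLA-like locus, reports the haplotype labels
#' carried by the daughter's two chromatids at that position and whether
#' the locus has become homozygous.
#'
#' @param daughter A `daughter_genome`.
#' @param hla_features Feature rows with `kind == "hla_locus"`.
#' @return data.frame with columns `locus`, `allele1`, `allele2`,
#'   `homozygous`.
#' @export
hla_report <- function(daughter, hla_features) {
  hla <- hla_features[hla_features$kind == "hla_locus", , drop = FALSE]
  if (nrow(hla) == 0) stop("no hla_locus features supplied")
  ch1 <- daughter$chromatids[[1]]; ch2 <- daughter$chromatids[[2]]
  h1 <- hap_at(ch1, hla$pos); h2 <- hap_at(ch2, hla$pos)
  lab <- function(row, h) if (h == 1) hla$hapA_label[row] else hla$hapB_label[row]
  a1 <- vapply(seq_len(nrow(hla)), function(i) lab(i, h1[i]), "")
  a2 <- vapply(seq_len(nrow(hla)), function(i) lab(i, h2[i]), "")
  data.frame(locus = hla$label, allele1 = a1, allele2 = a2,
             homozygous = a1 == a2, stringsAsFactors = FALSE)
}

#' Panel SNP positions on the cassette arm
#'
#' @param genome A [phased_genome()].
#' @param chrom Chromosome name.
#' @return Sorted het SNP positions on the arm carrying the cassette.
#' @export
panel_positions <- function(genome, chrom) {
  spec <- genome$specs[[chrom]]
  cas <- genome_feature(genome, "cassette_site", chrom)
  if (nrow(cas) != 1) stop("no cassette on ", chrom)
  snp <- genome$snps[genome$snps$chrom == chrom, ]
  dir <- arm_direction(spec, cas$pos)
  if (dir > 0) sort(snp$pos[snp$pos > spec$cen_end])
  else sort(snp$pos[snp$pos < spec$cen_start])
}
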