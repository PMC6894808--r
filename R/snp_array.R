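#' Simulate a BAF/LRR array profile for a daughter cell
#'
#' The B allele is the hapB allele at each het locus. Ideal B-allele
#' frequency is the fraction of present copies carrying hapB (0.5 at
#' retained het sites, 0 or 1 in copy-neutral LOH); ideal log R ratio is
#' `log2(copies / 2)` (0 for two copies, -1 in a hemizygous deletion).
#' Gaussian noise is added to both channels; BAF is truncated to [0, 1].
#'
#' @param daughter A `daughter_genome`.
#' @param positions Probe positions (het loci of the parent genome).
#' @param noise_sd_baf,noise_sd_lrr Gaussian noise SDs.
#' @return data.frame of class `array_profile`: `pos`, `baf`, `lrr`.
#' @export
simulate_baf_lrr <- function(daughter, positions, noise_sd_baf = 0.05,
                             noise_sd_lrr = 0.15) {
  positions <- sort(positions)
  ch1 <- daughter$chromatids[[1]]; ch2 <- daughter$chromatids[[2]]
  c1 <- 1 - is_deleted_at(ch1, positions)
  c2 <- 1 - is_deleted_at(ch2, positions)
  cn <- c1 + c2
  bcopies <- c1 * (hap_at(ch1, positions) == 2L) +
             c2 * (hap_at(ch2, positions) == 2L)
  baf <- ifelse(cn > 0, bcopies / cn, 0.5)
  lrr <- ifelse(cn > 0, log2(cn / 2), -4)
  n <- length(positions)
  if (noise_sd_baf > 0) baf <- baf + stats::rnorm(n, 0, noise_sd_baf)
  if (noise_sd_lrr > 0) lrr <- lrr + stats::rnorm(n, 0, noise_sd_lrr)
  out <- data.frame(pos = positions, baf = pmin(1, pmax(0, baf)), lrr = lrr)
  class(out) <- c("array_profile", "data.frame")
  out
}

#' Segment an array profile into LOH classes
#'
#' Rule-based sliding-median segmentation: probes where the running
#' median of the mirrored BAF deviation `|baf - 0.5|` is at least
#' `baf_dev_threshold` are in LOH; within LOH, probes whose running
#' median LRR is at most `lrr_threshold` are deletions, the rest
#' copy-neutral LOH. Runs are merged into maximal segments whose
#' boundaries sit at the midpoint between flanking probes, tiling the
#' profiled region. Profiles shorter than the window collapse to a single
#' segment labelled by global medians.
#'
#' @param profile An [simulate_baf_lrr()] profile.
#' @param window Odd probe count for the running medians (>= 5 for
#'   meaningful calls).
#' @param baf_dev_threshold Mirrored-BAF deviation marking LOH.
#' @param lrr_threshold LRR at or below which LOH is called a deletion.
#' @return data.frame with `chrom`-free columns `start`, `end` (1-based
#'   closed, tiling `[min(pos), max(pos)]`) and `class`
#'   (`normal`/`cn_loh`/`deletion`).
#' @export
segment_loh <- function(profile, window = 25, baf_dev_threshold = 0.35,
                        lrr_threshold = -0.5) {
  stopifnot(nrow(profile) >= 1)
  if (window %% 2 == 0) window <- window + 1
  dev <- abs(profile$baf - 0.5)
  n <- nrow(profile)
  if (n < window) {
    cls <- if (stats::median(dev) >= baf_dev_threshold) {
      if (stats::median(profile$lrr) <= lrr_threshold) "deletion" else "cn_loh"
    } else "normal"
    return(data.frame(start = profile$pos[1], end = profile$pos[n],
                      class = cls, stringsAsFactors = FALSE))
  }
  med_dev <- stats::runmed(dev, window, endrule = "constant")
  med_lrr <- stats::runmed(profile$lrr, window, endrule = "constant")
  loh <- med_dev >= baf_dev_threshold
  cls <- ifelse(!loh, "normal",
                ifelse(med_lrr <= lrr_threshold, "deletion", "cn_loh"))
  r <- rle(cls)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- c(1, utils::head(ends_idx, -1) + 1)
  seg_start <- profile$pos[starts_idx]
  seg_end <- profile$pos[ends_idx]
  if (length(seg_start) > 1) {
    mids <- floor((profile$pos[utils::head(ends_idx, -1)] +
                   profile$pos[starts_idx[-1]]) / 2)
    seg_end[-length(seg_end)] <- mids
    seg_start[-1] <- mids + 1
  }
  data.frame(start = seg_start, end = seg_end, class = r$values,
             stringsAsFactors = FALSE)
}

#' Write an array profile as TSV
#' @param profile An [simulate_baf_lrr()] profile.
#' @param path Output path.
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an array profile TSV
#' @param path Path written by [write_profile_tsv()].
#' @return An `array_profile` data.frame.
#' @export
read_profile_tsv <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t")
  class(out) <- c("array_profile", "data.frame")
  out
}
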