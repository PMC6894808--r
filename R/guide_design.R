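#' Scan a sequence for SpCas9 protospacer + PAM sites
#'
#' Finds every position on both strands where a full 20-nt protospacer is
#' followed by an NGG PAM. Reverse-strand sites are reported in forward
#' coordinates. The blunt cut falls between protospacer positions 17 and
#' 18 (3 bp 5' of the PAM); `cut_pos` is the forward-strand coordinate of
#' the base immediately on the lower-coordinate side of the cut.
#'
#' @param seq Character or `Biostrings::DNAString` over `{A,C,G,T}`,
#'   length >= 23; ambiguity codes are an error (synthetic sequences
#'   only).
#' @param origin Genomic coordinate of the first base of `seq` (1-based).
#' @return data.frame with columns `strand`, `protospacer` (5'->3' on its
#'   strand), `pam`, `cut_pos`, `pam_start` (forward coordinate of the
#'   PAM's first base), `proto_start`, `proto_end` (forward coordinates of
#'   the protospacer footprint).
#' @export
scan_pam_sites <- function(seq, origin = 1) {
  s <- toupper(as.character(seq))
  if (nchar(s) < 23) stop("sequence shorter than 23 nt")
  if (grepl("[^ACGT]", s)) stop("ambiguity codes not supported")
  dna <- Biostrings::DNAString(s)
  n <- nchar(s)
  # forward: protospacer [i-20, i-1], PAM NGG at [i, i+2]
  gg <- Biostrings::start(Biostrings::matchPattern("GG", dna))
  fwd_pam <- (gg - 1)[gg - 1 >= 21 & gg + 1 <= n]
  # reverse: PAM CCN at [j, j+2] on forward, protospacer [j+3, j+22]
  cc <- Biostrings::start(Biostrings::matchPattern("CC", dna))
  rev_pam <- cc[cc + 22 <= n & cc >= 1]
  sub <- function(a, b) substring(s, a, b)
  rc <- function(x) vapply(x, function(z)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(z))), "")
  out <- list()
  if (length(fwd_pam)) {
    out[[1]] <- data.frame(
      strand = "+",
      protospacer = sub(fwd_pam - 20, fwd_pam - 1),
      pam = sub(fwd_pam, fwd_pam + 2),
      cut_pos = origin + (fwd_pam - 4) - 1,
      pam_start = origin + fwd_pam - 1,
      proto_start = origin + (fwd_pam - 20) - 1,
      proto_end = origin + (fwd_pam - 1) - 1,
      stringsAsFactors = FALSE)
  }
  if (length(rev_pam)) {
    out[[2]] <- data.frame(
      strand = "-",
      protospacer = unname(rc(sub(rev_pam + 3, rev_pam + 22))),
      pam = unname(rc(sub(rev_pam, rev_pam + 2))),
      cut_pos = origin + (rev_pam + 5) - 1,
      pam_start = origin + (rev_pam + 2) - 1,
      proto_start = origin + (rev_pam + 3) - 1,
      proto_end = origin + (rev_pam + 22) - 1,
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(strand = character(0), protospacer = character(0),
                      pam = character(0), cut_pos = numeric(0),
                      pam_start = numeric(0), proto_start = numeric(0),
                      proto_end = numeric(0)))
  res <- do.call(rbind, out)
  res[order(res$cut_pos, res$strand), , drop = FALSE]
}

#' Extract the two haplotype sequences of a genomic window
#'
#' Substitutes the genome's phased het alleles into a supplied backbone
#' sequence, yielding two sequences identical except at het SNPs.
#'
#' @param genome A [phased_genome()].
#' @param chrom Chromosome name.
#' @param center,halfwidth Window centre and half-width in bp.
#' @param backbone Character backbone sequence covering
#'   `[center - halfwidth, center + halfwidth]`.
#' @return List with `seqA`, `seqB` and `origin` (window start in bp).
#' @export
haplotype_window <- function(genome, chrom, center, halfwidth, backbone) {
  spec <- genome$specs[[chrom]]
  lo <- center - halfwidth; hi <- center + halfwidth
  if (lo < 1 || hi > spec$length) stop("window exceeds chromosome bounds")
  backbone <- toupper(as.character(backbone))
  if (nchar(backbone) != hi - lo + 1)
    stop("backbone length must equal window width")
  snp <- genome$snps[genome$snps$chrom == chrom &
                     genome$snps$pos >= lo & genome$snps$pos <= hi, ]
  seqA <- seqB <- backbone
  if (nrow(snp)) {
    off <- snp$pos - lo + 1
    for (i in seq_len(nrow(snp))) {
      substr(seqA, off[i], off[i]) <- snp$allele_hapA[i]
      substr(seqB, off[i], off[i]) <- snp$allele_hapB[i]
    }
  }
  list(seqA = seqA, seqB = seqB, origin = lo)
}

#' Find allele-specific Cas9 target sites
#'
#' Compares the PAM-site lists of the two haplotype sequences. A site
#' whose NGG exists on exactly one haplotype yields a PAM-disrupting
#' guide targeting that haplotype (the design used for allele-specific
#' DSBs). Optionally, sites with intact PAMs on both haplotypes but a SNP
#' within the PAM-proximal `seed_len` nt of the protospacer are emitted
#' as seed-mismatch guides (an extension beyond PAM SNPs; off by
#' default). Sites differing only PAM-distal of the seed are never
#' emitted.
#'
#' @param seqA,seqB Haplotype sequences of equal length
#'   (from [haplotype_window()]).
#' @param origin Forward coordinate of the first base.
#' @param seed_len Seed length in nt (PAM-proximal).
#' @param allow_seed_mismatch Emit seed-mismatch guides as well.
#' @return data.frame of guides: site columns as in [scan_pam_sites()]
#'   plus `target_hap` and `discrimination`
#'   (`pam_disrupting`/`seed_mismatch`) and `snp_pos`.
#' @export
find_allele_specific_sites <- function(seqA, seqB, origin = 1, seed_len = 10,
                                       allow_seed_mismatch = FALSE) {
  stopifnot(nchar(seqA) == nchar(seqB))
  sa <- scan_pam_sites(seqA, origin)
  sb <- scan_pam_sites(seqB, origin)
  key <- function(x) paste(x$strand, x$pam_start)
  diffs <- origin - 1 + which(strsplit(seqA, "")[[1]] != strsplit(seqB, "")[[1]])
  snp_in <- function(lo, hi) {
    hit <- diffs[diffs >= lo & diffs <= hi]
    if (length(hit)) hit[1] else NA_real_
  }
  emit <- list()
  one_sided <- function(sites, other_keys, hap) {
    only <- sites[!(key(sites) %in% other_keys), , drop = FALSE]
    if (!nrow(only)) return(NULL)
    # the discriminating SNP must fall in the PAM footprint
    pam_lo <- ifelse(only$strand == "+", only$pam_start, only$pam_start - 2)
    pam_hi <- ifelse(only$strand == "+", only$pam_start + 2, only$pam_start)
    snp <- mapply(snp_in, pam_lo, pam_hi)
    keep <- !is.na(snp)
    if (!any(keep)) return(NULL)
    cbind(only[keep, , drop = FALSE],
          target_hap = hap, discrimination = "pam_disrupting",
          snp_pos = snp[keep], stringsAsFactors = FALSE)
  }
  emit$a <- one_sided(sa, key(sb), "hapA")
  emit$b <- one_sided(sb, key(sa), "hapB")
  if (allow_seed_mismatch) {
    shared <- sa[key(sa) %in% key(sb), , drop = FALSE]
    if (nrow(shared)) {
      # PAM-proximal seed_len nt of the protospacer, forward coordinates
      seed_lo <- ifelse(shared$strand == "+",
                        shared$proto_end - seed_len + 1, shared$proto_start)
      seed_hi <- ifelse(shared$strand == "+",
                        shared$proto_end, shared$proto_start + seed_len - 1)
      snp <- mapply(snp_in, seed_lo, seed_hi)
      keep <- !is.na(snp)
      if (any(keep)) {
        sh <- shared[keep, , drop = FALSE]
        sb_m <- sb[match(key(sh), key(sb)), , drop = FALSE]
        emit$seedA <- cbind(sh, target_hap = "hapA",
                            discrimination = "seed_mismatch",
                            snp_pos = snp[keep], stringsAsFactors = FALSE)
        emit$seedB <- cbind(sb_m, target_hap = "hapB",
                            discrimination = "seed_mismatch",
                            snp_pos = snp[keep], stringsAsFactors = FALSE)
      }
    }
  }
  emit <- Filter(Negate(is.null), emit)
  if (!length(emit))
    return(data.frame(strand = character(0), protospacer = character(0),
                      pam = character(0), cut_pos = numeric(0),
                      pam_start = numeric(0), proto_start = numeric(0),
                      proto_end = numeric(0), target_hap = character(0),
                      discrimination = character(0), snp_pos = numeric(0)))
  res <- do.call(rbind, emit)
  rownames(res) <- NULL
  res[order(res$cut_pos, res$strand, res$target_hap), , drop = FALSE]
}

#' Filter guides away from the cassette and centromere
#'
#' The DSB must be centromeric to the cassette for the
#' duplication-selection scheme to work; guides whose protospacer+PAM
#' footprint overlaps the cassette site or the centromere are dropped.
#'
#' @param guides Output of [find_allele_specific_sites()].
#' @param spec The [chromosome_spec()].
#' @param cassette_pos Cassette position in bp.
#' @return The filtered guide table.
#' @export
filter_guides <- function(guides, spec, cassette_pos) {
  if (!nrow(guides)) return(guides)
  lo <- pmin(guides$proto_start, guides$pam_start)
  hi <- pmax(guides$proto_end, guides$pam_start + 2)
  bad <- (cassette_pos >= lo & cassette_pos <= hi) |
         (hi >= spec$cen_start & lo <= spec$cen_end)
  guides[!bad, , drop = FALSE]
}
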