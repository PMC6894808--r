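# Shared fixtures: tiny genomes and forced-outcome daughters built in code.

toy_genome <- function(seed = 11, density = 1 / 2000) {
  make_genome("toy", snp_density = density, seed = seed)
}

chr19_genome <- function(seed = 11, density = 1 / 5000) {
  make_genome("chr19_aavs1", snp_density = density, seed = seed)
}

# Build a daughter with a single forced crossover at breakpoint b and the
# given segregation type, after iCre with per-copy inversion flags.
forced_crossover_daughter <- function(genome, chrom, b, x_type = TRUE,
                                      inv = c(FALSE, TRUE)) {
  tet <- replicate_to_4n(genome, chrom)
  tet <- lohsim:::apply_icre_with_draws(tet, 1,
                                        u = ifelse(inv, 0, 1))  # forced flips
  tet <- apply_outcome(tet, "B1", "crossover", breakpoint = b,
                       side = NA, partner = "A1")
  # recombinants: A1' (lost distal cassette), B1' (gained it).
  # X-type puts the recombinants in different daughters; daughter 1 below
  # is the dual-cassette one {A2, B1'}.
  if (x_type) segregate_with_picks(tet, 2, 1)[[1]]
  else segregate_with_picks(tet, 1, 1)[[1]]
}

# Uniform random DNA string
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# Brute-force double-strand regex oracle for SpCas9 NGG sites.
regex_pam_oracle <- function(seq, origin = 1) {
  s <- toupper(seq)
  n <- nchar(s)
  revcomp <- function(x) chartr("ACGT", "TGCA",
                                paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  hits <- list()
  for (i in seq_len(n)) {
    # forward PAM at [i, i+2]
    if (i >= 21 && i + 2 <= n &&
        grepl("^[ACGT]GG$", substring(s, i, i + 2))) {
      hits[[length(hits) + 1]] <- data.frame(
        strand = "+", protospacer = substring(s, i - 20, i - 1),
        pam = substring(s, i, i + 2), cut_pos = origin + (i - 4) - 1,
        stringsAsFactors = FALSE)
    }
    # reverse PAM: CCN on forward at [i, i+2]
    if (i + 22 <= n && grepl("^CC[ACGT]$", substring(s, i, i + 2))) {
      hits[[length(hits) + 1]] <- data.frame(
        strand = "-", protospacer = revcomp(substring(s, i + 3, i + 22)),
        pam = revcomp(substring(s, i, i + 2)), cut_pos = origin + (i + 5) - 1,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) return(data.frame(strand = character(0),
                                       protospacer = character(0),
                                       pam = character(0),
                                       cut_pos = numeric(0)))
  out <- do.call(rbind, hits)
  out[order(out$cut_pos, out$strand), , drop = FALSE]
}

# Minimal phased VCF text fixture
write_test_vcf <- function(path, records, sample = "S1",
                           contigs = c(chrTest = 1e6)) {
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                      as.integer(contigs)),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                     sample))
  writeLines(c(header, records), path)
  path
}
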