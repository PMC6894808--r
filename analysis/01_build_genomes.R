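#!/usr/bin/env Rscript
# Build the two synthetic phased genomes used throughout the analysis:
# the chr19 safe-harbor design (cassette at 55.1 Mb, DSBs at 9/14/19 Mb
# from the centromere edge) and the chr6p HLA design (cassette near the
# p telomere, DSB between the class I and III blocks). Writes the phased
# het SNPs as VCF and the feature annotations as BED under results/.

library(lohsim)

out <- "results/genomes"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 1

for (preset in c("chr19_aavs1", "chr6p_hla")) {
  g <- make_genome(preset, snp_density = 1 / 5000, seed = seed)
  chrom <- names(g$specs)[1]
  write_phased_vcf(g, file.path(out, paste0(preset, ".vcf.gz")))
  feats <- g$features
  write_loh_bed(data.frame(chrom = feats$chrom, start = feats$pos,
                           end = feats$pos,
                           class = paste0(feats$kind, ":", feats$label)),
                file.path(out, paste0(preset, "_features.bed")))
  message(sprintf("%s: %d het SNPs on %s (%.1f Mb), %d features",
                  preset, nrow(g$snps), chrom,
                  g$specs[[chrom]]$length / 1e6, nrow(feats)))
}

# Allele-specific guide design demonstration around the chr19 9M DSB:
# a synthetic backbone window with the genome's het SNPs substituted,
# scanned for PAM sites that exist on exactly one haplotype.
g <- make_genome("chr19_aavs1", snp_density = 1 / 500, seed = seed + 1)
set.seed(seed + 2)
half <- 2500
backbone <- paste(sample(c("A", "C", "G", "T"), 2 * half + 1,
                         replace = TRUE), collapse = "")
w <- haplotype_window(g, "chr19", 36e6, half, backbone)
guides <- find_allele_specific_sites(w$seqA, w$seqB, origin = w$origin)
guides <- filter_guides(guides, g$specs$chr19, cassette_pos = 55.1e6)
write.table(guides, file.path(out, "guides_9M.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("guide design: %d allele-specific (PAM-disrupting) guides in a %d kb window",
                nrow(guides), (2 * half + 1) %/% 1000))
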