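test_that("replication to 4N builds identical sisters with two cassettes", {
  g <- toy_genome()
  tet <- replicate_to_4n(g, "toy")
  expect_length(tet$chromatids, 4)
  expect_identical(tet$chromatids$A1, tet$chromatids$A2)
  expect_identical(tet$chromatids$B1, tet$chromatids$B2)
  ncas <- vapply(tet$chromatids, function(c) length(c$cas_pos), 0L)
  expect_equal(unname(ncas), c(1L, 1L, 0L, 0L))  # carrier = hapA sisters
  g2 <- phased_genome(g$specs, g$snps)  # no cassette annotation
  expect_error(replicate_to_4n(g2, "toy"), "cassette")
})

test_that("iCre inversion: limits and binomial behaviour at q = 0.25", {
  g <- toy_genome()
  tet <- replicate_to_4n(g, "toy")
  set.seed(5)
  t0 <- apply_icre(tet, 0)
  expect_false(any(unlist(lapply(t0$chromatids, `[[`, "cas_inv"))))
  t1 <- apply_icre(tet, 1)
  expect_equal(sum(unlist(lapply(t1$chromatids, `[[`, "cas_inv"))), 2)
  # fraction of inverted copies across 10,000 tetrads within 3 sigma of 0.25
  set.seed(17)
  q <- 0.25; n <- 10000
  inv <- replicate(n, sum(unlist(lapply(
    apply_icre(tet, q)$chromatids, `[[`, "cas_inv"))))
  phat <- sum(inv) / (2 * n)
  expect_lt(abs(phat - q), 3 * sqrt(q * (1 - q) / (2 * n)))
})

test_that("crossover exchange is reciprocal and conserves material", {
  g <- chr19_genome()
  tet <- replicate_to_4n(g, "chr19")
  b <- 35.5e6
  tet <- apply_outcome(tet, "B1", "crossover", breakpoint = b, partner = "A1")
  a1 <- tet$chromatids$A1; b1 <- tet$chromatids$B1
  len <- g$specs$chr19$length
  # distal (q-telomeric) material swapped, proximal retained
  expect_equal(hap_at(a1, c(b - 1, b + 1)), c(1L, 2L))
  expect_equal(hap_at(b1, c(b - 1, b + 1)), c(2L, 1L))
  # the cassette (telomeric to the breakpoint) moved from A1 to B1
  expect_length(a1$cas_pos, 0)
  expect_equal(b1$cas_pos, 55.1e6)
  # total hapA material conserved across the pair
  hapA_len <- function(ch) {
    starts <- c(0, utils::head(ch$ends, -1))
    sum((ch$ends - starts)[ch$haps == 1L])
  }
  expect_equal(hapA_len(a1) + hapA_len(b1), len)
  expect_error(cross_chromatids(a1, b1, 25e6, g$specs$chr19), "centromere")
})

test_that("p-arm crossover exchanges the low-coordinate (telomeric) side", {
  g <- make_genome("chr6p_hla", 1 / 20000, seed = 2)
  tet <- replicate_to_4n(g, "chr6")
  b <- 31.42e6  # centromeric to the DSB on the p arm
  tet <- apply_outcome(tet, "B1", "crossover", breakpoint = b, partner = "A1")
  b1 <- tet$chromatids$B1
  expect_equal(hap_at(b1, c(b - 1e6, b + 1e6)), c(1L, 2L))
  # cassette near the p telomere travels with the distal segment
  expect_equal(b1$cas_pos, 0.2e6)
  expect_length(tet$chromatids$A1$cas_pos, 0)
})

test_that("cut probability zero and unsuppressed BLM produce no crossovers", {
  g <- toy_genome()
  dsb <- genome_feature(g, "dsb_site", label = "D1")
  tet <- replicate_to_4n(g, "toy")
  set.seed(9)
  cfg0 <- experiment_config(p_cut = 0)
  t0 <- induce_dsb_and_repair(tet, dsb, cfg0)
  expect_length(t0$outcomes, 0)
  expect_identical(t0$chromatids, tet$chromatids)
  # BLM unsuppressed: cuts happen, crossovers never do
  cfg1 <- experiment_config(blm_suppressed = FALSE, p_cut = 1)
  kinds <- unlist(replicate(200, vapply(
    induce_dsb_and_repair(tet, dsb, cfg1)$outcomes, `[[`, "", "kind")))
  expect_false("crossover" %in% kinds)
  expect_true(all(kinds %in% c("deletion", "gene_conversion", "none")))
})

test_that("deletion and gene conversion act on the cut chromatid only", {
  g <- toy_genome()
  dsb <- genome_feature(g, "dsb_site", label = "D1")
  tet <- replicate_to_4n(g, "toy")
  td <- apply_outcome(tet, "B1", "deletion", breakpoint = dsb$pos,
                      tract_len = 5000)
  expect_true(is_deleted_at(td$chromatids$B1, dsb$pos + 2500))
  expect_false(is_deleted_at(td$chromatids$B2, dsb$pos + 2500))
  tg <- apply_outcome(tet, "B1", "gene_conversion", breakpoint = dsb$pos,
                      partner = "A1", tract_len = 2000)
  expect_equal(hap_at(tg$chromatids$B1, dsb$pos + 1000), 1L)
  expect_equal(hap_at(tg$chromatids$B1, dsb$pos + 3000), 2L)
  expect_length(tg$chromatids$B1$cas_pos, 0)  # conversion never moves cassette
})

test_that("segregation enumeration: X-type in exactly half of assignments", {
  g <- toy_genome()
  tet <- replicate_to_4n(g, "toy")
  b <- 7.5e5
  tet <- apply_outcome(tet, "B1", "crossover", breakpoint = b, partner = "A1")
  probe <- c(b + 1e4, 9.9e5)
  # exhaustive enumeration of the 4 pole assignments
  homo_distal <- dual_cassette <- logical(0)
  for (s1 in 1:2) for (s2 in 1:2) {
    ds <- segregate_with_picks(tet, s1, s2)
    for (d in ds) {
      h1 <- hap_at(d$chromatids[[1]], probe)
      h2 <- hap_at(d$chromatids[[2]], probe)
      homo_distal <- c(homo_distal, all(h1 == h2))
      dual_cassette <- c(dual_cassette,
                         sum(vapply(d$chromatids,
                                    function(c) length(c$cas_pos), 0L)) == 2)
    }
  }
  expect_equal(mean(homo_distal), 0.5)      # X-type fraction exactly 1/2
  expect_equal(sum(dual_cassette), 2)       # one daughter per X-type config
  # Monte Carlo within 3 sigma of the enumeration value
  set.seed(23)
  n <- 10000
  x <- replicate(n, {
    d <- segregate(tet)[[1]]
    all(hap_at(d$chromatids[[1]], probe) == hap_at(d$chromatids[[2]], probe))
  })
  expect_lt(abs(mean(x) - 0.5), 3 * sqrt(0.25 / n))
  # no crossover: both daughters heterozygous at every probe
  tet0 <- replicate_to_4n(g, "toy")
  for (d in segregate_with_picks(tet0, 1, 2))
    expect_true(all(hap_at(d$chromatids[[1]], probe) !=
                    hap_at(d$chromatids[[2]], probe)))
})

test_that("dual-resistance fraction among X-type daughters matches 2q(1-q)", {
  g <- toy_genome()
  q <- 0.25; n <- 10000
  set.seed(31)
  hits <- replicate(n, {
    tet <- replicate_to_4n(g, "toy")
    tet <- apply_icre(tet, q)
    tet <- apply_outcome(tet, "B1", "crossover", breakpoint = 7.5e5,
                         partner = "A1")
    d <- segregate_with_picks(tet, 2, 1)[[1]]  # the dual-cassette daughter
    all(resistance_phenotype(d))
  })
  p <- 2 * q * (1 - q)
  expect_lt(abs(mean(hits) - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("resistance phenotype truth table", {
  g <- toy_genome()
  mk <- function(inv) {
    d <- forced_crossover_daughter(g, "toy", 7.5e5, inv = inv)
    resistance_phenotype(d)
  }
  expect_equal(unname(mk(c(FALSE, TRUE))), c(TRUE, TRUE))    # N + P
  expect_equal(unname(mk(c(FALSE, FALSE))), c(TRUE, FALSE))  # N only
  tet <- replicate_to_4n(g, "toy")
  d_empty <- segregate_with_picks(tet, 1, 1)[[2]]
  d_empty$chromatids <- lapply(d_empty$chromatids, function(ch) {
    ch$cas_pos <- numeric(0); ch$cas_inv <- logical(0); ch
  })
  expect_equal(unname(resistance_phenotype(d_empty)), c(FALSE, FALSE))
})

test_that("competitive PCR separates crossover, amplification and parental", {
  g <- toy_genome()
  # X-type crossover daughter, one N one P copy -> positive
  d <- forced_crossover_daughter(g, "toy", 7.5e5, inv = c(FALSE, TRUE))
  expect_setequal(competitive_pcr(d), c("N_allele", "P_allele"))
  # amplification without crossover keeps the wildtype allele
  tet <- replicate_to_4n(g, "toy")
  tet <- lohsim:::apply_icre_with_draws(tet, 1, u = c(0, 1))  # invert A1 copy
  ch <- tet$chromatids$A1
  tet$chromatids$A1 <- lohsim:::duplicate_cassette(ch, 1, inverted = FALSE)
  d_amp <- segregate_with_picks(tet, 1, 1)[[1]]  # {A1 dup, B1 wildtype}
  expect_setequal(competitive_pcr(d_amp),
                  c("wildtype", "N_allele", "P_allele"))
  expect_true(all(resistance_phenotype(d_amp)))
  # parental daughter: wildtype + N
  d_par <- segregate_with_picks(replicate_to_4n(g, "toy"), 1, 1)[[1]]
  expect_setequal(competitive_pcr(d_par), c("wildtype", "N_allele"))
})

test_that("rare events: UPD homozygoses the whole chromosome", {
  g <- toy_genome()
  tet <- replicate_to_4n(g, "toy")
  set.seed(2)
  tet <- apply_rare_events(tet, experiment_config(p_upd = 1,
                                                  p_amplification = 0))
  expect_true(tet$upd)
  d <- segregate_with_picks(tet, 1, 1, updpick = 1)[[1]]
  pos <- panel_positions(g, "toy")
  calls <- genotype_panel(d, pos)
  expect_true(all(calls$call == "homA"))  # centromeric SNPs included
  # both rates zero: no effect
  tet2 <- apply_rare_events(replicate_to_4n(g, "toy"),
                            experiment_config(p_upd = 0, p_amplification = 0))
  expect_false(tet2$upd)
  expect_length(tet2$outcomes, 0)
})

test_that("simulated cohorts are deterministic and respect the BLM switch", {
  g <- toy_genome()
  cfg <- make_cohort_config(overrides = list(
    n_cells = 3000, seed = 41,
    crossover_prob_given_cut_suppressed = 0.2))
  c1 <- simulate_experiment(g, "D1", cfg)
  c2 <- simulate_experiment(g, "D1", cfg)
  expect_identical(c1$clones, c2$clones)
  expect_identical(c1$counters, c2$counters)
  expect_gt(c1$counters$n_positive, 0)
  # negative arm: no BLM suppression -> no crossover-positive clones
  cfg_off <- make_cohort_config(overrides = list(
    n_cells = 3000, seed = 41, blm_suppressed = FALSE,
    p_amplification = 0, p_upd = 0))
  c0 <- simulate_experiment(g, "D1", cfg_off)
  expect_equal(c0$counters$n_crossover_outcomes, 0)
  expect_equal(c0$counters$n_positive, 0)
})

test_that("positive clones carry a contiguous LOH tract to the telomere", {
  g <- toy_genome()
  cfg <- make_cohort_config(overrides = list(
    n_cells = 4000, seed = 13, crossover_prob_given_cut_suppressed = 0.2,
    p_amplification = 0, p_upd = 0, genotype_error = 0))
  cohort <- simulate_experiment(g, "D1", cfg)
  pos <- panel_positions(g, "toy")
  positives <- Filter(function(cl) cl$positive, cohort$clones)
  expect_gt(length(positives), 0)
  for (cl in positives[seq_len(min(20, length(positives)))]) {
    if (cl$truth$n_crossovers != 1) next
    calls <- genotype_panel(cl$daughter, pos)
    hom <- calls$call != "het"
    b <- cl$truth$breakpoint
    expect_true(all(hom[calls$pos > b]))   # LOH from breakpoint to q telomere
    expect_false(any(hom[calls$pos < b]))
  }
})
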