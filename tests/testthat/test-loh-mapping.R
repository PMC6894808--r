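test_that("genotype panels reflect the daughter's haplotype structure", {
  g <- toy_genome()
  pos <- panel_positions(g, "toy")
  # no crossover -> all het
  d0 <- segregate_with_picks(replicate_to_4n(g, "toy"), 1, 1)[[1]]
  expect_true(all(genotype_panel(d0, pos)$call == "het"))
  # X-type daughter: het centromeric of b, hom telomeric of it
  b <- 7.6e5
  d <- forced_crossover_daughter(g, "toy", b)
  calls <- genotype_panel(d, pos)
  expect_true(all(calls$call[calls$pos < b] == "het"))
  expect_true(all(calls$call[calls$pos > b] == "homA"))
  # deletion -> hemizygous hom of the remaining haplotype
  dd <- d0
  dd$chromatids[[2]] <- add_deletion(dd$chromatids[[2]], 7e5, 7.2e5)
  cd <- genotype_panel(dd, pos)
  in_del <- cd$pos >= 7e5 & cd$pos <= 7.2e5
  expect_true(all(cd$call[in_del] == "homA"))
})

test_that("genotype error flips calls at the configured binomial rate", {
  g <- toy_genome(density = 1 / 100)  # dense panel -> many calls
  pos <- panel_positions(g, "toy")
  d0 <- segregate_with_picks(replicate_to_4n(g, "toy"), 1, 1)[[1]]
  err <- 0.01
  set.seed(3)
  reps <- ceiling(10000 / length(pos))
  flips <- sum(replicate(reps,
    sum(genotype_panel(d0, pos, genotype_error = err)$call != "het")))
  n <- reps * length(pos)
  expect_lt(abs(flips / n - err), 3 * sqrt(err * (1 - err) / n))
})

test_that("panel smoothing flips short flanked runs and nothing else", {
  mk <- function(calls) data.frame(pos = seq_along(calls) * 1000,
                                   call = calls)
  x <- mk(c(rep("het", 10), "homA", rep("het", 10)))
  expect_true(all(smooth_panel(x, 3)$call == "het"))
  expect_equal(smooth_panel(x, 1), x)                     # k = 1 is identity
  y <- mk(c(rep("het", 10), rep("homA", 10)))
  expect_equal(smooth_panel(y, 3), y)                     # clean transition
  z <- mk(c(rep("homA", 5), rep("het", 2), rep("homA", 5)))
  expect_true(all(smooth_panel(z, 3)$call == "homA"))
  # run flanked by discordant values stays
  w <- mk(c(rep("het", 5), "homA", rep("homB", 5)))
  expect_equal(smooth_panel(w, 3), w)
  expect_error(smooth_panel(x, 2), "k")
})

test_that("midpoint rule: forced boundaries, rounding, degenerate panels", {
  spec <- chromosome_spec("chr19", 58.6e6, 24.5e6, 27.0e6)
  dsb <- 36e6
  mk <- function(pos, call) data.frame(pos = pos, call = call)
  calls <- mk(c(28e6, 8990000 + 27e6, 9010000 + 27e6, 58e6),
              c("het", "het", "homB", "homB"))
  cp <- infer_crossover_point(calls, spec, dsb)
  expect_equal(cp$status, "crossover")
  expect_equal(cp$point, 27e6 + 9000000)
  expect_equal(cp$bounding, c(35990000, 36010000))
  expect_equal(cp$side, "spanning")  # bounding interval straddles the DSB
  # odd midpoint rounds toward the centromere: down on q, up on p
  cq <- infer_crossover_point(mk(c(30e6, 30e6 + 1), c("het", "homA")),
                              spec, dsb)
  expect_equal(cq$point, 30e6)
  spec_p <- chromosome_spec("chr6", 170.8e6, 59e6, 60.5e6)
  cp_p <- infer_crossover_point(mk(c(31e6 + 1, 31e6), c("het", "homA")),
                                spec_p, 30e6)
  expect_equal(cp_p$point, 31e6 + 1)  # centromere is at higher coordinate
  # all het / all hom / re-entrant patterns
  expect_equal(infer_crossover_point(mk(c(28e6, 40e6), c("het", "het")),
                                     spec, dsb)$status, "no_loh")
  expect_equal(infer_crossover_point(mk(c(28e6, 40e6), c("homA", "homA")),
                                     spec, dsb)$status, "whole_chromosome")
  expect_equal(infer_crossover_point(
    mk(c(28e6, 30e6, 32e6), c("het", "homA", "het")), spec, dsb)$status,
    "complex")
})

test_that("side assignment matches truth for all error-free crossover clones", {
  g <- chr19_genome(seed = 19, density = 1 / 2000)
  cfg <- make_cohort_config(overrides = list(
    n_cells = 6000, seed = 71, crossover_prob_given_cut_suppressed = 0.3,
    p_amplification = 0, p_upd = 0, genotype_error = 0))
  cohort <- simulate_experiment(g, "9M", cfg)
  mapped <- map_cohort(cohort, panel_positions(g, "chr19"),
                       genotype_error = 0, k = 1)
  xo <- mapped[mapped$class == "crossover" &
               !is.na(mapped$true_breakpoint) &
               mapped$side %in% c("centromeric", "telomeric"), ]
  expect_gt(nrow(xo), 30)
  expect_equal(xo$side, xo$true_side)
  # inferred point lies inside the bounding interval of the true breakpoint
  pos <- panel_positions(g, "chr19")
  for (i in seq_len(nrow(xo))) {
    b <- xo$true_breakpoint[i]
    lo <- max(pos[pos < b]); hi <- min(pos[pos > b])
    expect_gte(xo$point[i], lo)
    expect_lte(xo$point[i], hi)
  }
})

test_that("clone classification separates the four outcome classes", {
  spec <- chromosome_spec("chr19", 58.6e6, 24.5e6, 27.0e6)
  dsb <- 36e6
  het_hom <- data.frame(pos = c(30e6, 35e6, 37e6, 50e6),
                        call = c("het", "het", "homA", "homA"))
  all_hom <- data.frame(pos = c(30e6, 50e6), call = c("homA", "homA"))
  all_het <- data.frame(pos = c(30e6, 50e6), call = c("het", "het"))
  expect_equal(classify_clone(c("wildtype", "N_allele", "P_allele"),
                              het_hom, spec, dsb), "aberrant_duplication")
  expect_equal(classify_clone(c("N_allele", "P_allele"), het_hom, spec, dsb),
               "crossover")
  expect_equal(classify_clone(c("N_allele", "P_allele"), all_hom, spec, dsb),
               "whole_chromosome_loh")
  expect_equal(classify_clone(c("N_allele", "P_allele"), all_het, spec, dsb),
               "no_loh")
})

test_that("aberrant duplications are always flagged by the wildtype band", {
  g <- toy_genome()
  cfg <- make_cohort_config(overrides = list(
    n_cells = 2000, seed = 5, p_cut = 0, p_amplification = 1, p_upd = 0))
  cohort <- simulate_experiment(g, "D1", cfg)
  mapped <- map_cohort(cohort, panel_positions(g, "toy"))
  expect_gt(nrow(mapped), 0)
  amp <- mapped[mapped$true_amplification, ]
  expect_true(all(amp$class == "aberrant_duplication"))
  expect_true(all(grepl("wildtype", amp$bands)))
})

test_that("midpoint estimator error shrinks with SNP spacing", {
  g <- chr19_genome(seed = 29)
  spec <- g$specs$chr19
  cfg <- make_cohort_config(overrides = list(
    n_cells = 3000, seed = 37, crossover_prob_given_cut_suppressed = 0.3,
    p_amplification = 0, p_upd = 0, genotype_error = 0))
  cohort <- simulate_experiment(g, "9M", cfg)
  prev <- Inf
  for (sp in c(50e3, 10e3, 2e3)) {
    panel <- seq(spec$cen_end + sp, spec$length, by = sp)
    mapped <- map_cohort(cohort, panel, genotype_error = 0, k = 1)
    xo <- mapped[mapped$class == "crossover" &
                 !is.na(mapped$true_breakpoint), ]
    err <- mean(abs(xo$point - xo$true_breakpoint))
    expect_lte(err, sp / 2 + 1)  # within half the inter-SNP spacing
    expect_lt(err, prev)        # bias and error shrink with spacing
    prev <- err
  }
})

test_that("cohort summary aggregates classes and per-side distances", {
  tab <- data.frame(
    id = sprintf("c%d", 1:5),
    bands = "N_allele+P_allele",
    class = c("crossover", "crossover", "crossover",
              "whole_chromosome_loh", "no_loh"),
    point = c(1, 2, 3, NA, NA),
    side = c("centromeric", "centromeric", "telomeric", NA, NA),
    distance_bp = c(18e3, 26e3, 310e3, NA, NA),
    stringsAsFactors = FALSE)
  s <- summarize_cohort(tab, n_screened = 1000)
  expect_equal(unname(s$counts["crossover"]), 3L)
  expect_equal(s$per_side$centromeric$n, 2)
  expect_equal(s$per_side$centromeric$mean_kb, 22)
  expect_equal(s$per_side$telomeric$median_kb, 310)
  expect_equal(s$efficiency, 5 / 1000)
  expect_error(summarize_cohort(tab[0, ]), "empty")
})

test_that("HLA report propagates haplotype labels through a crossover", {
  g <- make_genome("chr6p_hla", 1 / 20000, seed = 8)
  hla <- genome_feature(g, "hla_locus")
  # parental daughter: everything heterozygous
  d0 <- segregate_with_picks(replicate_to_4n(g, "chr6"), 1, 1)[[1]]
  r0 <- hla_report(d0, hla)
  expect_false(any(r0$homozygous))
  expect_setequal(unlist(r0[r0$locus == "A", c("allele1", "allele2")]),
                  c("A2", "A32"))
  # crossover between class I and III: class I homozygous, DRB1 het
  d <- forced_crossover_daughter(g, "chr6", 31.42e6, inv = c(FALSE, TRUE))
  r <- hla_report(d, hla)
  classI <- r[r$locus %in% c("A", "C", "B"), ]
  expect_true(all(classI$homozygous))
  expect_equal(unlist(r[r$locus == "A", c("allele1", "allele2")],
                      use.names = FALSE), c("A2", "A2"))
  expect_false(r$homozygous[r$locus == "DRB1"])
  expect_false(r$homozygous[r$locus == "DQB1"])
  # custom labels propagate verbatim
  hla2 <- make_hla_haplotypes(list(A = c("A24", "A11")))
  r2 <- hla_report(d0, hla2)
  expect_setequal(unlist(r2[r2$locus == "A", c("allele1", "allele2")]),
                  c("A24", "A11"))
})
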