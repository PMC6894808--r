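#' Experiment configuration
#'
#' All simulator probabilities, offset scales, noise rates and the root
#' seed. Defaults encode the study conditions: per-copy Cre inversion
#' probability 0.25 (observed inversion efficiency 20--30%), crossover
#' resolution offsets exponential with side-specific scales of 20 kb
#' (centromeric) and 300 kb (telomeric), and no crossover at all when BLM
#' is not suppressed (positive clones arise only when BLM suppression and
#' the DSB are combined).
#'
#' @param q_inversion Per-cassette-copy Cre inversion probability.
#' @param p_cut Per-target-haplotype-chromatid cut probability.
#' @param blm_suppressed Logical; dox Tet-Off and ML216 are both
#'   parameterisations of this one flag (`blm_agent` is metadata only).
#' @param blm_agent `"dox"` or `"ML216"`; recorded, no effect on rates.
#' @param crossover_prob_given_cut_suppressed,crossover_prob_given_cut_unsuppressed
#'   Probability that a cut resolves as a crossover under each BLM state.
#' @param p_centromeric_side Probability a crossover resolves centromeric
#'   to the DSB.
#' @param offset_scale_centromeric,offset_scale_telomeric Exponential
#'   scales (bp) of the crossover-to-DSB offset per side.
#' @param p_deletion,p_gene_conversion Conditional on a cut that does not
#'   resolve as crossover: probability of a distal deletion / a short
#'   gene-conversion tract (remaining mass resolves as `none`).
#' @param deletion_scale,gc_tract_scale Exponential scales (bp) of
#'   deletion and gene-conversion tract lengths.
#' @param p_amplification Per-cell probability of in-place cassette
#'   duplication without crossover (locus amplification).
#' @param p_upd Per-cell probability of whole-homolog replacement at
#'   segregation (uniparental disomy).
#' @param genotype_error Per-call het/hom flip probability in panels.
#' @param n_cells Cells per simulated experiment.
#' @param seed Root seed; all stage substreams derive from it.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(q_inversion = 0.25,
                              p_cut = 0.8,
                              blm_suppressed = TRUE,
                              blm_agent = "dox",
                              crossover_prob_given_cut_suppressed = 0.05,
                              crossover_prob_given_cut_unsuppressed = 0,
                              p_centromeric_side = 0.7,
                              offset_scale_centromeric = 2e4,
                              offset_scale_telomeric = 3e5,
                              p_deletion = 0.3,
                              p_gene_conversion = 0.4,
                              deletion_scale = 1e4,
                              gc_tract_scale = 1e3,
                              p_amplification = 1e-5,
                              p_upd = 1e-6,
                              genotype_error = 0.002,
                              n_cells = 10000,
                              seed = 1) {
  cfg <- list(q_inversion = q_inversion, p_cut = p_cut,
              blm_suppressed = blm_suppressed, blm_agent = blm_agent,
              crossover_prob_given_cut_suppressed = crossover_prob_given_cut_suppressed,
              crossover_prob_given_cut_unsuppressed = crossover_prob_given_cut_unsuppressed,
              p_centromeric_side = p_centromeric_side,
              offset_scale_centromeric = offset_scale_centromeric,
              offset_scale_telomeric = offset_scale_telomeric,
              p_deletion = p_deletion, p_gene_conversion = p_gene_conversion,
              deletion_scale = deletion_scale, gc_tract_scale = gc_tract_scale,
              p_amplification = p_amplification, p_upd = p_upd,
              genotype_error = genotype_error,
              n_cells = as.integer(n_cells), seed = as.integer(seed))
  probs <- cfg[grep("^(q_|p_|crossover_prob|genotype_error)", names(cfg))]
  probs <- probs[vapply(probs, is.numeric, TRUE)]
  if (any(unlist(probs) < 0 | unlist(probs) > 1))
    stop("probabilities must lie in [0, 1]")
  if (cfg$p_deletion + cfg$p_gene_conversion > 1)
    stop("p_deletion + p_gene_conversion must not exceed 1")
  if (cfg$offset_scale_centromeric <= 0 || cfg$offset_scale_telomeric <= 0 ||
      cfg$deletion_scale <= 0 || cfg$gc_tract_scale <= 0)
    stop("scales must be positive")
  structure(cfg, class = "experiment_config")
}

crossover_prob <- function(cfg) {
  if (cfg$blm_suppressed) cfg$crossover_prob_given_cut_suppressed
  else cfg$crossover_prob_given_cut_unsuppressed
}

# deterministic substream seed from (root seed, stream name); < 2^31
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

#' Replicate a chromosome to the 4N (G2) state
#'
#' Builds the post-replication tetrad: two sister chromatids per homolog.
#' The cassette-carrier sisters each carry one cassette in the default N
#' orientation; sisters are identical until iCre and the DSB act.
#'
#' @param genome A [phased_genome()] with a `cassette_site` on `chrom`.
#' @param chrom Chromosome name.
#' @return An object of class `tetrad` with chromatids `A1,A2,B1,B2`
#'   (pair 1 from homolog hapA, pair 2 from hapB).
#' @export
replicate_to_4n <- function(genome, chrom) {
  spec <- genome$specs[[chrom]]
  if (is.null(spec)) stop("unknown chromosome ", chrom)
  cas <- genome_feature(genome, "cassette_site", chrom)
  if (nrow(cas) != 1) stop("chromosome ", chrom, " has no cassette_site")
  carrier <- hap_code(cas$hap)
  mk <- function(hap) {
    if (hap == carrier)
      new_chromatid(chrom, spec$length, hap, cas$pos, FALSE)
    else new_chromatid(chrom, spec$length, hap)
  }
  structure(list(chrom = chrom, spec = spec, carrier = carrier,
                 cassette_pos = cas$pos,
                 chromatids = list(A1 = mk(1L), A2 = mk(1L),
                                   B1 = mk(2L), B2 = mk(2L)),
                 upd = FALSE, outcomes = list()),
            class = "tetrad")
}

# flip cassette copies given one uniform draw per copy (fixed order:
# chromatid A1,A2,B1,B2, copies in storage order)
apply_icre_with_draws <- function(tetrad, q_inversion, u) {
  k <- 0
  for (nm in names(tetrad$chromatids)) {
    ch <- tetrad$chromatids[[nm]]
    nc <- length(ch$cas_pos)
    if (nc) {
      flip <- u[k + seq_len(nc)] < q_inversion
      ch$cas_inv <- ch$cas_inv | flip
      tetrad$chromatids[[nm]] <- ch
      k <- k + nc
    }
  }
  tetrad
}

#' Cre-mediated cassette inversion
#'
#' Each cassette copy is independently inverted (N orientation to P
#' orientation) with probability `q_inversion`; inversion is modelled as
#' absorbing for the single exposure.
#'
#' @param tetrad A [replicate_to_4n()] tetrad.
#' @param q_inversion Per-copy inversion probability.
#' @return The tetrad with updated orientations.
#' @export
apply_icre <- function(tetrad, q_inversion) {
  ncop <- sum(vapply(tetrad$chromatids, function(c) length(c$cas_pos), 0L))
  apply_icre_with_draws(tetrad, q_inversion, stats::runif(ncop))
}

# which chromatid slots carry the DSB target haplotype
target_slots <- function(tetrad, target_hap) {
  if (hap_code(target_hap) == 1L) c("A1", "A2") else c("B1", "B2")
}

non_sisters <- function(slot) {
  if (slot %in% c("A1", "A2")) c("B1", "B2") else c("A1", "A2")
}

# draw a crossover breakpoint around the DSB; resample if it leaves the
# centromere-cassette interval (counted)
draw_breakpoint <- function(spec, dsb_pos, cassette_pos, side, scale,
                            off = NULL) {
  dir <- arm_direction(spec, dsb_pos)
  lim_c <- if (dir > 0) spec$cen_end else spec$cen_start
  resampled <- 0L
  repeat {
    o <- if (is.null(off)) stats::rexp(1, rate = 1 / scale) else off
    b <- if (side == "centromeric") dsb_pos - dir * o else dsb_pos + dir * o
    ok <- if (dir > 0) (b > lim_c && b < cassette_pos)
          else (b < lim_c && b > cassette_pos)
    if (ok) return(list(b = b, resampled = resampled))
    off <- NULL
    resampled <- resampled + 1L
  }
}

#' Apply one resolved repair outcome to a tetrad (deterministic core)
#'
#' Deterministic counterpart of [induce_dsb_and_repair()] for forcing a
#' known scenario: applies a crossover, deletion or gene-conversion
#' outcome at a given breakpoint to the named chromatid. Used by the
#' simulator's fast path and for constructing truth cases.
#'
#' @param tetrad A tetrad.
#' @param slot Chromatid name (`"A1"`, `"A2"`, `"B1"`, `"B2"`).
#' @param kind One of `crossover`, `deletion`, `gene_conversion`, `none`.
#' @param breakpoint Breakpoint / cut position in bp.
#' @param side `"centromeric"` or `"telomeric"` (crossovers; metadata).
#' @param partner Non-sister chromatid name (crossover, conversion donor).
#' @param tract_len Tract length in bp (deletion / gene conversion).
#' @return The modified tetrad; the outcome is appended to
#'   `tetrad$outcomes`.
#' @export
apply_outcome <- function(tetrad, slot, kind, breakpoint = NA, side = NA,
                          partner = NA, tract_len = NA) {
  spec <- tetrad$spec
  out <- list(chromatid = slot, kind = kind, breakpoint = breakpoint,
              side = side, partner = partner)
  if (kind == "crossover") {
    cr <- cross_chromatids(tetrad$chromatids[[slot]],
                           tetrad$chromatids[[partner]], breakpoint, spec)
    tetrad$chromatids[[slot]] <- cr$x
    tetrad$chromatids[[partner]] <- cr$y
  } else if (kind == "deletion") {
    ch <- tetrad$chromatids[[slot]]
    dir <- arm_direction(spec, breakpoint)
    s <- min(breakpoint, breakpoint + dir * tract_len)
    e <- max(breakpoint, breakpoint + dir * tract_len)
    tetrad$chromatids[[slot]] <- add_deletion(ch, round(s), round(e))
    out$interval <- c(round(s), round(e))
  } else if (kind == "gene_conversion") {
    ch <- tetrad$chromatids[[slot]]
    donor <- tetrad$chromatids[[partner]]
    dir <- arm_direction(spec, breakpoint)
    s <- min(breakpoint, breakpoint + dir * tract_len)
    e <- max(breakpoint, breakpoint + dir * tract_len)
    hap <- hap_at(donor, round((s + e) / 2))
    tetrad$chromatids[[slot]] <- set_tract(ch, max(1, round(s)),
                                           min(spec$length, round(e)), hap)
    out$interval <- c(round(s), round(e))
  }
  tetrad$outcomes <- c(tetrad$outcomes, list(out))
  tetrad
}

#' Allele-specific DSB induction and repair
#'
#' Each chromatid of the DSB's target haplotype is cut with probability
#' `p_cut`. A cut resolves as a crossover with a non-sister with
#' probability `crossover_prob_given_cut_*` (per the BLM-suppression
#' flag); the breakpoint sits at the DSB plus a side-specific exponential
#' offset (centromeric with probability `p_centromeric_side`). Breakpoints
#' falling inside the centromere or beyond the cassette-bearing interval
#' are resampled and counted. A cut that does not cross over resolves as a
#' distal deletion, a short gene-conversion tract copied from a
#' non-sister, or no scored change, per the configured priors.
#'
#' @param tetrad A tetrad (post [apply_icre()]).
#' @param dsb One row of the genome's features with `kind == "dsb_site"`.
#' @param cfg An [experiment_config()].
#' @return The tetrad; resolved outcomes accumulate in `tetrad$outcomes`.
#' @export
induce_dsb_and_repair <- function(tetrad, dsb, cfg) {
  stopifnot(dsb$kind == "dsb_site")
  spec <- tetrad$spec
  if (arm_direction(spec, dsb$pos) != arm_direction(spec, tetrad$cassette_pos) ||
      abs_telomeric_offset(spec, dsb$pos) >=
        abs_telomeric_offset(spec, tetrad$cassette_pos))
    stop("DSB must be centromeric to the cassette")
  cp <- crossover_prob(cfg)
  for (slot in target_slots(tetrad, dsb$hap)) {
    if (stats::runif(1) >= cfg$p_cut) next
    u <- stats::runif(1)
    partner <- sample(non_sisters(slot), 1)
    if (u < cp) {
      side <- if (stats::runif(1) < cfg$p_centromeric_side)
        "centromeric" else "telomeric"
      scale <- if (side == "centromeric") cfg$offset_scale_centromeric
               else cfg$offset_scale_telomeric
      bp <- draw_breakpoint(spec, dsb$pos, tetrad$cassette_pos, side, scale)
      tetrad <- apply_outcome(tetrad, slot, "crossover",
                              breakpoint = round(bp$b), side = side,
                              partner = partner)
    } else {
      v <- (u - cp) / max(1 - cp, .Machine$double.eps)
      if (v < cfg$p_deletion) {
        len <- stats::rexp(1, 1 / cfg$deletion_scale)
        tetrad <- apply_outcome(tetrad, slot, "deletion",
                                breakpoint = dsb$pos, tract_len = len)
      } else if (v < cfg$p_deletion + cfg$p_gene_conversion) {
        len <- stats::rexp(1, 1 / cfg$gc_tract_scale)
        tetrad <- apply_outcome(tetrad, slot, "gene_conversion",
                                breakpoint = dsb$pos, partner = partner,
                                tract_len = len)
      } else {
        tetrad <- apply_outcome(tetrad, slot, "none")
      }
    }
  }
  tetrad
}

#' Rare whole-chromosome and amplification events
#'
#' With probability `p_amplification` a cassette copy on a carrier
#' chromatid is duplicated in place (the wildtype homolog is untouched);
#' the duplicate's orientation is re-drawn with the Cre inversion
#' probability, since Cre is still active when amplification occurs. With
#' probability `p_upd` the chromosome is marked for whole-homolog
#' replacement at segregation (uniparental disomy).
#'
#' @inheritParams induce_dsb_and_repair
#' @return The tetrad, possibly with an `amplified` outcome or `upd` flag.
#' @export
apply_rare_events <- function(tetrad, cfg) {
  if (stats::runif(1) < cfg$p_amplification) {
    carriers <- names(tetrad$chromatids)[
      vapply(tetrad$chromatids, function(c) length(c$cas_pos) > 0, TRUE)]
    if (length(carriers)) {
      slot <- if (length(carriers) == 1) carriers else sample(carriers, 1)
      ch <- tetrad$chromatids[[slot]]
      k <- if (length(ch$cas_pos) == 1) 1L else sample(length(ch$cas_pos), 1)
      inv <- if (stats::runif(1) < cfg$q_inversion) !ch$cas_inv[k]
             else ch$cas_inv[k]
      tetrad$chromatids[[slot]] <- duplicate_cassette(ch, k, inv)
      tetrad$outcomes <- c(tetrad$outcomes,
                           list(list(chromatid = slot, kind = "amplification")))
    }
  }
  if (stats::runif(1) < cfg$p_upd) tetrad$upd <- TRUE
  tetrad
}

#' Deterministic segregation core
#'
#' Counterpart of [segregate()] with explicit pole assignments: `s1`,
#' `s2` pick which sister of the hapA and hapB pair goes to daughter 1;
#' under the UPD flag, `updpick` selects the pair daughter 1 keeps.
#' Enumerating `s1, s2` over `{1,2} x {1,2}` enumerates the full
#' segregation outcome space.
#'
#' @param tetrad A resolved tetrad.
#' @param s1,s2 Sister picks (1 or 2) for the hapA / hapB pair.
#' @param updpick Pair (1 = hapA, 2 = hapB) kept by daughter 1 under UPD.
#' @return List of two `daughter_genome` objects.
#' @export
segregate_with_picks <- function(tetrad, s1, s2, updpick = 1L) {
  ch <- tetrad$chromatids
  mk <- function(slots) {
    structure(list(chrom = tetrad$chrom, spec = tetrad$spec,
                   carrier = tetrad$carrier,
                   cassette_pos = tetrad$cassette_pos,
                   chromatids = ch[slots], provenance = slots,
                   upd = tetrad$upd, outcomes = tetrad$outcomes),
              class = "daughter_genome")
  }
  if (tetrad$upd) {
    pairs <- list(c("A1", "A2"), c("B1", "B2"))
    return(list(mk(pairs[[updpick]]), mk(pairs[[3 - updpick]])))
  }
  a <- c("A1", "A2")[c(s1, 3 - s1)]
  b <- c("B1", "B2")[c(s2, 3 - s2)]
  list(mk(c(a[1], b[1])), mk(c(a[2], b[2])))
}

#' Mitotic segregation of the tetrad
#'
#' Sisters of each centromere pair go to opposite poles; the two pole
#' assignments are independent and uniform. With a single crossover this
#' yields X-type segregation (recombinant distal segments co-segregate,
#' one daughter homozygous distal to the breakpoint) and Z-type
#' (heterozygosity retained) with probability 1/2 each. Under the UPD
#' flag, one daughter receives both chromatids of one homolog.
#'
#' @param tetrad A resolved tetrad.
#' @return List of two `daughter_genome` objects.
#' @export
segregate <- function(tetrad) {
  segregate_with_picks(tetrad, sample(2L, 1), sample(2L, 1), sample(2L, 1))
}

#' Drug-resistance phenotype of a daughter cell
#'
#' G418 resistance requires at least one non-deleted cassette copy in the
#' default N orientation; puromycin resistance requires at least one
#' Cre-inverted P copy.
#'
#' @param daughter A `daughter_genome`.
#' @return Named logical vector `c(g418, puro)`.
#' @export
resistance_phenotype <- function(daughter) {
  inv <- unlist(lapply(daughter$chromatids, `[[`, "cas_inv"))
  c(g418 = any(!inv), puro = any(inv))
}

#' Competitive PCR band pattern at the cassette site
#'
#' The wildtype band is present iff any chromatid carries the
#' non-cassette allele at the cassette site; the N and P bands report
#' cassette copies in default and inverted orientation. A clone is
#' "positive" (crossover candidate) iff the bands are exactly
#' `{N_allele, P_allele}` — losing the wildtype band is what distinguishes
#' cassette duplication by crossover from aberrant amplification.
#'
#' @param daughter A `daughter_genome`.
#' @param cassette_pos Cassette site in bp (defaults to the daughter's).
#' @return Character vector, subset of
#'   `c("wildtype", "N_allele", "P_allele")`.
#' @export
competitive_pcr <- function(daughter, cassette_pos = daughter$cassette_pos) {
  bands <- character(0)
  for (ch in daughter$chromatids) {
    has_cas <- any(abs(ch$cas_pos - cassette_pos) < 1)
    site_deleted <- is_deleted_at(ch, cassette_pos)
    if (!has_cas && !site_deleted) bands <- c(bands, "wildtype")
    if (any(!ch$cas_inv)) bands <- c(bands, "N_allele")
    if (any(ch$cas_inv)) bands <- c(bands, "P_allele")
  }
  sort(unique(bands))
}

is_positive_bands <- function(bands) setequal(bands, c("N_allele", "P_allele"))

#' Simulate a full selection experiment
#'
#' Runs `cfg$n_cells` cells through replication, iCre inversion, DSB and
#' repair, rare events and segregation, and retains daughters that pass
#' double (G418 + puromycin) selection. All randomness derives from
#' `cfg$seed` through named stage substreams, so cohorts are reproducible
#' component-wise; cells whose pre-drawn events cannot produce a
#' cassette-duplicated daughter (no crossover, amplification or UPD) are
#' counted and skipped without building chromatid structures.
#'
#' @param genome A [phased_genome()].
#' @param dsb_label Label of the `dsb_site` feature to use (e.g. `"9M"`).
#' @param cfg An [experiment_config()].
#' @return An object of class `clone_cohort`: list of clone records
#'   (daughter, bands, phenotype, truth metadata) plus per-stage counters.
#' @export
simulate_experiment <- function(genome, dsb_label, cfg) {
  dsb <- genome_feature(genome, "dsb_site", label = dsb_label)
  if (nrow(dsb) != 1) stop("dsb_site '", dsb_label, "' not found")
  chrom <- dsb$chrom
  spec <- genome$specs[[chrom]]
  cas <- genome_feature(genome, "cassette_site", chrom)
  n <- cfg$n_cells
  cp <- crossover_prob(cfg)

  draw <- function(name, fn) {
    set.seed(substream_seed(cfg$seed, name))
    fn()
  }
  u_inv <- draw("icre", function() matrix(stats::runif(2 * n), n))
  u_cut <- draw("cut", function() matrix(stats::runif(2 * n), n))
  rep_d <- draw("repair", function() list(
    out = matrix(stats::runif(2 * n), n),
    side = matrix(stats::runif(2 * n), n),
    off = matrix(stats::rexp(2 * n), n),
    len = matrix(stats::rexp(2 * n), n),
    partner = matrix(sample(2L, 2 * n, replace = TRUE), n)))
  rare <- draw("rare", function() list(
    amp = stats::runif(n), upd = stats::runif(n),
    amp_pick = stats::runif(n), amp_flip = stats::runif(n)))
  seg <- draw("segregate", function() list(
    s1 = sample(2L, n, replace = TRUE), s2 = sample(2L, n, replace = TRUE),
    updpick = sample(2L, n, replace = TRUE)))

  cut <- u_cut < cfg$p_cut
  xo <- cut & (rep_d$out < cp)
  is_amp <- rare$amp < cfg$p_amplification
  is_upd <- rare$upd < cfg$p_upd
  candidate <- xo[, 1] | xo[, 2] | is_amp | is_upd

  # per-chromatid outcome kinds, for counters
  v <- (rep_d$out - cp) / max(1 - cp, .Machine$double.eps)
  kind_mat <- matrix("none", n, 2)
  kind_mat[cut & rep_d$out < cp] <- "crossover"
  kind_mat[cut & rep_d$out >= cp & v < cfg$p_deletion] <- "deletion"
  kind_mat[cut & rep_d$out >= cp & v >= cfg$p_deletion &
             v < cfg$p_deletion + cfg$p_gene_conversion] <- "gene_conversion"
  kind_mat[!cut] <- "not_cut"

  set.seed(substream_seed(cfg$seed, "resample"))
  clones <- list()
  n_resampled <- 0L
  counters <- list(n_cells = n, n_cut = sum(cut),
                   n_crossover_outcomes = sum(kind_mat == "crossover"),
                   n_deletion_outcomes = sum(kind_mat == "deletion"),
                   n_gc_outcomes = sum(kind_mat == "gene_conversion"),
                   n_amplification = sum(is_amp), n_upd = sum(is_upd),
                   n_candidates = sum(candidate))
  for (i in which(candidate)) {
    tet <- replicate_to_4n(genome, chrom)
    tet <- apply_icre_with_draws(tet, cfg$q_inversion, u_inv[i, ])
    slots <- target_slots(tet, dsb$hap)
    for (k in 1:2) {
      if (!cut[i, k]) next
      slot <- slots[k]
      partner <- non_sisters(slot)[rep_d$partner[i, k]]
      kind <- kind_mat[i, k]
      if (kind == "crossover") {
        side <- if (rep_d$side[i, k] < cfg$p_centromeric_side)
          "centromeric" else "telomeric"
        scale <- if (side == "centromeric") cfg$offset_scale_centromeric
                 else cfg$offset_scale_telomeric
        bp <- draw_breakpoint(spec, dsb$pos, cas$pos, side, scale,
                              off = rep_d$off[i, k] * scale)
        n_resampled <- n_resampled + bp$resampled
        tet <- apply_outcome(tet, slot, "crossover", breakpoint = round(bp$b),
                             side = side, partner = partner)
      } else if (kind == "deletion") {
        tet <- apply_outcome(tet, slot, "deletion", breakpoint = dsb$pos,
                             tract_len = rep_d$len[i, k] * cfg$deletion_scale)
      } else if (kind == "gene_conversion") {
        tet <- apply_outcome(tet, slot, "gene_conversion",
                             breakpoint = dsb$pos, partner = partner,
                             tract_len = rep_d$len[i, k] * cfg$gc_tract_scale)
      } else {
        tet <- apply_outcome(tet, slot, "none")
      }
    }
    if (is_amp[i]) {
      carriers <- names(tet$chromatids)[
        vapply(tet$chromatids, function(c) length(c$cas_pos) > 0, TRUE)]
      if (length(carriers)) {
        slot <- carriers[1 + floor(rare$amp_pick[i] * length(carriers))]
        ch <- tet$chromatids[[slot]]
        inv <- if (rare$amp_flip[i] < cfg$q_inversion) !ch$cas_inv[1]
               else ch$cas_inv[1]
        tet$chromatids[[slot]] <- duplicate_cassette(ch, 1L, inv)
        tet$outcomes <- c(tet$outcomes,
                          list(list(chromatid = slot, kind = "amplification")))
      }
    }
    if (is_upd[i]) tet$upd <- TRUE
    daughters <- segregate_with_picks(tet, seg$s1[i], seg$s2[i], seg$updpick[i])
    for (d in daughters) {
      phen <- resistance_phenotype(d)
      if (!all(phen)) next
      bands <- competitive_pcr(d)
      xo_outs <- Filter(function(o) o$kind == "crossover", tet$outcomes)
      truth <- list(
        kinds = vapply(tet$outcomes, `[[`, "", "kind"),
        breakpoint = if (length(xo_outs) == 1) xo_outs[[1]]$breakpoint else NA,
        side = if (length(xo_outs) == 1) xo_outs[[1]]$side else NA,
        n_crossovers = length(xo_outs),
        amplification = is_amp[i], upd = is_upd[i], dsb_pos = dsb$pos)
      clones[[length(clones) + 1]] <- list(
        id = sprintf("clone_%05d", length(clones) + 1),
        cell = i, daughter = d, bands = bands,
        g418 = unname(phen["g418"]), puro = unname(phen["puro"]),
        positive = is_positive_bands(bands), truth = truth)
    }
  }
  counters$n_breakpoint_resampled <- n_resampled
  counters$n_survivors <- length(clones)
  counters$n_positive <- sum(vapply(clones, `[[`, TRUE, "positive"))
  counters$n_excluded_aberrant <- counters$n_survivors - counters$n_positive
  structure(list(clones = clones, counters = counters, cfg = cfg,
                 chrom = chrom, spec = spec,
                 dsb = list(label = dsb_label, pos = dsb$pos, hap = dsb$hap),
                 cassette_pos = cas$pos, carrier = cas$hap),
            class = "clone_cohort")
}

#' @export
print.clone_cohort <- function(x, ...) {
  ct <- x$counters
  cat("Clone cohort:", ct$n_cells, "cells on", x$chrom,
      "(DSB", x$dsb$label, "at", format(x$dsb$pos, big.mark = ","), "bp)\n")
  cat("  crossover outcomes:", ct$n_crossover_outcomes,
      "| survivors (NR PR):", ct$n_survivors,
      "| positive (no wildtype band):", ct$n_positive, "\n")
  invisible(x)
}
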