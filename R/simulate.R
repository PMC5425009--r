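#' Simulation configuration for the mapping study design
#'
#' Bundles every parameter of the synthetic study: a three-generation
#' backcross cohort segregating a completely dominant causal allele, plus
#' two small divergent resequencing panels fixed for opposite alleles
#' around the causal position (a selective-sweep signature).
#'
#' The default genome is a miniature three-chromosome analog ("1" = 20 Mb,
#' "2" = 15 Mb, "9" = 5 Mb) with the causal locus at 8.46 Mb on
#' chromosome "2", so per-chromosome density comparisons and Mb-scale
#' window scans are exercisable at desk scale.
#'
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param recomb_rate Recombination rate in cM/Mb; crossovers follow the
#'   Haldane (no-interference) map. Default 3 cM/Mb, a chicken
#'   macrochromosome-scale value.
#' @param founder_fst Divergence of the two founder breeds in `[0, 1)`;
#'   neutral allele frequencies are drawn per breed from a Balding-Nichols
#'   model with this parameter around a shared ancestral frequency.
#' @param n_sites_per_chrom Number of variant sites per chromosome (single
#'   count recycled, or a vector matching `chrom_lengths`).
#' @param causal_chrom,causal_pos Chromosome and 1-based position of the
#'   dominant causal variant.
#' @param penetrance Probability that a carrier of at least one causal
#'   allele is affected. 1 = complete dominance.
#' @param sweep_halfwidth Half-width in bp of the fixed-difference region
#'   around `causal_pos` (the swept haplotype).
#' @param n_f2 Number of backcross (F2) offspring.
#' @param n_families Number of wild-type dams (= families) in the backcross.
#' @param indel_fraction Fraction of sites labelled as InDels; they carry
#'   multi-base alleles and are distinguished only by the
#'   opposite-homozygote scan.
#' @param seed Integer seed; it fully determines all simulated output.
#'
#' @return An object of class `sim_config` (a named list).
#' @export
sim_config <- function(chrom_lengths = c("1" = 20e6, "2" = 15e6, "9" = 5e6),
                       recomb_rate = 3,
                       founder_fst = 0.15,
                       n_sites_per_chrom = 1667L,
                       causal_chrom = "2",
                       causal_pos = 8460000L,
                       penetrance = 1,
                       sweep_halfwidth = 200000L,
                       n_f2 = 98L,
                       n_families = 11L,
                       indel_fraction = 0.1,
                       seed = 1L) {
  chrom_lengths <- stats::setNames(as.numeric(chrom_lengths),
                                   names(chrom_lengths))
  if (is.null(names(chrom_lengths)) || any(names(chrom_lengths) == "")) {
    stop("`chrom_lengths` must be a named vector")
  }
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  n_sites_per_chrom <- as.integer(rep(n_sites_per_chrom,
                                      length.out = length(chrom_lengths)))
  if (any(n_sites_per_chrom <= 0)) stop("need at least one site per chromosome")
  if (!causal_chrom %in% names(chrom_lengths)) {
    stop("`causal_chrom` not in `chrom_lengths`")
  }
  if (causal_pos < 1 || causal_pos > chrom_lengths[[causal_chrom]]) {
    stop("`causal_pos` outside chromosome ", causal_chrom)
  }
  if (founder_fst < 0 || founder_fst >= 1) stop("`founder_fst` must be in [0, 1)")
  if (penetrance < 0 || penetrance > 1) stop("`penetrance` must be in [0, 1]")
  if (n_families > n_f2) stop("`n_families` cannot exceed `n_f2`")
  structure(list(chrom_lengths = chrom_lengths,
                 recomb_rate = recomb_rate,
                 founder_fst = founder_fst,
                 n_sites_per_chrom = n_sites_per_chrom,
                 causal_chrom = as.character(causal_chrom),
                 causal_pos = as.integer(causal_pos),
                 penetrance = penetrance,
                 sweep_halfwidth = as.integer(sweep_halfwidth),
                 n_f2 = as.integer(n_f2),
                 n_families = as.integer(n_families),
                 indel_fraction = indel_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Derive a per-stage sub-seed so that, e.g., adding sites does not perturb
# the phenotype draws (each stage has its own RNG stream).
sub_seed <- function(seed, stage) {
  (as.numeric(seed) * 2654435761 + stage * 97) %% 2147483647
}

# Site table shared by all simulated individuals. The causal position is
# always present as a site (the nearest drawn position is moved onto it).
sim_sites <- function(config) {
  set.seed(sub_seed(config$seed, 1))
  chroms <- names(config$chrom_lengths)
  tabs <- lapply(seq_along(chroms), function(k) {
    n <- config$n_sites_per_chrom[k]
    L <- config$chrom_lengths[[k]]
    pos <- sort(sample.int(L, n))
    data.frame(chrom = chroms[k], pos = pos, stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, tabs)
  ic <- which(sites$chrom == config$causal_chrom)
  nearest <- ic[which.min(abs(sites$pos[ic] - config$causal_pos))]
  sites$pos[nearest] <- config$causal_pos
  sites <- sites[order(sites$chrom, sites$pos), ]
  sites <- sites[!duplicated(sites[c("chrom", "pos")]), ]
  rownames(sites) <- NULL
  n <- nrow(sites)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  is_indel <- stats::runif(n) < config$indel_fraction
  ref[is_indel] <- paste0(ref[is_indel], "A")
  sites$id <- paste0("v", seq_len(n))
  sites$ref <- ref
  sites$alt <- unname(alt)
  sites$vtype <- ifelse(is_indel, "InDel", "SNP")
  causal_index <- which(sites$chrom == config$causal_chrom &
                          sites$pos == config$causal_pos)
  # the causal variant itself is a clean SNP
  if (sites$vtype[causal_index] == "InDel") {
    sites$ref[causal_index] <- substr(sites$ref[causal_index], 1, 1)
    sites$vtype[causal_index] <- "SNP"
  }
  attr(sites, "causal_index") <- causal_index
  sites
}

sweep_mask <- function(sites, config) {
  lo <- config$causal_pos - config$sweep_halfwidth
  hi <- config$causal_pos + config$sweep_halfwidth
  L <- config$chrom_lengths[[config$causal_chrom]]
  if (lo < 1 || hi > L) {
    warning("sweep region clipped to chromosome ", config$causal_chrom,
            " bounds")
    lo <- max(lo, 1)
    hi <- min(hi, L)
  }
  sites$chrom == config$causal_chrom & sites$pos >= lo & sites$pos <= hi
}

# Balding-Nichols founder allele frequencies. The alt allele is oriented as
# the BF (sweep) allele inside the sweep region: frequency 1 in BF, 0 in SZ.
founder_freqs <- function(config, sites) {
  set.seed(sub_seed(config$seed, 2))
  n <- nrow(sites)
  anc <- stats::runif(n, 0.05, 0.95)
  f <- config$founder_fst
  if (f > 0) {
    shape1 <- anc * (1 - f) / f
    shape2 <- (1 - anc) * (1 - f) / f
    bf <- stats::rbeta(n, shape1, shape2)
    sz <- stats::rbeta(n, shape1, shape2)
  } else {
    bf <- anc
    sz <- anc
  }
  swp <- sweep_mask(sites, config)
  bf[swp] <- 1
  sz[swp] <- 0
  list(bf = bf, sz = sz, ancestral = anc, sweep = swp)
}

draw_haplotype <- function(freqs) {
  as.integer(stats::runif(length(freqs)) < freqs)
}

# Recombination fraction between adjacent sites under the Haldane map.
# recomb_rate is cM/Mb, i.e. recomb_rate * 1e-8 Morgans per bp.
adjacent_recomb <- function(pos, recomb_rate) {
  d <- diff(pos)
  0.5 * (1 - exp(-2 * d * recomb_rate * 1e-8))
}

# Form one gamete from a pair of haplotypes, recombining independently per
# chromosome (Markov switch process == Poisson crossovers, no interference).
make_gamete <- function(hap1, hap2, sites, rmaps) {
  out <- integer(length(hap1))
  for (ch in names(rmaps)) {
    idx <- which(sites$chrom == ch)
    r <- rmaps[[ch]]
    state <- integer(length(idx))
    state[1] <- stats::rbinom(1, 1, 0.5)
    if (length(idx) > 1) {
      switches <- stats::runif(length(r)) < r
      state <- cumsum(c(state[1], switches)) %% 2
    }
    out[idx] <- ifelse(state == 0, hap1[idx], hap2[idx])
  }
  out
}

#' Simulate founder individuals of the two breeds
#'
#' Draws BF (carrier breed) and SZ (wild-type breed) founders. BF founders
#' are homozygous for the dominant causal allele and carry the fixed sweep
#' haplotype; SZ founders carry zero copies. Neutral-site genotypes are
#' drawn from breed-specific Balding-Nichols frequencies.
#'
#' @param config A [sim_config()].
#' @param n_bf,n_sz Number of founders per breed.
#' @return A `sim_cohort` list: `genotypes` ([genotype_matrix()]),
#'   `pedigree` (data frame), `causal_site_index`, `freqs` (the founder
#'   allele frequencies, for diagnostics), `config`.
#' @export
simulate_founders <- function(config, n_bf = 1L, n_sz = 1L) {
  stopifnot(inherits(config, "sim_config"))
  sites <- sim_sites(config)
  freqs <- founder_freqs(config, sites)
  set.seed(sub_seed(config$seed, 3))
  haps <- c(lapply(seq_len(n_bf), function(i) {
    list(draw_haplotype(freqs$bf), draw_haplotype(freqs$bf))
  }),
  lapply(seq_len(n_sz), function(i) {
    list(draw_haplotype(freqs$sz), draw_haplotype(freqs$sz))
  }))
  ids <- c(paste0("BF", seq_len(n_bf)), paste0("SZ", seq_len(n_sz)))
  codes <- t(vapply(haps, function(h) h[[1]] + h[[2]], integer(nrow(sites))))
  rownames(codes) <- ids
  gm <- genotype_matrix(codes, sites, ids)
  ci <- attr(sites, "causal_index")
  pop <- rep(c("BF", "SZ"), c(n_bf, n_sz))
  set.seed(sub_seed(config$seed, 5))
  carrier <- codes[, ci] >= 1
  affected <- carrier & stats::runif(length(ids)) < config$penetrance
  ped <- data.frame(family = "F0", id = ids, sire = NA_character_,
                    dam = NA_character_,
                    sex = rep_len(c(1L, 2L), length(ids)),
                    generation = "P", population = pop,
                    phenotype = factor(ifelse(affected, "case", "control"),
                                       levels = c("control", "case")),
                    stringsAsFactors = FALSE)
  structure(list(genotypes = gm, pedigree = ped, causal_site_index = ci,
                 freqs = freqs, haplotypes = haps, config = config),
            class = "sim_cohort")
}

#' Simulate the three-generation backcross mapping cohort
#'
#' Crosses one purebred BF male to one SZ female, then backcrosses the F1
#' sire to `n_families` unrelated SZ dams, producing `n_f2` offspring.
#' Gametes recombine under the Haldane map at `recomb_rate`; an offspring
#' carrying at least one causal allele is affected with probability
#' `penetrance`. With the defaults (98 F2, 11 dams, plus 2 founders and the
#' F1 sire) the cohort has 112 genotyped individuals.
#'
#' @param config A [sim_config()].
#' @return A `sim_cohort` list as in [simulate_founders()], with the full
#'   pedigree (generations `P`, `F1`, `F2`).
#' @export
simulate_backcross <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_families > config$n_f2) stop("`n_families` cannot exceed `n_f2`")
  sites <- sim_sites(config)
  freqs <- founder_freqs(config, sites)
  ci <- attr(sites, "causal_index")
  chroms <- names(config$chrom_lengths)
  rmaps <- lapply(stats::setNames(chroms, chroms), function(ch) {
    adjacent_recomb(sites$pos[sites$chrom == ch], config$recomb_rate)
  })

  set.seed(sub_seed(config$seed, 3))
  bf <- list(draw_haplotype(freqs$bf), draw_haplotype(freqs$bf))
  sz <- list(draw_haplotype(freqs$sz), draw_haplotype(freqs$sz))
  dams <- lapply(seq_len(config$n_families), function(i) {
    list(draw_haplotype(freqs$sz), draw_haplotype(freqs$sz))
  })

  set.seed(sub_seed(config$seed, 4))
  f1 <- list(make_gamete(bf[[1]], bf[[2]], sites, rmaps),
             make_gamete(sz[[1]], sz[[2]], sites, rmaps))
  dam_of <- rep(seq_len(config$n_families), length.out = config$n_f2)
  f2 <- lapply(seq_len(config$n_f2), function(i) {
    d <- dams[[dam_of[i]]]
    list(make_gamete(f1[[1]], f1[[2]], sites, rmaps),
         make_gamete(d[[1]], d[[2]], sites, rmaps))
  })

  haps <- c(list(bf, sz, f1), dams, f2)
  ids <- c("BF1", "SZ1", "F1-1",
           paste0("DAM", seq_len(config$n_families)),
           paste0("F2-", seq_len(config$n_f2)))
  codes <- t(vapply(haps, function(h) h[[1]] + h[[2]], integer(nrow(sites))))
  rownames(codes) <- ids
  gm <- genotype_matrix(codes, sites, ids)

  set.seed(sub_seed(config$seed, 5))
  carrier <- codes[, ci] >= 1
  affected <- carrier & stats::runif(length(ids)) < config$penetrance
  fam <- c("F0", "F0", "F0",
           paste0("FAM", seq_len(config$n_families)),
           paste0("FAM", dam_of))
  ped <- data.frame(
    family = fam,
    id = ids,
    sire = c(NA, NA, "BF1", rep(NA_character_, config$n_families),
             rep("F1-1", config$n_f2)),
    dam = c(NA, NA, "SZ1", rep(NA_character_, config$n_families),
            ids[3 + dam_of]),
    sex = c(1L, 2L, 1L, rep(2L, config$n_families),
            rep_len(c(1L, 2L), config$n_f2)),
    generation = c("P", "P", "F1", rep("P", config$n_families),
                   rep("F2", config$n_f2)),
    population = c("BF", "SZ", "BFxSZ", rep("SZ", config$n_families),
                   rep("BFxSZ", config$n_f2)),
    phenotype = factor(ifelse(affected, "case", "control"),
                       levels = c("control", "case")),
    stringsAsFactors = FALSE)
  structure(list(genotypes = gm, pedigree = ped, causal_site_index = ci,
                 freqs = freqs, config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("sim_cohort:", length(x$genotypes$samples), "individuals,",
      nrow(x$genotypes$sites), "sites\n")
  print(table(x$pedigree$generation, x$pedigree$phenotype))
  invisible(x)
}

#' Simulate the divergent resequencing panels
#'
#' Two small panels of the carrier breed, divergently fixed across the
#' sweep region: the "poly" group is homozygous for the sweep (alt)
#' haplotype over `causal_pos +/- sweep_halfwidth`, the "normal" group
#' homozygous for the reference alleles there. Neutral sites are drawn for
#' both groups from the same BF breed frequencies, so only the sweep region
#' is systematically differentiated.
#'
#' @param config A [sim_config()].
#' @param n_per_group Diploid individuals per panel (default 3, the
#'   three-versus-three resequencing design).
#' @return List with elements `poly` and `normal`, each a
#'   [genotype_matrix()] over the same site table.
#' @export
simulate_divergent_panels <- function(config, n_per_group = 3L) {
  stopifnot(inherits(config, "sim_config"))
  if (n_per_group < 1) stop("`n_per_group` must be >= 1")
  sites <- sim_sites(config)
  freqs <- founder_freqs(config, sites)
  swp <- freqs$sweep
  set.seed(sub_seed(config$seed, 6))
  draw_panel <- function(fixed_code, prefix) {
    codes <- t(vapply(seq_len(n_per_group), function(i) {
      g <- draw_haplotype(freqs$bf) + draw_haplotype(freqs$bf)
      g[swp] <- fixed_code
      g
    }, integer(nrow(sites))))
    rownames(codes) <- paste0(prefix, seq_len(n_per_group))
    genotype_matrix(codes, sites)
  }
  list(poly = draw_panel(2L, "POLY"),
       normal = draw_panel(0L, "NORM"))
}

#' Simulate offspring counts of a single mating
#'
#' Single-locus Mendelian transmission with a dominant-penetrance phenotype
#' model: each offspring receives one allele from each parent (a parent with
#' dosage g transmits the dominant allele with probability g/2), and a
#' carrier of at least one dominant allele is affected with probability
#' `penetrance`.
#'
#' @param n_offspring Number of offspring to simulate.
#' @param sire_genotype,dam_genotype Parental dosages in `{0, 1, 2}` of the
#'   dominant allele.
#' @param penetrance Carrier penetrance in `[0, 1]`.
#' @param seed Integer seed.
#' @return A list with `n_affected`, `n_unaffected` and `n_carriers`.
#' @export
simulate_breeding_program <- function(n_offspring, sire_genotype,
                                      dam_genotype, penetrance = 1,
                                      seed = 1L) {
  if (n_offspring < 1) stop("`n_offspring` must be >= 1")
  stopifnot(sire_genotype %in% 0:2, dam_genotype %in% 0:2,
            penetrance >= 0, penetrance <= 1)
  set.seed(seed)
  from_sire <- stats::rbinom(n_offspring, 1, sire_genotype / 2)
  from_dam <- stats::rbinom(n_offspring, 1, dam_genotype / 2)
  carrier <- (from_sire + from_dam) >= 1
  affected <- carrier & stats::runif(n_offspring) < penetrance
  list(n_affected = sum(affected),
       n_unaffected = sum(!affected),
       n_carriers = sum(carrier))
}

#' Genotype-phenotype validation panel at the candidate SNP
#'
#' Reconstructs, as individual records, the 138-bird validation panel
#' genotyped at the candidate G/T variant (rs80659072): affected birds are
#' 0 GG / 39 GT / 52 TT and normal birds 45 GG / 2 GT / 0 TT. The panel is
#' a deterministic fixture (no randomness).
#'
#' @return A list with `genotypes` (a one-site [genotype_matrix()]) and
#'   `phenotypes` (factor `control`/`case` aligned with samples).
#' @export
make_validation_fixture <- function() {
  counts <- c(case_GG = 0L, case_GT = 39L, case_TT = 52L,
              control_GG = 45L, control_GT = 2L, control_TT = 0L)
  dose <- rep(c(0L, 1L, 2L, 0L, 1L, 2L), counts)
  pheno <- rep(c("case", "control"), c(sum(counts[1:3]), sum(counts[4:6])))
  ids <- paste0(ifelse(pheno == "case", "PO", "NO"),
                unlist(lapply(c(sum(counts[1:3]), sum(counts[4:6])), seq_len)))
  site <- data.frame(chrom = "2", pos = 8460000L, id = "rs80659072",
                     ref = "G", alt = "T", vtype = "SNP",
                     stringsAsFactors = FALSE)
  gm <- genotype_matrix(matrix(dose, ncol = 1, dimnames = list(ids, NULL)),
                        site, ids)
  list(genotypes = gm,
       phenotypes = factor(pheno, levels = c("control", "case")))
}

#' Check Mendelian consistency of a simulated cohort
#'
#' Verifies for every offspring with recorded parents that each genotype is
#' attainable from the parental dosages (e.g. two homozygous-reference
#' parents cannot produce a heterozygote).
#'
#' @param cohort A `sim_cohort` from [simulate_backcross()].
#' @return `TRUE` if consistent, otherwise a character vector describing
#'   the first few violations.
#' @export
check_mendelian <- function(cohort) {
  ped <- cohort$pedigree
  codes <- cohort$genotypes$codes
  kids <- which(!is.na(ped$sire) & !is.na(ped$dam))
  viol <- character(0)
  for (k in kids) {
    s <- codes[ped$sire[k], ]
    d <- codes[ped$dam[k], ]
    o <- codes[ped$id[k], ]
    # transmissible allele sets: dosage 0 -> {0}, 1 -> {0,1}, 2 -> {1}
    min_ok <- (s == 2) + (d == 2)
    max_ok <- (s >= 1) + (d >= 1)
    bad <- which(o < min_ok | o > max_ok)
    if (length(bad)) {
      viol <- c(viol, paste0(ped$id[k], "@site", bad[1]))
      if (length(viol) >= 5) break
    }
  }
  if (length(viol) == 0) TRUE else viol
}
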