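#' Per-mating penetrance summaries
#'
#' Counts affected and unaffected offspring per mating group. Offspring
#' are the pedigree rows with both parents recorded and a non-missing
#' phenotype; groups with zero such offspring are omitted.
#'
#' @param pedigree Data frame with columns `id`, `sire`, `dam` and
#'   `phenotype` (factor/character `control`/`case`), e.g. the `pedigree`
#'   element of a `sim_cohort` or [read_samples()] output.
#' @param group_by `"sire"` (default, matching sire-centric selection),
#'   `"dam"` or `"pair"`.
#' @return Data frame with the grouping columns, `n_poly` (affected),
#'   `n_wild` (unaffected) and `penetrance = n_poly / (n_poly + n_wild)`.
#' @export
penetrance_by_mating <- function(pedigree, group_by = c("sire", "dam", "pair")) {
  group_by <- match.arg(group_by)
  off <- pedigree[!is.na(pedigree$sire) & !is.na(pedigree$dam) &
                    !is.na(pedigree$phenotype), , drop = FALSE]
  key <- switch(group_by,
                sire = off$sire,
                dam = off$dam,
                pair = paste(off$sire, off$dam, sep = " x "))
  aff <- as.character(off$phenotype) == "case"
  n_poly <- tapply(aff, key, sum)
  n_wild <- tapply(!aff, key, sum)
  out <- data.frame(group = names(n_poly),
                    n_poly = as.integer(n_poly),
                    n_wild = as.integer(n_wild),
                    stringsAsFactors = FALSE)
  names(out)[1] <- group_by
  out$penetrance <- out$n_poly / (out$n_poly + out$n_wild)
  rownames(out) <- NULL
  out
}

#' Select parents whose penetrance exceeds a threshold
#'
#' Strict inequality, so "above 90 percent" excludes a parent at exactly 0.90.
#'
#' @param summaries Output of [penetrance_by_mating()].
#' @param threshold Minimum (exclusive) penetrance.
#' @return The qualifying subset of `summaries`.
#' @export
select_by_penetrance <- function(summaries, threshold) {
  summaries[summaries$penetrance > threshold, , drop = FALSE]
}

#' Reciprocal-cross test for sex linkage
#'
#' Pools offspring counts by the sex of the carrier parent and tests
#' whether the affected proportion differs between the two orientations
#' (carrier sire vs carrier dam) with a two-sided Fisher exact test.
#' Under autosomal inheritance the proportions agree and sex linkage is
#' rejected as an explanation.
#'
#' @param summaries Data frame with columns `carrier_sex` (values
#'   `"male"`/`"female"`), `n_poly` and `n_wild`, one row per mating or
#'   per pooled group.
#' @return List with `table` (2x2 orientation x phenotype counts),
#'   `odds_ratio` (sample odds ratio of the pooled table) and `p_value`.
#' @export
reciprocal_cross_test <- function(summaries) {
  need <- c("carrier_sex", "n_poly", "n_wild")
  if (!all(need %in% names(summaries))) {
    stop("`summaries` must have columns ", paste(need, collapse = ", "))
  }
  orient <- factor(summaries$carrier_sex, levels = c("male", "female"))
  if (any(is.na(orient))) stop("carrier_sex must be \"male\" or \"female\"")
  if (length(unique(orient)) < 2) {
    stop("both cross orientations must be present")
  }
  tab <- rbind(male = c(poly = sum(summaries$n_poly[orient == "male"]),
                        wild = sum(summaries$n_wild[orient == "male"])),
               female = c(poly = sum(summaries$n_poly[orient == "female"]),
                          wild = sum(summaries$n_wild[orient == "female"])))
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  p <- stats::fisher.test(tab)$p.value
  list(table = tab, odds_ratio = unname(or), p_value = p)
}

#' Expected affected fraction under dominant Mendelian transmission
#'
#' @param sire_genotype,dam_genotype Parental dosages in `{0, 1, 2}` of
#'   the dominant allele.
#' @param penetrance Carrier penetrance in `[0, 1]`.
#' @return `P(offspring carries >= 1 dominant allele) * penetrance`.
#' @export
dominance_expectation <- function(sire_genotype, dam_genotype,
                                  penetrance = 1) {
  stopifnot(all(sire_genotype %in% 0:2), all(dam_genotype %in% 0:2),
            penetrance >= 0, penetrance <= 1)
  (1 - (1 - sire_genotype / 2) * (1 - dam_genotype / 2)) * penetrance
}

#' Exact binomial test of an observed segregation ratio
#'
#' Two-sided exact binomial test of the affected count against a Mendelian
#' expectation (e.g. 0.5 for a backcross of a heterozygote, 0.75 for an
#' intercross).
#'
#' @param n_poly,n_total Affected count and total offspring.
#' @param expected Expected affected fraction in `[0, 1]`.
#' @return The two-sided exact p-value.
#' @export
segregation_fit <- function(n_poly, n_total, expected) {
  stopifnot(expected >= 0, expected <= 1, n_poly <= n_total)
  # binom.test returns a logical at the degenerate p = 0 / p = 1 bounds
  as.numeric(stats::binom.test(n_poly, n_total, p = expected)$p.value)
}

#' Genotype-by-phenotype contingency analysis at one site
#'
#' Tabulates phenotype (rows) against the three genotype classes of one
#' biallelic site (columns labelled by allele pairs, e.g. GG/GT/TT), then
#' evaluates the dominant model by collapsing to carrier vs non-carrier:
#' carrier penetrance (affected carriers over all carriers) and a
#' two-sided Fisher exact p-value on the collapsed 2x2 table.
#'
#' @param x A one-site [genotype_matrix()] (or larger, with `site`
#'   selecting the column).
#' @param phenotypes Factor `control`/`case` aligned with samples.
#' @param site Site index (default 1).
#' @return List with `table` (2x3 counts over non-missing samples),
#'   `carrier_penetrance`, `affected_noncarriers`, `fisher_p` and
#'   `collapsed` (the 2x2 carrier table).
#' @export
genotype_phenotype_table <- function(x, phenotypes, site = 1) {
  stopifnot(inherits(x, "genotype_matrix"))
  g <- x$codes[, site]
  ref <- x$sites$ref[site]
  alt <- x$sites$alt[site]
  ph <- factor(as.character(phenotypes), levels = c("case", "control"))
  keep <- !is.na(g) & !is.na(ph)
  g <- g[keep]; ph <- ph[keep]
  glab <- factor(c(paste0(ref, ref), paste0(ref, alt),
                   paste0(alt, alt))[g + 1],
                 levels = c(paste0(ref, ref), paste0(ref, alt),
                            paste0(alt, alt)))
  tab <- table(phenotype = ph, genotype = glab)
  carrier <- factor(ifelse(g >= 1, "carrier", "non-carrier"),
                    levels = c("carrier", "non-carrier"))
  coll <- table(phenotype = ph, carrier)
  n_car <- sum(coll[, "carrier"])
  pen <- if (n_car > 0) coll["case", "carrier"] / n_car else NA_real_
  p <- if (all(dim(coll) == c(2, 2)) && sum(coll) > 0) {
    stats::fisher.test(coll)$p.value
  } else {
    NA_real_
  }
  list(table = tab,
       carrier_penetrance = unname(pen),
       affected_noncarriers = unname(coll["case", "non-carrier"]),
       fisher_p = p,
       collapsed = coll)
}
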