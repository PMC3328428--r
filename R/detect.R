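#' Infer a male genotype from allele read depths
#'
#' A male's genotype at a candidate sex-linked site cannot be trusted from a
#' diploid caller, which assumes both alleles are expressed at similar
#' levels; a weakly expressed Y allele makes heterozygous males look
#' homozygous.  Genotypes are therefore re-inferred from the allele depths.
#' Under the default `"support"` rule a male is heterozygous as soon as both
#' alleles have at least `min_y_reads` supporting reads (and the minor
#' fraction meets `min_minor_fraction`); homozygous when only one allele has
#' support; missing when the total depth is below `min_depth`.  Equal
#' depths still count as heterozygous: the rule is support-based, not
#' ratio-based.  The `"binomial"` rule instead rejects homozygosity when
#' the minor depth is unlikely under a per-read error rate.
#'
#' @param depth_ref,depth_alt Numeric vectors of per-allele read depths.
#' @param control A [sexlink_control()] object.
#' @return Character vector: `"het"`, `"hom"` or `"missing"`.
#' @examples
#' infer_male_genotype(c(30, 30, 0), c(1, 0, 0))
#' @export
infer_male_genotype <- function(depth_ref, depth_alt,
                                control = sexlink_control()) {
  stopifnot(length(depth_ref) == length(depth_alt))
  total <- depth_ref + depth_alt
  minor <- pmin(depth_ref, depth_alt)
  frac <- ifelse(total > 0, minor / total, 0)
  if (control$male_rule == "support") {
    het <- depth_ref >= control$min_y_reads &
      depth_alt >= control$min_y_reads &
      frac >= control$min_minor_fraction &
      minor >= 1L
  } else {
    p <- pbinom(minor - 1, total, control$binom_error, lower.tail = FALSE)
    het <- minor >= 1L & p < control$binom_alpha
  }
  out <- ifelse(het, "het", "hom")
  out[total < control$min_depth] <- "missing"
  out
}

# Vectorized site classification over a whole snp_table.  Returns a
# data.frame aligned with snps$sites: status, reason, x_is_ref.
classify_sites_core <- function(snps, control) {
  samples <- snps$samples
  m <- samples$sex == "male"
  f <- samples$sex == "female"
  nm <- sum(m); nf <- sum(f)
  n <- nrow(snps$sites)

  mg <- matrix(infer_male_genotype(snps$ad_ref[, m], snps$ad_alt[, m], control),
               nrow = n)
  male_missing <- rowSums(mg == "missing") > 0L
  male_all_het <- rowSums(mg == "het") == nm

  fgt <- snps$gt[, f, drop = FALSE]
  fem_missing <- rowSums(is.na(fgt)) > 0L
  hom_ref <- !is.na(fgt) & fgt == "0/0"
  hom_alt <- !is.na(fgt) & fgt == "1/1"
  if (control$strict_females) {
    fr <- snps$ad_ref[, f, drop = FALSE]
    fa <- snps$ad_alt[, f, drop = FALSE]
    tot <- fr + fa
    ok_ref <- tot == 0 | fa / pmax(tot, 1L) <= control$female_max_minor
    ok_alt <- tot == 0 | fr / pmax(tot, 1L) <= control$female_max_minor
    hom_ref <- hom_ref & ok_ref
    hom_alt <- hom_alt & ok_alt
  }
  fem_all_ref <- rowSums(hom_ref) == nf
  fem_all_alt <- rowSums(hom_alt) == nf

  sl <- !male_missing & !fem_missing & male_all_het &
    (fem_all_ref | fem_all_alt)
  reason <- rep("sex_linked", n)
  reason[!sl & (male_missing | fem_missing)] <- "missing_individual"
  reason[!sl & !male_missing & !fem_missing & !male_all_het] <- "male_not_all_het"
  reason[!sl & !male_missing & !fem_missing & male_all_het] <- "females_not_hom_same"
  data.frame(contig_id = snps$sites$contig_id,
             position = snps$sites$position,
             status = ifelse(sl, "sex_linked",
                             ifelse(reason == "missing_individual",
                                    "disqualified", "not_sex_linked")),
             reason = reason,
             x_is_ref = ifelse(sl, fem_all_ref, NA),
             stringsAsFactors = FALSE)
}

#' Classify all sites of an SNP table for sex linkage
#'
#' Applies the segregation filter site by site: a SNP is sex-linked when
#' every male is heterozygous (genotypes re-inferred from read depths, see
#' [infer_male_genotype()]) and every female is homozygous for the same
#' allele (female genotypes taken from the genotype column as produced
#' upstream).  A site at which any individual is missing is disqualified.
#' At a sex-linked SNP the shared female allele is the X allele and the
#' other allele is the Y allele.
#'
#' @param snps A [snp_table()].
#' @param control A [sexlink_control()].
#' @return A `data.frame` aligned with `snps$sites`: `contig_id`,
#'   `position`, `status` (`"sex_linked"`, `"not_sex_linked"` or
#'   `"disqualified"`), `reason`, and `x_is_ref` (`TRUE` when the reference
#'   allele is the X allele; `NA` for non-sex-linked sites).
#' @export
classify_sites <- function(snps, control = sexlink_control()) {
  stopifnot(inherits(snps, "snp_table"))
  check_samples(snps$samples)
  classify_sites_core(snps, control)
}

#' Classify a single site
#'
#' Convenience wrapper around [classify_sites()] for one site given as
#' per-individual vectors; useful for small worked examples and for
#' property checks against exhaustive enumeration.
#'
#' @param genotype Character vector of genotypes (`"0/0"`, `"0/1"`,
#'   `"1/1"`, `NA`), one per individual.  Only female entries are used.
#' @param depth_ref,depth_alt Per-individual allele depths.
#' @param sex Character vector, `"male"`/`"female"`.
#' @param ref,alt Allele labels (defaults `"A"`/`"B"`).
#' @param control A [sexlink_control()].
#' @return A list with `sex_linked` (logical), `x_allele`, `y_allele`
#'   (allele labels or `NA`) and `reason`.
#' @examples
#' classify_site(c("0/1", "0/1", "0/0", "0/0"),
#'               depth_ref = c(30, 25, 40, 38), depth_alt = c(5, 1, 0, 0),
#'               sex = c("male", "male", "female", "female"))
#' @export
classify_site <- function(genotype, depth_ref, depth_alt, sex,
                          ref = "A", alt = "B",
                          control = sexlink_control()) {
  samples <- sample_table(paste0("i", seq_along(sex)), sex)
  st <- snp_table(data.frame(contig_id = "c", position = 1L,
                             ref = ref, alt = alt, stringsAsFactors = FALSE),
                  gt = matrix(genotype, nrow = 1),
                  ad_ref = matrix(as.integer(depth_ref), nrow = 1),
                  ad_alt = matrix(as.integer(depth_alt), nrow = 1),
                  samples = samples)
  cl <- classify_sites_core(st, control)
  sl <- cl$status == "sex_linked"
  list(sex_linked = sl,
       x_allele = if (sl) { if (cl$x_is_ref) ref else alt } else NA_character_,
       y_allele = if (sl) { if (cl$x_is_ref) alt else ref } else NA_character_,
       reason = cl$reason)
}

# Per-site X-polymorphism flag on sites that are NOT sex-linked:
#  (a) any female heterozygous (from GT),
#  (b) any male heterozygous (from read depths),
#  (c) all individuals homozygous but not all for the same allele.
# Sites with a missing individual are not counted as evidence.
xpoly_site_flags <- function(snps, control) {
  samples <- snps$samples
  m <- samples$sex == "male"
  f <- samples$sex == "female"
  n <- nrow(snps$sites)
  fgt <- snps$gt[, f, drop = FALSE]
  any_f_het <- rowSums(!is.na(fgt) & fgt == "0/1") > 0L
  fem_missing <- rowSums(is.na(fgt)) > 0L

  mg <- matrix(infer_male_genotype(snps$ad_ref[, m], snps$ad_alt[, m], control),
               nrow = n)
  any_m_het <- rowSums(mg == "het") > 0L
  male_missing <- rowSums(mg == "missing") > 0L

  # homozygous-allele identity: males by read majority, females by GT
  m_ref <- snps$ad_ref[, m, drop = FALSE] >= snps$ad_alt[, m, drop = FALSE]
  all_hom <- !any_f_het & !any_m_het & !fem_missing & !male_missing
  f_is_ref <- !is.na(fgt) & fgt == "0/0"
  n_ref <- rowSums(m_ref & mg == "hom") + rowSums(f_is_ref)
  n_hom <- rowSums(mg == "hom") + rowSums(!is.na(fgt) & fgt != "0/1")
  hom_discordant <- all_hom & n_ref > 0L & n_ref < n_hom

  flag <- (any_f_het | any_m_het | hom_discordant) & !fem_missing & !male_missing
  flag
}

#' Detect X-linked polymorphism on sex-linked contigs
#'
#' On a sex-linked contig, the sites that are not themselves sex-linked can
#' still reveal polymorphism among the X copies: a heterozygous female, a
#' heterozygous male at a non-sex-linked site, or all individuals
#' homozygous but not for the same allele.  Residual X heterozygosity that
#' is *expressed* in females is the signal used to discriminate between
#' dosage-compensation mechanisms (an X-inactivation-like mechanism would
#' silence one female allele and hide such polymorphism).
#'
#' @param snps A [snp_table()].
#' @param site_class Result of [classify_sites()] on `snps`.
#' @param control A [sexlink_control()].
#' @return Named logical vector over sex-linked contigs: `TRUE` when at
#'   least one non-sex-linked site of the contig shows X polymorphism.
#' @export
detect_x_polymorphism <- function(snps, site_class,
                                  control = sexlink_control()) {
  stopifnot(inherits(snps, "snp_table"))
  flags <- xpoly_site_flags(snps, control)
  sl_contigs <- unique(site_class$contig_id[site_class$status == "sex_linked"])
  non_sl <- site_class$status != "sex_linked"
  res <- vapply(sl_contigs, function(cid) {
    idx <- non_sl & site_class$contig_id == cid
    any(flags[idx])
  }, logical(1))
  setNames(res, sl_contigs)
}

#' Classify contigs from per-site results
#'
#' Counts sex-linked SNPs per contig and sets the contig-level flags: a
#' contig with at least one sex-linked SNP is called sex-linked; at least
#' two sex-linked SNPs gives the stricter flag (`passes_strict`), the set
#' used when an especially low false-positive rate is needed.
#'
#' @param snps A [snp_table()].
#' @param site_class Result of [classify_sites()]; computed if missing.
#' @param control A [sexlink_control()].
#' @return A `data.frame` with one row per contig: `contig_id`,
#'   `n_sexlinked_snps`, `is_sex_linked`, `passes_strict`,
#'   `x_polymorphic` (`NA` for non-sex-linked contigs).
#' @export
classify_contigs <- function(snps, site_class = NULL,
                             control = sexlink_control()) {
  stopifnot(inherits(snps, "snp_table"))
  if (is.null(site_class)) site_class <- classify_sites(snps, control)
  contigs <- unique(site_class$contig_id)
  n_sl <- rowsum((site_class$status == "sex_linked") + 0L,
                 group = site_class$contig_id)[, 1]
  n_sl <- n_sl[contigs]
  out <- data.frame(contig_id = contigs,
                    n_sexlinked_snps = as.integer(n_sl),
                    is_sex_linked = n_sl >= 1L,
                    passes_strict = n_sl >= 2L,
                    x_polymorphic = NA,
                    stringsAsFactors = FALSE)
  if (any(out$is_sex_linked)) {
    xp <- detect_x_polymorphism(snps, site_class, control)
    out$x_polymorphic[match(names(xp), out$contig_id)] <- xp
  }
  rownames(out) <- NULL
  out
}
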