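#' Sex-linkage and dosage-compensation analysis
#'
#' The main driver: detects sex-linked SNPs by their family segregation
#' pattern (every male heterozygous, every female homozygous for the same
#' allele), quantifies normalized X- and Y-allele expression at the
#' sex-linked SNP positions, forms the per-contig Y/X and Xmale/2Xfemale
#' ratios, and runs the degeneration and dosage-compensation tests.
#'
#' Inputs can be file paths (VCF with `GT`/`AD`, TSVs) or the in-memory
#' objects produced by the package, including a whole simulated dataset
#' from [simulate_dataset()] as the first argument.
#'
#' @param vcf Path to a VCF, a [snp_table()], or a `"sexlink_sim"` object
#'   (in which case the remaining data arguments are taken from it).
#' @param samples Sample table or path (see [sample_table()]); at least
#'   one male and one female.
#' @param composition Library-composition table or path
#'   (see [read_library_composition()]).
#' @param contig_lengths Optional contig-length table or path (TSV or
#'   FASTA); enables RPKM-based profiles.
#' @param control A [sexlink_control()].
#' @return An object of class `"sexlink"` with elements `samples`,
#'   `control`, `sites` (per-site classification), `contigs` (per-contig
#'   classification and dosage record), `expression` (long allele-class
#'   table), `summaries` (per-sex summaries), `tests` (Y-reduction and
#'   Xmale/2Xfemale Wilcoxon tests) and `log` (seed-free run metadata).
#' @examples
#' sim <- simulate_dataset(sim_config(n_sexlinked = 30, n_autosomal = 30,
#'                                    seed = 11))
#' fit <- sexlink(sim)
#' fit
#' summary(fit)
#' @seealso [build_dosage_profile()], [heterozygosity_comparison()],
#'   [write_report()]
#' @export
sexlink <- function(vcf, samples = NULL, composition = NULL,
                    contig_lengths = NULL,
                    control = sexlink_control()) {
  if (inherits(vcf, "sexlink_sim")) {
    if (is.null(samples)) samples <- vcf$samples
    if (is.null(composition)) composition <- vcf$library
    if (is.null(contig_lengths)) contig_lengths <- vcf$contigs
    snps <- vcf$snps
  } else {
    if (is.character(samples)) samples <- read_sample_table(samples)
    if (is.null(samples)) stop("'samples' is required")
    check_samples(samples)
    snps <- if (is.character(vcf)) read_snp_table(vcf, samples) else vcf
  }
  stopifnot(inherits(snps, "snp_table"))
  check_samples(snps$samples)
  if (is.null(composition))
    stop("'composition' (library composition) is required; see read_library_composition()")
  if (is.character(composition)) {
    if (!file.exists(composition))
      stop("library-composition file not found: ", composition)
    composition <- read_library_composition(composition)
  }
  composition <- validate_composition(composition)
  if (is.character(contig_lengths))
    contig_lengths <- read_contig_info(contig_lengths)

  sites <- classify_sites(snps, control)
  contigs <- classify_contigs(snps, sites, control)
  expr <- allele_expression(snps, sites, composition, contig_lengths)

  tests <- NULL
  if (nrow(expr) > 0L) {
    summ <- per_sex_summary(expr, stat = control$summary_stat, value = "E")
    rec <- compute_dosage_records(summ, control, expression = expr)
    ord <- contigs$contig_id
    contigs <- merge(contigs, rec, by = "contig_id", all.x = TRUE,
                     sort = FALSE)
    contigs <- contigs[match(ord, contigs$contig_id), ]
    rownames(contigs) <- NULL
    if (nrow(summ) >= 2L) {
      fin <- is.finite(rec$xm2xf_ratio)
      tests <- list(
        y_reduction = test_y_reduction(summ$X_male, summ$Y_male),
        xm2xf_overall = if (sum(fin) >= 2L)
          test_xm2xf_departure(rec$xm2xf_ratio[fin]) else NULL)
    }
  } else {
    summ <- NULL
    for (cn in c("yx_ratio", "xm2xf_ratio")) contigs[[cn]] <- NA_real_
    contigs$yx_bin <- NA_character_
    contigs$excluded_high_yx <- NA
    contigs$excluded_high_xm2xf <- NA
  }
  structure(list(samples = snps$samples, control = control,
                 sites = sites, contigs = contigs, expression = expr,
                 summaries = summ, tests = tests,
                 composition = composition,
                 library_size = normalized_library_size(composition),
                 contig_lengths = contig_lengths,
                 log = list(package_version =
                              as.character(utils::packageVersion("sexlinkr")),
                            r_version = R.version.string,
                            control = unclass(control)),
                 call = match.call()),
            class = "sexlink")
}

#' @export
print.sexlink <- function(x, digits = 3, ...) {
  cat("Sex-linkage and dosage-compensation analysis\n")
  cat("  individuals:", sum(x$samples$sex == "male"), "male,",
      sum(x$samples$sex == "female"), "female\n")
  cat("  sites:", nrow(x$sites), "biallelic SNVs;",
      sum(x$sites$status == "sex_linked"), "sex-linked\n")
  cat("  contigs:", nrow(x$contigs), "total;",
      sum(x$contigs$is_sex_linked), "sex-linked (>=1 SNP),",
      sum(x$contigs$passes_strict), "with >=2 SNPs\n")
  sl <- x$contigs[x$contigs$is_sex_linked, ]
  if (nrow(sl) && any(is.finite(sl$yx_ratio))) {
    cat("  median Y/X:",
        format(median(sl$yx_ratio[is.finite(sl$yx_ratio)]), digits = digits),
        "  median Xmale/2Xfemale:",
        format(median(sl$xm2xf_ratio[is.finite(sl$xm2xf_ratio)]),
               digits = digits), "\n")
  }
  if (!is.null(x$tests$y_reduction))
    cat("  Y-reduction Wilcoxon p:",
        format.pval(x$tests$y_reduction$p.value, digits = digits),
        "(", x$tests$y_reduction$direction, ")\n")
  invisible(x)
}

fig2_categories <- function(yx) {
  cut(yx, breaks = c(0, 0.5, 1, 1.5, Inf),
      labels = c("Y/X<0.5", "0.5<=Y/X<1", "1<=Y/X<1.5", "Y/X>=1.5"),
      right = FALSE)
}

#' Summarize a sex-linkage analysis
#'
#' Per-category medians of the Xmale/2Xfemale ratio across Y/X classes
#' (the contrast that reveals dosage compensation: the no-compensation
#' expectation is 0.5, and compensated contigs approach 1), with a
#' Wilcoxon test against 0.5 in each category, plus exclusion-filter
#' counts and the overall tests.
#'
#' @param object A `"sexlink"` object.
#' @param ... Unused.
#' @return An object of class `"summary.sexlink"`.
#' @export
summary.sexlink <- function(object, ...) {
  sl <- object$contigs[object$contigs$is_sex_linked, ]
  cats <- NULL
  if (nrow(sl) && any(is.finite(sl$yx_ratio))) {
    fin <- sl[is.finite(sl$yx_ratio) & is.finite(sl$xm2xf_ratio), ]
    cat_f <- fig2_categories(fin$yx_ratio)
    cats <- do.call(rbind, lapply(levels(cat_f), function(lv) {
      r <- fin$xm2xf_ratio[cat_f == lv]
      p <- if (length(r) >= 2L && !all(r == 0.5))
        suppressWarnings(wilcox.test(r, mu = 0.5)$p.value) else NA_real_
      data.frame(category = lv, n_contigs = length(r),
                 median_xm2xf = if (length(r)) median(r) else NA_real_,
                 p_vs_0.5 = p, stringsAsFactors = FALSE)
    }))
  }
  structure(list(fit = object, categories = cats,
                 n_excluded_yx = sum(sl$excluded_high_yx, na.rm = TRUE),
                 n_excluded_xm2xf = sum(sl$excluded_high_xm2xf, na.rm = TRUE)),
            class = "summary.sexlink")
}

#' @export
print.summary.sexlink <- function(x, digits = 3, ...) {
  print(x$fit, digits = digits)
  if (!is.null(x$categories)) {
    cat("\nXmale/2Xfemale by Y/X category:\n")
    print(x$categories, digits = digits, row.names = FALSE)
    cat("\nexcluded: Y/X >", x$fit$control$yx_exclude, ":",
        x$n_excluded_yx, " | Xmale/2Xfemale >",
        x$fit$control$xm2xf_exclude, ":", x$n_excluded_xm2xf, "\n")
  }
  invisible(x)
}

#' Plot diagnostics of a sex-linkage analysis
#'
#' `which = 1`: histogram of per-contig Y/X ratios (Y degeneration shows
#' as mass below 1); `which = 2`: histogram of Xmale/2Xfemale ratios with
#' the 0.5 (no compensation) and 1 (full compensation) references.
#' Medians are drawn in red.
#'
#' @param x A `"sexlink"` object.
#' @param which Subset of `1:2`.
#' @param ... Passed to [graphics::hist()].
#' @export
plot.sexlink <- function(x, which = 1:2, ...) {
  sl <- x$contigs[x$contigs$is_sex_linked, ]
  if (!nrow(sl)) {
    warning("no sex-linked contigs to plot")
    return(invisible(x))
  }
  if (1 %in% which) {
    v <- sl$yx_ratio[is.finite(sl$yx_ratio)]
    hist(pmin(v, 3), breaks = seq(0, 3, by = 0.1),
         main = "Y/X expression ratio", xlab = "Y/X (capped at 3)", ...)
    abline(v = median(v), col = "red", lwd = 2)
  }
  if (2 %in% which) {
    v <- sl$xm2xf_ratio[is.finite(sl$xm2xf_ratio)]
    hist(pmin(v, 3), breaks = seq(0, 3, by = 0.1),
         main = "Xmale/2Xfemale expression ratio",
         xlab = "Xmale/2Xfemale (capped at 3)", ...)
    abline(v = median(v), col = "red", lwd = 2)
    abline(v = c(0.5, 1), lty = 3, col = "grey40")
  }
  invisible(x)
}
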