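#' Tuning parameters for sex-linkage detection and dosage analysis
#'
#' Collects every threshold used by the detection filter and the downstream
#' ratio analysis.  The defaults are deliberately permissive on the male side:
#' a Y-linked allele is often weakly expressed, so requiring more than one
#' supporting read would discard genuinely sex-linked sites.
#'
#' @param min_y_reads Minimum number of reads supporting *each* allele for a
#'   male to be called heterozygous from its allele depths.  Default `1`.
#' @param min_minor_fraction Minimum minor-allele read fraction for a male
#'   heterozygote call.  Default `0` (no fraction requirement).
#' @param min_depth Minimum total depth for a call to be non-missing.
#'   Default `1`; an individual with fewer reads disqualifies the site.
#' @param male_rule `"support"` (default) calls a male heterozygous when both
#'   alleles meet `min_y_reads`/`min_minor_fraction`; `"binomial"` instead
#'   rejects homozygosity when the minor depth is improbably high under a
#'   sequencing-error model (one-sided binomial test).
#' @param binom_error Per-read error rate assumed by the binomial rule.
#' @param binom_alpha Significance level of the binomial rule.
#' @param strict_females If `TRUE`, a female homozygous genotype is only
#'   accepted when her minor-allele read fraction is at most
#'   `female_max_minor`; otherwise the genotype column is taken verbatim.
#' @param female_max_minor Maximum female minor-allele fraction under
#'   `strict_females`.
#' @param summary_stat Statistic used to aggregate normalized expression
#'   across individuals of a sex before ratios are formed: `"mean"`
#'   (default) or `"median"`.
#' @param ratio_mode `"of_summaries"` (default) forms the Y/X ratio from the
#'   per-sex summaries; `"per_individual"` averages per-male Y/X ratios
#'   instead (sensitivity mode).
#' @param yx_exclude Contigs with Y/X ratio strictly above this value are
#'   flagged for exclusion from dosage profiles (default 1.5).
#' @param xm2xf_exclude Contigs with Xmale/2Xfemale ratio strictly above this
#'   value are flagged for exclusion (default 2).
#'
#' @return An object of class `"sexlink_control"` (a named list).
#' @examples
#' sexlink_control(min_y_reads = 2)
#' @export
sexlink_control <- function(min_y_reads = 1L,
                            min_minor_fraction = 0,
                            min_depth = 1L,
                            male_rule = c("support", "binomial"),
                            binom_error = 0.005,
                            binom_alpha = 0.05,
                            strict_females = FALSE,
                            female_max_minor = 0.05,
                            summary_stat = c("mean", "median"),
                            ratio_mode = c("of_summaries", "per_individual"),
                            yx_exclude = 1.5,
                            xm2xf_exclude = 2) {
  male_rule <- match.arg(male_rule)
  summary_stat <- match.arg(summary_stat)
  ratio_mode <- match.arg(ratio_mode)
  stopifnot(min_y_reads >= 0, min_depth >= 1,
            min_minor_fraction >= 0, min_minor_fraction <= 1,
            binom_error > 0, binom_error < 1,
            binom_alpha > 0, binom_alpha < 1,
            female_max_minor >= 0, female_max_minor < 1,
            yx_exclude > 0, xm2xf_exclude > 0)
  structure(list(min_y_reads = as.integer(min_y_reads),
                 min_minor_fraction = min_minor_fraction,
                 min_depth = as.integer(min_depth),
                 male_rule = male_rule,
                 binom_error = binom_error,
                 binom_alpha = binom_alpha,
                 strict_females = isTRUE(strict_females),
                 female_max_minor = female_max_minor,
                 summary_stat = summary_stat,
                 ratio_mode = ratio_mode,
                 yx_exclude = yx_exclude,
                 xm2xf_exclude = xm2xf_exclude),
            class = "sexlink_control")
}

#' Construct a sample table
#'
#' Describes the individuals of the family: unique ids, sex, and an optional
#' sequencing-run batch (library composition, notably rRNA content, can
#' differ between runs).
#'
#' @param id Character vector of unique individual identifiers.
#' @param sex Character vector, `"male"` or `"female"`, same length as `id`.
#' @param run_batch Optional character vector of run labels; defaults to a
#'   single batch.
#' @return A `data.frame` with columns `id`, `sex`, `run_batch`.
#' @examples
#' sample_table(c("M1", "M2", "F1"), c("male", "male", "female"))
#' @export
sample_table <- function(id, sex, run_batch = NULL) {
  id <- as.character(id)
  sex <- tolower(as.character(sex))
  if (anyDuplicated(id))
    stop("individual ids must be unique")
  if (length(sex) != length(id))
    stop("'id' and 'sex' must have the same length")
  if (!all(sex %in% c("male", "female")))
    stop("'sex' must be \"male\" or \"female\"")
  if (is.null(run_batch)) run_batch <- rep("run1", length(id))
  if (length(run_batch) != length(id))
    stop("'run_batch' must match 'id' in length")
  data.frame(id = id, sex = sex, run_batch = as.character(run_batch),
             stringsAsFactors = FALSE)
}

#' Read a sample table from a TSV file
#'
#' Expects a header with columns `id` and `sex` (and optionally `run_batch`).
#'
#' @param path Path to a tab-separated file.
#' @return A `data.frame` as from [sample_table()].
#' @export
read_sample_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id", "sex") %in% names(d)))
    stop("sample table must have columns 'id' and 'sex': ", path)
  sample_table(d$id, d$sex, if ("run_batch" %in% names(d)) d$run_batch)
}

check_samples <- function(samples) {
  if (!is.data.frame(samples) || !all(c("id", "sex") %in% names(samples)))
    stop("'samples' must be a data frame with columns 'id' and 'sex'")
  if (!any(samples$sex == "male") || !any(samples$sex == "female"))
    stop("at least one male and one female are required")
  invisible(samples)
}
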