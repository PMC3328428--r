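#' Estimate the sex-linkage false-positive rate under an autosomal null
#'
#' Repeatedly simulates autosomal-only datasets (residual heterozygosity
#' `h`, base-call error `e`), runs the detector, and reports the fraction
#' of autosomal contigs falsely classified sex-linked — overall (at least
#' one sex-linked SNP) and restricted to the strict set (at least two).
#' Exact binomial confidence intervals are attached, and the rates can be
#' rescaled to the size of a detected set to give an expected number of
#' erroneous contigs.
#'
#' @param config A [sim_config()]; `n_sexlinked` is forced to 0 and the
#'   seed of replicate `r` is `config$seed + r - 1`.
#' @param control A [sexlink_control()].
#' @param n_reps Number of independent replicates (default 5).
#' @param scale_to Optional reference number of detected contigs; when
#'   given, expected false-positive counts `rate * scale_to` are reported.
#' @param conf Confidence level for the binomial intervals.
#' @return A list of class `"fp_estimate"`: `n_contigs`, `n_false_1`,
#'   `n_false_2`, `rate_1snp`, `rate_2snp`, `ci_1snp`, `ci_2snp`, and
#'   optionally `expected_1snp`/`expected_2snp`.
#' @examples
#' \donttest{
#' fp <- estimate_false_positive_rate(
#'   sim_config(n_autosomal = 2000, h = 0.05, e = 0.005, seed = 1),
#'   n_reps = 2)
#' fp$rate_2snp
#' }
#' @export
estimate_false_positive_rate <- function(config,
                                         control = sexlink_control(),
                                         n_reps = 5L, scale_to = NULL,
                                         conf = 0.95) {
  stopifnot(inherits(config, "sim_config"), n_reps >= 1)
  n_tot <- 0L; n1 <- 0L; n2 <- 0L
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    sim <- simulate_autosomal_null(cfg)
    cl <- classify_contigs(sim$snps, control = control)
    n_tot <- n_tot + nrow(cl)
    n1 <- n1 + sum(cl$is_sex_linked)
    n2 <- n2 + sum(cl$passes_strict)
  }
  ci <- function(x) as.numeric(binom.test(x, n_tot, conf.level = conf)$conf.int)
  out <- list(n_contigs = n_tot, n_false_1 = n1, n_false_2 = n2,
              rate_1snp = n1 / n_tot, rate_2snp = n2 / n_tot,
              ci_1snp = ci(n1), ci_2snp = ci(n2),
              n_reps = n_reps, conf = conf)
  if (!is.null(scale_to)) {
    out$expected_1snp <- out$rate_1snp * scale_to
    out$expected_2snp <- out$rate_2snp * scale_to
  }
  structure(out, class = "fp_estimate")
}

#' @export
print.fp_estimate <- function(x, ...) {
  cat("False-positive sex-linkage rate (autosomal null,",
      x$n_contigs, "contigs over", x$n_reps, "replicates)\n")
  cat(sprintf("  >=1 sex-linked SNP: %.3g  [%.3g, %.3g]\n",
              x$rate_1snp, x$ci_1snp[1], x$ci_1snp[2]))
  cat(sprintf("  >=2 sex-linked SNPs: %.3g  [%.3g, %.3g]\n",
              x$rate_2snp, x$ci_2snp[1], x$ci_2snp[2]))
  if (!is.null(x$expected_2snp))
    cat(sprintf("  expected erroneous contigs (scaled): %.3g (>=1), %.3g (>=2)\n",
                x$expected_1snp, x$expected_2snp))
  invisible(x)
}
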