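yx_breaks <- c(0, 0.25, 0.5, 0.75, 1, 1.5, Inf)
yx_labels <- c("[0,0.25)", "[0.25,0.5)", "[0.5,0.75)", "[0.75,1)",
               "[1,1.5)", "[1.5,Inf)")

#' Bin Y/X expression ratios
#'
#' Half-open bins `[0,0.25) [0.25,0.5) [0.5,0.75) [0.75,1) [1,1.5)
#' [1.5,Inf)`; every finite non-negative ratio falls in exactly one bin.
#'
#' @param yx Numeric vector of Y/X ratios (non-negative; `Inf` allowed and
#'   assigned to the top bin).
#' @return A factor with the six bin labels.
#' @export
yx_bin <- function(yx) {
  stopifnot(all(yx >= 0, na.rm = TRUE))
  b <- cut(yx, breaks = yx_breaks, labels = yx_labels, right = FALSE)
  b[is.infinite(yx)] <- yx_labels[length(yx_labels)]
  b
}

#' Per-contig dosage records
#'
#' Forms the two diagnostic expression ratios for every sex-linked contig:
#' the Y/X ratio in males (Y degeneration shows as Y/X < 1) and the
#' Xmale/2Xfemale ratio (single male X over both female X copies; 0.5
#' expected without dosage compensation, 1 under full compensation).
#' Ratios are formed from the per-sex summaries.  Contigs with Y/X
#' strictly above `control$yx_exclude` or Xmale/2Xfemale strictly above
#' `control$xm2xf_exclude` are flagged — such male-biased patterns suggest
#' sexually antagonistic expression rather than dosage effects — but are
#' not removed here; equality with the boundary is retained.
#'
#' @param summaries Per-sex summaries from [per_sex_summary()].
#' @param control A [sexlink_control()].
#' @param expression Optional long expression table; required for
#'   `ratio_mode = "per_individual"`, where the Y/X ratio is the mean of
#'   per-male ratios instead of the ratio of summaries.
#' @return A `data.frame`: `contig_id`, `yx_ratio`, `xm2xf_ratio`,
#'   `yx_bin`, `excluded_high_yx`, `excluded_high_xm2xf`.  A contig whose
#'   male X summary is zero gets `yx_ratio = Inf`, is assigned to the top
#'   bin and flagged `excluded_high_yx` (a detected contig cannot have a
#'   zero Y summary: detection requires Y-supporting reads in every male).
#' @export
compute_dosage_records <- function(summaries, control = sexlink_control(),
                                   expression = NULL) {
  yx <- summaries$Y_male / summaries$X_male
  if (control$ratio_mode == "per_individual") {
    if (is.null(expression))
      stop("ratio_mode 'per_individual' needs the expression table")
    ex <- expression[expression$allele_class %in% c("X_male", "Y_male"), ]
    key <- paste(ex$contig_id, ex$individual_id)
    xs <- ex$E[ex$allele_class == "X_male"]
    ys <- ex$E[ex$allele_class == "Y_male"]
    stopifnot(identical(key[ex$allele_class == "X_male"],
                        key[ex$allele_class == "Y_male"]))
    ratio <- ys / xs
    yx_i <- tapply(ratio, ex$contig_id[ex$allele_class == "X_male"],
                   mean)
    yx <- as.numeric(yx_i[summaries$contig_id])
  }
  xm2xf <- summaries$X_male / summaries$X_female_both
  data.frame(contig_id = summaries$contig_id,
             yx_ratio = yx,
             xm2xf_ratio = xm2xf,
             yx_bin = as.character(yx_bin(yx)),
             excluded_high_yx = yx > control$yx_exclude,
             excluded_high_xm2xf = xm2xf > control$xm2xf_exclude,
             stringsAsFactors = FALSE)
}

degenerate_test <- function(note) {
  structure(list(statistic = c(V = NA_real_), p.value = 1,
                 method = "Wilcoxon signed rank test (degenerate)",
                 alternative = "two.sided", note = note),
            class = "htest")
}

#' Paired test for reduced Y expression
#'
#' Wilcoxon signed-rank test pairing the X and Y expression summaries of
#' each contig.  Reduced Y expression relative to X is the expression-level
#' signature of Y degeneration.  Two-sided by default, with the direction
#' of the median difference reported alongside.
#'
#' @param x,y Per-contig male X and Y expression values (same length).
#' @param alternative Passed to [stats::wilcox.test()].
#' @return An `htest` object with an extra `direction` element
#'   (`"Y < X"`, `"Y > X"` or `"none"`).
#' @export
test_y_reduction <- function(x, y, alternative = "two.sided") {
  stopifnot(length(x) == length(y))
  if (length(x) < 2)
    stop("at least two contigs are required")
  d <- y - x
  if (all(d == 0)) {
    ht <- degenerate_test("all X-Y differences are zero")
  } else {
    ht <- suppressWarnings(wilcox.test(y, x, paired = TRUE,
                                       alternative = alternative))
  }
  md <- median(d)
  ht$direction <- if (md < 0) "Y < X" else if (md > 0) "Y > X" else "none"
  ht
}

#' One-sample test of Xmale/2Xfemale against a reference
#'
#' Wilcoxon signed-rank test of the per-contig Xmale/2Xfemale ratios
#' against the no-compensation expectation of 0.5 (or another reference).
#'
#' @param ratios Per-contig Xmale/2Xfemale ratios (non-finite values are
#'   dropped).
#' @param reference Null value, default 0.5.
#' @param alternative Passed to [stats::wilcox.test()].
#' @return An `htest` object.
#' @export
test_xm2xf_departure <- function(ratios, reference = 0.5,
                                 alternative = "two.sided") {
  ratios <- ratios[is.finite(ratios)]
  if (length(ratios) < 2)
    stop("at least two contigs are required")
  if (all(ratios == reference)) return(degenerate_test("all ratios equal the reference"))
  suppressWarnings(wilcox.test(ratios, mu = reference,
                               alternative = alternative))
}

#' Binned dosage profile with bootstrap confidence intervals
#'
#' Summarizes expression of the four allele classes — XX in females, X in
#' males, Y in males, and X+Y in males — within Y/X ratio bins, after
#' removing contigs flagged by the exclusion filters.  Within each bin the
#' median over all (contig, individual) pairs of the same sex is taken;
#' the male X+Y bin value is defined as the sum of the X and Y bin values,
#' so the identity XY = X + Y holds exactly at the bin level.  All four
#' values are rescaled by the female value, so XX females are 1 in every
#' bin; under full dosage compensation the male X value approaches 1 as
#' well, without compensation it sits near 0.5 while X+Y tracks 1.
#' Confidence intervals are percentile bootstrap over contigs, each
#' replicate being rescaled by its own female median (the female class is
#' therefore the reference and gets a degenerate interval).
#'
#' @param object A fitted [sexlink()] object.
#' @param value Expression measure: `"auto"` (RPKM when contig lengths are
#'   available, otherwise E), `"rpkm"` or `"E"`.
#' @param n_boot Number of bootstrap resamples (default 1000; 0 gives
#'   point estimates only).
#' @param conf Confidence level (default 0.95).
#' @param seed Optional seed for the bootstrap.
#' @return A `data.frame` of class `"dosage_profile"`: one row per bin and
#'   allele class with `n_contigs`, rescaled `estimate`, `lo`, `hi`, and
#'   the unrescaled `raw` median.  Empty bins are reported with
#'   `n_contigs = 0` and no interval.
#' @export
build_dosage_profile <- function(object, value = c("auto", "rpkm", "E"),
                                 n_boot = 1000, conf = 0.95, seed = NULL) {
  stopifnot(inherits(object, "sexlink"))
  value <- match.arg(value)
  expr <- object$expression
  if (value == "auto")
    value <- if (!all(is.na(expr$rpkm))) "rpkm" else "E"
  if (value == "rpkm" && all(is.na(expr$rpkm)))
    stop("RPKM values unavailable: supply contig lengths or use value = \"E\"")
  rec <- object$contigs
  keep <- rec$is_sex_linked & !is.na(rec$yx_ratio) &
    !rec$excluded_high_yx & !rec$excluded_high_xm2xf
  rec <- rec[keep, ]
  bins <- yx_labels[-length(yx_labels)]  # finite bins only after exclusion
  expr <- expr[expr$contig_id %in% rec$contig_id, ]
  v <- expr[[value]]

  key <- paste(expr$contig_id, expr$individual_id)
  fx <- expr$allele_class == "X_female_both"
  mx <- expr$allele_class == "X_male"
  my <- expr$allele_class == "Y_male"
  stopifnot(identical(key[mx], key[my]))
  pair <- list(f = split(v[fx], expr$contig_id[fx]),
               x = split(v[mx], expr$contig_id[mx]),
               y = split(v[my], expr$contig_id[my]),
               xy = split(v[mx] + v[my], expr$contig_id[mx]))
  bin_of <- setNames(rec$yx_bin, rec$contig_id)

  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  classes <- c("XX_females", "X_males", "Y_males", "XY_males")
  rows <- list()
  for (b in bins) {
    cb <- rec$contig_id[rec$yx_bin == b]
    nb <- length(cb)
    if (nb == 0L) {
      rows[[b]] <- data.frame(yx_bin = b, allele_class = classes,
                              n_contigs = 0L, estimate = NA_real_,
                              lo = NA_real_, hi = NA_real_, raw = NA_real_,
                              stringsAsFactors = FALSE)
      next
    }
    stat <- function(cs) {
      mf <- median(unlist(pair$f[cs], use.names = FALSE))
      mxv <- median(unlist(pair$x[cs], use.names = FALSE))
      myv <- median(unlist(pair$y[cs], use.names = FALSE))
      c(f = mf, x = mxv, y = myv, xy = mxv + myv)
    }
    pt <- stat(cb)
    est <- pt / pt["f"]
    if (n_boot > 0L) {
      bs <- matrix(NA_real_, nrow = n_boot, ncol = 4L)
      for (r in seq_len(n_boot)) {
        s <- stat(cb[sample.int(nb, nb, replace = TRUE)])
        bs[r, ] <- s / s["f"]
      }
      a <- (1 - conf) / 2
      lo <- apply(bs, 2L, quantile, probs = a, names = FALSE)
      hi <- apply(bs, 2L, quantile, probs = 1 - a, names = FALSE)
    } else {
      lo <- hi <- rep(NA_real_, 4L)
    }
    rows[[b]] <- data.frame(yx_bin = b, allele_class = classes,
                            n_contigs = nb,
                            estimate = unname(est), lo = lo, hi = hi,
                            raw = unname(pt), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "value") <- value
  attr(out, "conf") <- conf
  class(out) <- c("dosage_profile", "data.frame")
  out
}

#' @export
print.dosage_profile <- function(x, ...) {
  cat("Dosage profile (", attr(x, "value"),
      ", rescaled by XX females; ", attr(x, "conf") * 100,
      "% bootstrap CIs)\n\n", sep = "")
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Plot a dosage profile
#'
#' Point estimates with bootstrap intervals for the four allele classes
#' across Y/X bins, all rescaled so XX females equal 1.
#'
#' @param x A `"dosage_profile"` object.
#' @param ... Further arguments passed to [graphics::plot()].
#' @export
plot.dosage_profile <- function(x, ...) {
  d <- x[x$n_contigs > 0L, ]
  bins <- unique(d$yx_bin)
  classes <- c("XX_females", "X_males", "Y_males", "XY_males")
  cols <- c(XX_females = "grey40", X_males = "firebrick",
            Y_males = "steelblue", XY_males = "darkgreen")
  off <- setNames(seq(-0.24, 0.24, length.out = 4L), classes)
  xpos <- match(d$yx_bin, bins) + off[d$allele_class]
  ylim <- range(c(d$estimate, d$lo, d$hi), na.rm = TRUE)
  plot(xpos, d$estimate, pch = 19, col = cols[d$allele_class],
       xaxt = "n", xlab = "Y/X expression ratio bin",
       ylab = paste0("median expression (", attr(x, "value"),
                     "), XX females = 1"),
       xlim = c(0.5, length(bins) + 0.5), ylim = ylim, ...)
  axis(1, at = seq_along(bins), labels = bins)
  ok <- !is.na(d$lo)
  segments(xpos[ok], d$lo[ok], xpos[ok], d$hi[ok],
           col = cols[d$allele_class[ok]])
  abline(h = c(0.5, 1), lty = 3, col = "grey60")
  legend("topleft", legend = classes, col = cols[classes], pch = 19,
         bty = "n", cex = 0.8)
  invisible(x)
}

#' Compare X-allele heterozygosity between compensated and
#' non-compensated contigs
#'
#' If dosage compensation worked through an X-inactivation-like mechanism,
#' compensated contigs would express only one female X copy and expressed
#' X polymorphism would be depleted among them.  Contigs are partitioned
#' into a dosage-compensated stratum (by default Y/X < 0.5 and
#' Xmale/2Xfemale >= 0.75) and its complement, the expressed-polymorphism
#' flag is cross-tabulated, and the proportions are compared with Fisher's
#' exact test.  Similar proportions in both strata argue that both female
#' X copies are expressed regardless of compensation.
#'
#' @param object A fitted [sexlink()] object, or a per-contig `data.frame`
#'   with `yx_ratio`, `xm2xf_ratio`, `x_polymorphic`.
#' @param yx_max Compensated stratum: Y/X strictly below this (default 0.5).
#' @param xm2xf_min ... and Xmale/2Xfemale at least this (default 0.75).
#' @return A list of class `"het_comparison"`: `table` (2 x 2 counts),
#'   `proportions`, `test` (an `htest`, or `NULL` with a `note` when a
#'   stratum is empty).
#' @export
heterozygosity_comparison <- function(object, yx_max = 0.5,
                                      xm2xf_min = 0.75) {
  d <- if (inherits(object, "sexlink")) object$contigs else object
  d <- d[!is.na(d$x_polymorphic) & is.finite(d$yx_ratio) &
           is.finite(d$xm2xf_ratio), ]
  strat <- factor(ifelse(d$yx_ratio < yx_max & d$xm2xf_ratio >= xm2xf_min,
                         "compensated", "not_compensated"),
                  levels = c("compensated", "not_compensated"))
  poly <- factor(ifelse(d$x_polymorphic, "polymorphic", "monomorphic"),
                 levels = c("polymorphic", "monomorphic"))
  tab <- table(strat, poly)
  prop <- prop.table(tab + 0, margin = 1)[, "polymorphic"]
  note <- NULL
  test <- NULL
  if (any(rowSums(tab) == 0L)) {
    note <- "empty stratum; no test performed"
  } else if (nrow(d) < 2L) {
    note <- "too few contigs"
  } else {
    test <- fisher.test(tab)
  }
  structure(list(table = tab, proportions = prop, test = test, note = note,
                 yx_max = yx_max, xm2xf_min = xm2xf_min),
            class = "het_comparison")
}

#' @export
print.het_comparison <- function(x, ...) {
  cat("X-allele expressed heterozygosity by dosage-compensation stratum\n")
  cat("  (compensated: Y/X <", x$yx_max, "and Xmale/2Xfemale >=",
      x$xm2xf_min, ")\n\n")
  print(x$table)
  cat("\nproportion polymorphic:\n")
  print(round(x$proportions, 4))
  if (!is.null(x$test))
    cat("\nFisher exact p =", format.pval(x$test$p.value), "\n")
  if (!is.null(x$note)) cat("\nnote:", x$note, "\n")
  invisible(x)
}
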