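#' Normalized library size
#'
#' The library size used to normalize allele expression is the number of
#' nuclear-mRNA mapped reads, in millions: rRNA, mitochondrial, chloroplast
#' and transposable-element reads are subtracted from the total because
#' their proportions differ between sexes and between sequencing runs and
#' would otherwise bias between-individual comparisons.
#'
#' @param composition Library-composition `data.frame`
#'   (see [read_library_composition()]).
#' @return A `data.frame` with columns `individual_id` and `l` (millions of
#'   nuclear-mRNA mapped reads).  A non-positive corrected size is an error.
#' @examples
#' normalized_library_size(data.frame(individual_id = "M1",
#'   total_mapped = 10e6, rrna = 1e6, mito = 5e5, chloro = 5e5, te = 0))
#' @export
normalized_library_size <- function(composition) {
  composition <- validate_composition(composition)
  l <- (composition$total_mapped - composition$rrna - composition$mito -
          composition$chloro - composition$te) / 1e6
  if (any(l <= 0))
    stop("non-positive corrected library size for ",
         paste(composition$individual_id[l <= 0], collapse = ", "))
  data.frame(individual_id = composition$individual_id, l = l,
             stringsAsFactors = FALSE)
}

#' Normalized allele-class expression E = r / (n * l)
#'
#' @param r Summed read count of an allele class over the sex-linked SNPs
#'   of a contig.
#' @param n Number of sex-linked SNPs used (must be >= 1).
#' @param l Normalized library size in millions of reads (> 0).
#' @return `r / (n * l)`.
#' @examples
#' normalized_expression(120, 3, 2)  # 20
#' @export
normalized_expression <- function(r, n, l) {
  stopifnot(all(n >= 1), all(l > 0), all(r >= 0))
  r / (n * l)
}

#' Reads per kilobase per million mapped reads
#'
#' @param r Read count.
#' @param length_bp Contig length in base pairs (> 0).
#' @param total_mapped Total mapped reads of the library (> 0).
#' @return `r / ((length_bp/1000) * (total_mapped/1e6))`.
#' @examples
#' contig_rpkm(10, 500, 1e6)  # 20
#' @export
contig_rpkm <- function(r, length_bp, total_mapped) {
  stopifnot(all(length_bp > 0), all(total_mapped > 0), all(r >= 0))
  r / ((length_bp / 1000) * (total_mapped / 1e6))
}

#' Allele-class expression per contig and individual
#'
#' For every sex-linked contig, sums read counts *at the sex-linked SNP
#' positions only* (not over the whole contig, so that X and Y reads are
#' cleanly separated): per male the X-allele and Y-allele depths, per
#' female the total depth of her two X copies.  Each sum `r` is normalized
#' as `E = r/(n*l)` with `n` the number of sex-linked SNPs of the contig
#' and `l` the individual's normalized library size.  When contig lengths
#' are supplied an RPKM-style value is computed as well.
#'
#' @param snps A [snp_table()].
#' @param site_class Result of [classify_sites()] on `snps`.
#' @param composition Library-composition table.
#' @param contig_info Optional `data.frame` with `contig_id`, `length_bp`.
#' @return A long `data.frame`: `contig_id`, `individual_id`, `sex`,
#'   `allele_class` (`"X_male"`, `"Y_male"`, `"X_female_both"`), `r`, `n`,
#'   `E`, `rpkm` (`NA` when no length is available).
#' @export
allele_expression <- function(snps, site_class, composition,
                              contig_info = NULL) {
  stopifnot(inherits(snps, "snp_table"))
  lib <- normalized_library_size(composition)
  samples <- snps$samples
  miss <- setdiff(samples$id, lib$individual_id)
  if (length(miss))
    stop("individual(s) missing from library composition: ",
         paste(miss, collapse = ", "))
  sl <- site_class$status == "sex_linked"
  empty <- data.frame(contig_id = character(), individual_id = character(),
                      sex = character(), allele_class = character(),
                      r = numeric(), n = integer(), E = numeric(),
                      rpkm = numeric(), stringsAsFactors = FALSE)
  if (!any(sl)) return(empty)

  x_is_ref <- site_class$x_is_ref[sl]
  adr <- snps$ad_ref[sl, , drop = FALSE]
  ada <- snps$ad_alt[sl, , drop = FALSE]
  xmat <- adr; xmat[!x_is_ref, ] <- ada[!x_is_ref, ]
  ymat <- ada; ymat[!x_is_ref, ] <- adr[!x_is_ref, ]
  tot <- adr + ada
  grp <- site_class$contig_id[sl]

  males <- samples$id[samples$sex == "male"]
  fems <- samples$id[samples$sex == "female"]
  rx <- rowsum(xmat[, males, drop = FALSE], grp)
  ry <- rowsum(ymat[, males, drop = FALSE], grp)
  rf <- rowsum(tot[, fems, drop = FALSE], grp)
  nsnp <- rowsum(rep(1L, sum(sl)), grp)[, 1]
  contigs <- rownames(rx)

  lvec <- setNames(lib$l, lib$individual_id)
  tmvec <- setNames(composition$total_mapped, composition$individual_id)
  lenvec <- if (!is.null(contig_info))
    setNames(contig_info$length_bp, contig_info$contig_id)[contigs] else NULL

  block <- function(rmat, ids, class, sex) {
    nc <- length(contigs)
    r <- as.vector(rmat[, ids, drop = FALSE])
    ind <- rep(ids, each = nc)
    n <- rep(as.integer(nsnp), times = length(ids))
    E <- r / (n * lvec[ind])
    rpkm <- if (is.null(lenvec)) NA_real_ else
      contig_rpkm(r, rep(lenvec, times = length(ids)), tmvec[ind])
    data.frame(contig_id = rep(contigs, times = length(ids)),
               individual_id = ind, sex = sex, allele_class = class,
               r = r, n = n, E = E, rpkm = rpkm,
               stringsAsFactors = FALSE)
  }
  out <- rbind(block(rx, males, "X_male", "male"),
               block(ry, males, "Y_male", "male"),
               block(rf, fems, "X_female_both", "female"))
  rownames(out) <- NULL
  out
}

#' Summarize allele-class expression across individuals of a sex
#'
#' Aggregates expression across the individuals of each sex *before* any
#' between-class ratio is formed, with the mean (default) or median.
#'
#' @param expression Long table from [allele_expression()].
#' @param stat `"mean"` or `"median"`.
#' @param value Which column to summarize, `"E"` (default) or `"rpkm"`.
#' @return A `data.frame` with one row per contig and columns `X_male`,
#'   `Y_male`, `X_female_both`.
#' @export
per_sex_summary <- function(expression, stat = c("mean", "median"),
                            value = c("E", "rpkm")) {
  stat <- match.arg(stat)
  value <- match.arg(value)
  if (nrow(expression) == 0L)
    stop("empty expression table")
  v <- expression[[value]]
  if (all(is.na(v)))
    stop("no '", value, "' values available (missing contig lengths?)")
  fun <- if (stat == "mean") mean else median
  w <- tapply(v, list(expression$contig_id, expression$allele_class), fun)
  need <- c("X_male", "Y_male", "X_female_both")
  if (!all(need %in% colnames(w)))
    stop("expression table lacks allele class(es): ",
         paste(setdiff(need, colnames(w)), collapse = ", "))
  data.frame(contig_id = rownames(w),
             X_male = w[, "X_male"], Y_male = w[, "Y_male"],
             X_female_both = w[, "X_female_both"],
             row.names = NULL, stringsAsFactors = FALSE)
}
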