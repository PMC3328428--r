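#' Construct an SNP table
#'
#' The internal container shared by detection and quantification: a site
#' table plus aligned genotype and allele-depth matrices (one column per
#' individual, in the order of `samples$id`).
#'
#' @param sites `data.frame` with columns `contig_id`, `position`, `ref`,
#'   `alt` (strictly biallelic rows).
#' @param gt Character matrix of genotypes (`"0/0"`, `"0/1"`, `"1/1"` or
#'   `NA`), sites in rows, individuals in columns.
#' @param ad_ref,ad_alt Integer matrices of per-allele read depths, same
#'   shape as `gt`.
#' @param samples Sample table (see [sample_table()]).
#' @return An object of class `"snp_table"`.
#' @export
snp_table <- function(sites, gt, ad_ref, ad_alt, samples) {
  check_samples(samples)
  stopifnot(is.data.frame(sites),
            all(c("contig_id", "position", "ref", "alt") %in% names(sites)),
            nrow(gt) == nrow(sites), nrow(ad_ref) == nrow(sites),
            nrow(ad_alt) == nrow(sites))
  ids <- samples$id
  if (is.null(colnames(gt)))
    colnames(gt) <- colnames(ad_ref) <- colnames(ad_alt) <- ids
  missing <- setdiff(ids, colnames(gt))
  if (length(missing))
    stop("sample(s) absent from genotype data: ", paste(missing, collapse = ", "))
  gt <- gt[, ids, drop = FALSE]
  ad_ref <- ad_ref[, ids, drop = FALSE]
  ad_alt <- ad_alt[, ids, drop = FALSE]
  if (any(ad_ref < 0, na.rm = TRUE) || any(ad_alt < 0, na.rm = TRUE))
    stop("allele depths must be non-negative")
  ad_ref[is.na(ad_ref)] <- 0L
  ad_alt[is.na(ad_alt)] <- 0L
  storage.mode(ad_ref) <- "integer"
  storage.mode(ad_alt) <- "integer"
  if (any(sites$ref == sites$alt))
    stop("ref and alt allele must differ")
  rownames(gt) <- rownames(ad_ref) <- rownames(ad_alt) <- NULL
  structure(list(sites = sites, gt = gt,
                 ad_ref = ad_ref, ad_alt = ad_alt, samples = samples),
            class = "snp_table")
}

#' @export
print.snp_table <- function(x, ...) {
  cat("SNP table:", nrow(x$sites), "biallelic sites,",
      length(unique(x$sites$contig_id)), "contigs,",
      nrow(x$samples), "individuals (",
      sum(x$samples$sex == "male"), "male /",
      sum(x$samples$sex == "female"), "female )\n")
  invisible(x)
}

normalize_gt <- function(g) {
  d <- dim(g); dn <- dimnames(g)
  g <- gsub("|", "/", g, fixed = TRUE)
  out <- rep(NA_character_, length(g))
  out[g == "0/0"] <- "0/0"
  out[g == "0/1" | g == "1/0"] <- "0/1"
  out[g == "1/1"] <- "1/1"
  dim(out) <- d; dimnames(out) <- dn
  out
}

#' Read a multi-sample SNP table from a VCF file
#'
#' Reads a VCF with per-sample `GT` and `AD` FORMAT fields (e.g. GATK
#' output) into a [snp_table()].  Only single-nucleotide variants are kept.
#' Multi-allelic records are decomposed into biallelic ref/alt pairs; an
#' alternate allele with zero depth across all samples is dropped, and a
#' sample genotype that involves a third allele becomes missing for that
#' decomposed record.  Rows skipped as indels are reported in a warning.
#'
#' @param path Path to a VCF (v4.x) file.
#' @param samples Sample table; every `id` must be a sample column of the
#'   VCF (a missing sample is a hard error, as is an absent `AD` field —
#'   allele depths are required for male re-genotyping).
#' @return A [snp_table()].
#' @examples
#' \dontrun{
#' st <- read_snp_table("variants.vcf", read_sample_table("samples.tsv"))
#' }
#' @export
read_snp_table <- function(path, samples) {
  check_samples(samples)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt_raw <- tryCatch(vcfR::extract.gt(v, "GT"),
                     error = function(e) stop("VCF lacks a GT FORMAT field: ", path))
  ad_raw <- tryCatch(vcfR::extract.gt(v, "AD"),
                     error = function(e) stop("VCF lacks an AD FORMAT field (allele depths are required): ", path))
  if (all(is.na(ad_raw)))
    stop("VCF lacks usable AD values (allele depths are required): ", path)
  missing <- setdiff(samples$id, colnames(gt_raw))
  if (length(missing))
    stop("sample(s) not present in VCF: ", paste(missing, collapse = ", "))
  gt_raw <- gt_raw[, samples$id, drop = FALSE]
  ad_raw <- ad_raw[, samples$id, drop = FALSE]
  ns <- length(samples$id)
  n <- nrow(fix)

  alt_list <- strsplit(ifelse(is.na(fix$ALT), "", fix$ALT), ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  is_snv <- nchar(fix$REF) == 1L & n_alt >= 1L
  n_indel <- sum(!is_snv)

  ad_list <- strsplit(ifelse(is.na(ad_raw), "", ad_raw), ",", fixed = TRUE)
  dim(ad_list) <- dim(ad_raw)
  ad_num <- function(i, k) {   # depth of allele k (0-based) at row i, all samples
    vapply(ad_list[i, ], function(x) {
      d <- suppressWarnings(as.integer(x[k + 1L]))
      if (length(d) == 0L || is.na(d)) 0L else d
    }, integer(1))
  }

  out_sites <- vector("list", n)
  out_gt <- vector("list", n)
  out_ref <- vector("list", n)
  out_alt <- vector("list", n)
  n_skipped_alt <- 0L
  for (i in seq_len(n)) {
    if (!is_snv[i]) next
    alts <- alt_list[[i]]
    dref <- ad_num(i, 0L)
    g <- gsub("|", "/", gt_raw[i, ], fixed = TRUE)
    rows_s <- list(); rows_g <- list(); rows_r <- list(); rows_a <- list()
    for (k in seq_along(alts)) {
      if (nchar(alts[k]) != 1L) { n_skipped_alt <- n_skipped_alt + 1L; next }
      dalt <- ad_num(i, k)
      if (length(alts) > 1L && all(dalt == 0L)) next  # unsupported allele
      gk <- rep(NA_character_, ns)
      gl <- strsplit(g, "/", fixed = TRUE)
      for (j in seq_len(ns)) {
        a <- gl[[j]]
        if (length(a) != 2L || any(a == ".")) next
        a <- suppressWarnings(as.integer(a))
        if (any(is.na(a)) || !all(a %in% c(0L, k))) next
        gk[j] <- paste(sort(ifelse(a == k, 1L, 0L)), collapse = "/")
      }
      rows_s[[length(rows_s) + 1L]] <-
        data.frame(contig_id = fix$CHROM[i],
                   position = as.integer(fix$POS[i]),
                   ref = fix$REF[i], alt = alts[k],
                   stringsAsFactors = FALSE)
      rows_g[[length(rows_g) + 1L]] <- gk
      rows_r[[length(rows_r) + 1L]] <- dref
      rows_a[[length(rows_a) + 1L]] <- dalt
    }
    if (length(rows_s)) {
      out_sites[[i]] <- do.call(rbind, rows_s)
      out_gt[[i]] <- do.call(rbind, rows_g)
      out_ref[[i]] <- do.call(rbind, rows_r)
      out_alt[[i]] <- do.call(rbind, rows_a)
    }
  }
  if (n_indel > 0L)
    warning(n_indel, " non-SNV record(s) skipped")
  keep <- !vapply(out_sites, is.null, logical(1))
  if (!any(keep))
    stop("no usable biallelic SNV records in ", path)
  sites <- do.call(rbind, out_sites[keep])
  gt <- do.call(rbind, out_gt[keep])
  ad_ref <- do.call(rbind, out_ref[keep])
  ad_alt <- do.call(rbind, out_alt[keep])
  colnames(gt) <- colnames(ad_ref) <- colnames(ad_alt) <- samples$id
  snp_table(sites, normalize_gt(gt), ad_ref, ad_alt, samples)
}

#' Read a library-composition table
#'
#' One row per individual with total mapped reads and the read counts of
#' the non-nuclear-mRNA categories (rRNA, mitochondrial, chloroplast,
#' transposable elements) that are subtracted when normalizing library
#' size.  Tab-separated with a header naming the columns `individual_id`,
#' `total_mapped`, `rrna`, `mito`, `chloro`, `te`.
#'
#' @param path Path to a TSV file.
#' @return A validated `data.frame`.
#' @export
read_library_composition <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  validate_composition(d, path)
}

validate_composition <- function(d, what = "library composition") {
  need <- c("individual_id", "total_mapped", "rrna", "mito", "chloro", "te")
  if (!all(need %in% names(d)))
    stop(what, " must have columns: ", paste(need, collapse = ", "))
  num <- d[, need[-1]]
  if (any(is.na(num)) || any(num < 0))
    stop(what, ": counts must be non-negative")
  if (any(d$rrna + d$mito + d$chloro + d$te > d$total_mapped))
    stop(what, ": component reads exceed total mapped reads for ",
         paste(d$individual_id[d$rrna + d$mito + d$chloro + d$te > d$total_mapped],
               collapse = ", "))
  if (anyDuplicated(d$individual_id))
    stop(what, ": duplicated individual_id")
  d[, need]
}

#' Read contig lengths
#'
#' Accepts either a two-column TSV (`contig_id`, `length_bp`) or a FASTA
#' file, in which case sequence lengths are taken (requires the Biostrings
#' package).  Contigs shorter than 200 bp trigger a warning: such short
#' contigs are normally excluded upstream at assembly time.
#'
#' @param path Path to a TSV or FASTA file.
#' @return A `data.frame` with columns `contig_id`, `length_bp`.
#' @export
read_contig_info <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, ">")) {
    if (!requireNamespace("Biostrings", quietly = TRUE))
      stop("reading contig lengths from FASTA requires the Biostrings package")
    len <- Biostrings::fasta.seqlengths(path)
    d <- data.frame(contig_id = sub("\\s.*$", "", names(len)),
                    length_bp = as.integer(len), stringsAsFactors = FALSE)
  } else {
    d <- read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("contig_id", "length_bp") %in% names(d)))
      stop("contig info must have columns 'contig_id' and 'length_bp': ", path)
    d <- d[, c("contig_id", "length_bp")]
  }
  if (any(d$length_bp <= 0)) stop("contig lengths must be positive")
  if (any(d$length_bp < 200))
    warning(sum(d$length_bp < 200), " contig(s) shorter than 200 bp")
  d
}

report_columns <- c("contig_id", "n_sexlinked_snps", "is_sex_linked",
                    "passes_strict", "x_polymorphic", "yx_ratio",
                    "xm2xf_ratio", "yx_bin", "excluded_high_yx",
                    "excluded_high_xm2xf")

#' Write the per-contig report
#'
#' Emits a TSV with one row per contig: classification, number of
#' sex-linked SNPs, Y/X and Xmale/2Xfemale ratios, Y/X bin and exclusion
#' flags, in a fixed column order.  The output is deterministic: rerunning
#' an identical analysis reproduces the file byte for byte.
#'
#' @param x A fitted [sexlink()] object or a per-contig `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  if (inherits(x, "sexlink")) x <- x$contigs
  stopifnot(is.data.frame(x))
  for (cn in setdiff(report_columns, names(x))) x[[cn]] <- NA
  x <- x[, report_columns]
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read back a per-contig report written by [write_report()]
#' @param path Path to the TSV report.
#' @return A `data.frame` with the report columns.
#' @export
read_report <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

# Minimal VCFv4.2 writer for simulator output (GT:AD only).  Plain text and
# bit-stable so that identical seeds give byte-identical files.
write_vcf <- function(snps, path, contig_info = NULL) {
  stopifnot(inherits(snps, "snp_table"))
  ids <- snps$samples$id
  hdr <- c("##fileformat=VCFv4.2",
           "##source=sexlinkr")
  if (!is.null(contig_info))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          contig_info$contig_id, contig_info$length_bp))
  hdr <- c(hdr,
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths for the ref and alt alleles\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", ids), collapse = "\t"))
  gt <- snps$gt
  gt[is.na(gt)] <- "./."
  fields <- matrix(paste0(gt, ":", snps$ad_ref, ",", snps$ad_alt),
                   nrow = nrow(snps$sites))
  body <- do.call(paste, c(list(snps$sites$contig_id, snps$sites$position,
                                ".", snps$sites$ref, snps$sites$alt,
                                ".", ".", ".", "GT:AD"),
                           lapply(seq_along(ids), function(j) fields[, j]),
                           sep = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}
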