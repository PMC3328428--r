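# Shared fixtures built in code.

samples6 <- function() {
  sample_table(c("M1", "M2", "M3", "F1", "F2", "F3"),
               rep(c("male", "female"), each = 3),
               c("run2", "run1", "run2", "run2", "run1", "run2"))
}

# Build a snp_table from per-site lists: gt is a character matrix (sites x
# individuals), depths likewise.
make_table <- function(gt, ad_ref, ad_alt, samples = samples6(),
                       contig = "c1", pos = NULL) {
  gt <- rbind(gt)
  n <- nrow(gt)
  if (is.null(pos)) pos <- seq_len(n) * 10L
  snp_table(data.frame(contig_id = rep(contig, length.out = n),
                       position = pos,
                       ref = rep("A", n), alt = rep("C", n),
                       stringsAsFactors = FALSE),
            gt = gt, ad_ref = rbind(ad_ref), ad_alt = rbind(ad_alt),
            samples = samples)
}

# error-free depths consistent with a genotype code "AA"/"AB"/"BB"
# (A = ref): hom gets all reads on one allele, het splits them.
depths_for <- function(geno, depth = 30L) {
  switch(geno,
         AA = c(depth, 0L),
         AB = c(depth - depth %/% 3L, depth %/% 3L),
         BB = c(0L, depth))
}

gt_for <- function(geno) switch(geno, AA = "0/0", AB = "0/1", BB = "1/1")

# one-site table from genotype codes for 3M + 3F
site_from_genos <- function(genos, samples = samples6()) {
  ad <- unname(vapply(genos, depths_for, integer(2)))
  make_table(gt = unname(vapply(genos, gt_for, character(1))),
             ad_ref = ad[1, ], ad_alt = ad[2, ], samples = samples)
}

# independent brute-force oracle for the segregation pattern: sex-linked
# iff every male is heterozygous and every female homozygous for the same
# allele (error-free data).
oracle_sex_linked <- function(genos, sexes) {
  males <- genos[sexes == "male"]
  fems <- genos[sexes == "female"]
  all(males == "AB") && (all(fems == "AA") || all(fems == "BB"))
}

composition6 <- function(total = rep(10e6, 6)) {
  data.frame(individual_id = samples6()$id, total_mapped = total,
             rrna = 0.1 * total, mito = 0.01 * total,
             chloro = 0.02 * total, te = 0.02 * total,
             stringsAsFactors = FALSE)
}

# minimal VCF text fixture writer
vcf_lines <- function(rows, ids = samples6()$id) {
  c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t"),
    rows)
}
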