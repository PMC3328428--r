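test_that("male genotype inference follows the support rule", {
  expect_equal(infer_male_genotype(c(30, 30, 0, 15), c(1, 0, 0, 15)),
               c("het", "hom", "missing", "het"))  # ties are het (support-based)
  # raising the support threshold can only demote het calls
  ctl2 <- sexlink_control(min_y_reads = 2)
  expect_equal(infer_male_genotype(30, 1, ctl2), "hom")
  expect_equal(infer_male_genotype(30, 2, ctl2), "het")
  # minor-fraction requirement
  ctlf <- sexlink_control(min_minor_fraction = 0.1)
  expect_equal(infer_male_genotype(99, 1, ctlf), "hom")
  expect_equal(infer_male_genotype(9, 1, ctlf), "het")
})

test_that("binomial male rule rejects homozygosity only for improbable minor depths", {
  ctl <- sexlink_control(male_rule = "binomial", binom_error = 0.005,
                         binom_alpha = 0.05)
  # 1 error read in 30 is plausible under e = 0.005 -> hom
  expect_equal(infer_male_genotype(30, 1, ctl), "hom")
  # 5 minor reads in 35 are not -> het
  expect_equal(infer_male_genotype(30, 5, ctl), "het")
  expect_equal(infer_male_genotype(0, 0, ctl), "missing")
})

test_that("classify_site reproduces the diagnostic segregation pattern", {
  ok <- classify_site(c("0/1", "0/1", "0/1", "0/0", "0/0", "0/0"),
                      depth_ref = c(30, 28, 25, 40, 38, 33),
                      depth_alt = c(5, 6, 3, 0, 0, 0),
                      sex = rep(c("male", "female"), each = 3))
  expect_true(ok$sex_linked)
  expect_equal(ok$x_allele, "A")
  expect_equal(ok$y_allele, "B")

  # females homozygous but not for the same allele
  bad <- classify_site(c("0/1", "0/1", "0/1", "0/0", "1/1", "1/1"),
                       depth_ref = c(30, 28, 25, 40, 0, 0),
                       depth_alt = c(5, 6, 3, 0, 38, 33),
                       sex = rep(c("male", "female"), each = 3))
  expect_false(bad$sex_linked)
  expect_equal(bad$reason, "females_not_hom_same")

  # a missing individual disqualifies the site
  mis <- classify_site(c("0/1", "0/1", "0/1", "0/0", "0/0", NA),
                       depth_ref = c(30, 28, 25, 40, 38, 0),
                       depth_alt = c(5, 6, 3, 0, 0, 0),
                       sex = rep(c("male", "female"), each = 3))
  expect_false(mis$sex_linked)
  expect_equal(mis$reason, "missing_individual")
})

test_that("classification agrees with brute-force enumeration on all 729 configurations", {
  genos <- c("AA", "AB", "BB")
  grid <- expand.grid(rep(list(genos), 6), stringsAsFactors = FALSE)
  sexes <- rep(c("male", "female"), each = 3)
  got <- logical(nrow(grid))
  want <- logical(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- unlist(grid[i, ], use.names = FALSE)
    ad <- vapply(g, depths_for, integer(2))
    res <- classify_site(vapply(g, gt_for, character(1)),
                         depth_ref = ad[1, ], depth_alt = ad[2, ],
                         sex = sexes)
    got[i] <- res$sex_linked
    want[i] <- oracle_sex_linked(g, sexes)
  }
  expect_identical(got, want)
  expect_equal(sum(want), 2L)  # females all AA or all BB, males all AB
})

test_that("classification matches the oracle on random error-free depths", {
  set.seed(42)
  genos <- c("AA", "AB", "BB")
  sexes <- rep(c("male", "female"), each = 3)
  for (rep_i in 1:200) {
    g <- sample(genos, 6, replace = TRUE)
    depth <- sample(3:80, 6, replace = TRUE)
    ad <- mapply(function(gi, di) depths_for(gi, di), g, depth)
    res <- classify_site(vapply(g, gt_for, character(1)),
                         depth_ref = ad[1, ], depth_alt = ad[2, ],
                         sex = sexes)
    expect_equal(res$sex_linked, oracle_sex_linked(g, sexes))
  }
})

test_that("swapping ref/alt labels swaps X and Y and nothing else", {
  gt <- c("0/1", "0/1", "0/1", "0/0", "0/0", "0/0")
  dr <- c(30, 28, 25, 40, 38, 33); da <- c(5, 6, 3, 0, 0, 0)
  sexes <- rep(c("male", "female"), each = 3)
  a <- classify_site(gt, dr, da, sexes, ref = "A", alt = "C")
  swap <- chartr("01", "10", gt)
  swap <- vapply(strsplit(swap, "/"), function(x)
    paste(sort(x), collapse = "/"), character(1))
  b <- classify_site(swap, da, dr, sexes, ref = "C", alt = "A")
  expect_true(a$sex_linked && b$sex_linked)
  expect_equal(a$x_allele, b$x_allele)
  expect_equal(a$y_allele, b$y_allele)
})

test_that("raising min_y_reads only shrinks the sex-linked set", {
  sim <- simulate_dataset(sim_config(n_sexlinked = 100, n_autosomal = 50,
                                     d_dist = "lognormal", seed = 77))
  sets <- lapply(c(1, 2, 4, 8), function(k) {
    cl <- classify_sites(sim$snps, sexlink_control(min_y_reads = k))
    which(cl$status == "sex_linked")
  })
  for (i in 2:length(sets))
    expect_true(all(sets[[i]] %in% sets[[i - 1]]))
})

test_that("contig classification counts sex-linked SNPs and sets flags", {
  st <- make_table(
    gt = rbind(c("0/1", "0/1", "0/1", "0/0", "0/0", "0/0"),
               c("0/1", "0/1", "0/1", "1/1", "1/1", "1/1"),
               c("0/0", "0/0", "0/0", "0/0", "0/0", "0/0")),
    ad_ref = rbind(c(30, 28, 25, 40, 38, 33),
                   c(10, 12, 9, 0, 0, 0),
                   c(30, 30, 30, 30, 30, 30)),
    ad_alt = rbind(c(5, 6, 3, 0, 0, 0),
                   c(20, 18, 22, 35, 31, 29),
                   c(0, 0, 0, 0, 0, 0)),
    contig = c("c1", "c1", "c2"))
  cl <- classify_contigs(st)
  c1 <- cl[cl$contig_id == "c1", ]
  expect_equal(c1$n_sexlinked_snps, 2L)
  expect_true(c1$is_sex_linked && c1$passes_strict)
  c2 <- cl[cl$contig_id == "c2", ]
  expect_equal(c2$n_sexlinked_snps, 0L)
  expect_false(c2$is_sex_linked)
  expect_true(is.na(c2$x_polymorphic))
  # single sex-linked SNP: sex-linked but not strict
  one <- classify_contigs(site_from_genos(c("AB", "AB", "AB", "AA", "AA", "AA")))
  expect_true(one$is_sex_linked)
  expect_false(one$passes_strict)
})

test_that("X polymorphism is flagged by each clause of the filter", {
  sl_row <- list(gt = c("0/1", "0/1", "0/1", "0/0", "0/0", "0/0"),
                 dr = c(30, 28, 25, 40, 38, 33), da = c(5, 6, 3, 0, 0, 0))
  mk <- function(gt2, dr2, da2) {
    make_table(gt = rbind(sl_row$gt, gt2),
               ad_ref = rbind(sl_row$dr, dr2),
               ad_alt = rbind(sl_row$da, da2))
  }
  # heterozygous female
  st <- mk(c("0/0", "0/0", "0/0", "0/1", "0/0", "0/0"),
           c(30, 30, 30, 15, 30, 30), c(0, 0, 0, 14, 0, 0))
  expect_true(classify_contigs(st)$x_polymorphic)
  # all homozygous, same allele everywhere: no polymorphism
  st <- mk(c("0/0", "0/0", "0/0", "0/0", "0/0", "0/0"),
           rep(30, 6), rep(0, 6))
  expect_false(classify_contigs(st)$x_polymorphic)
  # all homozygous but not for the same allele
  st <- mk(c("0/0", "0/0", "0/0", "1/1", "1/1", "1/1"),
           c(30, 30, 30, 0, 0, 0), c(0, 0, 0, 30, 30, 30))
  expect_true(classify_contigs(st)$x_polymorphic)
  # heterozygous male at a non-sex-linked site (read-based)
  st <- mk(c("0/0", "0/0", "0/0", "0/0", "0/0", "0/0"),
           c(20, 30, 30, 30, 30, 30), c(10, 0, 0, 0, 0, 0))
  expect_true(classify_contigs(st)$x_polymorphic)
})

test_that("strict female mode disqualifies females with high minor fractions", {
  gt <- c("0/1", "0/1", "0/1", "0/0", "0/0", "0/0")
  dr <- c(30, 28, 25, 40, 30, 33); da <- c(5, 6, 3, 0, 10, 0)
  lax <- classify_site(gt, dr, da, rep(c("male", "female"), each = 3))
  expect_true(lax$sex_linked)   # GT taken verbatim
  strict <- classify_site(gt, dr, da, rep(c("male", "female"), each = 3),
                          control = sexlink_control(strict_females = TRUE))
  expect_false(strict$sex_linked)  # F2 has 25% alt reads
})
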