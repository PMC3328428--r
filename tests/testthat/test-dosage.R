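test_that("Y/X bins partition the nonnegative line with half-open intervals", {
  set.seed(1)
  v <- c(0, 0.249, 0.25, 0.5, 0.75, 0.999, 1, 1.49, 1.5, 7, runif(500, 0, 4))
  b <- yx_bin(v)
  expect_false(any(is.na(b)))                       # exactly one bin each
  expect_equal(as.character(b[1:4]),
               c("[0,0.25)", "[0,0.25)", "[0.25,0.5)", "[0.5,0.75)"))
  expect_equal(as.character(b[7]), "[1,1.5)")       # boundary goes right
  expect_equal(as.character(b[9]), "[1.5,Inf)")
  expect_equal(as.character(yx_bin(Inf)), "[1.5,Inf)")
})

test_that("dosage records form the ratios and apply strict-boundary exclusions", {
  summ <- data.frame(contig_id = c("a", "b", "c", "d"),
                     X_male = c(5, 10, 9, 10),
                     Y_male = c(4, 8, 13.5, 16),
                     X_female_both = c(10, 5, 6, 4))
  rec <- compute_dosage_records(summ)
  expect_equal(rec$xm2xf_ratio, c(0.5, 2, 1.5, 2.5))
  expect_equal(rec$yx_ratio, c(0.8, 0.8, 1.5, 1.6))
  expect_equal(rec$yx_bin[1], "[0.75,1)")
  # equality with the boundary is retained; only strictly-above is excluded
  expect_equal(rec$excluded_high_yx, c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(rec$excluded_high_xm2xf, c(FALSE, FALSE, FALSE, TRUE))
  # zero male X summary: top bin, flagged
  rec0 <- compute_dosage_records(data.frame(contig_id = "z", X_male = 0,
                                            Y_male = 3, X_female_both = 2))
  expect_true(is.infinite(rec0$yx_ratio))
  expect_equal(rec0$yx_bin, "[1.5,Inf)")
  expect_true(rec0$excluded_high_yx)
})

test_that("Y-reduction test behaves at the null, under domination, and degenerately", {
  set.seed(9)
  x <- rexp(100, 1 / 20)
  same <- test_y_reduction(x, x)
  expect_equal(same$p.value, 1)
  expect_match(same$method, "degenerate")
  half <- test_y_reduction(x, x / 2)
  expect_lt(half$p.value, 1e-10)
  expect_equal(half$direction, "Y < X")
  null <- test_y_reduction(x, x * exp(rnorm(100, 0, 0.05)))
  expect_gt(null$p.value, 0.001)
})

test_that("Xmale/2Xfemale departure test detects shifts from 0.5", {
  expect_equal(test_xm2xf_departure(rep(0.5, 50))$p.value, 1)
  expect_lt(test_xm2xf_departure(rep(1, 50))$p.value, 1e-8)
  set.seed(4)
  r <- 0.5 * exp(rnorm(200, 0, 0.1))
  expect_gt(test_xm2xf_departure(r)$p.value, 0.001)
})

test_that("no-compensation type-I error of the 0.5 test is near alpha", {
  # ratios centred at 0.5 by construction: d = 1, no compensation
  set.seed(6)
  rej <- vapply(1:60, function(i) {
    cfg <- sim_config(n_sexlinked = 40, n_autosomal = 0, compensation = "none",
                      d_dist = "fixed", d_par1 = 1, e = 0, snps_lambda = 5,
                      depth_mean = 400, depth_dispersion = 1e6, lib_cv = 0,
                      seed = 3000 + i)
    fit <- sexlink(simulate_dataset(cfg))
    r <- fit$contigs$xm2xf_ratio
    test_xm2xf_departure(r[is.finite(r)])$p.value < 0.05
  }, logical(1))
  # the ratio-of-means estimator has a small positive finite-sample bias,
  # so allow the rejection rate some room above the nominal 5%
  expect_lt(mean(rej), 0.35)
})

profile_fit <- function(mode, d_dist = "uniform", d1 = 0.05, d2 = 1.45,
                        seed = 61) {
  cfg <- sim_config(n_sexlinked = 400, n_autosomal = 0, compensation = mode,
                    d_dist = d_dist, d_par1 = d1, d_par2 = d2,
                    depth_mean = 80, seed = seed)
  sexlink(simulate_dataset(cfg))
}

test_that("profile conservation: XY equals X plus Y per bin, females are 1", {
  fit <- profile_fit("proportional")
  prof <- build_dosage_profile(fit, n_boot = 25, seed = 2)
  w <- reshape(prof[, c("yx_bin", "allele_class", "raw", "estimate")],
               idvar = "yx_bin", timevar = "allele_class", direction = "wide")
  occ <- w[!is.na(w$raw.XX_females), ]
  expect_equal(occ$raw.XY_males, occ$raw.X_males + occ$raw.Y_males)
  expect_true(all(occ$estimate.XX_females == 1))
  # point estimates only when n_boot = 0
  p0 <- build_dosage_profile(fit, n_boot = 0)
  expect_true(all(is.na(p0$lo)))
  # empty bins reported with n = 0
  fit2 <- profile_fit("none", d_dist = "fixed", d1 = 1.2)
  p2 <- build_dosage_profile(fit2, n_boot = 0)
  expect_true(any(p2$n_contigs == 0))
  expect_true(all(is.na(p2$estimate[p2$n_contigs == 0])))
})

test_that("profile recovers the expected dosage patterns by compensation mode", {
  # full compensation, strongly degenerated Y: male X matches female XX
  fit_full <- profile_fit("full", d1 = 0.1, d2 = 0.5, seed = 62)
  p <- build_dosage_profile(fit_full, n_boot = 0)
  low <- p[p$yx_bin %in% c("[0,0.25)", "[0.25,0.5)") & p$n_contigs > 10, ]
  xm <- low$estimate[low$allele_class == "X_males"]
  expect_true(all(abs(xm - 1) < 0.12))
  # no compensation, d = 1: male X near half, X+Y near the female level
  fit_none <- profile_fit("none", d_dist = "fixed", d1 = 1, seed = 63)
  p2 <- build_dosage_profile(fit_none, n_boot = 0)
  bin1 <- p2[p2$yx_bin == "[0.75,1)", ]
  expect_lt(abs(bin1$estimate[bin1$allele_class == "X_males"] - 0.5), 0.1)
  expect_lt(abs(bin1$estimate[bin1$allele_class == "XY_males"] - 1), 0.15)
})

test_that("heterozygosity comparison handles contrasts and degenerate tables", {
  rec <- data.frame(contig_id = paste0("c", 1:8),
                    yx_ratio = c(0.2, 0.3, 0.25, 0.4, 1.1, 1.2, 0.9, 1.0),
                    xm2xf_ratio = c(0.9, 1, 0.85, 0.95, 0.5, 0.55, 0.5, 0.6),
                    x_polymorphic = c(TRUE, FALSE, TRUE, FALSE,
                                      TRUE, FALSE, TRUE, FALSE))
  hc <- heterozygosity_comparison(rec)
  expect_equal(unname(hc$proportions), c(0.5, 0.5))
  expect_gt(hc$test$p.value, 0.9)      # identical proportions: no difference
  # all contigs monomorphic: degenerate but handled
  rec$x_polymorphic <- FALSE
  hc2 <- heterozygosity_comparison(rec)
  expect_equal(unname(hc2$proportions), c(0, 0))
  expect_equal(hc2$test$p.value, 1)
  # empty stratum: reported, no crash, no test
  rec$yx_ratio <- 1.2
  hc3 <- heterozygosity_comparison(rec)
  expect_null(hc3$test)
  expect_match(hc3$note, "empty stratum")
})

test_that("simulated X inactivation depletes expressed polymorphism on compensated contigs", {
  cfg <- sim_config(n_sexlinked = 600, n_autosomal = 0,
                    compensation = "proportional",
                    d_dist = "uniform", d_par1 = 0.1, d_par2 = 1.4,
                    x_poly_rate = 0.8, female_het_rate = 0.9,
                    x_inactivation = "compensated", seed = 71)
  fit <- sexlink(simulate_dataset(cfg))
  hc <- heterozygosity_comparison(fit)
  expect_lt(hc$proportions["compensated"],
            hc$proportions["not_compensated"] - 0.2)
  expect_lt(hc$test$p.value, 1e-6)
  # ... and with biallelic expression the strata look alike
  cfg$x_inactivation <- "none"
  hc0 <- heterozygosity_comparison(sexlink(simulate_dataset(cfg)))
  expect_gt(hc0$test$p.value, 0.001)
})

test_that("false-positive rate is zero on the pure null and monotone in h and e", {
  ctl <- sexlink_control()
  fp0 <- estimate_false_positive_rate(
    sim_config(n_autosomal = 1500, h = 0, e = 0, seed = 81), ctl, n_reps = 1)
  expect_equal(fp0$rate_1snp, 0)
  expect_equal(fp0$rate_2snp, 0)

  rates <- vapply(list(c(0.02, 0.001), c(0.08, 0.001), c(0.08, 0.01)),
                  function(pars) {
    fp <- estimate_false_positive_rate(
      sim_config(n_autosomal = 4000, h = pars[1], e = pars[2], seed = 82),
      ctl, n_reps = 1)
    expect_lte(fp$rate_2snp, fp$rate_1snp)   # strict set is a restriction
    fp$rate_1snp
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
  # scaling to a detected-set size gives expected counts
  fp <- estimate_false_positive_rate(
    sim_config(n_autosomal = 2000, h = 0.05, e = 0.005, seed = 83),
    ctl, n_reps = 1, scale_to = 1000)
  expect_equal(fp$expected_1snp, fp$rate_1snp * 1000)
})

test_that("the fitted object survives an end-to-end file round trip deterministically", {
  sim <- simulate_dataset(sim_config(n_sexlinked = 25, n_autosomal = 25,
                                     seed = 91))
  dir <- withr::local_tempdir()
  p <- write_dataset(sim, dir)
  fit <- sexlink(p[["vcf"]], p[["samples"]], p[["library"]], p[["contigs"]])
  expect_s3_class(fit, "sexlink")
  expect_gt(sum(fit$contigs$is_sex_linked), 0)
  r1 <- file.path(dir, "r1.tsv"); r2 <- file.path(dir, "r2.tsv")
  write_report(fit, r1)
  fit2 <- sexlink(p[["vcf"]], p[["samples"]], p[["library"]], p[["contigs"]])
  write_report(fit2, r2)
  expect_identical(readLines(r1), readLines(r2))
  # in-memory and file-based runs agree
  fit_mem <- sexlink(sim)
  expect_equal(fit_mem$contigs$yx_ratio, fit$contigs$yx_ratio)
  # missing library-composition file is a named, actionable error
  expect_error(sexlink(p[["vcf"]], p[["samples"]],
                       file.path(dir, "nope.tsv"), p[["contigs"]]),
               "nope.tsv")
})
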