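#' Configuration for the synthetic-data generator
#'
#' Describes a synthetic RNA-seq genotype dataset from an inbred XY family:
#' sex-linked contigs carrying X/Y allele pairs with per-contig Y
#' degeneration and X compensation, and autosomal contigs with residual
#' heterozygosity.  Inbreeding is represented by the single parameter `h`
#' (per-site residual heterozygosity) rather than an explicit pedigree:
#' only the genotype-pattern frequencies matter downstream.
#'
#' The expression model works per site and individual on a baseline `b =
#' depth_mean/2`, the expected depth of one expressed gene copy in an
#' average library.  A female at a sex-linked site is homozygous X/X with
#' expected total depth `2b`.  A male expresses his X at `c*b` and his Y at
#' `d*c*b`, where `d` is the contig's Y/X degeneration coefficient and `c`
#' its X-compensation factor: `c = 1` without compensation (so
#' Xmale/2Xfemale is expected at 0.5), `c = 2` under full compensation
#' (the single male X matches the combined female X output, ratio 1), and
#' `c = 2/(1+d)` under proportional compensation (total male X+Y output
#' equals total female output).  Depths are negative-binomial
#' (overdispersed) and scaled by each individual's nuclear-library size,
#' so the downstream library-size normalization is genuinely exercised;
#' finally every read is mis-assigned to the other allele with probability
#' `e` (base-call error).
#'
#' @param n_males,n_females Number of individuals per sex (defaults 3 + 3).
#' @param n_sexlinked,n_autosomal Number of contigs of each class.
#' @param snps_lambda,snps_min SNPs per contig: truncated Poisson mean and
#'   lower bound (defaults 3, 1).
#' @param length_meanlog,length_sdlog,length_min Contig length: log-normal
#'   parameters and hard floor (default floor 200 bp, mirroring the usual
#'   assembly cutoff).
#' @param depth_mean Expected total read depth at a site in an
#'   average-sized library for a two-copy genotype (default 50).
#' @param depth_dispersion Negative-binomial size parameter; smaller means
#'   more overdispersion (default 10, i.e. ~32% extra-Poisson CV per site).
#' @param d_dist,d_par1,d_par2 Sampler for the per-contig degeneration
#'   coefficient `d` on (0, Inf): `"lognormal"` (meanlog, sdlog; default
#'   centred on a median of 0.77), `"uniform"` (min, max) or `"fixed"`
#'   (`d_par1` everywhere).
#' @param compensation `"proportional"` (default), `"none"` or `"full"`.
#' @param h Residual per-site heterozygosity of an autosomal site in a
#'   given individual (default 0.05, a plausible leftover after ten
#'   generations of sib mating).
#' @param e Probability that a read supports the wrong allele
#'   (default 0.001).
#' @param x_poly_rate Probability that a sex-linked contig carries one
#'   additional X-polymorphic (not sex-linked) site.
#' @param female_het_rate At such a site, probability that a female is
#'   heterozygous for the two X haplotypes.
#' @param x_inactivation `"none"` (default): heterozygous females express
#'   both X copies; `"compensated"`: on compensated contigs (compensation
#'   factor > 1.25) every female silences the same X haplotype
#'   (chromosome-wide, imprinting-like), hiding her heterozygosity from
#'   the expressed reads; `"all"`: the same on every sex-linked contig.
#' @param lib_total_mean,lib_cv Mean and log-normal CV of total mapped
#'   reads per individual.
#' @param rrna_frac Named fractions of rRNA reads per run batch
#'   (`run1`, `run2`); the two-batch design puts one male and one female
#'   in `run1` and everyone else in `run2`.
#' @param mito_frac Mitochondrial fraction (both sexes).
#' @param chloro_frac,te_frac Named per-sex fractions (`male`, `female`).
#' @param seed Integer seed fixing the full output stream.
#' @return An object of class `"sim_config"`.
#' @examples
#' sim_config(n_sexlinked = 10, n_autosomal = 10, seed = 1)
#' @export
sim_config <- function(n_males = 3L, n_females = 3L,
                       n_sexlinked = 100L, n_autosomal = 100L,
                       snps_lambda = 3, snps_min = 1L,
                       length_meanlog = log(700), length_sdlog = 0.4,
                       length_min = 200L,
                       depth_mean = 50, depth_dispersion = 10,
                       d_dist = c("lognormal", "uniform", "fixed"),
                       d_par1 = log(0.77), d_par2 = 0.5,
                       compensation = c("proportional", "none", "full"),
                       h = 0.05, e = 0.001,
                       x_poly_rate = 0.1, female_het_rate = 0.6,
                       x_inactivation = c("none", "compensated", "all"),
                       lib_total_mean = 12e6, lib_cv = 0.1,
                       rrna_frac = c(run1 = 0.14, run2 = 0.06),
                       mito_frac = 0.015,
                       chloro_frac = c(male = 0.02, female = 0.05),
                       te_frac = c(male = 0.035, female = 0.02),
                       seed = 1L) {
  d_dist <- match.arg(d_dist)
  compensation <- match.arg(compensation)
  x_inactivation <- match.arg(x_inactivation)
  stopifnot(n_males >= 1, n_females >= 1,
            n_sexlinked >= 0, n_autosomal >= 0,
            snps_lambda > 0, snps_min >= 1,
            length_min >= 1, depth_mean > 0, depth_dispersion > 0,
            h >= 0, h <= 1, e >= 0, e <= 1,
            x_poly_rate >= 0, x_poly_rate <= 1,
            female_het_rate >= 0, female_het_rate <= 1,
            lib_total_mean > 0, lib_cv >= 0,
            all(rrna_frac >= 0), all(c("run1", "run2") %in% names(rrna_frac)),
            mito_frac >= 0,
            all(c("male", "female") %in% names(chloro_frac)),
            all(c("male", "female") %in% names(te_frac)))
  if (d_dist == "uniform" && !(d_par2 > d_par1 && d_par1 > 0))
    stop("uniform d sampler needs 0 < d_par1 < d_par2")
  if (d_dist == "fixed" && d_par1 <= 0)
    stop("fixed d must be positive")
  structure(as.list(environment()), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic dataset configuration\n")
  cat("  individuals:", x$n_males, "male +", x$n_females, "female\n")
  cat("  contigs:", x$n_sexlinked, "sex-linked /", x$n_autosomal,
      "autosomal; ~", x$snps_lambda, "SNPs per contig\n")
  cat("  depth:", x$depth_mean, "(NB size", x$depth_dispersion, ")",
      " error:", x$e, " residual het:", x$h, "\n")
  cat("  degeneration d:", x$d_dist, "(", x$d_par1, ",", x$d_par2, ")",
      " compensation:", x$compensation, "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

draw_d <- function(n, config) {
  switch(config$d_dist,
         lognormal = rlnorm(n, config$d_par1, config$d_par2),
         uniform = runif(n, config$d_par1, config$d_par2),
         fixed = rep(config$d_par1, n))
}

# truncated Poisson (>= min) via inverse CDF
rtpois <- function(n, lambda, min) {
  qpois(runif(n, ppois(min - 1L, lambda), 1), lambda)
}

# naive depth-based genotype caller emulating what an upstream caller sees
# in the RNA reads: monoallelic expression hides heterozygosity.
call_gt <- function(ref, alt, min_each = 2L, min_frac = 0.1) {
  tot <- ref + alt
  gt <- ifelse(ref >= alt, "0/0", "1/1")
  minor <- pmin(ref, alt)
  gt[minor >= min_each & minor / pmax(tot, 1L) >= min_frac] <- "0/1"
  gt[tot == 0L] <- NA_character_
  gt
}

#' Generate a synthetic dataset with ground truth
#'
#' Produces a complete in-memory dataset — SNP table, sample table,
#' library-composition table, contig lengths — plus a truth table
#' recording every contig's class, degeneration coefficient `d`,
#' compensation factor `c`, and every site's type and true genotypes.
#' Identical configurations (including the seed) give identical output;
#' [write_dataset()] serializes to VCF/TSV byte-stably.
#'
#' @param config A [sim_config()].
#' @return An object of class `"sexlink_sim"`: list with elements `snps`
#'   ([snp_table()]), `samples`, `library`, `contigs`, `truth` (list of
#'   `contigs`, `sites`, `genotypes`) and `config`.
#' @examples
#' sim <- simulate_dataset(sim_config(n_sexlinked = 5, n_autosomal = 5,
#'                                    seed = 7))
#' sim$truth$contigs[1:3, ]
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)

  nm <- config$n_males; nf <- config$n_females
  n_ind <- nm + nf
  ids <- c(sprintf("M%d", seq_len(nm)), sprintf("F%d", seq_len(nf)))
  sex <- rep(c("male", "female"), c(nm, nf))
  batch <- rep("run2", n_ind)
  if (nm >= 2L) batch[2L] <- "run1"
  if (nf >= 2L) batch[nm + 2L] <- "run1"
  samples <- sample_table(ids, sex, batch)

  # library composition; depth scale follows the nuclear library size
  total <- round(config$lib_total_mean * rlnorm(n_ind, 0, config$lib_cv))
  rr <- round(total * config$rrna_frac[batch])
  mt <- round(total * config$mito_frac)
  cp <- round(total * config$chloro_frac[sex])
  te <- round(total * config$te_frac[sex])
  comp <- data.frame(individual_id = ids, total_mapped = as.numeric(total),
                     rrna = as.numeric(rr), mito = as.numeric(mt),
                     chloro = as.numeric(cp), te = as.numeric(te),
                     stringsAsFactors = FALSE)
  lnuc <- (comp$total_mapped - comp$rrna - comp$mito - comp$chloro -
             comp$te) / 1e6
  sfac <- lnuc / mean(lnuc)

  b <- config$depth_mean / 2
  size <- config$depth_dispersion
  nsl <- config$n_sexlinked; naut <- config$n_autosomal
  nc <- nsl + naut
  if (nc == 0L) stop("no contigs requested")
  contig_id <- sprintf("tig%06d", seq_len(nc))
  cls <- rep(c("sex_linked", "autosomal"), c(nsl, naut))
  len <- pmax(config$length_min,
              round(rlnorm(nc, config$length_meanlog, config$length_sdlog)))
  k <- rtpois(nc, config$snps_lambda, config$snps_min)

  d <- rep(NA_real_, nc); cc <- rep(NA_real_, nc)
  xpoly <- rep(FALSE, nc); xinact <- rep(FALSE, nc)
  if (nsl > 0L) {
    i <- seq_len(nsl)
    d[i] <- draw_d(nsl, config)
    cc[i] <- switch(config$compensation,
                    none = rep(1, nsl),
                    full = rep(2, nsl),
                    proportional = 2 / (1 + d[i]))
    xpoly[i] <- runif(nsl) < config$x_poly_rate
    xinact[i] <- switch(config$x_inactivation,
                        none = rep(FALSE, nsl),
                        all = rep(TRUE, nsl),
                        compensated = cc[i] > 1.25)
  }

  # site scaffold
  n_site_contig <- k + (cls == "sex_linked") * xpoly
  site_contig <- rep(seq_len(nc), n_site_contig)
  ns <- length(site_contig)
  pos <- integer(ns)
  type <- character(ns)
  at <- 1L
  for (i in seq_len(nc)) {
    nsi <- n_site_contig[i]
    idx <- at:(at + nsi - 1L)
    pos[idx] <- sort(sample.int(len[i], nsi))
    if (cls[i] == "autosomal") {
      type[idx] <- "autosomal"
    } else {
      t <- rep("sex_linked", nsi)
      if (xpoly[i]) t[sample.int(nsi, 1L)] <- "x_poly"
      type[idx] <- t
    }
    at <- at + nsi
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, ns, replace = TRUE)
  alt <- bases[(match(ref, bases) - 1L + sample.int(3L, ns, replace = TRUE)) %% 4L + 1L]
  x_is_ref <- runif(ns) < 0.5
  d_s <- d[site_contig]; c_s <- cc[site_contig]
  xinact_s <- xinact[site_contig]

  i_sl <- type == "sex_linked"
  i_xp <- type == "x_poly"
  i_au <- type == "autosomal"

  ad_ref <- matrix(0L, ns, n_ind, dimnames = list(NULL, ids))
  ad_alt <- matrix(0L, ns, n_ind, dimnames = list(NULL, ids))
  gt_true <- matrix(NA_character_, ns, n_ind, dimnames = list(NULL, ids))

  put <- function(refv, altv, idx, x_cnt, y_cnt, on_x_is_ref) {
    refv[idx] <- ifelse(on_x_is_ref, x_cnt, y_cnt)
    altv[idx] <- ifelse(on_x_is_ref, y_cnt, x_cnt)
    list(refv, altv)
  }
  for (j in seq_len(n_ind)) {
    sj <- sfac[j]
    male <- sex[j] == "male"
    rt <- integer(ns); av <- integer(ns)
    if (any(i_sl)) {
      w <- which(i_sl)
      if (male) {
        x_cnt <- rnbinom(length(w), size = size, mu = b * c_s[w] * sj)
        y_cnt <- rnbinom(length(w), size = size, mu = b * c_s[w] * d_s[w] * sj)
        gt_true[w, j] <- "0/1"
      } else {
        x_cnt <- rnbinom(length(w), size = size, mu = 2 * b * sj)
        y_cnt <- 0L
        gt_true[w, j] <- ifelse(x_is_ref[w], "0/0", "1/1")
      }
      z <- put(rt, av, w, x_cnt, y_cnt, x_is_ref[w])
      rt <- z[[1]]; av <- z[[2]]
    }
    if (any(i_xp)) {
      w <- which(i_xp)
      if (male) {
        tot <- rnbinom(length(w), size = size,
                       mu = b * c_s[w] * (1 + d_s[w]) * sj)
        a1 <- tot; a2 <- 0L
        gt_true[w, j] <- ifelse(x_is_ref[w], "0/0", "1/1")
      } else {
        het <- runif(length(w)) < config$female_het_rate
        a1 <- integer(length(w)); a2 <- integer(length(w))
        hom <- !het
        a1[hom] <- rnbinom(sum(hom), size = size, mu = 2 * b * sj)
        gt_true[w, j] <- ifelse(het, "0/1",
                                ifelse(x_is_ref[w], "0/0", "1/1"))
        if (any(het)) {
          wh <- which(het)
          mono <- xinact_s[w][wh]
          nh <- length(wh)
          # inactivation silences the same X haplotype in every female
          # (chromosome-wide, imprinting-like), so all reads fall on the
          # haplotype shared with the males
          c1 <- integer(nh); c2 <- integer(nh)
          c1[mono] <- rnbinom(sum(mono), size = size, mu = 2 * b * sj)
          bi <- !mono
          c1[bi] <- rnbinom(sum(bi), size = size, mu = b * sj)
          c2[bi] <- rnbinom(sum(bi), size = size, mu = b * sj)
          a1[wh] <- c1; a2[wh] <- c2
        }
      }
      z <- put(rt, av, w, a1, a2, x_is_ref[w])
      rt <- z[[1]]; av <- z[[2]]
    }
    if (any(i_au)) {
      w <- which(i_au)
      g <- runif(length(w))
      het <- g < config$h
      hom_first <- !het & (g < config$h + (1 - config$h) / 2)
      a1 <- integer(length(w)); a2 <- integer(length(w))
      a1[het] <- rnbinom(sum(het), size = size, mu = b * sj)
      a2[het] <- rnbinom(sum(het), size = size, mu = b * sj)
      a1[hom_first] <- rnbinom(sum(hom_first), size = size, mu = 2 * b * sj)
      hom2 <- !het & !hom_first
      a2[hom2] <- rnbinom(sum(hom2), size = size, mu = 2 * b * sj)
      gt_true[w, j] <- ifelse(het, "0/1", ifelse(hom_first, "0/0", "1/1"))
      rt[w] <- a1; av[w] <- a2
    }
    # base-call error: each read supports the wrong allele with prob e
    if (config$e > 0) {
      f1 <- rbinom(ns, rt, config$e)
      f2 <- rbinom(ns, av, config$e)
      rt <- rt - f1 + f2
      av <- av - f2 + f1
    }
    ad_ref[, j] <- rt
    ad_alt[, j] <- av
  }
  gt <- matrix(call_gt(ad_ref, ad_alt), ns, n_ind, dimnames = list(NULL, ids))

  sites <- data.frame(contig_id = contig_id[site_contig],
                      position = pos, ref = ref, alt = alt,
                      stringsAsFactors = FALSE)
  snps <- snp_table(sites, gt, ad_ref, ad_alt, samples)
  truth <- list(contigs = data.frame(contig_id = contig_id, class = cls,
                                     d = d, c = cc, n_snps = as.integer(k),
                                     x_poly_site = xpoly,
                                     x_inactivated = xinact,
                                     stringsAsFactors = FALSE),
                sites = data.frame(contig_id = contig_id[site_contig],
                                   position = pos, type = type,
                                   x_is_ref = x_is_ref,
                                   stringsAsFactors = FALSE),
                genotypes = gt_true)
  structure(list(snps = snps, samples = samples, library = comp,
                 contigs = data.frame(contig_id = contig_id,
                                      length_bp = as.integer(len),
                                      stringsAsFactors = FALSE),
                 truth = truth, config = config),
            class = "sexlink_sim")
}

#' @export
print.sexlink_sim <- function(x, ...) {
  cat("Synthetic dataset:", nrow(x$truth$contigs), "contigs (",
      sum(x$truth$contigs$class == "sex_linked"), "sex-linked,",
      sum(x$truth$contigs$class == "autosomal"), "autosomal ),",
      nrow(x$snps$sites), "sites,", nrow(x$samples), "individuals\n")
  cat("  seed:", x$config$seed, "\n")
  invisible(x)
}

#' Autosomal-only null dataset
#'
#' Convenience wrapper forcing `n_sexlinked = 0`: every contig is
#' autosomal, so any contig the detector calls sex-linked is a false
#' positive.  Used for false-positive-rate calibration.
#'
#' @param config A [sim_config()]; its `n_sexlinked` is overridden to 0.
#' @return A `"sexlink_sim"` object whose truth table marks every contig
#'   autosomal.
#' @export
simulate_autosomal_null <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  config$n_sexlinked <- 0L
  if (config$n_autosomal < 1L)
    stop("null simulation needs autosomal contigs")
  simulate_dataset(config)
}

#' Write a synthetic dataset to files
#'
#' Serializes the dataset in the same dialects the readers consume: a
#' plain VCFv4.2 with `GT:AD`, TSVs for samples, library composition and
#' contig lengths, the truth tables, and the configuration as a flat
#' `key=value` file.  Output is byte-stable for a given configuration.
#'
#' @param sim A `"sexlink_sim"` object.
#' @param dir Output directory (created if needed).
#' @return Named character vector of paths, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "sexlink_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(vcf = file.path(dir, "variants.vcf"),
             samples = file.path(dir, "samples.tsv"),
             library = file.path(dir, "library_composition.tsv"),
             contigs = file.path(dir, "contigs.tsv"),
             truth_contigs = file.path(dir, "truth_contigs.tsv"),
             truth_sites = file.path(dir, "truth_sites.tsv"),
             config = file.path(dir, "config.txt"))
  write_vcf(sim$snps, paths["vcf"], sim$contigs)
  wt <- function(d, p) write.table(d, p, sep = "\t", quote = FALSE,
                                   row.names = FALSE)
  wt(sim$samples, paths["samples"])
  wt(sim$library, paths["library"])
  wt(sim$contigs, paths["contigs"])
  wt(sim$truth$contigs, paths["truth_contigs"])
  gtt <- as.data.frame(sim$truth$genotypes, stringsAsFactors = FALSE)
  names(gtt) <- paste0("gt_", names(gtt))
  wt(cbind(sim$truth$sites, gtt), paths["truth_sites"])
  cfg <- sim$config
  scal <- vapply(cfg, function(v) paste(
    if (is.null(names(v))) v else paste0(names(v), ":", v), collapse = ","),
    character(1))
  writeLines(paste0(names(cfg), "=", scal), paths["config"])
  invisible(paths)
}
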