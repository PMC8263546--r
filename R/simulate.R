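#' Simulation configuration
#'
#' Defines the synthetic clonal trial system: genotypes (allele-frequency
#' range, departure from HWE, missingness), the trial design (regions,
#' series-years, crops, partial replication), and the trait architecture
#' (target additive, dominance and additive-by-additive epistatic
#' variances, directional-dominance mean, residual variance, fixed-effect
#' spreads).
#'
#' @param n_clones,n_snps population and marker panel size.
#' @param maf_range range (low, high) within (0, 0.5] for the alternate
#'   allele frequency, drawn per locus from a uniform distribution.
#' @param inbreeding_f heterozygote deficit in [0, 1); 0 gives HWE
#'   genotype frequencies.
#' @param n_regions,years,crops design sizes; trials are nested in
#'   region x year (four per combination).
#' @param replication_rate probability that a clone is replicated in a
#'   second trial within its region-year (default 0.22, the average partial
#'   replication of the emulated trial system).
#' @param var_a,var_d,var_aa target genetic variances (additive, dominance,
#'   additive-by-additive); realized clone-level component variances are
#'   scaled to hit the targets exactly.
#' @param directional_dominance_mean mean of per-locus dominance effects
#'   before scaling; a positive value makes genome-wide heterozygosity
#'   positively correlated with genetic value (directional dominance).
#' @param n_epistatic_pairs number of random locus pairs carrying
#'   additive-by-additive effects.
#' @param var_e residual variance per record.
#' @param fixed_effect_sds named numeric: SDs of the year, crop, region and
#'   trial effects.
#' @param missing_rate genotype missingness rate.
#' @param seed integer seed.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(n_clones = 500L, n_snps = 2000L,
                       maf_range = c(0.05, 0.5), inbreeding_f = 0.1,
                       n_regions = 4L, years = 2013:2017,
                       crops = c("plant", "ratoon1", "ratoon2"),
                       replication_rate = 0.22,
                       var_a = 50, var_d = 30, var_aa = 40,
                       directional_dominance_mean = 0.5,
                       n_epistatic_pairs = 1000L,
                       var_e = 36,
                       fixed_effect_sds = c(year = 5, crop = 3, region = 5,
                                            trial = 2),
                       missing_rate = 0.01, seed = 1L) {
  stopifnot(var_a >= 0, var_d >= 0, var_aa >= 0, var_e > 0,
            maf_range[1L] > 0, maf_range[2L] <= 0.5,
            inbreeding_f >= 0, inbreeding_f < 1,
            replication_rate >= 0, replication_rate <= 1,
            missing_rate >= 0, missing_rate < 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Preset simulation configurations
#'
#' \code{mini} is the routine-validation scale (500 clones x 2,000 SNPs);
#' \code{full} matches the scale of a large commercial breeding data set
#' (3,000 clones x 25,000 SNPs).  Trait architectures: \code{TCH}-like
#' (substantial dominance and epistasis plus directional dominance, target
#' variances 50/30/40 and residual 36, broad-sense ratio 120/156);
#' \code{CCS}-like (mostly additive with moderate epistasis); and
#' \code{Fibre}-like (high-heritability additive).  Presets are
#' deterministic; randomness enters only through the seed at simulation
#' time.
#'
#' @param scale \code{"mini"} or \code{"full"}.
#' @param trait \code{"TCH"}, \code{"CCS"} or \code{"Fibre"} architecture.
#' @param seed integer seed stored in the config.
#' @return a \code{sim_config}.
#' @export
sim_preset <- function(scale = c("mini", "full"),
                       trait = c("TCH", "CCS", "Fibre"), seed = 1L) {
  scale <- match.arg(scale)
  trait <- match.arg(trait)
  size <- switch(scale,
                 mini = list(n_clones = 500L, n_snps = 2000L,
                             n_epistatic_pairs = 1000L),
                 full = list(n_clones = 3000L, n_snps = 25000L,
                             n_epistatic_pairs = 5000L))
  arch <- switch(trait,
    TCH = list(var_a = 50, var_d = 30, var_aa = 40, var_e = 36,
               directional_dominance_mean = 0.5,
               fixed_effect_sds = c(year = 5, crop = 3, region = 5,
                                    trial = 2)),
    CCS = list(var_a = 0.26, var_d = 0.01, var_aa = 0.11, var_e = 0.134,
               directional_dominance_mean = 0,
               fixed_effect_sds = c(year = 0.3, crop = 0.2, region = 0.3,
                                    trial = 0.1)),
    Fibre = list(var_a = 1.2, var_d = 0.05, var_aa = 0.25, var_e = 0.16,
                 directional_dominance_mean = 0,
                 fixed_effect_sds = c(year = 0.5, crop = 0.3, region = 0.5,
                                      trial = 0.2)))
  do.call(sim_config, c(size, arch, list(seed = seed)))
}

#' Simulate pseudo-diploid genotypes
#'
#' Per-locus alternate-allele frequencies are uniform on
#' \code{maf_range}; genotypes are drawn from the inbreeding-adjusted
#' frequencies P(het) = 2pq(1 - f), P(hom) = p^2 + fpq (and symmetrically),
#' so \code{inbreeding_f} = 0 gives HWE and larger values give the
#' heterozygote deficit typical of populations with related parents.
#' Missing calls are placed uniformly at \code{missing_rate}.
#'
#' @param cfg a \code{sim_config}.
#' @return a \code{geno_matrix}; the drawn allele frequencies are attached
#'   as attribute \code{alt_freqs}.
#' @export
simulate_genotypes <- function(cfg) {
  set.seed(cfg$seed)
  q <- stats::runif(cfg$n_snps, cfg$maf_range[1L], cfg$maf_range[2L])
  p <- 1 - q
  f <- cfg$inbreeding_f
  pr2 <- q^2 + f * p * q        # alt homozygote
  pr1 <- 2 * p * q * (1 - f)    # heterozygote
  pr0 <- 1 - pr1 - pr2
  codes <- vapply(seq_len(cfg$n_snps), function(l) {
    sample.int(3L, cfg$n_clones, replace = TRUE,
               prob = c(pr0[l], pr1[l], pr2[l])) - 1L
  }, integer(cfg$n_clones))
  if (cfg$missing_rate > 0) {
    nmiss <- round(cfg$missing_rate * length(codes))
    codes[sample.int(length(codes), nmiss)] <- NA_integer_
  }
  rownames(codes) <- sprintf("clone%04d", seq_len(cfg$n_clones))
  colnames(codes) <- sprintf("snp%05d", seq_len(cfg$n_snps))
  g <- geno_matrix(codes)
  attr(g, "alt_freqs") <- q
  g
}

#' Simulate trial records and trait values with known genetic architecture
#'
#' Builds clone-level genetic values from per-locus effects -- additive
#' (centred codes x normal substitution effects), dominance (NOIA
#' dominance incidence values x effects with mean
#' \code{directional_dominance_mean}, so the dominance covariance matches
#' G_D and, when the mean is nonzero, genome-wide heterozygosity
#' correlates with genetic value) and additive-by-additive epistasis
#' (products of centred codes over random locus pairs) -- each scaled so
#' its realized clone variance equals the target exactly.  Clones are
#' assigned to one region and one series-year, recorded for each crop in
#' one trial and, with probability \code{replication_rate}, replicated in a
#' second trial.  Year, crop, region and trial effects are drawn from
#' normal distributions with the configured SDs; residuals are i.i.d. per
#' record.
#'
#' @param g a \code{geno_matrix} from \code{\link{simulate_genotypes}}.
#' @param cfg the same \code{sim_config}.
#' @param trait_name column name for the simulated trait.
#' @return list with \code{phenotypes} (a \code{pheno_table}) and
#'   \code{truth} (per-clone true components and realized variances).
#' @export
simulate_phenotypes <- function(g, cfg, trait_name = "trait") {
  if (cfg$n_epistatic_pairs > choose(cfg$n_snps, 2))
    stop("n_epistatic_pairs exceeds the number of locus pairs")
  set.seed(cfg$seed + 1L)
  x <- impute_codes(g)
  n <- nrow(x); p <- ncol(x)
  xc <- sweep(x, 2L, colMeans(x))

  scale_to <- function(v, target) {
    s <- stats::sd(v)
    if (target <= 0 || s == 0) return(rep(0, length(v)))
    (v - mean(v)) / s * sqrt(target)
  }
  tbv <- scale_to(as.numeric(xc %*% stats::rnorm(p)), cfg$var_a)
  Hd <- noia_incidence(g, "dominance")
  deff <- stats::rnorm(p, mean = cfg$directional_dominance_mean, sd = 1)
  dom <- scale_to(as.numeric(Hd %*% deff), cfg$var_d)
  pairs <- matrix(0L, cfg$n_epistatic_pairs, 2L)
  if (cfg$n_epistatic_pairs > 0) {
    pairs[, 1L] <- sample.int(p, cfg$n_epistatic_pairs, replace = TRUE)
    pairs[, 2L] <- sample.int(p, cfg$n_epistatic_pairs, replace = TRUE)
    same <- pairs[, 1L] == pairs[, 2L]
    while (any(same)) {
      pairs[same, 2L] <- sample.int(p, sum(same), replace = TRUE)
      same <- pairs[, 1L] == pairs[, 2L]
    }
  }
  eeff <- stats::rnorm(nrow(pairs))
  epi_raw <- as.numeric((xc[, pairs[, 1L], drop = FALSE] *
                           xc[, pairs[, 2L], drop = FALSE]) %*% eeff)
  epi <- scale_to(epi_raw, cfg$var_aa)
  tgv <- tbv + dom + epi

  regions <- sprintf("R%d", seq_len(cfg$n_regions))
  clone_region <- regions[sample.int(length(regions), n, replace = TRUE)]
  clone_year <- cfg$years[sample.int(length(cfg$years), n, replace = TRUE)]
  year_eff <- stats::rnorm(length(cfg$years), 0, cfg$fixed_effect_sds["year"])
  names(year_eff) <- as.character(cfg$years)
  crop_eff <- stats::rnorm(length(cfg$crops), 0, cfg$fixed_effect_sds["crop"])
  names(crop_eff) <- cfg$crops
  region_eff <- stats::rnorm(length(regions), 0,
                             cfg$fixed_effect_sds["region"])
  names(region_eff) <- regions
  n_trials <- 4L
  trial_ids <- as.vector(outer(
    regions, as.vector(outer(cfg$years, seq_len(n_trials), paste, sep = "t")),
    paste, sep = "y"))
  trial_eff <- stats::rnorm(length(trial_ids), 0,
                            cfg$fixed_effect_sds["trial"])
  names(trial_eff) <- trial_ids

  home <- sample.int(n_trials, n, replace = TRUE)
  replicated <- stats::runif(n) < cfg$replication_rate
  second <- 1L + (home %% n_trials)
  rec <- vector("list", n)
  for (k in seq_len(n)) {
    tr <- paste0(clone_region[k], "y", clone_year[k], "t", home[k])
    trs <- tr
    if (replicated[k])
      trs <- c(tr, paste0(clone_region[k], "y", clone_year[k], "t",
                          second[k]))
    rec[[k]] <- expand.grid(clone = g$clone_ids[k], crop = cfg$crops,
                            trial = trs, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rec)
  df$year <- clone_year[match(df$clone, g$clone_ids)]
  df$region <- clone_region[match(df$clone, g$clone_ids)]
  m <- nrow(df)
  resid <- stats::rnorm(m, 0, sqrt(cfg$var_e))
  ci <- match(df$clone, g$clone_ids)
  df[[trait_name]] <- tgv[ci] +
    year_eff[as.character(df$year)] + crop_eff[df$crop] +
    region_eff[df$region] + trial_eff[df$trial] + resid
  ph <- pheno_table(df[, c("clone", "year", "crop", "region", "trial",
                           trait_name)])
  truth <- list(
    tbv = stats::setNames(tbv, g$clone_ids),
    dominance = stats::setNames(dom, g$clone_ids),
    epistasis = stats::setNames(epi, g$clone_ids),
    total = stats::setNames(tgv, g$clone_ids),
    realized_var = c(a = stats::var(tbv), d = stats::var(dom),
                     aa = stats::var(epi), e = cfg$var_e),
    epistatic_pairs = pairs,
    fixed_effects = list(year = year_eff, crop = crop_eff,
                         region = region_eff, trial = trial_eff))
  list(phenotypes = ph, truth = truth)
}
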