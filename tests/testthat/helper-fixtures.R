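# small in-code fixtures shared across test files

# genotype matrix with given codes (rows = clones)
make_geno <- function(codes, ...) {
  geno_matrix(as.matrix(codes), ...)
}

# random small genotype matrix without missing values
random_geno <- function(n, p, seed = 1) {
  set.seed(seed)
  q <- runif(p, 0.1, 0.5)
  codes <- vapply(q, function(qq) {
    sample(0:2, n, replace = TRUE,
           prob = c((1 - qq)^2, 2 * qq * (1 - qq), qq^2))
  }, integer(n))
  geno_matrix(codes)
}

# a tiny VCF written to a temp file
write_tiny_vcf <- function(gts, path = tempfile(fileext = ".vcf"),
                           alt = rep("T", nrow(gts))) {
  n <- ncol(gts)
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", paste0("clone", seq_len(n))),
                    collapse = "\t"))
  body <- vapply(seq_len(nrow(gts)), function(i) {
    paste(c("1", as.character(i * 100), paste0("snp", i), "A", alt[i], ".",
            "PASS", ".", "GT", gts[i, ]), collapse = "\t")
  }, character(1L))
  writeLines(c(header, body), path)
  path
}

# simulated data set + kernels for REML tests (cached per test run)
small_sim <- local({
  cache <- new.env()
  function(seed = 42, n = 200L, p = 500L, var_a = 50, var_d = 30,
           var_aa = 0, var_e = 36, ddm = 0.5) {
    key <- paste(seed, n, p, var_a, var_d, var_aa, var_e, ddm, sep = "_")
    if (!is.null(cache[[key]])) return(cache[[key]])
    cfg <- sim_config(n_clones = n, n_snps = p, var_a = var_a, var_d = var_d,
                      var_aa = var_aa,
                      n_epistatic_pairs = if (var_aa > 0) 500L else 0L,
                      var_e = var_e, directional_dominance_mean = ddm,
                      missing_rate = 0, seed = seed)
    g <- simulate_genotypes(cfg)
    sim <- simulate_phenotypes(g, cfg)
    kset <- build_kernel_set(g)
    out <- list(cfg = cfg, g = g, ph = sim$phenotypes, truth = sim$truth,
                kset = kset)
    cache[[key]] <- out
    out
  }
})

# subset a pheno_table to a clone set
ph_subset <- function(ph, clones) {
  df <- as.data.frame(ph)
  pheno_table(df[df$clone %in% clones, , drop = FALSE])
}
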