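#' Run the full genomic-prediction pipeline from a configuration
#'
#' Wires the stages end to end: simulate (optional) or read genotypes and
#' phenotypes, QC, kernel construction, REML fits for the requested model
#' labels, forward-prediction scenario, per-region accuracy, and artifact
#' persistence with a manifest.  The configuration is a named list or a
#' YAML file with (all optional unless noted):
#' \describe{
#'   \item{genotypes / phenotypes}{input paths (matrix_tsv and CSV); if
#'     absent, \code{simulate} must name a preset scale.}
#'   \item{simulate}{list(scale, trait) for \code{\link{sim_preset}}.}
#'   \item{qc}{list(maf_min, locus_call_min, clone_call_min).}
#'   \item{models}{model labels, default c("A", "ADEH").}
#'   \item{trait}{trait column (required for real inputs).}
#'   \item{scenario}{list(train_years, test_year); omitted = no accuracy
#'     stage.}
#'   \item{out_dir}{output directory (required).}
#'   \item{seed}{integer seed recorded in every output header.}
#' }
#' Every output file begins with comment lines carrying the package
#' version, the configuration hash and the seed.
#'
#' @param config named list or path to a YAML file.
#' @param dry_run if TRUE, print the planned stages and return them
#'   without computing.
#' @return invisibly, a manifest data.frame (file, md5) plus the fitted
#'   objects in attribute \code{results}.
#' @export
run_pipeline <- function(config, dry_run = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  cfg_hash <- substr(digest_config(config[setdiff(names(config),
                                                  "out_dir")]), 1L, 12L)
  models <- if (is.null(config$models)) c("A", "ADEH") else config$models
  lapply(models, model_spec)  # validate labels early

  plan <- c(
    if (!is.null(config$simulate)) "simulate" else "read",
    "qc", "kernels", paste0("fit:", models),
    if (!is.null(config$scenario)) "evaluate")
  if (dry_run) {
    message("pipeline plan: ", paste(plan, collapse = " -> "))
    return(invisible(plan))
  }
  if (is.null(config$simulate)) {
    for (p in c(config$genotypes, config$phenotypes))
      if (!file.exists(p)) stop("input path does not exist: ", p)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  header <- sprintf("# cloneGP %s | config %s | seed %d",
                    as.character(utils::packageVersion("cloneGP")),
                    cfg_hash, seed)
  stamp <- function(path) {
    txt <- readLines(path)
    writeLines(c(header, txt), path)
    path
  }
  files <- character(0)
  emit <- function(writer, obj, name) {
    path <- file.path(config$out_dir, name)
    writer(obj, path)
    files <<- c(files, stamp(path))
  }

  trait <- config$trait
  if (!is.null(config$simulate)) {
    scfg <- sim_preset(scale = config$simulate$scale %||% "mini",
                       trait = config$simulate$trait %||% "TCH",
                       seed = seed)
    g <- simulate_genotypes(scfg)
    sim <- simulate_phenotypes(g, scfg, trait_name = "trait")
    ph <- sim$phenotypes
    trait <- "trait"
    emit(write_genotypes, g, "genotypes.tsv")
    emit(write_phenotypes, ph, "phenotypes.csv")
    truth_df <- data.frame(clone = names(sim$truth$total),
                           tbv = sim$truth$tbv,
                           dominance = sim$truth$dominance,
                           epistasis = sim$truth$epistasis,
                           total = sim$truth$total)
    emit(function(o, p) utils::write.csv(o, p, row.names = FALSE),
         truth_df, "truth.csv")
  } else {
    g <- read_genotypes(config$genotypes,
                        format = config$format %||% "matrix_tsv")
    ph <- read_phenotypes(config$phenotypes)
    if (is.null(trait)) stop("config$trait is required for real inputs")
  }

  qc_args <- config$qc %||% list()
  qc <- do.call(apply_qc, c(list(g), qc_args))
  emit(write_qc_report, qc$report, "qc_report.tsv")

  need <- unique(unlist(lapply(models, function(m) model_spec(m)$kernels)))
  kset <- build_kernel_set(qc$genotypes, which = need)
  for (nm in need) emit(write_kernel, kset[[nm]], paste0(nm, ".tsv"))

  scen <- NULL
  ph_fit <- ph
  if (!is.null(config$scenario)) {
    scen <- build_scenario(ph, config$scenario$train_years,
                           config$scenario$test_year)
    keep <- as.data.frame(ph)$clone %in% scen$train_clones
    ph_fit <- pheno_table(as.data.frame(ph)[keep, , drop = FALSE])
  }

  fits <- list()
  acc_rows <- list()
  for (m in models) {
    fit <- fit_gblup(ph_fit, kset, trait, model = m)
    fits[[m]] <- fit
    vc <- fit$var_components
    vc$model <- m
    emit(function(o, p) utils::write.csv(o, p, row.names = FALSE),
         vc, paste0("fit_", m, ".csv"))
    if (!is.null(scen)) {
      preds <- predict(fit, what = if (m == "A") "gebv" else "gpcp")
      test_ph <- as.data.frame(ph)[as.data.frame(ph)$clone %in%
                                     scen$test_clones, , drop = FALSE]
      a <- accuracy(preds, pheno_table(test_ph), trait)
      a$model <- m
      acc_rows[[m]] <- a
    }
  }
  if (length(acc_rows)) {
    emit(function(o, p) utils::write.csv(o, p, row.names = FALSE),
         do.call(rbind, acc_rows), "accuracy.csv")
  }

  manifest <- data.frame(file = basename(files),
                         md5 = as.character(tools::md5sum(files)),
                         row.names = NULL)
  utils::write.csv(manifest, file.path(config$out_dir, "manifest.csv"),
                   row.names = FALSE)
  attr(manifest, "results") <- list(fits = fits, scenario = scen,
                                    qc = qc$report)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stable hash of a configuration list
#' @param config named list.
#' @return md5 hex string of the deparsed, name-sorted configuration.
#' @keywords internal
digest_config <- function(config) {
  canon <- function(x) {
    if (is.list(x)) {
      if (!is.null(names(x))) x <- x[order(names(x))]
      lapply(x, canon)
    } else x
  }
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(canon(config)), tmp)
  as.character(tools::md5sum(tmp))
}
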