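#' Build a forward-prediction scenario
#'
#' Emulates deployment in a breeding program: train on clones from earlier
#' series-years, predict clones first appearing in the test year.  A clone
#' with records in both the training years and the test year is removed
#' from the training side (no overlap between reference and validation
#' sets).
#'
#' @param ph a \code{pheno_table}.
#' @param train_years integer vector of training series-years.
#' @param test_year single test year.
#' @param name scenario label.
#' @return list of class \code{gp_scenario} with \code{train_clones},
#'   \code{test_clones}, \code{train_records}, \code{test_records}.
#' @export
build_scenario <- function(ph, train_years, test_year, name = NULL) {
  df <- as.data.frame(ph)
  if (!test_year %in% df$year) stop("test year absent from the table")
  test_clones <- unique(df$clone[df$year == test_year])
  if (!length(test_clones)) stop("empty test set for year ", test_year)
  # overlap rule: a clone recorded in both periods is evaluated, never
  # trained on, so reference and validation sets stay disjoint
  seen_train <- unique(df$clone[df$year %in% train_years])
  overlap <- intersect(seen_train, test_clones)
  train_clones <- setdiff(seen_train, test_clones)
  if (!length(train_clones)) stop("empty training set")
  structure(list(
    name = if (is.null(name))
      sprintf("train%s_test%d", paste(range(train_years), collapse = "-"),
              test_year) else name,
    train_years = sort(unique(train_years)), test_year = test_year,
    train_clones = train_clones, test_clones = test_clones,
    n_overlap_removed = length(overlap),
    train_records = which(df$year %in% train_years &
                            df$clone %in% train_clones),
    test_records = which(df$year == test_year & df$clone %in% test_clones)),
    class = "gp_scenario")
}

#' @export
print.gp_scenario <- function(x, ...) {
  cat(sprintf("scenario %s: %d training clones (%s), %d test clones (%d); %d overlapping removed\n",
              x$name, length(x$train_clones),
              paste(x$train_years, collapse = ","), length(x$test_clones),
              x$test_year, x$n_overlap_removed))
  invisible(x)
}

#' Prediction accuracy as Pearson correlation, by region
#'
#' r between clone-level genomic predictions and the (per-clone mean)
#' adjusted phenotypes, per region and averaged (unweighted) across
#' regions; the standard error of each correlation is
#' sqrt((1 - r^2) / (n - 2)).  A clone with test records in several regions
#' is evaluated within each.  Strata with fewer than 3 clones, or
#' zero-variance predictions, yield NA with a warning.
#'
#' @param preds named numeric vector of clone-level predictions.
#' @param ph a \code{pheno_table} restricted to the records to score (e.g.
#'   \code{ph[scenario$test_records, ]}).
#' @param trait trait name.
#' @param by_region also compute per-region correlations (default TRUE).
#' @return data.frame with columns region ("overall" row = unweighted mean
#'   of per-region r), n, r, se.
#' @export
accuracy <- function(preds, ph, trait, by_region = TRUE) {
  cm <- clone_means(pheno_table(as.data.frame(ph)), trait,
                    by_region = by_region)
  one <- function(sub, label) {
    n <- nrow(sub)
    p <- preds[sub$clone]
    if (n < 3L || anyNA(p)) {
      warning("stratum ", label, ": fewer than 3 scored clones or missing predictions")
      return(data.frame(region = label, n = n, r = NA_real_, se = NA_real_))
    }
    if (stats::sd(p) == 0 || stats::sd(sub$value) == 0) {
      warning("stratum ", label, ": zero variance, correlation undefined")
      return(data.frame(region = label, n = n, r = NA_real_, se = NA_real_))
    }
    r <- stats::cor(p, sub$value)
    data.frame(region = label, n = n, r = r,
               se = sqrt((1 - r^2) / (n - 2)))
  }
  if (by_region) {
    parts <- do.call(rbind, lapply(split(cm, cm$region),
                                   function(s) one(s, s$region[1L])))
    rbar <- mean(parts$r, na.rm = TRUE)
    overall <- data.frame(region = "overall", n = sum(parts$n),
                          r = rbar, se = NA_real_)
    out <- rbind(parts, overall)
  } else {
    out <- one(cm, "overall")
  }
  rownames(out) <- NULL
  out
}

#' Relative improvement in accuracy, integer percent
#'
#' round((r_new / r_base - 1) * 100), rounded half away from zero, the
#' granularity at which accuracy gains are usually reported.
#'
#' @param r_new,r_base accuracies; \code{r_base} must be positive.
#' @return integer percent.
#' @export
relative_improvement <- function(r_new, r_base) {
  if (any(r_base <= 0)) stop("baseline accuracy must be positive")
  x <- (r_new / r_base - 1) * 100
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Mean top-fraction genomic relationship between two clone sets
#'
#' Connectedness diagnostic: for each validation clone, average its largest
#' floor(fraction * |ref|) relationships (at least one) to the reference
#' set, then average over validation clones.  With fraction = 0.1 this is the
#' "average top 10% genomic relationship" measure of reference-validation
#' connectedness.
#'
#' @param G a \code{kernel_matrix} (typically G_A).
#' @param ref,valid disjoint clone-id sets present in \code{G}.
#' @param fraction in (0, 1].
#' @return scalar mean relationship.
#' @export
top_fraction_relatedness <- function(G, ref, valid, fraction = 0.1) {
  stopifnot(fraction > 0, fraction <= 1)
  if (!length(ref) || !length(valid)) stop("empty clone set")
  if (length(intersect(ref, valid))) stop("ref and valid sets must be disjoint")
  ri <- match(ref, rownames(G)); vi <- match(valid, rownames(G))
  if (anyNA(ri) || anyNA(vi)) stop("clones missing from the kernel")
  k <- max(1L, floor(fraction * length(ri)))
  block <- unclass(G)[vi, ri, drop = FALSE]
  mean(apply(block, 1L, function(x) mean(sort(x, decreasing = TRUE)[seq_len(k)])))
}
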