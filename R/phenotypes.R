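#' Phenotype table of spatially adjusted clone values
#'
#' One record per clone x year x crop x region x trial, with one column per
#' trait.  Values are assumed to be stage-one adjusted phenotypes (clone
#' BLUPs corrected for within-trial spatial effects); this package performs
#' only the second-stage genomic analysis on them.
#'
#' @param df data.frame with columns \code{clone}, \code{year},
#'   \code{crop}, \code{region}, \code{trial} and at least one trait column.
#' @return a \code{pheno_table} (a data.frame subclass).
#' @export
pheno_table <- function(df) {
  required <- c("clone", "year", "crop", "region", "trial")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  traits <- setdiff(names(df), required)
  if (!length(traits)) stop("no trait columns found")
  df$clone <- as.character(df$clone)
  df$year <- as.integer(df$year)
  df$crop <- as.character(df$crop)
  df$region <- as.character(df$region)
  df$trial <- as.character(df$trial)
  key <- do.call(paste, c(df[required], sep = "\r"))
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), required, drop = FALSE][1L, ]
    stop(sprintf("duplicate record key: clone=%s year=%d crop=%s region=%s trial=%s",
                 d$clone, d$year, d$crop, d$region, d$trial))
  }
  structure(df, traits = traits, class = c("pheno_table", "data.frame"))
}

#' Read a phenotype CSV
#'
#' Expects a header \code{clone,year,crop,region,trial,<trait...>}.  Rows
#' with an empty trait cell are retained and excluded per-trait downstream.
#'
#' @param path file path.
#' @return a \code{pheno_table}.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  pheno_table(df)
}

#' Write a phenotype table as CSV
#' @param ph a \code{pheno_table}.
#' @param path output file path.
#' @export
write_phenotypes <- function(ph, path) {
  utils::write.csv(as.data.frame(ph), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Trait names of a phenotype table
#' @param ph a \code{pheno_table}.
#' @export
trait_names <- function(ph) attr(ph, "traits")

#' Per-clone mean phenotype for one trait
#'
#' Averages a clone's records (over years, crops and trials), optionally
#' within region.  Used when correlating clone-level genomic predictions
#' with multi-record adjusted phenotypes.
#'
#' @param ph a \code{pheno_table}.
#' @param trait trait name.
#' @param by_region if TRUE, return means per (clone, region).
#' @return data.frame with columns \code{clone}, optionally \code{region},
#'   and \code{value}.
#' @export
clone_means <- function(ph, trait, by_region = FALSE) {
  if (!trait %in% trait_names(ph)) stop("unknown trait: ", trait)
  df <- as.data.frame(ph)
  df <- df[!is.na(df[[trait]]), , drop = FALSE]
  if (by_region) {
    agg <- stats::aggregate(df[[trait]],
                            by = list(clone = df$clone, region = df$region),
                            FUN = mean)
    names(agg)[3L] <- "value"
  } else {
    agg <- stats::aggregate(df[[trait]], by = list(clone = df$clone),
                            FUN = mean)
    names(agg)[2L] <- "value"
  }
  agg
}
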