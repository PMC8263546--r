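#' NOIA additive coefficients for one locus
#'
#' Under the natural and orthogonal interactions (NOIA) parameterization the
#' additive incidence value assigned to each genotype class is a function of
#' the observed genotype frequencies, not of Hardy-Weinberg allele
#' frequencies, so additive and dominance effects stay orthogonal in
#' populations that depart from HWE:
#' h_AA = -(-p_Aa - 2 p_aa), h_Aa = -(1 - p_Aa - 2 p_aa),
#' h_aa = -(2 - p_Aa - 2 p_aa).  The frequency-weighted mean of the three
#' coefficients is zero for any frequency triple.
#'
#' @param freqs numeric matrix (or length-3 vector) of genotype frequencies
#'   with columns p_AA, p_Aa, p_aa.
#' @return matrix with columns \code{h_AA}, \code{h_Aa}, \code{h_aa}.
#' @export
noia_additive_coeffs <- function(freqs) {
  freqs <- rbind(freqs)
  p_Aa <- freqs[, 2L]; p_aa <- freqs[, 3L]
  mu <- p_Aa + 2 * p_aa          # mean genotype code at the locus
  cbind(h_AA = mu, h_Aa = mu - 1, h_aa = mu - 2)
}

#' NOIA dominance coefficients for one locus
#'
#' With D = p_AA + p_aa - (p_AA - p_aa)^2 the dominance incidence values
#' are h_AA = -2 p_Aa p_aa / D, h_Aa = 4 p_AA p_aa / D,
#' h_aa = -2 p_AA p_Aa / D.  Loci with D = 0 (no homozygotes, or
#' monomorphic) carry no dominance contrast: their coefficients are set to
#' zero and flagged rather than raising an error, so matrix shapes stay
#' stable.
#'
#' @inheritParams noia_additive_coeffs
#' @return matrix with columns \code{h_AA}, \code{h_Aa}, \code{h_aa} and
#'   attribute \code{degenerate} (logical vector marking D = 0 loci).
#' @export
noia_dominance_coeffs <- function(freqs) {
  freqs <- rbind(freqs)
  p_AA <- freqs[, 1L]; p_Aa <- freqs[, 2L]; p_aa <- freqs[, 3L]
  D <- p_AA + p_aa - (p_AA - p_aa)^2
  degen <- !is.finite(D) | abs(D) < 1e-12
  Ds <- ifelse(degen, 1, D)
  out <- cbind(h_AA = -2 * p_Aa * p_aa / Ds,
               h_Aa =  4 * p_AA * p_aa / Ds,
               h_aa = -2 * p_AA * p_Aa / Ds)
  out[degen, ] <- 0
  attr(out, "degenerate") <- degen
  out
}

#' NOIA incidence matrix (H_A or H_D)
#'
#' Maps each clone's 0/1/2 code at each locus to the NOIA additive or
#' dominance coefficient for that genotype class.  Missing calls are
#' mean-imputed first; an imputed (fractional) code x is mapped by linear
#' interpolation between the class coefficients, which preserves the zero
#' frequency-weighted column means in expectation.  Monomorphic (additive)
#' and D = 0 (dominance) loci yield all-zero columns.
#'
#' @param g a \code{geno_matrix}.
#' @param kind \code{"additive"} or \code{"dominance"}.
#' @param freqs optional genotype-frequency matrix to use instead of
#'   \code{g$freqs} (e.g. frequencies computed on a larger analysis set).
#' @return numeric matrix [n_clones x n_snps] with attributes \code{kind}
#'   and \code{source_freqs}.
#' @export
noia_incidence <- function(g, kind = c("additive", "dominance"),
                           freqs = NULL) {
  kind <- match.arg(kind)
  if (is.null(freqs)) freqs <- g$freqs
  x <- impute_codes(g)
  cf <- if (kind == "additive") noia_additive_coeffs(freqs)
        else noia_dominance_coeffs(freqs)
  n <- nrow(x); p <- ncol(x)
  # value at code x in [0,2]: piecewise-linear through (0,h_AA),(1,h_Aa),(2,h_aa)
  h0 <- rep(cf[, 1L], each = n)
  h1 <- rep(cf[, 2L], each = n)
  h2 <- rep(cf[, 3L], each = n)
  w <- as.vector(x)
  lo <- pmin(pmax(w, 0), 1)
  hi <- pmin(pmax(w - 1, 0), 1)
  H <- matrix(h0 * (1 - lo) + h1 * (lo - hi) + h2 * hi, nrow = n)
  dimnames(H) <- dimnames(x)
  structure(H, kind = kind, source_freqs = freqs)
}

#' Kernel (relationship) matrix constructor
#'
#' @param values symmetric numeric matrix.
#' @param name kernel name (e.g. "G_A", "G_D", "G_AA", "K_gauss").
#' @param bandwidth Gaussian bandwidth, if applicable.
#' @param psd_check verify symmetry and positive semi-definiteness; small
#'   negative eigenvalues (below -1e-8 times the largest) trigger a
#'   diagonal jitter of 1e-6, reported via a message.
#' @return matrix of class \code{kernel_matrix} with attributes \code{name}
#'   and \code{bandwidth}.
#' @export
kernel_matrix <- function(values, name = "K", bandwidth = NULL,
                          psd_check = TRUE) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("kernel must be square")
  if (max(abs(values - t(values))) > 1e-10) stop("kernel must be symmetric")
  values <- (values + t(values)) / 2
  if (psd_check) {
    ev <- eigen(values, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev))) {
      message(sprintf("kernel %s: smallest eigenvalue %.3g; adding 1e-6 jitter",
                      name, min(ev)))
      diag(values) <- diag(values) + 1e-6
    }
  }
  structure(values, name = name, bandwidth = bandwidth,
            class = c("kernel_matrix", "matrix"))
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat(sprintf("kernel_matrix %s: %d x %d, mean diagonal %.4f\n",
              attr(x, "name"), nrow(x), ncol(x), mean(diag(x))))
  invisible(x)
}

#' Trace-normalized genomic relationship matrix from an incidence matrix
#'
#' G = H H' / (tr(H H') / n), so the diagonal averages exactly 1 and the
#' attached variance component is on the scale of the genetic variance in
#' the analysed population.
#'
#' @param H incidence matrix from \code{\link{noia_incidence}}.
#' @param name kernel name (defaults to G_A or G_D by the incidence kind).
#' @return a \code{kernel_matrix}.
#' @export
build_grm <- function(H, name = NULL) {
  if (is.null(name)) {
    kind <- attr(H, "kind")
    name <- if (identical(kind, "dominance")) "G_D" else "G_A"
  }
  HH <- tcrossprod(H)
  tr <- sum(diag(HH))
  if (tr <= 0) stop("degenerate incidence matrix (all columns zero)")
  G <- HH / (tr / nrow(HH))
  kernel_matrix(G, name = name, psd_check = FALSE)  # H H' is PSD by construction
}

#' Hadamard-product epistatic kernel
#'
#' The pairwise epistatic covariance of order (a, b) is approximated by the
#' elementwise product of the corresponding relationship matrices
#' (G_AA = G_A * G_A etc., assuming linkage equilibrium), rescaled so the
#' diagonal averages 1.  Composable for higher orders.
#'
#' @param Ga,Gb \code{kernel_matrix} objects with identical clone order.
#' @param name kernel name (default concatenates the inputs).
#' @return a \code{kernel_matrix}.
#' @export
hadamard_kernel <- function(Ga, Gb, name = NULL) {
  if (!identical(dim(Ga), dim(Gb)) ||
      !identical(rownames(Ga), rownames(Gb)))
    stop("kernels must share dimension and clone order")
  if (is.null(name))
    name <- paste0(attr(Ga, "name"), "*", attr(Gb, "name"))
  P <- unclass(Ga) * unclass(Gb)
  md <- mean(diag(P))
  if (md <= 0) stop("degenerate Hadamard product")
  kernel_matrix(P / md, name = name, psd_check = FALSE)  # Schur product of PSDs
}

#' Average genome-wide heterozygosity per clone
#'
#' Het_k = (sum_l h_kl) / (sum_l 2 p_l q_l), where h_kl is the dominance
#' incidence value of clone k at locus l and p_l, q_l are the reference and
#' alternate allele frequencies.  Under HWE a fully heterozygous clone has
#' Het = 1.  Loci with a degenerate dominance contrast (D = 0) contribute
#' zero to both numerator and denominator.  Fitted as a fixed regression
#' covariate, Het captures directional dominance (inbreeding depression /
#' heterosis).
#'
#' @param g a \code{geno_matrix}.
#' @param Hd optional dominance incidence matrix (built from \code{g} if
#'   absent).
#' @param freqs optional genotype frequencies (as in
#'   \code{\link{noia_incidence}}).
#' @return numeric vector of Het values named by clone, with attributes
#'   \code{normalizer} and \code{centered} (Het minus its mean).
#' @export
heterozygosity <- function(g, Hd = NULL, freqs = NULL) {
  if (is.null(freqs)) freqs <- g$freqs
  if (is.null(Hd)) Hd <- noia_incidence(g, "dominance", freqs = freqs)
  degen <- attr(noia_dominance_coeffs(freqs), "degenerate")
  p_ref <- freqs[, "p_AA"] + freqs[, "p_Aa"] / 2
  q_alt <- 1 - p_ref
  w <- 2 * p_ref * q_alt
  w[degen] <- 0
  norm <- sum(w)
  if (norm <= 0) stop("heterozygosity normalizer is zero (all loci degenerate)")
  het <- rowSums(Hd) / norm
  names(het) <- g$clone_ids
  attr(het, "normalizer") <- norm
  attr(het, "centered") <- het - mean(het)
  het
}

#' Gaussian kernel over marker vectors
#'
#' K(x_i, x_j) = exp(-h * sum_k (x_ik - x_jk)^2 / p), computed on the raw
#' (mean-imputed) 0/1/2 codes; p is the marker count and h the bandwidth
#' controlling the decay of similarity with squared Euclidean distance.
#' h = 0 yields the all-ones matrix.
#'
#' @param g a \code{geno_matrix}.
#' @param h bandwidth (>= 0).
#' @return a \code{kernel_matrix} named \code{K_gauss} with the bandwidth
#'   attribute set; entries in (0, 1], unit diagonal.
#' @export
gaussian_kernel <- function(g, h) {
  stopifnot(h >= 0)
  x <- impute_codes(g)
  p <- ncol(x)
  sq <- rowSums(x^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(x)
  d2[d2 < 0] <- 0
  K <- exp(-h * d2 / p)
  diag(K) <- 1
  dimnames(K) <- list(g$clone_ids, g$clone_ids)
  kernel_matrix(K, name = "K_gauss", bandwidth = h, psd_check = FALSE)
}

#' Build the standard kernel set for the nested GBLUP models
#'
#' Computes G_A and G_D from NOIA incidence matrices and the Hadamard
#' kernels G_AA (and optionally G_AD, G_DD), plus the heterozygosity
#' covariate, in one pass.
#'
#' @param g a \code{geno_matrix} covering the full analysis set (training
#'   plus prediction clones), so genotype frequencies are computed once on
#'   everybody.
#' @param which kernel names to build, subset of
#'   c("G_A", "G_D", "G_AA", "G_AD", "G_DD").
#' @return list of \code{kernel_matrix} objects plus element \code{het}.
#' @export
build_kernel_set <- function(g, which = c("G_A", "G_D", "G_AA")) {
  which <- match.arg(which, c("G_A", "G_D", "G_AA", "G_AD", "G_DD"),
                     several.ok = TRUE)
  Ha <- noia_incidence(g, "additive")
  Hd <- noia_incidence(g, "dominance")
  GA <- build_grm(Ha, "G_A")
  GD <- build_grm(Hd, "G_D")
  out <- list()
  if ("G_A" %in% which) out$G_A <- GA
  if ("G_D" %in% which) out$G_D <- GD
  if ("G_AA" %in% which) out$G_AA <- hadamard_kernel(GA, GA, "G_AA")
  if ("G_AD" %in% which) out$G_AD <- hadamard_kernel(GA, GD, "G_AD")
  if ("G_DD" %in% which) out$G_DD <- hadamard_kernel(GD, GD, "G_DD")
  out$het <- heterozygosity(g, Hd = Hd)
  out
}

#' Write / read a kernel matrix as tab-separated text
#'
#' Full square storage with a clone-id header row and first column, so
#' fixtures stay human-diffable.
#'
#' @param K a \code{kernel_matrix}.
#' @param path file path.
#' @export
write_kernel <- function(K, path) {
  tab <- data.frame(clone = rownames(K), unclass(K), check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kernel
#' @param name kernel name to attach on read.
#' @export
read_kernel <- function(path, name = "K") {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- as.character(tab[[1L]])
  kernel_matrix(m, name = name, psd_check = FALSE)
}
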