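#' Model labels for the nested GBLUP series
#'
#' The six standard models: A (additive), AD (+ dominance), ADE
#' (+ additive-by-additive epistasis), and their H variants, which add the
#' centred genome-wide heterozygosity covariate as a fixed regression.
#'
#' @param label one of "A", "AH", "AD", "ADH", "ADE", "ADEH".
#' @return list with \code{kernels} (kernel names) and \code{include_het}.
#' @export
model_spec <- function(label = c("A", "AH", "AD", "ADH", "ADE", "ADEH")) {
  label <- match.arg(label)
  base <- sub("H$", "", label)
  kernels <- switch(base,
                    A = "G_A",
                    AD = c("G_A", "G_D"),
                    ADE = c("G_A", "G_D", "G_AA"))
  list(label = label, kernels = kernels,
       include_het = grepl("H$", label))
}

#' Build the response and fixed-effect design for the second-stage model
#'
#' The second-stage model is
#' y = mean + Year + Crop + Region + Trial (+ b(Het - mean Het)) + Clone + e,
#' all terms except Clone fixed, no interactions.  Factors use treatment
#' coding with the first level as reference; factors with a single observed
#' level are dropped with a warning.  Multiple records of a clone share one
#' genetic effect (repeatability-style design).
#'
#' @param ph a \code{pheno_table}.
#' @param trait trait name.
#' @param het optional named heterozygosity vector (from
#'   \code{\link{heterozygosity}}); when supplied, its centred value is
#'   appended as covariate column \code{het_c}.
#' @param factors fixed factors to include, in order.
#' @param drop_aliased trial codes are nested within region and year, so a
#'   treatment-coded main-effects design is rank-deficient by construction;
#'   by default the aliased columns are dropped (QR pivoting, as standard
#'   mixed-model software does), with a warning naming them.  Set to FALSE
#'   to raise an error instead.
#' @return list with \code{y}, \code{X}, \code{clone} (character vector of
#'   record-level clone ids) and \code{records} (row index into \code{ph}).
#' @export
build_design <- function(ph, trait, het = NULL,
                         factors = c("year", "crop", "region", "trial"),
                         drop_aliased = TRUE) {
  df <- as.data.frame(ph)
  keep <- !is.na(df[[trait]])
  df <- df[keep, , drop = FALSE]
  if (!nrow(df)) stop("no non-missing records for trait ", trait)
  terms <- character(0)
  for (f in factors) {
    v <- factor(df[[f]])
    if (nlevels(v) < 2L) {
      warning("factor '", f, "' has a single level and was dropped")
    } else {
      df[[f]] <- v
      terms <- c(terms, f)
    }
  }
  fml <- if (length(terms))
    stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  else stats::as.formula("~ 1")
  X <- stats::model.matrix(fml, df)
  het_center <- NULL
  if (!is.null(het)) {
    miss <- setdiff(unique(df$clone), names(het))
    if (length(miss))
      stop("clones without heterozygosity values: ",
           paste(utils::head(miss, 3L), collapse = ", "))
    het_center <- mean(het[df$clone])
    X <- cbind(X, het_c = as.numeric(het[df$clone] - het_center))
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    if (!drop_aliased)
      stop("rank-deficient fixed design; aliased columns: ",
           paste(aliased, collapse = ", "))
    warning("dropping ", length(aliased),
            " aliased fixed-design column(s): ",
            paste(utils::head(aliased, 5L), collapse = ", "),
            if (length(aliased) > 5L) ", ..." else "")
    X <- X[, setdiff(colnames(X), aliased), drop = FALSE]
  }
  list(y = df[[trait]], X = X, clone = df$clone, records = which(keep),
       het_center = het_center)
}

# Apply P = V^-1 - V^-1 X (X'V^-1 X)^-1 X' V^-1 given precomputed pieces.
# All heavy algebra lives in clone space (q x q) via the Woodbury identity
# on V = Z K Z' + sigma_e I, with K = sum_k sigma2_k G_k over phenotyped
# clones and Z the record-to-clone indicator, so the per-iteration cost is
# O(q^3) regardless of the record count.

#' REML fit of a multi-kernel clonal mixed model
#'
#' Average-information (AI) REML with expectation-maximization startup
#' steps.  Variance components are initialized at var(y)/(k+1) split
#' equally; the first \code{n_em} iterations use EM updates, after which AI
#' updates with step-halving are used.  Convergence is declared when the
#' relative change in the restricted log-likelihood falls below \code{tol}.
#' Components driven to the lower bound are pinned at 1e-6 var(y) and
#' flagged as boundary ("~0"); their standard errors are reported as NA.
#'
#' @param y numeric response (one entry per record).
#' @param X fixed-effect design matrix (full rank, including intercept).
#' @param clone character vector of clone ids, one per record.
#' @param kernels named list of \code{kernel_matrix} objects over the full
#'   clone set (rownames are clone ids; may include clones without records,
#'   for which BLUPs are produced).
#' @param max_iter,tol,n_em iteration controls.
#' @param verbose print per-iteration log-likelihoods.
#' @return object of class \code{reml_fit}: variance components with SEs
#'   and boundary flags, fixed effects with SEs, REML log-likelihood,
#'   per-clone BLUPs per kernel, \code{gebv} (additive BLUP), \code{gpcp}
#'   (sum of genetic BLUPs), convergence information, and heritabilities.
#' @export
reml_fit <- function(y, X, clone, kernels, max_iter = 200L, tol = 1e-8,
                     n_em = 3L, verbose = FALSE) {
  n <- length(y)
  stopifnot(length(clone) == n, nrow(X) == n)
  if (n < ncol(X) + 2L) stop("too few records for the fixed design")
  knames <- names(kernels)
  if (is.null(knames) || any(!nzchar(knames)))
    stop("kernels must be a named list")
  if (is.null(colnames(X)))
    colnames(X) <- paste0("X", seq_len(ncol(X)))
  all_ids <- rownames(kernels[[1L]])
  for (K in kernels) {
    if (!identical(rownames(K), all_ids))
      stop("kernels must share clone order")
  }
  miss <- setdiff(unique(clone), all_ids)
  if (length(miss))
    stop("records reference clones absent from the kernels: ",
         paste(utils::head(miss, 3L), collapse = ", "))

  tid <- sort(match(unique(clone), all_ids))      # phenotyped clones
  q <- length(tid)
  ci <- match(match(clone, all_ids), tid)         # record -> 1..q
  d <- tabulate(ci, nbins = q)                    # records per clone
  Gt <- lapply(kernels, function(K) unclass(K)[tid, tid, drop = FALSE])
  p <- ncol(X)
  vy <- stats::var(y)
  lb <- 1e-6 * vy
  nk <- length(kernels)
  theta <- rep(vy / (nk + 1), nk + 1)             # genetic comps then residual
  names(theta) <- c(knames, "residual")

  # aggregate record-level vectors/matrices to clone level: t(Z) %*% A
  Zt <- function(A) {
    out <- rowsum(as.matrix(A), ci, reorder = TRUE)
    rownames(out) <- NULL
    out
  }

  eval_state <- function(theta) {
    se2 <- unname(theta[nk + 1L])
    K <- matrix(0, q, q)
    for (k in seq_len(nk)) K <- K + theta[k] * Gt[[k]]
    # factor K = R'R and apply the Woodbury identity through R, never K^-1:
    # V^-1 = (I - Z R' (se2 I + R M R')^-1 R Z') / se2 with M = Z'Z (diag).
    # This stays accurate when K is ill-conditioned (e.g. pinned components).
    R <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(R)) {
      diag(K) <- diag(K) + 1e-8 * mean(diag(K))
      R <- tryCatch(chol(K), error = function(e) NULL)
      if (is.null(R)) return(NULL)
    }
    B <- se2 * diag(q) + R %*% (d * t(R))
    Bch <- tryCatch(chol((B + t(B)) / 2), error = function(e) NULL)
    if (is.null(Bch)) return(NULL)
    C <- crossprod(R, chol2inv(Bch) %*% R)
    Vinv <- function(A) {
      ZtA <- Zt(A)
      (A - (C %*% ZtA)[ci, , drop = FALSE]) / se2
    }
    ViX <- Vinv(X)
    Viy <- Vinv(matrix(y, ncol = 1L))
    XtViX <- crossprod(X, ViX)
    Xch <- chol((XtViX + t(XtViX)) / 2)
    beta <- backsolve(Xch, forwardsolve(t(Xch), crossprod(ViX, y)))
    Py <- Viy - ViX %*% backsolve(Xch, forwardsolve(t(Xch), crossprod(X, Viy)))
    logdetV <- (n - q) * log(se2) + 2 * sum(log(diag(Bch)))
    logdetX <- 2 * sum(log(diag(Xch)))
    yPy <- sum(y * Py)
    ll <- -0.5 * (logdetV + logdetX + yPy + (n - p) * log(2 * pi))
    list(se2 = se2, C = C, ViX = ViX, XtViX = XtViX, Xch = Xch,
         beta = beta, Py = Py, ll = ll)
  }

  derivs <- function(st, theta) {
    se2 <- st$se2
    ZtPy <- Zt(st$Py)                              # q-vector
    SX <- Zt(st$ViX)                               # q x p, = Z'V^-1 X
    A_inv_SXt <- backsolve(st$Xch, forwardsolve(t(st$Xch), t(SX)))
    T1 <- t(SX %*% A_inv_SXt)                      # q x q (symmetric)
    Q <- (-(st$C * outer(d, d))) / se2
    diag(Q) <- diag(Q) + d / se2                   # Z'V^-1 Z
    trP <- numeric(nk + 1L)
    qf <- numeric(nk + 1L)
    for (k in seq_len(nk)) {
      trP[k] <- sum(Gt[[k]] * (Q - T1))
      qf[k] <- as.numeric(crossprod(ZtPy, Gt[[k]] %*% ZtPy))
    }
    trVinv <- (n - sum(diag(st$C) * d)) / se2
    XtV2X <- crossprod(st$ViX)
    trP[nk + 1L] <- trVinv -
      sum(diag(backsolve(st$Xch, forwardsolve(t(st$Xch), XtV2X))))
    qf[nk + 1L] <- sum(st$Py^2)
    score <- -0.5 * (trP - qf)
    list(score = score, trP = trP, qf = qf, ZtPy = ZtPy)
  }

  ai_matrix <- function(st, dv) {
    # f_k = dV_k P y; AI_ij = 0.5 f_i' P f_j
    fs <- vector("list", nk + 1L)
    for (k in seq_len(nk))
      fs[[k]] <- (Gt[[k]] %*% dv$ZtPy)[ci, , drop = FALSE]
    fs[[nk + 1L]] <- st$Py
    Fm <- do.call(cbind, fs)
    ZtF <- Zt(Fm)
    ViF <- (Fm - (st$C %*% ZtF)[ci, , drop = FALSE]) / st$se2
    XtViF <- crossprod(X, ViF)
    PF <- ViF - st$ViX %*%
      backsolve(st$Xch, forwardsolve(t(st$Xch), XtViF))
    0.5 * crossprod(Fm, PF)
  }

  st <- eval_state(theta)
  if (is.null(st)) stop("singular V at starting values; check kernels/QC")
  ll_old <- st$ll
  converged <- FALSE
  ai_singular <- FALSE
  AI <- NULL
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    dv <- derivs(st, theta)
    use_em <- iter <= n_em
    theta_new <- NULL
    if (!use_em) {
      AI <- ai_matrix(st, dv)
      free <- theta > lb | dv$score > 0    # pinned components stay pinned
      AIf <- AI[free, free, drop = FALSE]
      ok <- is.finite(rcond(AIf)) && rcond(AIf) > 1e-12
      if (ok) {
        step <- rep(0, nk + 1L)
        step[free] <- solve(AIf, dv$score[free])
        # step-halving until the likelihood does not deteriorate
        for (hf in 0:6) {
          cand <- pmax(theta + step / 2^hf, lb)
          st_c <- eval_state(cand)
          if (!is.null(st_c) && is.finite(st_c$ll) &&
              st_c$ll >= ll_old - 1e-6) {
            theta_new <- cand; st_new <- st_c; break
          }
        }
      } else {
        ai_singular <- TRUE
      }
    }
    if (is.null(theta_new)) {                      # EM update (always safe)
      theta_new <- theta
      for (k in seq_len(nk))
        theta_new[k] <- theta[k] +
          theta[k]^2 * (dv$qf[k] - dv$trP[k]) / q
      theta_new[nk + 1L] <- theta[nk + 1L] +
        theta[nk + 1L]^2 * (dv$qf[nk + 1L] - dv$trP[nk + 1L]) / n
      theta_new <- pmax(theta_new, lb)
      st_new <- eval_state(theta_new)
      if (is.null(st_new)) stop("singular V during REML; add jitter or tighten QC")
    }
    theta <- theta_new
    st <- st_new
    if (verbose)
      message(sprintf("iter %3d logL %.6f  [%s]", iter, st$ll,
                      paste(sprintf("%.4g", theta), collapse = ", ")))
    if (abs(st$ll - ll_old) / (abs(ll_old) + 1) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- st$ll
  }
  if (!converged)
    warning("REML did not converge in ", max_iter, " iterations")

  boundary <- theta <= lb * (1 + 1e-8)
  dv <- derivs(st, theta)
  AI <- ai_matrix(st, dv)
  se_theta <- rep(NA_real_, nk + 1L)
  free <- !boundary
  if (any(free)) {
    AIf <- AI[free, free, drop = FALSE]
    if (is.finite(rcond(AIf)) && rcond(AIf) > 1e-12) {
      se_theta[free] <- sqrt(pmax(diag(solve(AIf)), 0))
    } else {
      ai_singular <- TRUE
    }
  }

  # BLUPs for every clone in the kernels (incl. unphenotyped)
  blups <- matrix(0, length(all_ids), nk,
                  dimnames = list(all_ids, knames))
  for (k in seq_len(nk)) {
    Gcross <- unclass(kernels[[k]])[, tid, drop = FALSE]
    blups[, k] <- theta[k] * (Gcross %*% dv$ZtPy)
  }
  gpcp <- rowSums(blups)
  gebv <- if ("G_A" %in% knames) blups[, "G_A"] else rep(NA_real_, nrow(blups))

  XtViX_inv <- chol2inv(st$Xch)
  beta <- as.numeric(st$beta)
  names(beta) <- colnames(X)
  se_beta <- sqrt(diag(XtViX_inv))
  names(se_beta) <- colnames(X)

  vc <- data.frame(component = names(theta),
                   estimate = as.numeric(theta),
                   se = se_theta,
                   boundary = boundary,
                   row.names = NULL)
  sp2 <- sum(theta)
  fit <- structure(list(
    var_components = vc,
    fixed_effects = data.frame(term = names(beta), estimate = beta,
                               se = se_beta, row.names = NULL),
    loglik = st$ll,
    blups = blups,
    gebv = gebv,
    gpcp = gpcp,
    h2 = unname(if ("G_A" %in% knames) theta["G_A"] / sp2 else NA_real_),
    H2 = unname(sum(theta[seq_len(nk)]) / sp2),
    sigma_p2 = sp2,
    converged = converged,
    n_iter = iter,
    ai_singular = ai_singular,
    n_records = n,
    n_clones = q,
    kernel_names = knames,
    clone_ids = all_ids,
    phenotyped = all_ids[tid]),
    class = "reml_fit")
  fit
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf("REML fit: %d records, %d phenotyped clones, logL = %.3f%s\n",
              x$n_records, x$n_clones, x$loglik,
              if (x$converged) "" else " (NOT converged)"))
  vc <- x$var_components
  est <- ifelse(vc$boundary, "~0",
                sprintf("%.4g (%s)", vc$estimate,
                        ifelse(is.na(vc$se), "NA", sprintf("%.3g", vc$se))))
  cat(paste0("  ", format(vc$component, width = 10), est, collapse = "\n"),
      "\n")
  cat(sprintf("  h2 = %.3f, H2 = %.3f\n", x$h2, x$H2))
  invisible(x)
}

#' Fit one of the nested GBLUP models to a trait
#'
#' High-level wrapper: selects the kernels for the model label, builds the
#' fixed design (with the centred heterozygosity covariate for H models)
#' and runs \code{\link{reml_fit}}.
#'
#' @param ph a \code{pheno_table}.
#' @param kset kernel set from \code{\link{build_kernel_set}} (a named list
#'   of kernels plus element \code{het}).
#' @param trait trait name.
#' @param model model label, see \code{\link{model_spec}}.
#' @param ... passed to \code{\link{reml_fit}}.
#' @return a \code{reml_fit} with elements \code{model} and \code{trait}
#'   added; for H models the heterozygosity coefficient appears in
#'   \code{fixed_effects} as term \code{het_c} and the full centred
#'   covariate is stored in \code{het_centered}.
#' @export
fit_gblup <- function(ph, kset, trait, model = "A", ...) {
  spec <- model_spec(model)
  kernels <- kset[spec$kernels]
  if (any(vapply(kernels, is.null, logical(1L))))
    stop("kernel set lacks: ",
         paste(setdiff(spec$kernels, names(kset)), collapse = ", "))
  het <- if (spec$include_het) kset$het else NULL
  des <- build_design(ph, trait, het = het)
  fit <- reml_fit(des$y, des$X, des$clone, kernels, ...)
  fit$model <- spec$label
  fit$trait <- trait
  if (spec$include_het) {
    fit$het_centered <- kset$het - des$het_center
    fit$het_coefficient <- fit$fixed_effects$estimate[
      fit$fixed_effects$term == "het_c"]
  }
  fit
}

#' Clone-level genomic predictions from a fitted model
#'
#' \code{gebv} is the additive BLUP (breeding value); \code{gpcp} is the
#' total genetic value, the sum of all fitted genetic BLUPs.  For H models
#' the fitted heterozygosity regression b(Het - mean Het) is part of the
#' expected clonal performance and is added to GPCP by default (it carries
#' the directional-dominance signal).
#'
#' @param object a \code{reml_fit}.
#' @param what \code{"gpcp"} or \code{"gebv"}.
#' @param include_het add the heterozygosity regression term to GPCP when
#'   the model fitted one.
#' @param ... unused.
#' @return named numeric vector over all clones in the kernels.
#' @export
predict.reml_fit <- function(object, what = c("gpcp", "gebv"),
                             include_het = TRUE, ...) {
  what <- match.arg(what)
  out <- if (what == "gebv") object$gebv else object$gpcp
  names(out) <- object$clone_ids
  if (what == "gpcp" && include_het && !is.null(object$het_centered)) {
    out <- out + object$het_coefficient *
      object$het_centered[object$clone_ids]
  }
  out
}

#' Narrow- and broad-sense heritability from a fit
#'
#' h2 = sigma2_A / sigma2_P and H2 = (sum of genetic variances) / sigma2_P,
#' with sigma2_P the sum of all genetic components and the residual.
#'
#' @param fit a \code{reml_fit}.
#' @return named vector c(h2, H2).
#' @export
heritabilities <- function(fit) {
  c(h2 = fit$h2, H2 = fit$H2)
}

#' Likelihood-ratio test between nested REML fits
#'
#' stat = 2 (logL_full - logL_reduced), referred to a chi-squared
#' distribution with one degree of freedom at alpha = 0.05.  Applying the
#' plain chi-squared(1) reference to a boundary hypothesis (a variance
#' equal to zero) is conservative; the rejection rate under the null is
#' below the nominal level.
#'
#' @param full,reduced \code{reml_fit} objects on the same data with the
#'   reduced model's kernels a strict subset of the full model's.
#' @return list with \code{stat}, \code{df}, \code{p_value},
#'   \code{significant}.
#' @export
lrt <- function(full, reduced) {
  if (!all(reduced$kernel_names %in% full$kernel_names) ||
      length(reduced$kernel_names) >= length(full$kernel_names))
    stop("models are not nested (reduced kernels must be a strict subset)")
  if (full$n_records != reduced$n_records)
    stop("fits use different data")
  stat <- 2 * (full$loglik - reduced$loglik)
  if (stat < -1e-6)
    warning("negative LRT statistic; check convergence of the full model")
  p <- stats::pchisq(max(stat, 0), df = 1L, lower.tail = FALSE)
  list(stat = stat, df = 1L, p_value = p, significant = p < 0.05)
}

#' LRT statistic from two log-likelihood values
#'
#' Convenience for worked examples on published log-likelihoods.
#' @param loglik_full,loglik_reduced REML log-likelihoods.
#' @return list as in \code{\link{lrt}}.
#' @export
lrt_stat <- function(loglik_full, loglik_reduced) {
  stat <- 2 * (loglik_full - loglik_reduced)
  p <- stats::pchisq(max(stat, 0), df = 1L, lower.tail = FALSE)
  list(stat = stat, df = 1L, p_value = p, significant = p < 0.05)
}
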