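#' Marginal association scan
#'
#' Per SNP, fits the logistic regression
#' \eqn{logit P(y = 1) = \alpha + \beta x_m + \gamma^T Z} by maximum
#' likelihood and reports the Wald two-sided p-value for \eqn{\beta}
#' (observed-information standard error). Monomorphic SNPs and SNPs whose
#' fit fails to converge or yields a non-finite standard error (e.g.
#' complete separation) are reported with `beta = 0`, `p = 1` and
#' `flag = TRUE`; the scan never aborts.
#'
#' @param G a [GenotypeMatrix-class] with no missing entries.
#' @param pheno a [PhenotypeTable-class] aligned to `G`'s samples; its
#'   covariates are adjusted for.
#' @return a [SummaryStats-class] with the target minor allele as effect
#'   allele.
#' @export
marginalScan <- function(G, pheno) {
  x <- genotypes(G)
  if (anyNA(x)) stop("marginalScan requires complete genotypes; see imputeMode()")
  y <- unname(outcome(pheno))
  if (length(unique(y)) < 2L) stop("both outcome classes must be present")
  z <- covariates(pheno)
  m <- ncol(x)
  beta <- se <- numeric(m)
  p <- rep(1, m)
  flag <- logical(m)
  base_design <- cbind(`(Intercept)` = 1, z)
  for (j in seq_len(m)) {
    xm <- x[, j]
    if (length(unique(xm)) < 2L) {
      flag[j] <- TRUE
      next
    }
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(cbind(base_design[, 1, drop = FALSE],
                                            snp = xm,
                                            base_design[, -1, drop = FALSE]),
                                      y, family = stats::binomial())),
      error = function(e) NULL)
    ok <- !is.null(fit) && fit$converged
    if (ok) {
      # observed-information covariance from the weighted design
      w <- fit$weights
      xd <- cbind(base_design[, 1, drop = FALSE], snp = xm,
                  base_design[, -1, drop = FALSE])
      info <- crossprod(xd * sqrt(w))
      v <- tryCatch(solve(info), error = function(e) NULL)
      ok <- !is.null(v) && is.finite(v[2, 2]) && v[2, 2] > 0
    }
    if (!ok) {
      flag[j] <- TRUE
      next
    }
    beta[j] <- fit$coefficients[2]
    se[j] <- sqrt(v[2, 2])
    p[j] <- 2 * pnorm(-abs(beta[j] / se[j]))
    if (p[j] <= 0) p[j] <- .Machine$double.xmin  # keep p in (0, 1]
  }
  if (any(flag)) {
    beta[flag] <- 0
    se[flag] <- NA_real_
    p[flag] <- 1
    warning(sum(flag), " SNP(s) flagged (monomorphic or degenerate fit)")
  }
  v <- variantInfo(G)
  SummaryStats(id = v$id, effect_allele = v$alt, beta = beta, p = p,
               se = se, flag = flag)
}

#' Convert a p-value to an association z-value
#'
#' \eqn{z = |\Phi^{-1}(p/2)|}, the absolute standard-normal quantile of the
#' half p-value.
#'
#' @param p p-values in (0, 1].
#' @return non-negative z-values.
#' @export
pToZ <- function(p) {
  if (any(is.na(p) | p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]")
  abs(qnorm(p / 2))
}

#' Min-max weights from association z-values
#'
#' \eqn{w_m = (z_m - z_{min}) / (z_{max} - z_{min})}, so the strongest
#' association gets weight 1 and the weakest weight `weight_floor`
#' (default 0, meaning the weakest SNP can never be sampled as a split
#' candidate). When all z are equal the weights are uniformly 1.
#'
#' @param z finite non-negative z-values.
#' @param weight_floor lower bound applied to the weights.
#' @return numeric weights in [weight_floor, 1], aligned and named as `z`.
#' @export
zToWeights <- function(z, weight_floor = 0) {
  if (!length(z)) stop("empty z vector")
  if (any(!is.finite(z) | z < 0)) stop("z-values must be finite and >= 0")
  rng <- range(z)
  w <- if (rng[2] > rng[1]) (z - rng[1]) / (rng[2] - rng[1]) else rep(1, length(z))
  pmax(w, weight_floor)
}
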