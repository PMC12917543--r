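#' @include AllClasses.R utils.R
NULL

#' Build a group-contrast design matrix
#'
#' Intercept, group indicator (patient = 1), centred age, sex and site
#' dummies (nuisance regressors of no interest), with the contrast selecting
#' the group column.
#'
#' @param covariates data.frame with columns group ("patient"/"control"),
#'   age, sex, site.
#' @return list with \code{X} (design matrix), \code{contrastIndex} (group
#'   column), \code{nuisanceIndex} (all other columns).
#' @export
buildDesign <- function(covariates) {
  grp <- as.numeric(covariates$group == "patient")
  X <- cbind(intercept = 1, group = grp,
             age = covariates$age - mean(covariates$age),
             sex = covariates$sex)
  sites <- sort(unique(covariates$site))
  if (length(sites) > 1L)
    for (s in sites[-1L])
      X <- cbind(X, as.numeric(covariates$site == s))
  if (qr(X)$rank < ncol(X)) stop("invalid design: rank-deficient design matrix")
  list(X = X, contrastIndex = 2L, nuisanceIndex = setdiff(seq_len(ncol(X)), 2L))
}

# t statistics of the group column for (possibly permuted) response matrix Y
# (subjects x units), given precomputed pieces of the full design.
glmTStats <- function(Y, fit) {
  B <- fit$pinv %*% Y                           # coefficients
  R <- Y - fit$X %*% B
  sigma2 <- colSums(R^2) / fit$df
  tt <- B[fit$ci, ] / sqrt(pmax(sigma2 * fit$cgg, 1e-300))
  # perfectly fitted (e.g. constant) responses have no error variance; the
  # contrast is then exactly zero rather than roundoff over roundoff
  degenerate <- sigma2 <= 1e-24 * pmax(colMeans(Y^2), 1e-300)
  tt[degenerate] <- 0
  as.numeric(tt)
}

#' Permutation GLM for group contrasts
#'
#' One-sided (patient > control) permutation test of the group factor with
#' age, sex and site as nuisance covariates, following the Freedman-Lane
#' scheme: nuisance-only residuals are permuted, the full model is refit and
#' the group t statistic recomputed per unit. With TFCE parameters and mesh
#' edges, every permutation's t map is TFCE-transformed and family-wise
#' error is controlled through the max-statistic distribution over all
#' units; p = (1 + #\{perm >= observed\}) / (1 + nPerm). Scalar input skips
#' TFCE and yields the plain permutation p. When nPerm is at least the
#' number of distinct permutations, all permutations are enumerated exactly
#' (with a warning).
#'
#' @param Y numeric matrix (subjects x units) or vector (global metric).
#' @param design output of \code{\link{buildDesign}}.
#' @param nPerm number of permutations (>= 99).
#' @param seed integer seed.
#' @param tfce optional \linkS4class{TfceParams}.
#' @param edges mesh edge matrix (required with \code{tfce}).
#' @return a \linkS4class{StatResult}.
#' @export
permutationGlm <- function(Y, design, nPerm = 1000L, seed = 1L, tfce = NULL,
                           edges = NULL) {
  if (is.vector(Y)) Y <- matrix(Y, ncol = 1L)
  X <- design$X
  n <- nrow(X)
  if (nrow(Y) != n) stop("subjects in maps and design do not align")
  if (nPerm < 99L) stop("at least 99 permutations required")
  if (!is.null(tfce) && is.null(edges))
    stop("mesh edges are required for TFCE")
  ci <- design$contrastIndex
  n1 <- as.integer(sum(X[, ci] == 1)); n2 <- as.integer(sum(X[, ci] == 0))

  XtXinv <- solve(crossprod(X))
  fit <- list(X = X, pinv = XtXinv %*% t(X), ci = ci,
              cgg = XtXinv[ci, ci], df = n - ncol(X))

  # Freedman-Lane: residualize against nuisance-only model
  Z <- X[, design$nuisanceIndex, drop = FALSE]
  Hz <- Z %*% solve(crossprod(Z), t(Z))
  Rz <- Y - Hz %*% Y
  Zfit <- Hz %*% Y

  tObs <- glmTStats(Y, fit)
  enhanced <- function(tv) {
    if (is.null(tfce)) tv
    else tfceTransform(tv, edges, tfce)
  }
  eObs <- enhanced(tObs)

  nDistinct <- factorial(n)
  exhaustive <- is.finite(nDistinct) && nDistinct <= nPerm
  perms <- if (exhaustive) {
    warning(sprintf("nPerm capped at the %d distinct permutations", nDistinct))
    allPermutations(n)
  } else {
    withSeed(deriveSeed(seed, 77L),
             lapply(seq_len(nPerm), function(i) sample.int(n)))
  }

  nP <- length(perms)
  count <- numeric(length(tObs))
  maxCount <- numeric(length(tObs))
  for (p in perms) {
    Yp <- Zfit + Rz[p, , drop = FALSE]
    ep <- enhanced(glmTStats(Yp, fit))
    count <- count + (ep >= eObs)
    if (!is.null(tfce)) maxCount <- maxCount + (max(ep) >= eObs)
  }
  if (exhaustive) {
    # the identity permutation is part of the enumerated set
    pPlain <- count / nP
    pFwe <- if (is.null(tfce)) pPlain else maxCount / nP
  } else {
    pPlain <- (1 + count) / (1 + nP)
    pFwe <- if (is.null(tfce)) pPlain else (1 + maxCount) / (1 + nP)
  }
  new("StatResult", tMap = tObs,
      dMap = cohenDFromT(tObs, n1, n2),
      tfceMap = if (is.null(tfce)) numeric(0L) else eObs,
      pFwe = pFwe, neglog10P = -log10(pFwe),
      nPermutations = as.integer(nP), seed = as.integer(seed),
      tfceParams = if (is.null(tfce)) new("TfceParams") else tfce,
      n1 = n1, n2 = n2)
}

allPermutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- allPermutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (i in seq_len(n)) for (s in sub) {
    k <- k + 1L
    out[[k]] <- c(i, ifelse(s >= i, s + 1L, s))
  }
  out
}

#' Threshold-free cluster enhancement on a mesh
#'
#' For each vertex, integrates extent^E x height^H of the suprathreshold
#' connected component containing it over thresholds h = dh x max, 2 dh x
#' max, ... up to the map maximum. Negative values are enhanced on the
#' negated map and re-negated.
#'
#' @param statMap numeric per-vertex statistics.
#' @param edges integer matrix (edges x 2) of mesh adjacency.
#' @param params a \linkS4class{TfceParams}.
#' @return numeric, the enhanced map.
#' @export
tfceTransform <- function(statMap, edges, params = new("TfceParams")) {
  validObject(params)
  out <- tfcePositive(pmax(statMap, 0), edges, params) -
    tfcePositive(pmax(-statMap, 0), edges, params)
  out
}

# Positive-side TFCE via an incremental union-find: thresholds are processed
# from the map maximum downwards, vertices join as they cross each
# threshold, and connected-component sizes are maintained with vectorized
# pointer-jumping so the per-permutation cost stays small.
tfcePositive <- function(v, edges, params) {
  mx <- max(v)
  n <- length(v)
  out <- numeric(n)
  if (mx <= 0) return(out)
  step <- params@dh * mx
  hs <- seq(mx, step, by = -step)
  parent <- seq_len(n)
  active <- logical(n)
  e1 <- edges[, 1L]; e2 <- edges[, 2L]
  for (h in hs) {
    active <- active | v >= h
    keep <- active[e1] & active[e2]
    if (any(keep)) repeat {
      repeat {                                  # full path compression
        p2 <- parent[parent]
        if (identical(p2, parent)) break
        parent <- p2
      }
      r1 <- parent[e1[keep]]; r2 <- parent[e2[keep]]
      d <- r1 != r2
      if (!any(d)) break
      parent[pmax(r1[d], r2[d])] <- pmin(r1[d], r2[d])
    }
    act <- which(active)
    roots <- parent[act]
    sizes <- tabulate(roots, nbins = n)
    out[act] <- out[act] + sizes[roots]^params@E * h^params@H * step
  }
  out
}

#' Cohen d from a GLM t statistic
#'
#' d = t sqrt(1/n1 + 1/n2), the standardized group mean difference implied
#' by the covariate-adjusted t value. Conventional interpretation bands:
#' d >= 0.8 large, 0.5 medium, 0.2 small (attached as an attribute).
#'
#' @param t t statistic(s) of the group factor.
#' @param n1,n2 group sizes (>= 2).
#' @return numeric, same length as \code{t}.
#' @examples
#' cohenDFromT(2, 20, 20)  # 0.632
#' @export
cohenDFromT <- function(t, n1, n2) {
  if (n1 < 2L || n2 < 2L) stop("both groups need at least 2 subjects")
  d <- t * sqrt(1 / n1 + 1 / n2)
  attr(d, "interpretation") <- c(large = 0.8, medium = 0.5, small = 0.2)
  d
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up adjusted q-values with monotonicity enforcement, plus
#' significance flags at the 0.05 level.
#'
#' @param p numeric p-values in (0, 1].
#' @param alpha significance level for the flags (default 0.05).
#' @return list with \code{q} (adjusted values) and \code{significant}
#'   (logical flags).
#' @export
fdrBH <- function(p, alpha = 0.05) {
  if (any(p <= 0) || any(p > 1)) stop("p-values must lie in (0, 1]")
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, significant = q <= alpha)
}

#' Group balance tests for a cohort table
#'
#' Yates-continuity-corrected 2 x 2 chi-square for sex and one-way ANOVA F
#' for age, comparing patients with controls.
#'
#' @param covariates data.frame with columns group, sex, age.
#' @return list with \code{chiSquareSex}, \code{pSex}, \code{Fage},
#'   \code{pAge}.
#' @export
balanceTests <- function(covariates) {
  if (length(unique(covariates$group)) != 2L)
    stop("both groups must be present")
  tab <- table(factor(covariates$sex), factor(covariates$group))
  if (any(dim(tab) != c(2L, 2L)) || any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate sex by group table")
  cs <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
  av <- summary(stats::aov(age ~ group, data = covariates))[[1L]]
  list(chiSquareSex = unname(cs$statistic), pSex = cs$p.value,
       Fage = av[["F value"]][1L], pAge = av[["Pr(>F)"]][1L])
}
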