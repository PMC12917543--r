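# Independent Freedman-Lane oracle: explicit lm fits per enumerated
# permutation (one-sided p for the group coefficient).
freedmanLaneOracle <- function(y, covariates) {
  X <- data.frame(group = as.numeric(covariates$group == "patient"),
                  age = covariates$age - mean(covariates$age),
                  sex = covariates$sex)
  nuis <- stats::lm(y ~ age + sex, data = X)
  resid <- stats::resid(nuis)
  fitted <- stats::fitted(nuis)
  tOf <- function(yy) {
    fit <- stats::lm(yy ~ group + age + sex, data = X)
    summary(fit)$coefficients["group", "t value"]
  }
  tObs <- tOf(y)
  perms <- eegdens:::allPermutations(length(y))
  stats <- vapply(perms, function(p) tOf(fitted + resid[p]), numeric(1L))
  mean(stats >= tObs)
}


# brute-force TFCE: double loop over thresholds and vertices with literal
# component search per threshold
tfceOracle <- function(v, edges, E, H, dh) {
  mx <- max(abs(v))
  out <- numeric(length(v))
  if (mx <= 0) return(out)
  for (sign in c(1, -1)) {
    w <- sign * v
    mw <- max(w)
    if (mw <= 0) next
    step <- dh * mw
    for (h in seq(step, mw, by = step)) {
      above <- which(w >= h)
      for (u in above) {
        comp <- u
        repeat {
          grow <- unique(c(comp,
                           edges[edges[, 1L] %in% comp & edges[, 2L] %in% above, 2L],
                           edges[edges[, 2L] %in% comp & edges[, 1L] %in% above, 1L]))
          if (length(grow) == length(comp)) break
          comp <- grow
        }
        out[u] <- out[u] + sign * length(comp)^E * h^H * step
      }
    }
  }
  out
}

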