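# Independent reference implementations used to check the package's fast
# paths. Each is written with different machinery (explicit loops, lm(),
# closed-form algebra) than the code it validates.

# per-frame triple-nested-loop dot product of a map with a 4-D array
oracle_project <- function(weights_3d, data_4d) {
  d <- dim(data_4d)
  out <- numeric(d[4])
  for (t in seq_len(d[4])) {
    acc <- 0
    for (i in seq_len(d[1]))
      for (j in seq_len(d[2]))
        for (k in seq_len(d[3]))
          acc <- acc + weights_3d[i, j, k] * data_4d[i, j, k, t]
    out[t] <- acc
  }
  out
}

# normal-equations OLS solve
oracle_ols <- function(y, X) {
  as.vector(solve(t(X) %*% X) %*% t(X) %*% y)
}

# Huber IRLS with MAD scale, coded independently around lm.wfit
oracle_huber <- function(y, X, c = 1.345, tol = 1e-10, max_iter = 500) {
  X1 <- cbind(1, as.matrix(X))
  b <- oracle_ols(y, X1)
  for (it in seq_len(max_iter)) {
    r <- y - as.vector(X1 %*% b)
    s <- median(abs(r)) / 0.6745
    if (s < 1e-12) break
    w <- pmin(1, c / (abs(r) / s))
    b_new <- coef(lm.wfit(X1, y, w))
    if (max(abs(b_new - b)) < tol) { b <- b_new; break }
    b <- b_new
  }
  unname(b)
}

# stepwise selection via lm() and summary() p-values, same entry/removal
# thresholds, coded independently of the package's qr machinery
oracle_stepwise <- function(y, candidates, p_enter = 0.05, p_remove = 0.10) {
  dat <- data.frame(y = y, candidates)
  cand <- names(candidates)
  sel <- character(0)
  repeat {
    pool <- setdiff(cand, sel)
    if (!length(pool)) break
    ps <- sapply(pool, function(v) {
      f <- reformulate(c(sel, v), response = "y")
      ctab <- summary(lm(f, dat))$coefficients
      if (!v %in% rownames(ctab)) return(Inf)
      ctab[v, 4]
    })
    ps[is.na(ps)] <- Inf
    if (min(ps) >= p_enter) break
    sel <- c(sel, pool[which.min(ps)])
    repeat {
      ctab <- summary(lm(reformulate(sel, "y"), dat))$coefficients
      pv <- ctab[sel, 4]
      pv[is.na(pv)] <- 0
      if (max(pv) <= p_remove) break
      sel <- sel[-which.max(pv)]
      if (!length(sel)) break
    }
  }
  sel
}

# Brown-Forsythe via lm/anova on absolute deviations from group medians
oracle_brown_forsythe <- function(y, group) {
  z <- abs(y - ave(y, group, FUN = median))
  a <- anova(lm(z ~ factor(group)))
  list(F = a$`F value`[1], df1 = a$Df[1], df2 = a$Df[2],
       p = a$`Pr(>F)`[1])
}
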