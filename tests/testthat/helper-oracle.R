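# Independent oracles used across test files.
#
# The OLS oracle solves the normal equations directly (matrix inversion via
# solve()) and computes the beta1 p-value from the t distribution; it shares
# no code with the package's qr/lm.fit path.

oracle_ols <- function(y, x, pheno) {
  keep <- is.finite(y) & is.finite(x)
  y <- y[keep]; x <- x[keep]
  X <- cbind(intercept = rep(1, sum(keep)), meth = x)
  cand <- list(
    ERpos = as.numeric(pheno$er_status[keep] == "ERpos"),
    BasalA = as.numeric(pheno$subtype[keep] == "BasalA"),
    BasalB = as.numeric(pheno$subtype[keep] == "BasalB")
  )
  for (nm in names(cand))
    if (length(unique(cand[[nm]])) > 1) X <- cbind(X, cand[[nm]])
  XtX <- t(X) %*% X
  inv <- solve(XtX)
  beta <- inv %*% t(X) %*% y
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(diag(inv) * s2)
  t1 <- beta[2] / se[2]
  list(beta0 = beta[1], beta1 = beta[2], beta1_se = se[2],
       beta1_p = 2 * stats::pt(-abs(t1), df), residual_df = df,
       n_used = length(y))
}

# brute-force node degrees by scanning the edge list
oracle_degrees <- function(edges, nodes) {
  vapply(nodes, function(v)
    sum((edges$node_a == v | edges$node_b == v) & edges$node_a != edges$node_b),
    integer(1))
}
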