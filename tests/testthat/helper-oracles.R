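# Independent brute-force oracles, kept deliberately naive and separate from
# the package implementations they check.

# gift-wrapping (Jarvis march) convex hull, O(n h)
gift_wrap_hull <- function(x, y) {
  n <- length(x)
  if (n < 3) return(seq_len(n))
  pts <- unique(cbind(x, y))
  if (nrow(pts) < 3) return(NULL)
  start <- which.min(pts[, 1] + 1e-12 * pts[, 2])
  hull <- start
  current <- start
  repeat {
    cand <- if (current == 1) 2 else 1
    for (i in seq_len(nrow(pts))) {
      if (i == current) next
      cross <- (pts[cand, 1] - pts[current, 1]) * (pts[i, 2] - pts[current, 2]) -
        (pts[cand, 2] - pts[current, 2]) * (pts[i, 1] - pts[current, 1])
      d_cand <- sum((pts[cand, ] - pts[current, ])^2)
      d_i <- sum((pts[i, ] - pts[current, ])^2)
      if (cross < 0 || (cross == 0 && d_i > d_cand)) cand <- i
    }
    current <- cand
    if (current == start) break
    hull <- c(hull, current)
  }
  pts[hull, , drop = FALSE]
}

shoelace_area <- function(px, py) {
  n <- length(px)
  abs(sum(px * py[c(2:n, 1)] - px[c(2:n, 1)] * py)) / 2
}

brute_mcp_ha <- function(x, y) {
  h <- gift_wrap_hull(x, y)
  if (is.null(h) || nrow(h) < 3) return(0)
  shoelace_area(h[, 1], h[, 2]) / 1e4
}

# Pearson r and two-sided p from the definitional formulas
brute_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), df = n - 2))
}

# Benjamini-Hochberg from the direct definition p * m / rank with
# step-up monotonicity enforcement
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  if (m > 1)
    for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# check that groups share a letter exactly when adjusted p >= alpha
letters_sound <- function(letters, groups, p_matrix, alpha) {
  for (i in seq_along(groups)) {
    for (j in seq_along(groups)) {
      if (i >= j) next
      share <- length(intersect(strsplit(letters[i], "")[[1]],
                                strsplit(letters[j], "")[[1]])) > 0
      p <- p_matrix[groups[i], groups[j]]
      want <- is.na(p) || p >= alpha
      if (share != want) return(FALSE)
    }
  }
  TRUE
}

# REML log-likelihood for a Gaussian mixed model with independent random
# intercepts, evaluated directly from the marginal covariance matrix
brute_reml_loglik <- function(y, X, z_list, sigma2_b, sigma2_e) {
  n <- length(y)
  V <- diag(sigma2_e, n)
  for (k in seq_along(z_list)) {
    Z <- z_list[[k]]
    V <- V + sigma2_b[k] * tcrossprod(Z)
  }
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  p <- ncol(X)
  as.numeric(
    -0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
              t(r) %*% Vi %*% r + (n - p) * log(2 * pi)))
}
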