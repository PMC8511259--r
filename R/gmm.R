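## Three-component univariate Gaussian mixture by EM with restarts.
## Used for the ROH length-class model; unequal variances allowed.

gmm3_em <- function(x, n_restarts = 10L, max_iter = 500L, tol = 1e-8,
                    seed = 1L) {
  stopifnot(length(x) >= 6L)
  k <- 3L
  best <- NULL
  with_substream(seed, "gmm3", {
    for (r in seq_len(n_restarts)) {
      ## init: jittered quantile cut into 3 groups
      qcut <- stats::quantile(x, c(1, 2) / 3) +
        if (r == 1L) 0 else stats::rnorm(2, 0, stats::sd(x) / 4)
      grp <- findInterval(x, sort(qcut)) + 1L
      mu <- tapply(x, grp, mean)
      sdv <- tapply(x, grp, stats::sd)
      if (length(mu) < k || anyNA(sdv) || any(sdv < 1e-6)) {
        mu <- stats::quantile(x, c(1, 3, 5) / 6)
        sdv <- rep(stats::sd(x) / 3, k)
      }
      w <- rep(1 / k, k)
      ll_old <- -Inf
      degenerate <- FALSE
      for (it in seq_len(max_iter)) {
        dens <- vapply(seq_len(k), function(j)
          w[j] * stats::dnorm(x, mu[j], sdv[j]), numeric(length(x)))
        rowsum_d <- rowSums(dens)
        if (any(rowsum_d == 0)) { degenerate <- TRUE; break }
        resp <- dens / rowsum_d
        nk <- colSums(resp)
        if (any(nk / length(x) < 1e-3)) { degenerate <- TRUE; break }
        w <- nk / length(x)
        mu <- colSums(resp * x) / nk
        sdv <- sqrt(colSums(resp * (x - rep(mu, each = length(x)))^2) / nk)
        if (any(sdv < 1e-4)) { degenerate <- TRUE; break }
        ll <- sum(log(rowsum_d))
        if (abs(ll - ll_old) < tol) break
        ll_old <- ll
      }
      if (degenerate) next
      ll <- sum(log(rowSums(vapply(seq_len(k), function(j)
        w[j] * stats::dnorm(x, mu[j], sdv[j]), numeric(length(x))))))
      if (is.null(best) || ll > best$loglik) {
        ord <- order(mu)
        best <- list(means = unname(mu[ord]), sds = unname(sdv[ord]),
                     weights = unname(w[ord]), loglik = ll,
                     converged = TRUE)
      }
    }
  })
  best
}

## x where w1*N(x; m1, s1) = w2*N(x; m2, s2), restricted to (m1, m2);
## grid fallback when no analytic root lands in the interval.
gaussian_crossing <- function(w1, m1, s1, w2, m2, s2) {
  ## solve: log(w1) - log(s1) - (x-m1)^2/(2 s1^2) =
  ##        log(w2) - log(s2) - (x-m2)^2/(2 s2^2)
  A <- 1 / (2 * s2^2) - 1 / (2 * s1^2)
  B <- m1 / s1^2 - m2 / s2^2
  C <- m2^2 / (2 * s2^2) - m1^2 / (2 * s1^2) +
    log(w1 / s1) - log(w2 / s2)
  roots <- if (abs(A) < 1e-12) {
    if (abs(B) < 1e-12) numeric() else -C / B
  } else {
    disc <- B^2 - 4 * A * C
    if (disc < 0) numeric()
    else (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
  }
  inside <- roots[roots > m1 & roots < m2]
  if (length(inside)) return(inside[1])
  ## numeric fallback: densest grid point where the posterior flips
  xs <- seq(m1, m2, length.out = 2001L)
  d1 <- w1 * stats::dnorm(xs, m1, s1)
  d2 <- w2 * stats::dnorm(xs, m2, s2)
  flip <- which(diff(sign(d1 - d2)) != 0)
  if (length(flip)) xs[flip[1]] else (m1 + m2) / 2
}
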