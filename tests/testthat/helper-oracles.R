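## Independent brute-force oracles used to cross-check the implementation.

## Peak detector oracle: direct O(n^2) restatement of the detection rules,
## coded independently of the package's single-pass implementation.
oracle_detect <- function(x, fs, threshold, min_width_s = 5, min_distance_s = 5) {
  n <- length(x)
  peaks <- integer(0)
  for (i in 2:(n - 1)) {
    if (x[i] > x[i - 1]) {
      j <- i
      while (j < n && x[j + 1] == x[j]) j <- j + 1
      if (j < n && x[j + 1] < x[j]) peaks <- c(peaks, i)
    }
  }
  if (!length(peaks)) return(data.frame(idx = integer(0), amp = numeric(0)))
  prom <- wid <- numeric(length(peaks))
  for (k in seq_along(peaks)) {
    p <- peaks[k]; h <- x[p]
    higher_l <- which(x[1:p] > h)
    lo_l <- if (length(higher_l)) max(higher_l) + 1 else 1
    lmin <- min(x[lo_l:p])
    higher_r <- which(x[p:n] > h)
    hi_r <- if (length(higher_r)) p + min(higher_r) - 2 else n
    rmin <- min(x[p:hi_r])
    prom[k] <- h - max(lmin, rmin)
    ref <- h - prom[k] / 2
    a <- p
    while (a > 1 && x[a - 1] > ref) a <- a - 1
    xl <- if (a > 1) (a - 1) + (x[a - 1] - ref) / (x[a - 1] - x[a]) else 1
    b <- p
    while (b < n && x[b + 1] > ref) b <- b + 1
    xr <- if (b < n) (b + 1) - (x[b + 1] - ref) / (x[b + 1] - x[b]) else n
    wid[k] <- (xr - xl) / fs
  }
  ok <- wid >= min_width_s
  peaks <- peaks[ok]; wid <- wid[ok]
  keep <- rep(TRUE, length(peaks))
  ord <- order(-x[peaks], peaks)
  chosen <- integer(0)
  for (k in ord) {
    if (length(chosen) && any(abs(peaks[k] - chosen) < min_distance_s * fs)) {
      keep[k] <- FALSE
    } else chosen <- c(chosen, peaks[k])
  }
  peaks <- peaks[keep]
  peaks <- peaks[x[peaks] > threshold]
  peaks <- sort(peaks)
  data.frame(idx = peaks, amp = x[peaks])
}

## Exact Mann-Whitney two-sided p by full enumeration of label assignments.
oracle_mw_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pool <- c(a, b)
  combs <- utils::combn(n1 + n2, n1)
  ustat <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- ustat(a, b)
  us <- apply(combs, 2, function(idx) ustat(pool[idx], pool[-idx]))
  p_le <- mean(us <= u_obs); p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

## Exact Wilcoxon signed-rank two-sided p by enumeration of sign patterns.
oracle_wsr_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  p_le <- mean(vs <= v_obs); p_ge <- mean(vs >= v_obs)
  min(1, 2 * min(p_le, p_ge))
}

## Gaussian bump trace builder for detector tests.
bump_trace <- function(times_s, peaks, sigma_s = 4, fs = 2, duration_s = 400) {
  tt <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  x <- numeric(length(tt))
  for (i in seq_along(times_s))
    x <- x + peaks[i] * exp(-(tt - times_s[i])^2 / (2 * sigma_s^2))
  ca_trace(x, fs)
}

## Small constant-fluorescence movie helper.
const_movie <- function(value, t = 4, h = 3, w = 3, fs = 2) {
  movie_stack(array(value, dim = c(t, h, w)), fs)
}
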