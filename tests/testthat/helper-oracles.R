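# Independent brute-force oracles used to check the implementation.

# Flood-fill 8-connected labelling by repeated neighbourhood growth
# (independent of the package's union-find labeller).
oracle_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    frontier <- start
    lab[start] <- nxt
    while (length(frontier) > 0) {
      r <- (frontier - 1L) %% nrow(mask) + 1L
      c <- (frontier - 1L) %/% nrow(mask) + 1L
      nb <- unique(unlist(lapply(seq_along(frontier), function(i) {
        rr <- r[i] + c(-1, -1, -1, 0, 0, 1, 1, 1)
        cc <- c[i] + c(-1, 0, 1, -1, 1, -1, 0, 1)
        ok <- rr >= 1 & rr <= nrow(mask) & cc >= 1 & cc <= ncol(mask)
        (cc[ok] - 1L) * nrow(mask) + rr[ok]
      })))
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- nxt
      frontier <- nb
    }
  }
  lab
}

# Topographic prominence by scanning outwards to the first higher sample on
# each side and taking the minima of the scanned stretches.
oracle_prominence <- function(x, p) {
  left <- x[seq_len(p - 1)]
  right <- x[seq(p + 1, length(x))]
  higher_l <- which(left > x[p])
  higher_r <- which(right > x[p])
  lmin <- min(left[seq(if (length(higher_l)) max(higher_l) else 1, p - 1)])
  rmin <- min(right[seq(1, if (length(higher_r)) min(higher_r) else length(right))])
  x[p] - max(lmin, rmin)
}

# Mann-Whitney U by pair counting, and its exact two-sided p-value by
# recursive enumeration of all group-label assignments.
oracle_u <- function(a, b) {
  sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
}
oracle_mw_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  idx_sets <- utils::combn(length(pooled), na, simplify = FALSE)
  us <- vapply(idx_sets, function(ix) oracle_u(pooled[ix], pooled[-ix]),
               numeric(1))
  u_obs <- oracle_u(a, b)
  mu <- na * length(b) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# Signed-rank exact two-sided p by enumerating sign patterns, with the
# statistic recomputed from scratch (mid-ranks of |d|).
oracle_wsr_p <- function(before, after) {
  d <- (after - before)
  d <- d[d != 0]
  r <- rank(abs(d))
  n <- length(d)
  w_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ws <- vapply(0:(2^n - 1), function(m) {
    sum(r[bitwAnd(m, 2^(seq_len(n) - 1)) > 0])
  }, numeric(1))
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
}

# Kruskal-Wallis H from the rank formula, with tie correction
oracle_kw_h <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  n <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  h <- 12 / (n * (n + 1)) * sum(lengths(groups) * (rbar - (n + 1) / 2)^2)
  tt <- table(r)
  h / (1 - sum(tt^3 - tt) / (n^3 - n))
}

# Polygon area of an axis-aligned rectangle intersection (for square cases)
oracle_rect_overlap <- function(ax, ay, bx, by) {
  w <- max(0, min(ax[2], bx[2]) - max(ax[1], bx[1]))
  h <- max(0, min(ay[2], by[2]) - max(ay[1], by[1]))
  w * h
}

# match detected event times to ground truth within a tolerance; returns
# sensitivity and precision
match_events <- function(detected, truth, tol) {
  if (length(truth) == 0) {
    return(c(sensitivity = NA_real_,
             precision = if (length(detected) == 0) NA_real_ else 0))
  }
  hits <- vapply(truth, function(t) any(abs(detected - t) <= tol), logical(1))
  matched <- if (length(detected) == 0) logical(0) else
    vapply(detected, function(t) any(abs(truth - t) <= tol), logical(1))
  c(sensitivity = mean(hits),
    precision = if (length(detected) == 0) NA_real_ else mean(matched))
}
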