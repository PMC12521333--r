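# Independent oracles used by the tests. These deliberately use different
# algorithms from the package implementation.

# Winding-number point-in-polygon via signed angle summation.
pip_winding <- function(px, py, poly) {
  n <- nrow(poly)
  vapply(seq_along(px), function(q) {
    dx <- poly[, 1] - px[q]; dy <- poly[, 2] - py[q]
    ang <- atan2(dy, dx)
    d <- diff(c(ang, ang[1]))
    d <- ifelse(d > pi, d - 2 * pi, ifelse(d < -pi, d + 2 * pi, d))
    abs(sum(d)) > pi  # winding number != 0
  }, logical(1))
}

# Star-shaped simple polygon with random vertices around a center.
random_star_polygon <- function(n_vertices, cx, cy, rmin, rmax) {
  ang <- sort(stats::runif(n_vertices, 0, 2 * pi))
  r <- stats::runif(n_vertices, rmin, rmax)
  cbind(x = cx + r * cos(ang), y = cy + r * sin(ang))
}

# Two-sided Fisher p by full hypergeometric enumeration over all tables
# with the observed margins.
fisher_enum_p <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  xs <- max(0, k - n2):min(k, m)
  probs <- stats::dhyper(xs, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Studentized within-block permutation enumeration for Conover pairs.
# Recomputes the Conover t statistic (its SE term B varies under
# permutation) over all k!^n within-block orderings; mid-p convention for
# ties against the discrete permutation distribution.
perm_list <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in perm_list(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  }
  out
}

conover_perm_p <- function(tab, i, j) {
  n <- nrow(tab); k <- ncol(tab)
  r <- t(apply(tab, 1, rank))
  a <- sum(r^2)
  tstat <- function(rp) {
    rj <- colSums(rp); b <- sum(rj^2) / n
    se <- sqrt(2 * n * max(a - b, 0) / ((n - 1) * (k - 1)))
    d <- abs(rj[i] - rj[j])
    if (se == 0) ifelse(d == 0, 0, Inf) else d / se
  }
  obs <- tstat(r)
  pl <- perm_list(seq_len(k))
  idx <- rep(1L, n); gt <- 0; eq <- 0; tot <- 0
  repeat {
    rp <- t(vapply(seq_len(n), function(bk) r[bk, pl[[idx[bk]]]], numeric(k)))
    s <- tstat(rp)
    if (is.infinite(s) && is.infinite(obs)) {
      eq <- eq + 1
    } else if (s > obs + 1e-9) {
      gt <- gt + 1
    } else if (abs(s - obs) <= 1e-9) {
      eq <- eq + 1
    }
    tot <- tot + 1
    pos <- 1
    repeat {
      idx[pos] <- idx[pos] + 1L
      if (idx[pos] <= length(pl)) break
      idx[pos] <- 1L; pos <- pos + 1L
      if (pos > n) return((gt + eq / 2) / tot)
    }
  }
}
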