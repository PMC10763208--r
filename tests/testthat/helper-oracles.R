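# Independent oracles: brute-force or truncated-series implementations kept
# deliberately naive, against which the closed forms are checked.

# cone-averaged Fresnel transmittance by fine trapezoid quadrature
oracle_tav <- function(alpha, n, nodes = 1e5) {
  th <- seq(1e-9, alpha * pi / 180, length.out = nodes)
  ci <- cos(th)
  st <- sin(th) / n
  ct <- sqrt(1 - st^2)
  rs <- ((ci - n * ct) / (ci + n * ct))^2
  rp <- ((n * ci - ct) / (n * ci + ct))^2
  tf <- 1 - (rs + rp) / 2
  w <- sin(th) * cos(th)
  trap <- function(y) sum((y[-1] + y[-length(y)]) / 2 * diff(th))
  trap(tf * w) / trap(w)
}

# E1 by adaptive quadrature
oracle_e1 <- function(x) {
  vapply(x, function(xi) {
    integrate(function(t) exp(-t) / t, xi, Inf, rel.tol = 1e-13)$value
  }, numeric(1))
}

# single plate by explicit bounce enumeration (n_bounce internal returns)
oracle_plate <- function(ta, to, ri, tau, n_bounce = 60) {
  geo <- (ri^2 * tau^2)^(0:(n_bounce - 1))
  list(R = (1 - ta) + ta * tau^2 * ri * to * sum(geo),
       T = ta * tau * to * sum(geo))
}

# couple two 4-component layers by truncated interlayer bounce series
oracle_combine <- function(top, bot, n_bounce = 80) {
  geo <- (top$R_up * bot$R_dn)^(0:(n_bounce - 1))
  list(R_dn = top$R_dn + top$T_dn * bot$R_dn * top$T_up * sum(geo),
       T_dn = top$T_dn * bot$T_dn * sum(geo))
}

# pile of n identical plates by repeated pairwise adding (integer n)
oracle_pile <- function(layer, n) {
  out <- layer
  if (n == 1) return(out)
  for (i in seq_len(n - 1)) out <- combine_two_layers(out, layer)
  out
}

# brute-force non-dominated sorting via the full dominance matrix
oracle_sort <- function(F) {
  n <- nrow(F)
  dom <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && all(F[i, ] <= F[j, ]) && any(F[i, ] < F[j, ])) dom[i, j] <- TRUE
    }
  }
  rank <- rep(NA_integer_, n)
  level <- 0
  remaining <- seq_len(n)
  while (length(remaining) > 0) {
    level <- level + 1
    fr <- remaining[vapply(remaining, function(j) {
      !any(dom[remaining, j])
    }, logical(1))]
    rank[fr] <- level
    remaining <- setdiff(remaining, fr)
  }
  rank
}

# naive per-band loop for the relative-deviation fitness
oracle_fitness <- function(r_mod, r_meas) {
  y <- 0
  for (l in seq_along(r_mod)) y <- y + abs(r_mod[l] - r_meas[l]) / r_meas[l]
  y
}

# naive loop relative RMSE over a wavelength window
oracle_rmse <- function(meas, mod, wl, lo, hi) {
  ss <- 0; n <- 0; msum <- 0
  for (l in seq_along(wl)) {
    inside <- if (lo <= 400) wl[l] >= lo && wl[l] <= hi else wl[l] > lo && wl[l] <= hi
    if (inside) {
      ss <- ss + (meas[l] - mod[l])^2
      msum <- msum + meas[l]
      n <- n + 1
    }
  }
  sqrt(ss / n) / (msum / n)
}

# two-pass population variance
oracle_var <- function(x) {
  m <- sum(x) / length(x)
  sum((x - m)^2) / length(x)
}

# textbook Pearson correlation
oracle_cor <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
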