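# Brute-force simplex-grid oracle for the contribution optimiser.

# Enumerate compositions of `units` grid steps over k candidates.
compositions <- function(units, k) {
  if (k == 1) return(matrix(units, 1))
  out <- list()
  for (u in 0:units) {
    rest <- compositions(units - u, k - 1)
    out[[u + 1]] <- cbind(u, rest)
  }
  unname(do.call(rbind, out))
}

# Vectorised brute-force maximum of r'n over the within-sex simplex grids
# subject to n'Qn/2 <= qbar (males are the first n_m entries of r/Q).
grid_max <- function(r, Q, qbar, n_m, step = 0.05) {
  units <- round(0.5 / step)
  Gm <- compositions(units, n_m) * step
  Gf <- compositions(units, length(r) - n_m) * step
  im <- seq_len(n_m); if_ <- setdiff(seq_along(r), im)
  qm <- rowSums((Gm %*% Q[im, im]) * Gm) / 2
  qf <- rowSums((Gf %*% Q[if_, if_]) * Gf) / 2
  cross <- (Gm %*% Q[im, if_]) %*% t(Gf)
  quad <- outer(qm, qf, "+") + cross
  obj <- outer(drop(Gm %*% r[im]), drop(Gf %*% r[if_]), "+")
  obj[quad > qbar] <- -Inf
  max(obj)
}
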