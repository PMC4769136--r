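# independently coded classical RSF (isotropic window), plain R
rsf_oracle <- function(img255, phi, sigma, lambda1, lambda2, nu, mu,
                       eps, dt, iters) {
  R <- ceiling(3 * sigma)
  d2 <- outer((-R:R)^2, (-R:R)^2, "+")
  K <- exp(-d2 / (2 * sigma^2)) * (d2 <= (3 * sigma)^2)
  K <- K / sum(K)
  conv <- function(m) {
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_len(2 * R + 1)) for (j in seq_len(2 * R + 1)) {
      if (K[i, j] == 0) next
      ri <- pmin(pmax(seq_len(nrow(m)) + i - R - 1, 1), nrow(m))
      ci <- pmin(pmax(seq_len(ncol(m)) + j - R - 1, 1), ncol(m))
      out <- out + K[i, j] * m[ri, ci]
    }
    out
  }
  grad <- function(m, axis) {
    if (axis == 1) (rbind(m[-1, ], m[nrow(m), ]) - rbind(m[1, ], m[-nrow(m), ])) / 2
    else (cbind(m[, -1], m[, ncol(m)]) - cbind(m[, 1], m[, -ncol(m)])) / 2
  }
  KI <- conv(img255)
  for (it in seq_len(iters)) {
    H <- 0.5 * (1 + (2 / pi) * atan(phi / eps))
    dirac <- (eps / pi) / (eps^2 + phi^2)
    KH <- conv(H); KHI <- conv(H * img255)
    f2 <- KHI / pmax(KH, 1e-8)
    f1 <- (KI - KHI) / pmax(1 - KH, 1e-8)
    e1 <- img255^2 - 2 * img255 * conv(f1) + conv(f1^2)
    e2 <- img255^2 - 2 * img255 * conv(f2) + conv(f2^2)
    px <- grad(phi, 2); py <- grad(phi, 1)
    mag <- sqrt(px^2 + py^2) + 1e-10
    kap <- grad(px / mag, 2) + grad(py / mag, 1)
    lap <- rbind(phi[-1, ], phi[nrow(phi), ]) + rbind(phi[1, ], phi[-nrow(phi), ]) +
      cbind(phi[, -1], phi[, ncol(phi)]) + cbind(phi[, 1], phi[, -ncol(phi)]) -
      4 * phi
    phi <- phi + dt * (dirac * (lambda1 * e1 - lambda2 * e2 + nu * kap) +
                         mu * (lap - kap))
  }
  phi
}
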