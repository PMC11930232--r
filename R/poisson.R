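# Direct Poisson solvers for the pressure projection on the MAC grid.
#
# Cell-centered 5-point Laplacian with homogeneous Neumann (mirror ghost)
# boundaries diagonalizes in the DCT-II basis; periodic boundaries in the
# Fourier basis. Solutions are exact for the discrete operator, so the
# projected velocity field is discretely divergence-free to rounding.

# orthonormal DCT-II basis matrix (rows = modes)
dct_basis <- function(n) {
  j <- seq_len(n) - 0.5
  k <- seq_len(n) - 1
  C <- sqrt(2 / n) * cos(pi * outer(k, j) / n)
  C[1, ] <- sqrt(1 / n)
  C
}

# solver closure for lap(phi) = f with the given boundary condition;
# the zero mode (additive constant) is set to zero
make_poisson_solver <- function(nx, ny, h, bc = c("noslip", "periodic")) {
  bc <- match.arg(bc)
  if (bc == "noslip") {
    Cx <- dct_basis(nx); Cy <- dct_basis(ny)
    lx <- (2 * cos(pi * (seq_len(nx) - 1) / nx) - 2) / h^2
    ly <- (2 * cos(pi * (seq_len(ny) - 1) / ny) - 2) / h^2
    den <- outer(lx, ly, "+")
    den[1, 1] <- 1
    function(f) {
      fh <- Cx %*% f %*% t(Cy)
      fh <- fh / den
      fh[1, 1] <- 0
      t(Cx) %*% fh %*% Cy
    }
  } else {
    lx <- (2 * cos(2 * pi * (seq_len(nx) - 1) / nx) - 2) / h^2
    ly <- (2 * cos(2 * pi * (seq_len(ny) - 1) / ny) - 2) / h^2
    den <- outer(lx, ly, "+")
    den[1, 1] <- 1
    function(f) {
      fh <- t(stats::mvfft(t(stats::mvfft(f))))
      fh <- fh / den
      fh[1, 1] <- 0
      out <- t(stats::mvfft(t(stats::mvfft(fh, inverse = TRUE)),
                            inverse = TRUE)) / (nx * ny)
      Re(out)
    }
  }
}
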