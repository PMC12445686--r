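# Independent oracles used by several test files.

# exhaustive guanine 4-cycle enumeration over the Hoogsteen donor graph
quartet_oracle <- function(hbonds) {
  hg <- hbonds[
    hbonds$donor_base == "G" & hbonds$acceptor_base == "G" &
      ((hbonds$h_atom == "H1" & hbonds$acceptor_atom == "O6") |
        (hbonds$h_atom == "H21" & hbonds$acceptor_atom == "N7")),
  ]
  gs <- sort(unique(c(hg$donor_res, hg$acceptor_res)))
  edge <- function(a, b) any(hg$donor_res == a & hg$acceptor_res == b)
  sets <- list()
  if (length(gs) >= 4) {
    cmb <- utils::combn(gs, 4)
    for (k in seq_len(ncol(cmb))) {
      four <- cmb[, k]
      perms <- rbind(
        c(1, 2, 3, 4), c(1, 2, 4, 3), c(1, 3, 2, 4),
        c(1, 3, 4, 2), c(1, 4, 2, 3), c(1, 4, 3, 2)
      )
      for (r in seq_len(nrow(perms))) {
        cyc <- four[perms[r, ]]
        ok <- all(vapply(1:4, function(i) {
          edge(cyc[i], cyc[i %% 4 + 1])
        }, logical(1)))
        if (ok) {
          sets[[length(sets) + 1]] <- sort(four)
          break
        }
      }
    }
  }
  unique(sets)
}

# quaternion (Horn) superposition oracle, independent of the SVD route
horn_oracle <- function(A, B) {
  ca <- colMeans(A)
  cb <- colMeans(B)
  Ac <- sweep(A, 2, ca)
  Bc <- sweep(B, 2, cb)
  M <- t(Bc) %*% Ac
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy, Szx - Sxz, Sxy - Syx,
    Syz - Szy, Sxx - Syy - Szz, Sxy + Syx, Szx + Sxz,
    Szx - Sxz, Sxy + Syx, -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx, Szx + Sxz, Syz + Szy, -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
  Bt <- sweep(Bc %*% t(R), 2, ca, `+`)
  sqrt(mean(rowSums((Bt - A)^2)))
}
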