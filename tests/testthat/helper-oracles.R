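# matrix-free Hotelling oracle: explicit sums and a 2x2 adjugate inverse
bf_hotelling <- function(A, B) {
  na <- nrow(A); nb <- nrow(B)
  ma <- c(sum(A[, 1]) / na, sum(A[, 2]) / na)
  mb <- c(sum(B[, 1]) / nb, sum(B[, 2]) / nb)
  S <- matrix(0, 2, 2)
  for (i in seq_len(na)) {
    v <- c(A[i, 1] - ma[1], A[i, 2] - ma[2])
    S <- S + v %o% v
  }
  for (i in seq_len(nb)) {
    v <- c(B[i, 1] - mb[1], B[i, 2] - mb[2])
    S <- S + v %o% v
  }
  S <- S / (na + nb - 2)
  det <- S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]
  inv <- matrix(c(S[2, 2], -S[2, 1], -S[1, 2], S[1, 1]), 2, 2) / det
  d <- ma - mb
  (na * nb / (na + nb)) *
    (d[1] * (inv[1, 1] * d[1] + inv[1, 2] * d[2]) +
       d[2] * (inv[2, 1] * d[1] + inv[2, 2] * d[2]))
}
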