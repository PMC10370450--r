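# Exact k-nearest-neighbour search in the latent space.
#
# Determinism contract: Euclidean distances are computed per query as
# sqrt(colSums((x_j - q)^2)) (identical floating-point result to the
# naive per-pair formula), and distance ties at the k-th position are
# broken by training-row index.

.knnSearch <- function(trainX, Q, k, excludeSelf = FALSE) {
  n <- nrow(trainX)
  m <- nrow(Q)
  if (k < 1L || k > (n - as.integer(excludeSelf)))
    .satStop("invalidArgumentError",
             sprintf("k = %d out of range for %d training cells", k, n))
  tX <- t(trainX)
  idx <- matrix(0L, m, k)
  dst <- matrix(0, m, k)
  for (i in seq_len(m)) {
    dv <- sqrt(colSums((tX - Q[i, ])^2))
    if (excludeSelf) dv[i] <- Inf
    o <- order(dv, seq_len(n))[seq_len(k)]
    idx[i, ] <- o
    dst[i, ] <- dv[o]
  }
  list(idx = idx, dist = dst)
}
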