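# Independent brute-force oracles for the evaluation metrics.

overlap_oracle <- function(a, b) {
  A <- which(a != 0); B <- which(b != 0)
  I <- length(intersect(A, B))
  list(dsc = 2 * I / (length(A) + length(B)),
       precision = I / length(A), recall = I / length(B))
}

# 6-neighbour boundary extraction and all-pairs distances, O(n^2)
surface_oracle <- function(pair) {
  sp <- pair$pred$spacing
  bnd <- function(m) {
    d <- dim(m)
    idx <- which(m > 0, arr.ind = TRUE)
    keep <- apply(idx, 1, function(p) {
      for (ax in 1:3) for (dd in c(-1, 1)) {
        q <- p; q[ax] <- q[ax] + dd
        if (any(q < 1) || any(q > d)) return(TRUE)
        if (m[q[1], q[2], q[3]] == 0) return(TRUE)
      }
      FALSE
    })
    sweep(idx[keep, , drop = FALSE], 2, sp, "*")
  }
  A <- bnd(pair$pred$data); B <- bnd(pair$truth$data)
  dmat <- outer(seq_len(nrow(A)), seq_len(nrow(B)), Vectorize(function(i, j)
    sqrt(sum((A[i, ] - B[j, ])^2))))
  dab <- apply(dmat, 1, min); dba <- apply(dmat, 2, min)
  list(assd = (mean(dab) + mean(dba)) / 2, hd = max(dab, dba))
}
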