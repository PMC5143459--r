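# Brute-force oracle for the 3'-end aligner: enumerates every monotone
# gapped alignment as a monotone matching of x positions to y positions
# and scores it in closed form, independently of the dynamic program.
# Leading gaps cost g * min(i1 - 1, j1 - 1) (the path may enter from
# either zero boundary), interior gaps g per skipped residue, trailing
# x residues g each; trailing y is free. The empty alignment scores 0.
oracleBestScore <- function(x, y, match = 4, mismatch = 1, gap = -5,
                            bonus = 0, bonusMask = NULL) {
  pairing <- c("AU", "UA", "CG", "GC", "GU", "UG")
  sc <- function(a, b) if (paste0(a, b) %in% pairing) match else mismatch
  m <- length(x); n <- length(y)
  if (is.null(bonusMask)) bonusMask <- matrix(FALSE, m, n)
  best <- 0
  for (k in seq_len(min(m, n))) {
    xs <- utils::combn(m, k)
    ys <- utils::combn(n, k)
    for (a in seq_len(ncol(xs))) {
      xi <- xs[, a]
      trail <- gap * (m - xi[k])
      xInter <- if (k > 1) gap * sum(diff(xi) - 1) else 0
      for (b in seq_len(ncol(ys))) {
        yj <- ys[, b]
        s <- sum(mapply(sc, x[xi], y[yj])) +
          bonus * sum(bonusMask[cbind(xi, yj)])
        lead <- gap * min(xi[1] - 1, yj[1] - 1)
        yInter <- if (k > 1) gap * sum(diff(yj) - 1) else 0
        best <- max(best, s + lead + xInter + yInter + trail)
      }
    }
  }
  best
}

randomBaseVec <- function(n) sample(c("A", "C", "G", "U"), n, replace = TRUE)

# Independent G statistic: 2 * sum(O * ln(O / E)), E from margins.
oracleG <- function(m) {
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  2 * sum(ifelse(m > 0, m * log(m / E), 0))
}
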