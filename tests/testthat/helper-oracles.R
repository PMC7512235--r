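# Independent brute-force information oracles: term-by-term evaluation of the
# defining sums over raw samples, sharing no code with the package estimators.

mi_oracle <- function(x, y) {
  n <- length(x)
  s <- 0
  for (a in unique(x)) for (b in unique(y)) {
    p <- sum(x == a & y == b) / n
    if (p > 0) {
      s <- s + p * log2(p / ((sum(x == a) / n) * (sum(y == b) / n)))
    }
  }
  s
}

cmi_oracle <- function(x, y, z) {
  n <- length(x)
  s <- 0
  for (a in unique(x)) for (b in unique(y)) for (cc in unique(z)) {
    pxyz <- sum(x == a & y == b & z == cc) / n
    if (pxyz > 0) {
      pz <- sum(z == cc) / n
      pxz <- sum(x == a & z == cc) / n
      pyz <- sum(y == b & z == cc) / n
      s <- s + pxyz * log2(pxyz * pz / (pxz * pyz))
    }
  }
  s
}
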