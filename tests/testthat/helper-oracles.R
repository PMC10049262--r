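# Independent brute-force oracles, deliberately naive implementations.

# sliding-extrema TopHat: erosion then dilation with replicate padding,
# computed with explicit O(n*w) loops
tophat_oracle <- function(x, w) {
  n <- length(x)
  h <- w %/% 2
  slide <- function(v, fun) {
    pad <- c(rep(v[1], h), v, rep(v[n], h))
    vapply(seq_len(n), function(i) fun(pad[i:(i + 2 * h)]), numeric(1))
  }
  opening <- slide(slide(x, min), max)
  x - opening
}

# all-pairs concordance count (ties = 1/2)
auroc_oracle <- function(pos, neg) {
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}
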