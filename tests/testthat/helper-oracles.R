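# exhaustive enumeration oracle: maximum pairs over all valid non-crossing
# pairings of s[i..j], canonical pairs only, min loop 3
bf_can_pair <- function(a, b) {
  p <- paste0(a, b)
  p %in% c("AT", "TA", "GC", "CG", "GT", "TG")
}

bf_max_pairs <- function(chars, i, j) {
  if (j - i < 4) return(0L)
  best <- bf_max_pairs(chars, i + 1L, j)           # i unpaired
  for (k in (i + 4L):j) {                          # i paired with k
    if (bf_can_pair(chars[i], chars[k])) {
      v <- 1L + bf_max_pairs(chars, i + 1L, k - 1L) +
        (if (k < j) bf_max_pairs(chars, k + 1L, j) else 0L)
      if (v > best) best <- v
    }
  }
  best
}
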