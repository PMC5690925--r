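# Locate the pass/fail boundary of a detection check by bisection over the
# injected-error magnitude. `fails_at` must be monotone in the magnitude.
boundary_bisect <- function(fails_at, lo, hi, iters = 12L) {
  stopifnot(!fails_at(lo), fails_at(hi))
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (fails_at(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# TRUE iff any check row whose item matches `item_pattern` failed.
any_fail <- function(verification, item_pattern) {
  r <- verification$results
  any(r$status == "fail" & grepl(item_pattern, r$item))
}
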