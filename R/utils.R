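# Benjamini-Hochberg step-up at level q; returns logical pass vector.
# Thin wrapper over stats::p.adjust so every pipeline selects identically.
bh_pass <- function(p, q = 0.05) {
  if (length(p) == 0L) return(logical(0L))
  stats::p.adjust(pmin(p, 1), method = "BH") <= q
}
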