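# deterministic seed derivation: master seed + counter -> child seed
# (kept below 2^31 so it is always a valid integer seed)
derive_seed <- function(master, counter) {
  s <- (as.double(master %% 1000003L) * 1009 + as.double(counter) * 7919) %%
    2147483629
  as.integer(s) + 1L
}

# Pearson correlation that degrades gracefully: returns NA (flagged) when
# either vector has zero variance instead of erroring
safe_cor <- function(a, b) {
  if (length(a) < 2L || stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}
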