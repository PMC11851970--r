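# Direct-form LTI filtering built on stats::filter (C implementations):
# FIR part as one-sided convolution, IIR part as the recursive filter.
# Identical output to a transposed-direct-form loop with zero initial state.
lti_filter <- function(b, a, x) {
  b <- as.numeric(b); a <- as.numeric(a)
  if (a[1] != 1) { b <- b / a[1]; a <- a / a[1] }
  nb <- length(b)
  y <- if (nb > 1) {
    y <- stats::filter(c(rep(0, nb - 1), x), b, method = "convolution",
                       sides = 1)
    as.numeric(y[-seq_len(nb - 1)])
  } else b * x
  if (length(a) > 1)
    y <- as.numeric(stats::filter(y, -a[-1], method = "recursive"))
  y
}

# forward-backward (zero-phase) filtering; squares the magnitude response
# and cancels the group delay. Edge transients decay over the filter's
# impulse-response length and are not padded away.
lti_filtfilt <- function(b, a, x) {
  rev(lti_filter(b, a, rev(lti_filter(b, a, x))))
}
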