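# Internal helpers shared across modules.

# Round half away from zero, as printed tables do (base round() is half-even).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Pick the delimiter (tab, comma or semicolon) that splits a header line into
# the most fields. AFLP matrices circulate in all three; tab is canonical on
# write.
detect_delim <- function(line) {
  cand <- c("\t", ",", ";")
  n <- vapply(cand, function(s) length(strsplit(line, s, fixed = TRUE)[[1]]),
              integer(1))
  cand[which.max(n)]
}

stop_hs <- function(...) stop(..., call. = FALSE)
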