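# Deterministic seed streams: a replicate's seed is a pure function of
# (root seed, scenario id, replicate id), so any scenario can be re-run in
# isolation and studies are resumable.
derive_seed <- function(root, key) {
  h <- as.numeric(root) %% 2147483647
  for (c in utf8ToInt(as.character(key))) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

effective_n <- function(n1, n2) n1 * n2 / (n1 + n2)

`%||%` <- function(a, b) if (is.null(a)) b else a
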