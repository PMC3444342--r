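# Shared test helpers: deterministic random sequences and binary vectors.

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_binary <- function(n) sample(0:1, n, replace = TRUE)
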