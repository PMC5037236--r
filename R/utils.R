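# Deterministic integer seed derivation. Mixes a root seed with integer
# components (model code, design sizes, replication / chain / stream indices)
# into a value in [1, 2^31 - 2] using multiply-and-add hashing kept inside
# the exactly-representable double range.
mix_seed <- function(root, ...) {
  m <- 2147483629 # prime < 2^31
  x <- as.numeric(root) %% m
  comps <- c(...)
  for (c in comps) {
    x <- (x * 1009 + as.numeric(c) + 1) %% m
  }
  as.integer(x + 1)
}

model_code <- function(model) match(model, c("1PL", "2PL"))

check_binary_matrix <- function(Y) {
  if (anyNA(Y)) stop("response matrix contains missing entries")
  if (!all(Y %in% c(0L, 1L))) stop("responses must be coded 0/1")
  invisible(TRUE)
}
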