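# Internal utilities: reproducible seed substreams, k-mer hashing, misc helpers.

# Derive a deterministic 32-bit seed for a named substream of a top-level seed.
# Every stochastic stage draws from its own substream so that adding a stage
# never perturbs the draws of another.
substreamSeed <- function(seed, label) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(label))
  codes <- utf8ToInt(label)
  h <- (as.numeric(seed) %% 2147483647) * 48271
  for (c in codes) h <- (h * 131 + c) %% 2147483629
  as.integer(h %% 2147483647)
}

# Evaluate `expr` under the substream RNG state, restoring the caller's state.
withSubstream <- function(seed, label, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(substreamSeed(seed, label))
  expr
}

# Vectorised polynomial hash of all k-mers of one sequence (mod 2^31 - 1).
# Doubles stay below 2^38 throughout, so arithmetic is exact.
hashKmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(numeric(0))
  codes <- utf8ToInt(seq)
  mod <- 2147483647
  base <- 131
  pows <- numeric(k)
  pows[k] <- 1
  if (k > 1) for (i in (k - 1):1) pows[i] <- (pows[i + 1] * base) %% mod
  nk <- n - k + 1
  h <- numeric(nk)
  for (j in seq_len(k)) {
    h <- (h + (codes[j:(j + nk - 1)] * pows[j]) %% mod) %% mod
  }
  h
}

# Random amino-acid sequence over the 20 standard residues.
randomProtein <- function(len) {
  paste(sample(Biostrings::AA_STANDARD, len, replace = TRUE), collapse = "")
}

# Point-mutate a protein: each site substituted with probability `rate`
# (substitutions always change the residue, so 1 - rate is the expected identity).
mutateProtein <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- runif(length(chars)) < rate
  if (any(hit)) {
    alph <- Biostrings::AA_STANDARD
    repl <- vapply(chars[hit], function(ch) sample(setdiff(alph, ch), 1L), "")
    chars[hit] <- repl
  }
  paste(chars, collapse = "")
}

# rbind a list of data.frames without row-name mangling.
bindRows <- function(lst) {
  lst <- Filter(Negate(is.null), lst)
  if (!length(lst)) return(NULL)
  out <- do.call(rbind, lst)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
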