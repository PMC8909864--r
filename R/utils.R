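# internal utilities

# evaluate code under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

# deterministic sub-seed below 2^31 from a base seed and coordinate strings;
# FNV-style polynomial hash so campaign cells are independently reproducible
derive_seed <- function(seed, ...) {
  key <- paste(c(as.character(seed), vapply(list(...), as.character,
                                            character(1))), collapse = "\r")
  h <- 0
  for (v in utf8ToInt(key)) h <- (h * 31 + v) %% 2147483629
  as.integer(h + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
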