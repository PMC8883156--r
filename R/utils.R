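# internal helpers shared across modules

# run code under a temporary RNG state; restores the caller's stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# deterministic integer seed (< 2^31) derived from a master seed and a tag;
# polynomial string hash so every (task, object, illumination, pose, value)
# tuple gets its own reproducible stream
derive_seed <- function(master, ...) {
  tag <- paste(c(master, ...), collapse = "|")
  h <- 0
  for (k in utf8ToInt(tag)) h <- (h * 31 + k) %% 2147483629
  as.integer(h + 1)
}

# package-level cache (psychometric lookup tables etc.)
.matodd_cache <- new.env(parent = emptyenv())
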