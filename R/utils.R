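## Deterministic seeding helpers.
##
## Each generator operation draws from its own RNG stream, seeded by the
## user seed combined with an operation tag, so adding or removing one
## generator call never perturbs the randomness of another.

## FNV-1a style 31-bit string hash; stable across platforms/locales.
hash_tag <- function(tag) {
  h <- 2166136261 %% 2147483647
  for (b in utf8ToInt(tag)) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 2147483647
  }
  as.integer(h)
}

derive_seed <- function(seed, tag) {
  as.integer((as.numeric(seed) %% 2147483647 + hash_tag(tag)) %% 2147483647)
}

## Evaluate expr under a temporary RNG state seeded by (seed, tag); the
## caller's .Random.seed is restored afterwards.
with_op_seed <- function(seed, tag, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(derive_seed(seed, tag))
  expr
}

## Deterministic total order on gene ids (C collation, locale-independent).
order_radix <- function(...) order(..., method = "radix")

## Small content hash for reproducibility stamps in reports (hex string).
content_hash <- function(x) {
  txt <- paste(deparse(x, control = "all"), collapse = "\n")
  h1 <- 2166136261 %% 2147483647; h2 <- 5381
  for (b in utf8ToInt(txt)) {
    h1 <- bitwXor(h1, b); h1 <- (h1 * 16777619) %% 2147483647
    h2 <- (h2 * 33 + b) %% 2147483647
  }
  sprintf("%08x%08x", as.integer(h1), as.integer(h2))
}
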