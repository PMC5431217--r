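# Internal helpers shared across modules.

# Deterministic 31-bit hash of a site identifier, used to derive an
# independent RNG substream per site from one master seed: a polynomial
# rolling hash over UTF-8 bytes modulo the Mersenne prime 2^31 - 1, so
# the result is always a valid R seed.
site_seed <- function(master_seed, site_id) {
  stopifnot(length(site_id) == 1L)
  bytes <- utf8ToInt(enc2utf8(as.character(site_id)))
  h <- 17
  for (b in bytes) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer((h * 131071 + as.numeric(master_seed)) %% 2147483647)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Guess the field separator of a delimited text file from its first line.
sniff_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) {
    rlang::abort(sprintf("file '%s' is empty", path))
  }
  if (grepl("\t", first)) "\t" else ","
}

`%||%` <- rlang::`%||%`
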