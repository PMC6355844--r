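# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.  All exported stochastic functions route through this so a
# single integer seed gives byte-identical output.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        },
        add = TRUE
      )
    }
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a stream-specific child seed from a master seed, kept inside the
# 32-bit signed integer range R requires.
derive_seed <- function(seed, k) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(k) %% 1000L
}

# Genotype calls are strings over {"A","B"}: "A", "B" (homozygous or
# hemizygous single allele), "AB" (heterozygous); NA is a missing call.
call_alleles <- function(call) {
  if (is.na(call)) character(0) else strsplit(call, "", fixed = TRUE)[[1L]]
}

has_allele <- function(call, x) {
  !is.na(call) && grepl(x, call, fixed = TRUE)
}

is_het_call <- function(call) !is.na(call) && call == "AB"

is_single_call <- function(call) !is.na(call) && nchar(call) == 1L

normalize_call <- function(alleles) {
  paste(sort(unique(alleles)), collapse = "")
}

other_allele <- function(x) if (x == "A") "B" else "A"

# log(sum(exp(x))) without overflow.
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small non-cryptographic hash of a configuration list, for output headers.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = " ")
  h <- 2166136261
  for (v in utf8ToInt(s)) {
    h <- (bitwXor(as.integer(h %% 2147483647), v) * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}
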