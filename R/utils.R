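# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's .Random.seed is restored afterwards so package functions never
# perturb the session RNG. seed = NULL means "use the current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Deterministic child seeds below 2^31, derived from a root seed and a
# stream index; used so pipeline stages are independently reproducible.
derive_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + 7919 * stream) %% 2147483647)
}

as_expr_matrix <- function(x) {
  if (is(x, "ExpressionMatrix")) return(exprValues(x))
  if (is.matrix(x)) return(x)
  stop("expected an ExpressionMatrix or a numeric matrix")
}

# Jaccard index between two character sets.
jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}
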