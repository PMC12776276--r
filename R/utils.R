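# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}

# case-insensitive, whitespace-stripped symbol key (original casing kept elsewhere)
symbol_key <- function(x) tolower(trimws(x))

# resolve query symbols against dataset gene names case-insensitively;
# returns integer indices with NA for unresolvable symbols
match_genes <- function(symbols, genes) {
  match(symbol_key(symbols), symbol_key(genes))
}

is_wholenumber <- function(x, tol = 1e-8) abs(x - round(x)) < tol

# coerce any matrix-like to a general numeric CsparseMatrix (dgCMatrix)
as_sparse <- function(m) {
  m <- methods::as(m, "CsparseMatrix")
  m <- methods::as(m, "generalMatrix")
  methods::as(m, "dMatrix")
}
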