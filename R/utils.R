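# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so no function ever perturbs global state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a parent seed and a stream offset, staying inside
# 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) %% 2147483647 * 48271 + offset) %% 2147483647)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

item_cols <- function() paste0("item", 1:9)

# Sanity-check a labelled dataset (complete items, total, logical label).
check_labeled <- function(data, call = sys.call(-1)) {
  cols <- item_cols()
  if (!all(cols %in% names(data)))
    stop("labelled dataset must contain columns ", paste(cols, collapse = ", "))
  items <- as.matrix(data[cols])
  if (anyNA(items))
    stop("labelled dataset must not contain missing item responses")
  if (!all(items %in% 0:3))
    stop("item responses must lie in {0,1,2,3}")
  if (!"label" %in% names(data))
    stop("labelled dataset must contain a 'label' column")
  invisible(data)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
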