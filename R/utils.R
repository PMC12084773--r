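# Internal helpers: seeded evaluation without touching global RNG state,
# small validators shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under set.seed(seed), restoring the caller's RNG state.
# All exported stochastic operations route their randomness through this.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

check_square <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || nrow(x) != ncol(x))
    stop(sprintf("'%s' must be a square matrix", name), call. = FALSE)
  invisible(x)
}

check_symmetric <- function(x, tol = 1e-8, name = deparse(substitute(x))) {
  check_square(x, name)
  if (max(abs(x - t(x))) > tol)
    stop(sprintf("'%s' must be symmetric", name), call. = FALSE)
  invisible(x)
}

is_pd <- function(x, tol = 0) {
  ev <- eigen(x, symmetric = TRUE, only.values = TRUE)$values
  min(ev) > tol
}

# FNV-1a 32-bit hash of a character scalar; used for provenance tags only.
# Arithmetic stays within exact double range: the xor touches only the low
# byte, and the 32-bit modular product is computed in 16-bit halves.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  m <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- (h0 * m + ((h1 * m) %% 65536) * 65536) %% 4294967296
  }
  paste0(sprintf("%04x", h %/% 65536), sprintf("%04x", h %% 65536))
}

upper_tri_vec <- function(m) m[upper.tri(m)]

edge_names_upper <- function(nodes) {
  p <- length(nodes)
  idx <- which(upper.tri(diag(p)), arr.ind = TRUE)
  paste(nodes[idx[, 1]], nodes[idx[, 2]], sep = "--")
}
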