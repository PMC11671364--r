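# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package functions never clobber the
# session RNG.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Derive a module-level seed from a global seed
#'
#' One global seed deterministically drives every stochastic stage; each
#' module draws its own stream from a (seed, module-name) hash so modules stay
#' independent of each other's consumption of random numbers. The result is
#' always in `[0, 2^31 - 2]`.
#'
#' @param seed integer global seed.
#' @param module character module name (e.g. `"simulate"`, `"select"`).
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, module) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(module))
  h <- 0
  for (ch in utf8ToInt(module)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

# Stratified fold assignment: returns an integer vector of fold ids in 1..k,
# balanced within each level of `y`.
stratified_folds <- function(y, k) {
  y <- as.factor(y)
  folds <- integer(length(y))
  for (lev in levels(y)) {
    idx <- which(y == lev)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

# Stratified subsample of indices: `fraction` of each class, at least one per
# class.
stratified_subsample <- function(y, fraction) {
  y <- as.factor(y)
  unlist(lapply(levels(y), function(lev) {
    idx <- which(y == lev)
    n <- max(1L, round(length(idx) * fraction))
    sample(idx, n)
  }), use.names = FALSE)
}

# Inverse-frequency class weights, named by class, mean-normalized to 1.
balanced_weights <- function(y) {
  tab <- table(y)
  w <- length(y) / (length(tab) * tab)
  stats::setNames(as.numeric(w), names(tab))
}

# Largest-remainder apportionment of n into proportions p (sums to n exactly).
apportion <- function(n, p) {
  stopifnot(abs(sum(p) - 1) < 1e-9)
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    order_idx <- order(raw - base, decreasing = TRUE)
    base[order_idx[seq_len(rem)]] <- base[order_idx[seq_len(rem)]] + 1
  }
  as.integer(base)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
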