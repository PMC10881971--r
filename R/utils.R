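# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so simulation calls do not perturb user code.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Per-plate stream: plate i (1-based counter in a fixed plate enumeration
# order) uses seed (master * 7919 + i) mod (2^31 - 1), so any plate can be
# regenerated independently of the others.
plate_seed <- function(master_seed, counter) {
  as.integer((as.numeric(master_seed) * 7919 + counter) %% 2147483647)
}

# Multiplicative log-normal noise factors with unit mean and coefficient of
# variation `cv`; degenerates to exactly 1 when cv == 0.
ln_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  exp(rnorm(n, mean = -s^2 / 2, sd = s))
}

# Four-parameter Hill viability decline with top 1, bottom 0.
hill_viability <- function(dose, ec50, slope) {
  ifelse(dose <= 0, 1, 1 / (1 + (dose / ec50)^slope))
}

# Standard error of the mean.
sem <- function(x) {
  n <- length(x)
  if (n < 2) return(0)
  stats::sd(x) / sqrt(n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
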