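# Internal helpers shared across modules.

# Proton gyromagnetic ratio expressed in rad / (um * (mT/m) * ms), so that
# b = gammaEff^2 G^2 delta^2 (Delta - delta/3) comes out in ms/um^2 when G is
# in mT/m and delta, Delta in ms.  1000 s/mm^2 == 1 ms/um^2.
.gammaEff <- 2.6751525e-4

# Convert b-values given in s/mm^2 to ms/um^2.
.bToMsUm2 <- function(b) b / 1000

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs \code{expr} with the RNG seeded to \code{seed} and restores the
#' caller's RNG state afterwards; all seeded package functions use this so
#' they never perturb the session's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @export
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))
.relu <- function(x) (x > 0) * x
.softplus <- function(x) {
  # numerically stable log(1 + exp(x))
  ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
}

.unitRows <- function(m, tol = 1e-9) {
  nrm <- sqrt(rowSums(m^2))
  all(abs(nrm - 1) < tol | nrm < tol)
}

# Cheap numeric fingerprint of a matrix/vector used in provenance metadata.
.dataFingerprint <- function(x) {
  x <- as.numeric(x)
  sprintf("%.6e/%.6e/%d", sum(x), sum(x * seq_along(x) %% 97), length(x))
}

.pkgEnv <- new.env(parent = emptyenv())
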