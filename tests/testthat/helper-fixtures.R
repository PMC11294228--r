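# Shared fixtures: small schemes and dictionaries built in code.

# compact two-shell scheme with HCP-like timing: 1 b0 + 2 x nDir directions
tinyScheme <- function(nDir = 12, bs = c(1000, 3000), seed = 42) {
  dirs <- rbind(c(0, 0, 0))
  bv <- 0
  for (i in seq_along(bs)) {
    dirs <- rbind(dirs, sphereDirections(nDir, seed = seed + i))
    bv <- c(bv, rep(bs[i], nDir))
  }
  makeScheme(dirs, bv, delta = 12.9, Delta = 21.8)
}

# small analytic dictionary on a coarse grid
tinyDict <- function(scheme = tinyScheme(), nFvf = 5, nDex = 2) {
  buildDictionary(buildParameterGrid(nFvf = nFvf, nDex = nDex), scheme)
}

# near-uniform deterministic point set (Fibonacci spiral)
fibonacciSphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  ga <- pi * (3 - sqrt(5))
  phi <- ga * (seq_len(n) - 1)
  cbind(r * cos(phi), r * sin(phi), z)
}

randomUnit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# brute-force NNLS via support enumeration (independent oracle)
bruteNnls <- function(A, y) {
  P <- ncol(A)
  best <- list(w = rep(0, P), resid = sqrt(sum(y^2)))
  for (mask in 1:(2^P - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(P) - 1)) > 0)
    As <- A[, S, drop = FALSE]
    ws <- tryCatch(solve(crossprod(As), crossprod(As, y)),
                   error = function(e) NULL)
    if (is.null(ws) || any(ws < 0)) next
    r <- sqrt(sum((y - As %*% ws)^2))
    if (r < best$resid - 1e-12) {
      w <- rep(0, P); w[S] <- ws
      best <- list(w = w, resid = r)
    }
  }
  best
}
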