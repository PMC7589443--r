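# Shared generators and small oracles for the test-suite.

# random 8-connected polyomino of n cells grown on an nr x nc canvas
randomPolyomino <- function(seed, n = 30L, nr = 40L, nc = 40L) {
  set.seed(seed)
  px <- matrix(FALSE, nr, nc)
  r <- nr %/% 2L; c <- nc %/% 2L
  px[r, c] <- TRUE
  cells <- list(c(r, c))
  dr <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  dc <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  while (length(cells) < n) {
    base <- cells[[sample(length(cells), 1L)]]
    d <- sample(8L, 1L)
    r2 <- base[1] + dr[d]; c2 <- base[2] + dc[d]
    if (r2 > 1L && r2 < nr && c2 > 1L && c2 < nc && !px[r2, c2]) {
      px[r2, c2] <- TRUE
      cells[[length(cells) + 1L]] <- c(r2, c2)
    }
  }
  px
}

# random RGB frame over a given mask canvas (deterministic from seed)
randomFrame <- function(seed, nr = 40L, nc = 40L, view = "side") {
  set.seed(seed)
  px <- array(sample(0:255, nr * nc * 3, replace = TRUE), c(nr, nc, 3))
  RGBFrame(px, view, frameId = paste0("rnd", seed))
}

# canonical form of a sinusoid parameter vector: a >= 0, c in (-pi, pi]
canonicalSin <- function(cf) {
  if (cf[["a"]] < 0) { cf[["a"]] <- -cf[["a"]]; cf[["c"]] <- cf[["c"]] + pi }
  cf[["c"]] <- ((cf[["c"]] + pi) %% (2 * pi)) - pi
  cf
}

# the six growth-family mean functions with reference parameter sets of
# realistic projected-area magnitude
growthGenerators <- function() {
  list(
    Lin = list(f = function(t, p) p[["a"]] + p[["b"]] * t,
               p = c(a = 5000, b = 3000)),
    Qua = list(f = function(t, p) p[["a"]] + p[["b"]] * t + p[["c"]] * t^2,
               p = c(a = 2000, b = 1000, c = 300)),
    Exp = list(f = function(t, p) p[["a"]] * exp(p[["b"]] * t),
               p = c(a = 2000, b = 0.25)),
    Pow = list(f = function(t, p) p[["a"]] * t^p[["b"]],
               p = c(a = 3000, b = 1.2)),
    Log = list(f = function(t, p) p[["a"]] + p[["b"]] * log(t),
               p = c(a = 3000, b = 12000)),
    Sin = list(f = function(t, p) p[["a"]] * sin(p[["b"]] * t + p[["c"]]) +
                 p[["d"]],
               p = c(a = 8000, b = 0.4, c = 0.5, d = 20000)))
}

growthPredict <- function(model, cf, t) {
  switch(model,
         Lin = cf[["a"]] + cf[["b"]] * t,
         Qua = cf[["a"]] + cf[["b"]] * t + cf[["c"]] * t^2,
         Exp = cf[["a"]] * exp(cf[["b"]] * t),
         Pow = cf[["a"]] * t^cf[["b"]],
         Log = cf[["a"]] + cf[["b"]] * log(t),
         Sin = cf[["a"]] * sin(cf[["b"]] * t + cf[["c"]]) + cf[["d"]])
}

# order-k Sierpinski triangle raster via the bitwise-and construction
sierpinskiMask <- function(k = 7L) {
  n <- 2L^k
  xy <- expand.grid(x = 0:(n - 1L), y = 0:(n - 1L))
  keep <- bitwAnd(xy$x, xy$y) == 0L
  m <- matrix(FALSE, n, n)
  m[cbind(xy$y[keep] + 1L, xy$x[keep] + 1L)] <- TRUE
  m
}
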