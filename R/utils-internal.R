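# Internal helpers: typed conditions, small vector algebra, seeded evaluation.

cyStop <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "cyslock_error")))
}

# Evaluate `expr` under a Mersenne-Twister stream seeded with `seed`,
# restoring the caller's RNG state afterwards. Fixture generators are pure
# functions of (seed, parameters) because of this.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    cyStop("cyslock_value_error", "seed must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max, kind = "Mersenne-Twister")
  expr
}

vnorm <- function(v) sqrt(sum(v * v))

vunit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) cyStop("cyslock_geometry_error", "cannot normalize a zero vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rotation matrix for angle `theta` (radians) about unit axis `u` (Rodrigues).
rotationMatrix <- function(u, theta) {
  ct <- cos(theta); st <- sin(theta)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3, 3, byrow = TRUE)
  diag(3) * ct + st * K + (1 - ct) * (u %o% u)
}

# Squared cross-distance matrix between row-wise coordinate matrices.
crossDist2 <- function(a, b) {
  d2 <- outer(rowSums(a * a), rowSums(b * b), "+") - 2 * (a %*% t(b))
  d2[d2 < 0] <- 0
  d2
}

extdata <- function(name) {
  p <- system.file("extdata", name, package = "cyslock")
  if (!nzchar(p)) cyStop("cyslock_value_error", "packaged file %s not found", name)
  p
}
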