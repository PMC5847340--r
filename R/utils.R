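# Small geometry and RNG helpers shared across modules.

# Cross product of two 3-vectors.
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Orthogonalization matrix (fractional -> orthogonal, angstrom) for cell
# parameters (a, b, c, alpha, beta, gamma in degrees). PDB convention:
# a along x, b in the xy plane.
cellOrthMatrix <- function(cell) {
  stopifnot(length(cell) == 6)
  a <- cell[1]; b <- cell[2]; cc <- cell[3]
  al <- cell[4] * pi / 180; be <- cell[5] * pi / 180; ga <- cell[6] * pi / 180
  v <- sqrt(1 - cos(al)^2 - cos(be)^2 - cos(ga)^2 +
              2 * cos(al) * cos(be) * cos(ga))
  matrix(c(
    a, b * cos(ga), cc * cos(be),
    0, b * sin(ga), cc * (cos(al) - cos(be) * cos(ga)) / sin(ga),
    0, 0, cc * v / sin(ga)
  ), nrow = 3, byrow = TRUE)
}

# Rotation matrix from a unit quaternion.
quatToRot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

# Uniform random rotation matrix (uses the current RNG stream).
randomRotation <- function() {
  quatToRot(stats::rnorm(4))
}

# Rotation by `angle` radians about unit axis `u` (Rodrigues).
axisRotation <- function(u, angle) {
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              nrow = 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# All pairwise distances between rows of two coordinate matrices.
crossDist <- function(a, b) {
  a <- matrix(as.numeric(a), ncol = 3)
  b <- matrix(as.numeric(b), ncol = 3)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

# Minimum distance between rows of two coordinate matrices.
minCrossDist <- function(a, b) min(crossDist(a, b))

#' @noRd
aaOne <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

aaThree <- stats::setNames(names(aaOne), aaOne)

STANDARD_AA <- unname(aaOne)

# Residues mapped to a standard parent before analysis.
NONSTANDARD_MAP <- c(MSE = "MET")

WATER_RESID <- c("HOH", "WAT", "DOD")

# Evaluate expr with pooled-calibration fallback warnings muffled (batch
# paths emit them once per run instead of once per sequence).
quietCalibrationFallback <- function(expr) {
  withCallingHandlers(expr, pipiUnseenIdentity = function(w)
    invokeRestart("muffleWarning"))
}

# Run a block of code under a private, seeded RNG stream, restoring the
# caller's stream afterwards.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  force(expr)
}
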