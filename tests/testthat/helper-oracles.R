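# Independent oracles and toy-geometry generators used across the suite.

# Quaternion-method RMSD (Horn 1987): independent of the SVD-based Kabsch
# implementation it cross-checks. The largest eigenvalue of the 4x4
# quaternion matrix gives the optimal (proper) rotation directly.
quaternion_rmsd <- function(xm, xr) {
  pm <- scale(xm, scale = FALSE)
  pr <- scale(xr, scale = FALSE)
  S <- t(pm) %*% pr
  Sxx <- S[1, 1]; Sxy <- S[1, 2]; Sxz <- S[1, 3]
  Syx <- S[2, 1]; Syy <- S[2, 2]; Syz <- S[2, 3]
  Szx <- S[3, 1]; Szy <- S[3, 2]; Szz <- S[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,        Szx - Sxz,        Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz,  Sxy + Syx,        Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz,  Syz + Szy,
    Sxy - Syx,       Szx + Sxz,        Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(0, (sum(pm^2) + sum(pr^2) - 2 * lam) / nrow(xm)))
}

# ideal alpha-helix Calpha trace: rise 1.5 A, 100 degree twist, 2.3 A radius
helix_xyz <- function(n, rise = 1.5, twist = 100, radius = 2.3) {
  k <- seq_len(n) - 1
  ang <- k * twist * pi / 180
  cbind(radius * cos(ang), radius * sin(ang), rise * k)
}

# near-linear extended chain with 3.8 A Calpha steps and a slight zigzag
# (kept off an exact line so superpositions stay well-conditioned)
extended_xyz <- function(n) {
  k <- seq_len(n) - 1
  cbind(3.8 * k * sqrt(1 - (0.3 / 3.8)^2), 0.15 * (-1)^k, 0.02 * k)
}

random_structure <- function(n, label = "rand", scale = 5) {
  ca_structure(label, seq_len(n), rep("ALA", n),
               matrix(stats::rnorm(3 * n, sd = scale), n, 3))
}

random_proper_rotation <- function() {
  q <- qr(matrix(stats::rnorm(9), 3))
  r <- qr.Q(q) %*% diag(sign(diag(qr.R(q))))
  if (det(r) < 0) r[, 1] <- -r[, 1]
  r
}

as_ca <- function(xyz, label = "s") {
  ca_structure(label, seq_len(nrow(xyz)), rep("ALA", nrow(xyz)), xyz)
}

# brute-force reference for the domain-hit filter: E-value cutoff, then
# stable ascending sort, then cap
brute_filter_hits <- function(ev, cutoff = 1e-10, cap = 5L) {
  idx <- which(ev <= cutoff)
  idx[order(ev[idx])][seq_len(min(cap, length(idx)))]
}

# brute-force column-count identity score used against score2
brute_score2 <- function(target, template) {
  tc <- strsplit(toupper(target), "")[[1]]
  mc <- strsplit(toupper(template), "")[[1]]
  hits <- 0L
  for (i in seq_along(tc))
    if (tc[i] != "-" && mc[i] != "-" && tc[i] != "X" && tc[i] == mc[i])
      hits <- hits + 1L
  10 * (1 - hits / length(tc))
}
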