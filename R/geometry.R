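vnorm <- function(v) sqrt(sum(v * v))

unit3 <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("degenerate geometry: zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# row-wise cross product for n x 3 matrices
cross3_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Build the local orthonormal frame of a residue
#'
#' The frame sits at the Calpha position. Its first axis points from
#' Calpha to the carbonyl C; the third axis is the unit cross product of
#' the first axis with the Calpha-to-N direction; the second completes a
#' right-handed basis (e2 = e3 x e1). Any fixed three-backbone-atom frame
#' works for the orientational potential as long as maps and predictions
#' share the convention; the convention is stamped into potential files.
#'
#' @param n,ca,c Numeric 3-vectors: backbone N, Calpha and C coordinates
#'   in Angstrom.
#' @return A list with `origin` (Calpha) and the right-handed orthonormal
#'   basis `e1`, `e2`, `e3`.
#' @examples
#' f <- build_frame(c(-1, 0, 0), c(0, 0, 0), c(1, 1, 0))
#' f$e1  # (1,1,0)/sqrt(2)
#' @export
build_frame <- function(n, ca, c) {
  u_c <- c - ca
  u_n <- n - ca
  if (vnorm(u_c) < 1e-9 || vnorm(u_n) < 1e-9) {
    stop("degenerate geometry: coincident backbone atoms")
  }
  e1 <- unit3(u_c)
  cr <- cross3(e1, unit3(u_n))
  if (vnorm(cr) < 1e-9) {
    stop("degenerate geometry: collinear backbone atoms")
  }
  e3 <- unit3(cr)
  e2 <- cross3(e3, e1)
  list(origin = ca, e1 = e1, e2 = e2, e3 = e3)
}

# Frames for all residues of a structure, as n x 3 matrices.
# Returns list(origin, e1, e2, e3), each n x 3.
build_frames <- function(structure) {
  res <- structure$residues
  ca <- as.matrix(res[, c("cax", "cay", "caz")])
  nn <- as.matrix(res[, c("nx", "ny", "nz")])
  cc <- as.matrix(res[, c("cx", "cy", "cz")])
  u_c <- cc - ca
  u_n <- nn - ca
  nc <- sqrt(rowSums(u_c^2))
  nn2 <- sqrt(rowSums(u_n^2))
  if (any(nc < 1e-9) || any(nn2 < 1e-9)) {
    stop("degenerate geometry: coincident backbone atoms")
  }
  e1 <- u_c / nc
  un <- u_n / nn2
  cr <- cross3_rows(e1, un)
  ncr <- sqrt(rowSums(cr^2))
  if (any(ncr < 1e-9)) stop("degenerate geometry: collinear backbone atoms")
  e3 <- cr / ncr
  e2 <- cross3_rows(e3, e1)
  dimnames(ca) <- NULL
  list(origin = ca, e1 = e1, e2 = e2, e3 = e3)
}

#' Signed dihedral angle over four points
#'
#' Standard torsion convention: the angle in (-pi, pi] between the plane
#' (p1,p2,p3) and the plane (p2,p3,p4), positive for a right-handed twist
#' about p2->p3. Invariant under reversal of the point order.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors.
#' @return Angle in radians.
#' @export
dihedral4 <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit3(b2))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

#' 6D descriptor of a residue pair
#'
#' Describes the relative placement of two residue frames by the
#' Calpha-Calpha distance `r`, per-side polar angles (`theta_i`, `phi_i`)
#' of the inter-residue direction in each local frame (the side-j angles
#' use the reversed direction), and the signed torsion `omega` of the two
#' third axes about the inter-residue axis. Swapping i and j preserves
#' `r` and `omega` and exchanges the two angle pairs.
#'
#' @param f_i,f_j Frames from [build_frame()].
#' @param seq_sep Signed residue separation (j - i) within a chain, or
#'   `NA` for an inter-chain pair.
#' @return A list with `r`, `theta_i`, `phi_i`, `theta_j`, `phi_j`,
#'   `omega`, `seq_sep`.
#' @details At the polar singularity (the inter-residue direction parallel
#'   to a frame's third axis) the azimuth of that side is set to 0 so that
#'   binning is deterministic.
#' @export
pair_descriptor <- function(f_i, f_j, seq_sep = NA_integer_) {
  dv <- f_j$origin - f_i$origin
  r <- vnorm(dv)
  if (r < 1e-9) stop("degenerate geometry: coincident frame origins")
  d <- dv / r

  ang <- function(f, dd) {
    ct <- max(-1, min(1, sum(dd * f$e3)))
    theta <- acos(ct)
    if (abs(ct) >= 1 - 1e-12) {
      phi <- 0
    } else {
      phi <- atan2(sum(dd * f$e2), sum(dd * f$e1))
    }
    c(theta, phi)
  }
  ai <- ang(f_i, d)
  aj <- ang(f_j, -d)
  omega <- dihedral4(f_i$origin + f_i$e3, f_i$origin,
                     f_j$origin, f_j$origin + f_j$e3)
  list(r = r,
       theta_i = ai[1], phi_i = ai[2],
       theta_j = aj[1], phi_j = aj[2],
       omega = omega, seq_sep = seq_sep)
}

# Vectorized descriptors for index pairs (ii, jj) into precomputed frames.
# Returns a data.frame with one row per pair.
pair_descriptors_idx <- function(frames, ii, jj, seq_sep) {
  oi <- frames$origin[ii, , drop = FALSE]
  oj <- frames$origin[jj, , drop = FALSE]
  dv <- oj - oi
  r <- sqrt(rowSums(dv^2))
  if (any(r < 1e-9)) stop("degenerate geometry: coincident frame origins")
  d <- dv / r

  side <- function(e1, e2, e3, dd) {
    ct <- pmax(-1, pmin(1, rowSums(dd * e3)))
    theta <- acos(ct)
    phi <- atan2(rowSums(dd * e2), rowSums(dd * e1))
    phi[abs(ct) >= 1 - 1e-12] <- 0
    cbind(theta, phi)
  }
  si <- side(frames$e1[ii, , drop = FALSE], frames$e2[ii, , drop = FALSE],
             frames$e3[ii, , drop = FALSE], d)
  sj <- side(frames$e1[jj, , drop = FALSE], frames$e2[jj, , drop = FALSE],
             frames$e3[jj, , drop = FALSE], -d)

  # dihedral (oi + e3i, oi, oj, oj + e3j), vectorized
  b1 <- -frames$e3[ii, , drop = FALSE]
  b2 <- dv
  b3 <- frames$e3[jj, , drop = FALSE]
  n1 <- cross3_rows(b1, b2)
  n2 <- cross3_rows(b2, b3)
  b2u <- b2 / sqrt(rowSums(b2^2))
  m1 <- cross3_rows(n1, b2u)
  omega <- atan2(rowSums(m1 * n2), rowSums(n1 * n2))

  data.frame(r = r,
             theta_i = si[, 1], phi_i = si[, 2],
             theta_j = sj[, 1], phi_j = sj[, 2],
             omega = omega, seq_sep = seq_sep)
}
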