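#' Bin geometry of the orientational potential
#'
#' Defines the discretisation of the 6D pair descriptor: `n_r` uniform
#' distance bins on `[r_min, r_max)`, `n_theta` uniform polar bins on
#' `[0, pi]` per side, `n_phi` uniform azimuth bins on `(-pi, pi]` per
#' side, and `n_omega` torsion bins on `(-pi, pi]`. All bins are
#' half-open `[lo, hi)` with the final bin closed at the top. Pairs
#' closer in sequence than `min_seq_sep` (same chain) are not counted;
#' inter-chain pairs always qualify.
#'
#' @param r_min,r_max Distance window in Angstrom.
#' @param n_r,n_theta,n_phi,n_omega Bin counts (all >= 1).
#' @param min_seq_sep Minimum |sequence separation| within a chain.
#' @return A `bin_geometry` object.
#' @export
bin_geometry <- function(r_min = 3, r_max = 16, n_r = 13,
                         n_theta = 6, n_phi = 8, n_omega = 8,
                         min_seq_sep = 2) {
  stopifnot(r_min < r_max, n_r >= 1, n_theta >= 1, n_phi >= 1,
            n_omega >= 1, min_seq_sep >= 0)
  g <- list(r_min = r_min, r_max = r_max, n_r = as.integer(n_r),
            n_theta = as.integer(n_theta), n_phi = as.integer(n_phi),
            n_omega = as.integer(n_omega),
            min_seq_sep = as.integer(min_seq_sep))
  g$n_bins <- g$n_r * g$n_theta^2 * g$n_phi^2 * g$n_omega
  class(g) <- "bin_geometry"
  g
}

#' @export
print.bin_geometry <- function(x, ...) {
  cat(sprintf(
    "<bin_geometry r [%g, %g) A x %d; theta x %d; phi x %d; omega x %d; |sep| >= %d; %d bins/pair type>\n",
    x$r_min, x$r_max, x$n_r, x$n_theta, x$n_phi, x$n_omega,
    x$min_seq_sep, x$n_bins))
  invisible(x)
}

# uniform binning on [lo, hi), final bin closed; x assumed in [lo, hi]
ubin <- function(x, lo, hi, n) {
  b <- 1L + as.integer(floor((x - lo) / (hi - lo) * n))
  pmin(b, n)
}

# Descriptor rows -> flat bin index (vectorized); NA when out of distance
# range. Assumes angles within their ranges. Canonicalization across
# amino-acid order is handled by the callers.
bin_index <- function(geom, r, theta_i, phi_i, theta_j, phi_j, omega) {
  ok <- r >= geom$r_min & r < geom$r_max
  ir <- ubin(r, geom$r_min, geom$r_max, geom$n_r)
  ti <- ubin(theta_i, 0, pi, geom$n_theta)
  tj <- ubin(theta_j, 0, pi, geom$n_theta)
  pi_ <- ubin(phi_i + pi, 0, 2 * pi, geom$n_phi)
  pj <- ubin(phi_j + pi, 0, 2 * pi, geom$n_phi)
  om <- ubin(omega + pi, 0, 2 * pi, geom$n_omega)
  sideblock <- geom$n_theta * geom$n_phi
  # layout: r fastest, then (theta_i, phi_i), (theta_j, phi_j), omega;
  # for same-aa pair types the two side tuples are ordered so the smaller
  # flat side index is side i (exchange symmetry; see count_contacts)
  idx <- ir +
    geom$n_r * ((ti - 1L) + geom$n_theta * (pi_ - 1L)) +
    geom$n_r * sideblock * ((tj - 1L) + geom$n_theta * (pj - 1L)) +
    geom$n_r * sideblock^2 * (om - 1L)
  idx[!ok] <- NA_integer_
  idx
}

# side tuple flat index (1-based), used for canonical ordering of sides
side_flat <- function(geom, theta, phi) {
  ti <- ubin(theta, 0, pi, geom$n_theta)
  pi_ <- ubin(phi + pi, 0, 2 * pi, geom$n_phi)
  (pi_ - 1L) * geom$n_theta + ti
}

# unordered amino-acid pair -> pair-type column index in 1..210
pair_type <- function(ai, bi) {
  a <- pmin(ai, bi); b <- pmax(ai, bi)
  (a - 1L) * 20L - (a - 1L) * a %/% 2L + b - a + 1L
}
N_PAIR_TYPES <- 210L

# canonical bin for one descriptor row between amino acids aa_i, aa_j
# (indices into AA_CODES). Returns list(pt, idx). Vectorized.
canonical_bins <- function(geom, ai, aj, d) {
  swap <- ai > aj
  eq <- ai == aj
  if (any(eq)) {
    si <- side_flat(geom, d$theta_i, d$phi_i)
    sj <- side_flat(geom, d$theta_j, d$phi_j)
    swap <- swap | (eq & si > sj)
  }
  ti <- ifelse(swap, d$theta_j, d$theta_i)
  pi_ <- ifelse(swap, d$phi_j, d$phi_i)
  tj <- ifelse(swap, d$theta_i, d$theta_j)
  pj <- ifelse(swap, d$phi_i, d$phi_j)
  list(pt = pair_type(ai, aj),
       idx = bin_index(geom, d$r, ti, pi_, tj, pj, d$omega))
}

#' Count binned residue-pair contacts over a structure set
#'
#' For every unordered residue pair whose Calpha distance falls in the
#' geometry's distance window and which is either inter-chain or at least
#' `min_seq_sep` apart in sequence, one count is accumulated at the
#' canonical bin: amino-acid order is fixed alphabetically, descriptors
#' are computed with the lower-sequence-position residue as side i, and
#' for same-type pairs the two side-angle bins are ordered so lookup is
#' exchange-symmetric.
#'
#' @param structures List of [new_structure()] objects (or a single one).
#' @param geom A [bin_geometry()].
#' @return A `contact_counts` object: sparse counts (`data.frame` of
#'   `pt`, `idx`, `n`), the geometry, and the `total` contact count.
#' @export
count_contacts <- function(structures, geom = bin_geometry()) {
  if (inherits(structures, "ddg_structure")) structures <- list(structures)
  acc <- list()
  total <- 0L
  for (s in structures) {
    pr <- structure_pairs(s, geom)
    if (is.null(pr)) next
    cb <- canonical_bins(geom, pr$ai, pr$aj, pr$desc)
    keep <- !is.na(cb$idx)
    if (!any(keep)) next
    acc[[length(acc) + 1L]] <- data.frame(pt = cb$pt[keep],
                                          idx = cb$idx[keep])
    total <- total + sum(keep)
  }
  if (length(acc)) {
    all <- do.call(rbind, acc)
    counts <- stats::aggregate(list(n = rep(1L, nrow(all))),
                               by = list(pt = all$pt, idx = all$idx), FUN = sum)
  } else {
    counts <- data.frame(pt = integer(), idx = integer(), n = integer())
  }
  structure(list(counts = counts, geom = geom, total = total,
                 n_structures = length(structures)),
            class = "contact_counts")
}

# enumerate qualifying pairs of one structure; returns list(ai, aj, desc)
# with descriptors computed from the lower-ordered residue as side i
structure_pairs <- function(s, geom) {
  res <- s$residues
  n <- nrow(res)
  if (n < 2L) return(NULL)
  ca <- as.matrix(res[, c("cax", "cay", "caz")])
  dm <- as.matrix(stats::dist(ca))
  pair <- which(upper.tri(dm) & dm >= geom$r_min & dm < geom$r_max,
                arr.ind = TRUE)
  if (!nrow(pair)) return(NULL)
  ii <- pair[, 1]; jj <- pair[, 2]  # ii < jj in residue order
  same_chain <- res$chain[ii] == res$chain[jj]
  # author numbering, so gaps from skipped residues keep true separations
  sep <- ifelse(same_chain, res$resno[jj] - res$resno[ii], NA_integer_)
  keep <- !same_chain | abs(sep) >= geom$min_seq_sep
  ii <- ii[keep]; jj <- jj[keep]; sep <- sep[keep]
  if (!length(ii)) return(NULL)
  frames <- build_frames(s)
  desc <- pair_descriptors_idx(frames, ii, jj, sep)
  list(ai = aa_index(res$aa[ii]), aj = aa_index(res$aa[jj]), desc = desc)
}

#' Derive the orientational potential by Boltzmann inversion
#'
#' Converts binned contact counts into energies. For each amino-acid pair
#' type, observed probabilities are the pseudo-counted bin frequencies
#' normalised over the 6D bins of that type; the reference distribution
#' pools counts over all pair types and is normalised the same way. The
#' energy is `-RT * log(P_obs / P_ref)`, in kcal/mol: geometries a pair
#' type adopts more often than the residue-blind background score
#' favourably.
#'
#' @param counts A `contact_counts` object from [count_contacts()].
#' @param rt Thermal energy RT in kcal/mol (default 0.593, T = 298 K).
#' @param pseudo Pseudo-count lambda added to every bin before
#'   normalisation (> 0 keeps energies finite with sparse statistics).
#' @return A `potential_map`: dense energy matrix `E` (`n_bins` x 210
#'   pair types), the bin geometry, `rt`, `pseudo` and provenance fields.
#' @export
derive_potential <- function(counts, rt = 0.593, pseudo = 1) {
  stopifnot(inherits(counts, "contact_counts"))
  if (rt <= 0) stop("RT must be positive")
  if (pseudo <= 0) stop("pseudo-count must be positive")
  geom <- counts$geom
  nb <- geom$n_bins
  C <- matrix(0, nrow = nb, ncol = N_PAIR_TYPES)
  if (nrow(counts$counts)) {
    C[cbind(counts$counts$idx, counts$counts$pt)] <- counts$counts$n
  }
  obs <- C + pseudo
  pobs <- sweep(obs, 2, colSums(obs), "/")
  pooled <- rowSums(C) + pseudo
  pref <- pooled / sum(pooled)
  E <- -rt * log(pobs / pref)
  structure(list(E = E, geom = geom, rt = rt, pseudo = pseudo,
                 frame_convention = "CA-C/e3=e1x(N-CA)",
                 n_structures = counts$n_structures,
                 total_contacts = as.numeric(counts$total),
                 exclusion_hash = ""),
            class = "potential_map")
}

#' @export
print.potential_map <- function(x, ...) {
  cat(sprintf(
    "<potential_map %d bins x %d pair types; RT = %g kcal/mol; lambda = %g; %g contacts from %d structures>\n",
    nrow(x$E), ncol(x$E), x$rt, x$pseudo, x$total_contacts,
    x$n_structures))
  invisible(x)
}

#' Look up pair energies in a potential map
#'
#' Returns the energy of one or more descriptors between amino-acid types
#' `aa_i` and `aa_j`. Lookup canonicalizes exactly as counting does, so
#' `energy(map, a, b, desc(i,j)) == energy(map, b, a, desc(j,i))`.
#' Descriptors outside the distance window score 0 by convention.
#'
#' @param map A `potential_map`.
#' @param aa_i,aa_j One-letter amino-acid codes (recycled to the number
#'   of descriptor rows).
#' @param desc A descriptor from [pair_descriptor()] or a `data.frame`
#'   of descriptor rows.
#' @return Numeric vector of energies in kcal/mol.
#' @export
energy <- function(map, aa_i, aa_j, desc) {
  if (!is.data.frame(desc)) desc <- as.data.frame(desc[c(
    "r", "theta_i", "phi_i", "theta_j", "phi_j", "omega")])
  nr <- nrow(desc)
  ai <- rep_len(aa_index(aa_i), nr)
  aj <- rep_len(aa_index(aa_j), nr)
  cb <- canonical_bins(map$geom, ai, aj, desc)
  e <- rep(0, nr)
  ok <- !is.na(cb$idx)
  e[ok] <- map$E[cbind(cb$idx[ok], cb$pt[ok])]
  e
}

#' Filter a structure set against a blacklist (ids and homologs)
#'
#' Removes structures whose id is blacklisted, or whose sequence falls in
#' the same homology cluster as any blacklisted sequence (clustering via
#' [cluster_families()] at the given identity cutoff). Used to keep
#' potential-derivation sets disjoint from curated mutation datasets.
#'
#' @param structures List of structures.
#' @param excluded_ids Character vector of blacklisted ids.
#' @param excluded_sequences Optional character vector of blacklisted
#'   sequences for homology screening.
#' @param identity_cutoff Sequence-identity threshold for the homology
#'   screen.
#' @return The surviving structures (same list type, order preserved).
#' @export
rebuild_exclusion <- function(structures, excluded_ids = character(),
                              excluded_sequences = character(),
                              identity_cutoff = 0.25) {
  ids <- vapply(structures, function(s) s$id, character(1))
  drop <- ids %in% excluded_ids
  if (length(excluded_sequences)) {
    seqs <- vapply(structures, structure_sequence, character(1))
    cl <- cluster_families(c(excluded_sequences, seqs),
                           identity_cutoff = identity_cutoff)
    bad_cl <- unique(cl$cluster[seq_along(excluded_sequences)])
    drop <- drop | cl$cluster[length(excluded_sequences) +
                                seq_along(structures)] %in% bad_cl
  }
  structures[!drop]
}
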