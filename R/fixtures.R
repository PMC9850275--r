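# internal-coordinate atom placement (NeRF): position D given A, B, C,
# the C-D bond length, the B-C-D angle and the A-B-C-D torsion
place_atom <- function(a, b, c, bond, angle, dihedral) {
  bc <- unit3(c - b)
  n <- unit3(cross3(b - a, bc))
  m <- cross3(n, bc)
  d <- c(-bond * cos(angle),
         bond * sin(angle) * cos(dihedral),
         -bond * sin(angle) * sin(dihedral))
  c + d[1] * bc + d[2] * m + d[3] * n
}

BB_GEOM <- list(b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329,
                a_n_ca_c = 111.2 * pi / 180,
                a_ca_c_n = 116.2 * pi / 180,
                a_c_n_ca = 121.7 * pi / 180)

#' Generate an ideal helical (or extended) backbone
#'
#' Builds an n-residue single-chain backbone with ideal bond lengths
#' (N-CA 1.458, CA-C 1.525, C-N 1.329 Angstrom), ideal bond angles and
#' the template dihedrals: alpha-helix phi = -57, psi = -47 degrees
#' (consecutive Calpha separations near 3.8 Angstrom) or extended
#' phi = -139, psi = 135. Optional Gaussian jitter of every coordinate
#' emulates imperfect real geometry. Deterministic given `seed`.
#'
#' @param n_residues Chain length (>= 3).
#' @param sequence One-letter sequence of length `n_residues`; `NULL`
#'   draws a random sequence over the 20 amino acids.
#' @param coord_noise Standard deviation (Angstrom) of i.i.d. Gaussian
#'   coordinate jitter.
#' @param seed Integer seed (sequence and jitter).
#' @param template `"helix"` or `"extended"`.
#' @param id,chain Structure id and chain letter.
#' @return A [new_structure()] object.
#' @export
make_helix <- function(n_residues, sequence = NULL, coord_noise = 0,
                       seed = 1L, template = c("helix", "extended"),
                       id = "HLX1", chain = "A") {
  template <- match.arg(template)
  if (n_residues < 3L) stop("need at least 3 residues")
  set.seed(seed)
  if (is.null(sequence)) {
    sequence <- paste0(sample(AA_CODES, n_residues, replace = TRUE),
                       collapse = "")
  }
  aa <- strsplit(sequence, "")[[1]]
  if (length(aa) != n_residues) stop("sequence length != n_residues")
  if (!all(is_canonical_aa(aa))) stop("non-canonical letters in sequence")
  tors <- switch(template,
                 helix = c(phi = -57, psi = -47) * pi / 180,
                 extended = c(phi = -139, psi = 135) * pi / 180)
  omega <- pi
  g <- BB_GEOM
  N <- matrix(0, n_residues, 3)
  CA <- matrix(0, n_residues, 3)
  C <- matrix(0, n_residues, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_n_ca, 0, 0)
  C[1, ] <- CA[1, ] + g$b_ca_c *
    c(-cos(g$a_n_ca_c), sin(g$a_n_ca_c), 0)
  for (i in seq_len(n_residues - 1L)) {
    N[i + 1, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                             g$b_c_n, g$a_ca_c_n, tors["psi"])
    CA[i + 1, ] <- place_atom(CA[i, ], C[i, ], N[i + 1, ],
                              g$b_n_ca, g$a_c_n_ca, omega)
    C[i + 1, ] <- place_atom(C[i, ], N[i + 1, ], CA[i + 1, ],
                             g$b_ca_c, g$a_n_ca_c, tors["phi"])
  }
  if (coord_noise > 0) {
    jitter <- function(m) m + matrix(stats::rnorm(length(m), 0, coord_noise),
                                     nrow(m), 3)
    N <- jitter(N); CA <- jitter(CA); C <- jitter(C)
  }
  residues <- data.frame(chain = chain, resno = seq_len(n_residues),
                         ins = "", aa = aa,
                         nx = N[, 1], ny = N[, 2], nz = N[, 3],
                         cax = CA[, 1], cay = CA[, 2], caz = CA[, 3],
                         cx = C[, 1], cy = C[, 2], cz = C[, 3],
                         stringsAsFactors = FALSE)
  new_structure(id = id, residues = residues, oligomeric_state = "monomer",
                resolution = 1.5)
}

#' Synthetic potential map
#'
#' Either derives a map from a generated set of jittered helices through
#' the real counting/inversion path (`mode = "derived"`), or fills the
#' energy tensor with seeded Gaussian values of controlled magnitude
#' (`mode = "random"`; magnitude 0 gives the zero potential). Both are
#' finite everywhere and deterministic per seed.
#'
#' @param seed Integer seed.
#' @param geom A [bin_geometry()].
#' @param mode `"derived"` or `"random"`.
#' @param n_structures Helices to generate in derived mode.
#' @param n_residues Residues per helix in derived mode.
#' @param magnitude Energy scale (kcal/mol) in random mode.
#' @return A `potential_map`.
#' @export
make_synthetic_potential <- function(seed = 1L, geom = bin_geometry(),
                                     mode = c("derived", "random"),
                                     n_structures = 5L, n_residues = 30L,
                                     magnitude = 1) {
  mode <- match.arg(mode)
  if (mode == "derived") {
    helices <- lapply(seq_len(n_structures), function(i) {
      make_helix(n_residues, coord_noise = 0.3, seed = seed * 1000L + i,
                 id = sprintf("SYN%d", i))
    })
    return(derive_potential(count_contacts(helices, geom)))
  }
  set.seed(seed)
  E <- matrix(stats::rnorm(geom$n_bins * N_PAIR_TYPES, 0, magnitude),
              nrow = geom$n_bins, ncol = N_PAIR_TYPES)
  structure(list(E = E, geom = geom, rt = 0.593, pseudo = 1,
                 frame_convention = "CA-C/e3=e1x(N-CA)",
                 n_structures = 0L, total_contacts = 0,
                 exclusion_hash = ""),
            class = "potential_map")
}

#' Synthetic mutation dataset with known ground truth
#'
#' Samples point mutations uniformly over (structure, scoreable site,
#' mutant type != wild type) and sets each experimental ddG to the
#' model's own prediction under `true_weights` plus Gaussian noise —
#' synthetic data FROM the model, for parameter-recovery testing of the
#' fitting machinery, not for biological realism. Sites with empty
#' contact sets are skipped (they carry no signal by construction).
#' Records get standard conditions (25 C, pH 7) and one family id per
#' structure. Deterministic per seed.
#'
#' @param structures List of structures.
#' @param true_weights A [weight_set()]: the ground truth.
#' @param map A `potential_map`.
#' @param n_mutations Number of records to generate.
#' @param noise_sd Gaussian ddG noise sigma in kcal/mol.
#' @param seed Integer seed.
#' @return Mutation records (`data.frame` as in
#'   [read_mutation_table()]) with extra column `ddg_true` (the
#'   noise-free value); attribute `"true_weights"` carries the ground
#'   truth.
#' @export
make_synthetic_ddg <- function(structures, true_weights, map,
                               n_mutations = 500L, noise_sd = 0,
                               seed = 1L) {
  if (inherits(structures, "ddg_structure")) structures <- list(structures)
  # scoreable sites: non-empty contact set under the map's geometry
  sites <- list()
  for (si in seq_along(structures)) {
    s <- structures[[si]]
    for (ri in seq_len(nrow(s$residues))) {
      cs <- contacts_of(s, s$residues$chain[ri], s$residues$resno[ri],
                        s$residues$ins[ri], geom = map$geom)
      if (length(cs$contacts) > 0L) {
        sites[[length(sites) + 1L]] <- c(si, ri)
      }
    }
  }
  if (!length(sites)) stop("no scoreable sites in the structure set")
  sites <- do.call(rbind, sites)
  set.seed(seed)
  pick_site <- sample(nrow(sites), n_mutations, replace = TRUE)
  recs <- vector("list", n_mutations)
  noise <- stats::rnorm(n_mutations, 0, noise_sd)
  for (m in seq_len(n_mutations)) {
    si <- sites[pick_site[m], 1]; ri <- sites[pick_site[m], 2]
    s <- structures[[si]]
    wt <- s$residues$aa[ri]
    mut <- sample(setdiff(AA_CODES, wt), 1L)
    p <- predict_ddg(s, s$residues$chain[ri], s$residues$resno[ri],
                     wt, mut, true_weights, map, ins = s$residues$ins[ri])
    recs[[m]] <- data.frame(
      id = s$id, chain = s$residues$chain[ri],
      resno = s$residues$resno[ri], ins = s$residues$ins[ri],
      wt = wt, mut = mut,
      ddg = p$ddg + noise[m],
      temp = 25, pH = 7,
      is_interface = FALSE, near_ligand = FALSE,
      family = sprintf("fam_%s", s$id),
      ddg_true = p$ddg,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  attr(out, "true_weights") <- true_weights
  out
}
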