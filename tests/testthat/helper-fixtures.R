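# shared desk-scale fixtures

# small bin geometry keeping tensors tiny
toy_geom <- function(...) {
  bin_geometry(n_theta = 3, n_phi = 4, n_omega = 4, ...)
}

# a reproducible set of jittered helices keyed by id
toy_helices <- function(n = 5L, len = 30L, noise = 0.25, seed = 100L) {
  hs <- lapply(seq_len(n), function(i) {
    make_helix(len, coord_noise = noise, seed = seed + i,
               id = sprintf("FIX%d", i))
  })
  names(hs) <- vapply(hs, function(s) s$id, character(1))
  hs
}

toy_true_weights <- function() {
  weight_set(c(1.2, 0.8, 1.7, 1.0, 1.4, 2.2, 0.7, 1.9, 1.1, 2.5, 1.5, 0.9))
}

# minimal hand-written 3-residue PDB text (full backbones)
toy_pdb_lines <- function() {
  c("REMARK   2 RESOLUTION.    1.80 ANGSTROMS.",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00",
    "ATOM      3  C   ALA A   1       2.009   1.421   0.000  1.00  0.00",
    "ATOM      4  N   GLY A   2       3.332   1.536   0.000  1.00  0.00",
    "ATOM      5  CA  GLY A   2       4.122   2.743   0.214  1.00  0.00",
    "ATOM      6  C   GLY A   2       5.571   2.420   0.553  1.00  0.00",
    "ATOM      7  N   VAL A   3       6.441   3.414   0.402  1.00  0.00",
    "ATOM      8  CA  VAL A   3       7.866   3.276   0.688  1.00  0.00",
    "ATOM      9  C   VAL A   3       8.602   4.590   0.456  1.00  0.00",
    "END")
}

write_toy_pdb <- function(lines = toy_pdb_lines()) {
  path <- withr::local_tempfile(fileext = ".pdb",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# random valid frame from a seeded jittered residue
random_frame <- function() {
  repeat {
    n <- stats::rnorm(3)
    ca <- stats::rnorm(3, sd = 3)
    c_ <- ca + stats::rnorm(3)
    ok <- tryCatch({
      f <- build_frame(ca + n, ca, c_)
      return(f)
    }, error = function(e) NULL)
  }
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

transform_frame <- function(f, R, t = c(0, 0, 0)) {
  list(origin = as.numeric(R %*% f$origin + t),
       e1 = as.numeric(R %*% f$e1),
       e2 = as.numeric(R %*% f$e2),
       e3 = as.numeric(R %*% f$e3))
}

# record table builder for curation tests
mut_rec <- function(id = "1ABC", chain = "A", resno = 1L, ins = "",
                    wt = "A", mut = "G", ddg = -1, temp = 25, pH = 7,
                    family = "f1") {
  data.frame(id = id, chain = chain, resno = resno, ins = ins,
             wt = wt, mut = mut, ddg = ddg, temp = temp, pH = pH,
             is_interface = FALSE, near_ligand = FALSE, family = family,
             stringsAsFactors = FALSE)
}

mut_recs <- function(...) {
  do.call(rbind, list(...))
}
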