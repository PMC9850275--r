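#' Construct a backbone structure object
#'
#' A `ddg_structure` holds, per retained residue, the chain, author residue
#' number, insertion code, one-letter amino-acid type and the N / Calpha /
#' C backbone coordinates, plus any HETATM heavy atoms (for
#' ligand-proximity screening), the crystallographic resolution and an
#' oligomeric-state annotation. Residues are kept strictly ordered by
#' (chain, residue number, insertion code).
#'
#' @param id Structure identifier (e.g. a PDB code).
#' @param residues `data.frame` with columns `chain`, `resno`, `ins`,
#'   `aa`, `nx`,`ny`,`nz`, `cax`,`cay`,`caz`, `cx`,`cy`,`cz`.
#' @param het Optional `data.frame` of heteroatom heavy atoms with columns
#'   `elem`, `x`, `y`, `z`, `group` (het-group id); waters excluded.
#' @param resolution Resolution in Angstrom, or `NA`.
#' @param oligomeric_state `"monomer"`, `"oligomer"` or `"unknown"`.
#' @param skipped `data.frame` describing residues dropped at parse time
#'   (incomplete backbone, non-canonical type), with columns `chain`,
#'   `resno`, `ins`, `resid`, `reason`.
#' @return An object of class `ddg_structure`.
#' @export
new_structure <- function(id, residues, het = NULL, resolution = NA_real_,
                          oligomeric_state = c("unknown", "monomer", "oligomer"),
                          skipped = NULL) {
  oligomeric_state <- match.arg(oligomeric_state)
  stopifnot(is.data.frame(residues))
  need <- c("chain", "resno", "ins", "aa",
            "nx", "ny", "nz", "cax", "cay", "caz", "cx", "cy", "cz")
  miss <- setdiff(need, names(residues))
  if (length(miss)) stop("residues lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(residues)) {
    if (!all(is_canonical_aa(residues$aa))) {
      stop("non-canonical amino acid in residue table")
    }
    coords <- as.matrix(residues[, need[5:13]])
    if (!all(is.finite(coords))) stop("non-finite backbone coordinates")
    o <- order(residues$chain, residues$resno, residues$ins)
    residues <- residues[o, , drop = FALSE]
    rownames(residues) <- NULL
  }
  if (is.null(het)) {
    het <- data.frame(elem = character(), x = numeric(), y = numeric(),
                      z = numeric(), group = character())
  }
  if (is.null(skipped)) {
    skipped <- data.frame(chain = character(), resno = integer(),
                          ins = character(), resid = character(),
                          reason = character())
  }
  structure(list(id = id, residues = residues, het = het,
                 resolution = resolution,
                 oligomeric_state = oligomeric_state,
                 skipped = skipped),
            class = "ddg_structure")
}

#' @export
print.ddg_structure <- function(x, ...) {
  cat(sprintf("<ddg_structure %s: %d residues, %d chains, %d het atoms",
              x$id, nrow(x$residues), length(unique(x$residues$chain)),
              nrow(x$het)))
  if (!is.na(x$resolution)) cat(sprintf(", %.2f A", x$resolution))
  cat(sprintf(", %s>\n", x$oligomeric_state))
  if (nrow(x$skipped)) {
    cat(sprintf("  %d residue(s) skipped at parse time\n", nrow(x$skipped)))
  }
  invisible(x)
}

#' Number of retained residues
#' @param x A `ddg_structure`.
#' @export
n_residues <- function(x) nrow(x$residues)

# resolve an author-numbered site to a residue row index; NA if absent
resolve_site <- function(structure, chain, resno, ins = "") {
  res <- structure$residues
  w <- which(res$chain == chain & res$resno == resno & res$ins == ins)
  if (length(w) == 1L) w else NA_integer_
}

# one-letter sequence of a chain (or whole structure in residue order)
structure_sequence <- function(structure, chain = NULL) {
  res <- structure$residues
  if (!is.null(chain)) res <- res[res$chain == chain, , drop = FALSE]
  paste0(res$aa, collapse = "")
}

#' Read a protein backbone structure from a PDB file
#'
#' Parses a PDB file (via bio3d) and retains, for the requested model and
#' chains, every canonical residue whose N, Calpha and C atoms are all
#' present with finite coordinates. Residues failing that test are not
#' silently dropped: they are listed in the returned object's `skipped`
#' table with a reason. For alternate conformations the highest-occupancy
#' altloc is kept (ties broken towards altloc "A"). HETATM heavy atoms are
#' retained for ligand-proximity screening; waters and hydrogens are
#' excluded. The resolution is taken from the REMARK 2 record when
#' present.
#'
#' @param path Path to a PDB file.
#' @param model Model number (1-based) for multi-model files.
#' @param chains Optional character vector restricting parsing to these
#'   chain identifiers.
#' @param oligomeric_state Oligomeric-state annotation to attach
#'   (`"unknown"`, `"monomer"` or `"oligomer"`); biological-assembly
#'   judgement is upstream metadata, not recomputed here.
#' @return A [new_structure()] object.
#' @export
read_structure <- function(path, model = 1L, chains = NULL,
                           oligomeric_state = "unknown") {
  if (!file.exists(path)) stop("cannot read structure: no such file: ", path)
  pdb <- tryCatch(
    withCallingHandlers(
      # rm.alt=FALSE: altloc selection (highest occupancy, tie to A) is
      # done here, not by dropping everything but conformer A
      bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE),
      # altloc-bearing entries legitimately repeat serial numbers
      warning = function(w) {
        if (grepl("duplicated element numbers", conditionMessage(w)))
          invokeRestart("muffleWarning")
      }),
    error = function(e) stop("PDB parse error in ", path, ": ",
                             conditionMessage(e)))
  at <- pdb$atom
  nmodel <- max(1L, nrow(pdb$xyz))
  if (model < 1L || model > nmodel) {
    stop(sprintf("model %d requested but file has %d model(s)", model, nmodel))
  }
  if (model > 1L) {
    xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  }
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  if (!is.null(chains)) at <- at[at$chain %in% chains, , drop = FALSE]

  prot <- at[at$type == "ATOM", , drop = FALSE]
  # altloc: keep highest occupancy, tie -> 'A' (then first)
  if (any(prot$alt != "")) {
    key <- paste(prot$chain, prot$resno, prot$insert, prot$elety, sep = "|")
    occ <- ifelse(is.na(prot$o), 1, prot$o)
    pref <- order(key, -occ, prot$alt != "A", prot$alt)
    prot <- prot[pref, , drop = FALSE]
    prot <- prot[!duplicated(paste(prot$chain, prot$resno, prot$insert,
                                   prot$elety, sep = "|")), , drop = FALSE]
  }

  rk <- paste(prot$chain, prot$resno, prot$insert, sep = "|")
  ures <- !duplicated(rk)
  keys <- rk[ures]
  meta <- prot[ures, c("chain", "resno", "insert", "resid")]

  pick <- function(elety) {
    idx <- match(paste(keys, elety, sep = "|"),
                 paste(rk, prot$elety, sep = "|"))
    cbind(prot$x[idx], prot$y[idx], prot$z[idx])
  }
  N <- pick("N"); CA <- pick("CA"); C <- pick("C")
  aa1 <- unname(AA_THREE[meta$resid])

  bad_aa <- is.na(aa1)
  bad_bb <- !bad_aa & (rowSums(is.na(cbind(N, CA, C))) > 0 |
                         !is.finite(rowSums(cbind(N, CA, C))))
  keep <- !bad_aa & !bad_bb

  skipped <- data.frame(
    chain = meta$chain[!keep], resno = meta$resno[!keep],
    ins = meta$insert[!keep], resid = meta$resid[!keep],
    reason = ifelse(bad_aa[!keep], "non-canonical residue",
                    "incomplete backbone"),
    stringsAsFactors = FALSE)
  if (any(bad_aa)) {
    warning(sum(bad_aa), " non-canonical residue(s) rejected in ", path)
  }

  residues <- data.frame(
    chain = meta$chain[keep], resno = meta$resno[keep],
    ins = meta$insert[keep], aa = aa1[keep],
    nx = N[keep, 1], ny = N[keep, 2], nz = N[keep, 3],
    cax = CA[keep, 1], cay = CA[keep, 2], caz = CA[keep, 3],
    cx = C[keep, 1], cy = C[keep, 2], cz = C[keep, 3],
    stringsAsFactors = FALSE)
  if (nrow(residues) == 0L) {
    stop("empty structure: no backbone-complete residues in ", path)
  }

  het <- at[at$type == "HETATM" & !(at$resid %in% c("HOH", "DOD", "WAT")) &
              !(at$elesy %in% c("H", "D")), , drop = FALSE]
  het_df <- data.frame(elem = het$elesy,
                       x = het$x, y = het$y, z = het$z,
                       group = paste(het$resid, het$chain, het$resno,
                                     sep = "_"),
                       stringsAsFactors = FALSE)

  id <- sub("\\.(pdb|ent)(\\.gz)?$", "", basename(path))
  new_structure(id = id, residues = residues, het = het_df,
                resolution = parse_resolution(path),
                oligomeric_state = oligomeric_state,
                skipped = skipped)
}

parse_resolution <- function(path) {
  ln <- tryCatch(readLines(path, n = 2000L, warn = FALSE),
                 error = function(e) character())
  rl <- grep("^REMARK   2 RESOLUTION", ln, value = TRUE)
  if (!length(rl)) return(NA_real_)
  m <- regmatches(rl[1], regexpr("[0-9]+\\.[0-9]+", rl[1]))
  if (!length(m)) NA_real_ else as.numeric(m)
}

#' Write a backbone structure as minimal PDB text
#'
#' Fixture-quality PDB writing: ATOM records for N, CA, C of every
#' residue (3-decimal coordinates), HETATM records for stored heavy
#' atoms, and a REMARK 2 resolution line when known. Intended for tests
#' and synthetic fixtures, not full-fidelity archiving.
#'
#' @param structure A `ddg_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  res <- structure$residues
  aa3 <- names(AA_THREE)[match(res$aa, AA_THREE)]
  lines <- character()
  if (!is.na(structure$resolution)) {
    lines <- c(lines, sprintf(
      "REMARK   2 RESOLUTION.    %.2f ANGSTROMS.", structure$resolution))
  }
  serial <- 0L
  fmt <- function(serial, name, resid, chain, resno, ins, x, y, z) {
    sprintf("ATOM  %5d  %-3s%4s %1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00",
            serial, name, resid, chain, resno,
            ifelse(ins == "", " ", ins), x, y, z)
  }
  for (i in seq_len(nrow(res))) {
    for (atom in c("N", "CA", "C")) {
      serial <- serial + 1L
      xyz <- switch(atom,
                    N = c(res$nx[i], res$ny[i], res$nz[i]),
                    CA = c(res$cax[i], res$cay[i], res$caz[i]),
                    C = c(res$cx[i], res$cy[i], res$cz[i]))
      lines <- c(lines, fmt(serial, atom, aa3[i], res$chain[i],
                            res$resno[i], res$ins[i], xyz[1], xyz[2], xyz[3]))
    }
  }
  if (nrow(structure$het)) {
    for (i in seq_len(nrow(structure$het))) {
      serial <- serial + 1L
      h <- structure$het[i, ]
      lines <- c(lines, sprintf(
        "HETATM%5d %-4s LIG L%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        serial, h$elem, 1L, h$x, h$y, h$z, h$elem))
    }
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}
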