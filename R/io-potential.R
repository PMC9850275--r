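POTENTIAL_FORMAT_VERSION <- 1L

#' Write / read a potential map
#'
#' Self-describing text container: a versioned header records the frame
#' convention, RT, pseudo-count, full bin geometry and provenance, then
#' the energy tensor follows in column order, one pair type per line.
#' Numbers are serialised with 17 significant digits, so a write/read
#' round trip reproduces every IEEE double bit-exactly. The bin geometry
#' travels with the energies because the tensor is meaningless without
#' it.
#'
#' @param map A `potential_map` from [derive_potential()].
#' @param path Output path.
#' @return `path` invisibly (`write_potential`); a `potential_map`
#'   (`read_potential`).
#' @export
write_potential <- function(map, path) {
  stopifnot(inherits(map, "potential_map"))
  if (!all(is.finite(map$E))) {
    stop("refusing to write potential with non-finite energies")
  }
  g <- map$geom
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ORIENTPOT %d", POTENTIAL_FORMAT_VERSION),
    sprintf("frame %s", map$frame_convention),
    sprintf("rt %.17g", map$rt),
    sprintf("pseudo %.17g", map$pseudo),
    sprintf("bins %.17g %.17g %d %d %d %d %d",
            g$r_min, g$r_max, g$n_r, g$n_theta, g$n_phi, g$n_omega,
            g$min_seq_sep),
    sprintf("provenance %d %.17g %s", map$n_structures,
            map$total_contacts,
            if (nzchar(map$exclusion_hash)) map$exclusion_hash else "-"),
    sprintf("tensor %d %d", nrow(map$E), ncol(map$E))), con)
  for (j in seq_len(ncol(map$E))) {
    writeLines(paste(sprintf("%.17g", map$E[, j]), collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_potential
#' @export
read_potential <- function(path) {
  ln <- readLines(path, warn = FALSE)
  if (!length(ln) || !grepl("^ORIENTPOT ", ln[1])) {
    stop("incompatible potential file: missing ORIENTPOT header")
  }
  ver <- as.integer(sub("^ORIENTPOT ", "", ln[1]))
  if (is.na(ver) || ver != POTENTIAL_FORMAT_VERSION) {
    stop("incompatible potential file: version ", ln[1])
  }
  field <- function(key) {
    hit <- grep(paste0("^", key, " "), ln, value = TRUE)
    if (!length(hit)) stop("incompatible potential file: missing '", key, "'")
    sub(paste0("^", key, " "), "", hit[1])
  }
  frame_convention <- field("frame")
  rt <- as.numeric(field("rt"))
  pseudo <- as.numeric(field("pseudo"))
  b <- strsplit(field("bins"), " ")[[1]]
  geom <- bin_geometry(r_min = as.numeric(b[1]), r_max = as.numeric(b[2]),
                       n_r = as.integer(b[3]), n_theta = as.integer(b[4]),
                       n_phi = as.integer(b[5]), n_omega = as.integer(b[6]),
                       min_seq_sep = as.integer(b[7]))
  prov <- strsplit(field("provenance"), " ")[[1]]
  tz <- as.integer(strsplit(field("tensor"), " ")[[1]])
  first <- grep("^tensor ", ln)[1] + 1L
  rows <- ln[first:length(ln)]
  rows <- rows[nzchar(rows)]
  if (length(rows) != tz[2]) {
    stop("incompatible potential file: truncated tensor (", length(rows),
         " of ", tz[2], " pair types)")
  }
  E <- matrix(NA_real_, nrow = tz[1], ncol = tz[2])
  for (j in seq_len(tz[2])) {
    v <- as.numeric(strsplit(rows[j], " ")[[1]])
    if (length(v) != tz[1]) {
      stop("incompatible potential file: truncated tensor row ", j)
    }
    E[, j] <- v
  }
  if (nrow(E) != geom$n_bins) {
    stop("incompatible potential file: tensor/geometry size mismatch")
  }
  structure(list(E = E, geom = geom, rt = rt, pseudo = pseudo,
                 frame_convention = frame_convention,
                 n_structures = as.integer(prov[1]),
                 total_contacts = as.numeric(prov[2]),
                 exclusion_hash = if (prov[3] == "-") "" else prov[3]),
            class = "potential_map")
}
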