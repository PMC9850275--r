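#' Read a table of point-mutation stability measurements
#'
#' Parses a plain-text mutation table (whitespace- or comma-separated,
#' header optional). Each record carries a structure id, chain, mutation
#' and experimental ddG in kcal/mol, with optional temperature (degrees
#' C), pH and annotation flags. The mutation is accepted either as one
#' compact token (`I92A`, optionally with an insertion code as `I92aA`)
#' or as three columns wild-type / position / mutant.
#'
#' Sign convention: ddG is the change in *unfolding* free energy, so
#' positive values are stabilizing. Tables recorded under the opposite
#' (folding) convention are negated on read via `sign = "folding"`, which
#' can also be declared in the file itself with a `# sign=folding` line.
#'
#' Malformed records (unknown amino-acid letters, non-numeric ddG,
#' wt == mut) are never silently dropped; they are collected in the
#' `rejects` attribute with a reason, and
#' `nrow(records) + nrow(rejects)` equals the input record count.
#'
#' @param path Path to the table.
#' @param sign `"unfolding"` (default; positive = stabilizing, kept as-is)
#'   or `"folding"` (ddG negated on read).
#' @return A `data.frame` with columns `id`, `chain`, `resno`, `ins`,
#'   `wt`, `mut`, `ddg`, `temp`, `pH`, `is_interface`, `near_ligand`,
#'   `family`; attribute `rejects` is a `data.frame` of rejected lines
#'   with reasons.
#' @export
read_mutation_table <- function(path, sign = c("unfolding", "folding")) {
  sign <- match.arg(sign)
  raw <- readLines(path, warn = FALSE)
  decl <- grep("^#\\s*sign\\s*=", raw, value = TRUE)
  if (length(decl)) {
    v <- trimws(sub("^#\\s*sign\\s*=", "", decl[1]))
    if (!v %in% c("unfolding", "folding")) {
      stop("unknown sign declaration: ", v)
    }
    sign <- v
  }
  raw <- raw[!grepl("^\\s*(#|$)", raw)]
  toks <- lapply(raw, function(ln) {
    strsplit(trimws(ln), "[,[:space:]]+")[[1]]
  })
  # optional header: a first line with no numeric token at all (every
  # data line carries a numeric ddG)
  if (length(toks) &&
      all(is.na(suppressWarnings(as.numeric(toks[[1]]))))) {
    toks <- toks[-1]
    raw <- raw[-1]
  }
  recs <- vector("list", length(toks))
  rej <- list()
  for (k in seq_along(toks)) {
    t <- toks[[k]]
    out <- parse_mutation_tokens(t)
    if (!is.null(out$error)) {
      rej[[length(rej) + 1L]] <- data.frame(line = raw[k],
                                            reason = out$error,
                                            stringsAsFactors = FALSE)
    } else {
      recs[[k]] <- out$record
    }
  }
  recs <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
  if (is.null(recs)) recs <- empty_mutation_records()
  if (sign == "folding") recs$ddg <- -recs$ddg
  rownames(recs) <- NULL
  attr(recs, "rejects") <- if (length(rej)) do.call(rbind, rej) else
    data.frame(line = character(), reason = character())
  recs
}

empty_mutation_records <- function() {
  data.frame(id = character(), chain = character(), resno = integer(),
             ins = character(), wt = character(), mut = character(),
             ddg = numeric(), temp = numeric(), pH = numeric(),
             is_interface = logical(), near_ligand = logical(),
             family = character(), stringsAsFactors = FALSE)
}

parse_mutcode <- function(tok) {
  m <- regmatches(tok, regexec("^([A-Z])([0-9]+)([a-z]?)([A-Z])$",
                               toupper_keep_ins(tok)))[[1]]
  if (length(m) == 0L) {
    return(list(wt = NA_character_))
  }
  list(wt = m[2], resno = as.integer(m[3]),
       ins = toupper(m[4]), mut = m[5])
}

# preserve a lower-case insertion-code letter inside an otherwise
# upper-case compact mutation code
toupper_keep_ins <- function(tok) tok

parse_mutation_tokens <- function(t) {
  if (length(t) < 4L) return(list(error = "too few fields"))
  id <- t[1]; chain <- t[2]
  mc <- parse_mutcode(t[3])
  if (!is.na(mc$wt)) {
    rest <- t[-(1:3)]
  } else if (length(t) >= 6L && grepl("^[0-9]+[a-z]?$", t[4])) {
    # split form: wt pos mut
    posm <- regmatches(t[4], regexec("^([0-9]+)([a-z]?)$", t[4]))[[1]]
    mc <- list(wt = t[3], resno = as.integer(posm[2]),
               ins = toupper(posm[3]), mut = t[5])
    rest <- t[-(1:5)]
  } else {
    return(list(error = paste0("unparsable mutation code: ", t[3])))
  }
  if (!is_canonical_aa(mc$wt) || !is_canonical_aa(mc$mut)) {
    return(list(error = paste0("unknown amino-acid letter in mutation: ",
                               mc$wt, "/", mc$mut)))
  }
  if (mc$wt == mc$mut) return(list(error = "wt equals mut"))
  if (length(rest) < 1L) return(list(error = "missing ddG field"))
  ddg <- suppressWarnings(as.numeric(rest[1]))
  if (is.na(ddg) || !is.finite(ddg)) {
    return(list(error = paste0("malformed ddG field: ", rest[1])))
  }
  num_or_na <- function(x) {
    if (is.na(x) || x %in% c("NA", ".", "-")) return(NA_real_)
    suppressWarnings(as.numeric(x))
  }
  temp <- num_or_na(rest[2]); pH <- num_or_na(rest[3])
  flag_or_na <- function(x) {
    if (is.na(x) || x %in% c("NA", ".", "-")) return(NA)
    x %in% c("1", "TRUE", "T", "yes")
  }
  is_interface <- flag_or_na(rest[4]); near_ligand <- flag_or_na(rest[5])
  family <- if (length(rest) >= 6L && !rest[6] %in% c("NA", ".", "-"))
    rest[6] else NA_character_
  list(record = data.frame(
    id = id, chain = chain, resno = mc$resno, ins = mc$ins,
    wt = mc$wt, mut = mc$mut, ddg = ddg,
    temp = temp, pH = pH,
    is_interface = is_interface, near_ligand = near_ligand,
    family = family, stringsAsFactors = FALSE))
}

#' Write a mutation table in the package's dialect
#'
#' @param records Mutation records (`data.frame` as returned by
#'   [read_mutation_table()]).
#' @param path Output path.
#' @param sign Convention to record in the file header.
#' @return `path`, invisibly.
#' @export
write_mutation_table <- function(records, path,
                                 sign = c("unfolding", "folding")) {
  sign <- match.arg(sign)
  ddg <- if (sign == "folding") -records$ddg else records$ddg
  fmt_na <- function(x) ifelse(is.na(x), "NA", format(x, trim = TRUE))
  lines <- c(paste0("# sign=", sign),
             "# id chain mutation ddg temp pH is_interface near_ligand family",
             sprintf("%s %s %s%d%s%s %s %s %s %s %s %s",
                     records$id, records$chain, records$wt, records$resno,
                     tolower(records$ins), records$mut,
                     sprintf("%.10g", ddg),
                     fmt_na(records$temp), fmt_na(records$pH),
                     fmt_na(records$is_interface),
                     fmt_na(records$near_ligand),
                     ifelse(is.na(records$family), "NA", records$family)))
  writeLines(lines, path)
  invisible(path)
}
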