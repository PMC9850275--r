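curation_stage <- function(name, records, keep, reason) {
  removed <- records[!keep, , drop = FALSE]
  removed$reason <- if (nrow(removed)) reason[!keep] else character()
  list(stage = name, input = nrow(records), removed = nrow(removed),
       surviving = sum(keep), removed_records = removed)
}

#' Experimental-condition window filter
#'
#' Keeps measurements taken between 10 and 40 degrees C and pH 5 to 9
#' (both windows inclusive), dropping extreme-condition experiments.
#' Records missing either value are dropped by default (`missing =
#' "drop"`) or retained with `missing = "keep"`.
#'
#' @param records Mutation records.
#' @param t_range,ph_range Inclusive windows.
#' @param missing `"drop"` or `"keep"` records with missing T or pH.
#' @return Surviving records; attribute `"stage"` holds the bookkeeping
#'   (input, removed, surviving, per-record reasons).
#' @export
filter_conditions <- function(records, t_range = c(10, 40),
                              ph_range = c(5, 9),
                              missing = c("drop", "keep")) {
  missing <- match.arg(missing)
  has <- !is.na(records$temp) & !is.na(records$pH)
  in_t <- !is.na(records$temp) & records$temp >= t_range[1] &
    records$temp <= t_range[2]
  in_ph <- !is.na(records$pH) & records$pH >= ph_range[1] &
    records$pH <= ph_range[2]
  keep <- ifelse(has, in_t & in_ph, missing == "keep")
  reason <- ifelse(!has, "missing conditions",
                   ifelse(!in_t, "temperature window", "pH window"))
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "stage") <- curation_stage("conditions", records, keep, reason)
  out
}

# normalized distance to standard conditions (25 C, pH 7); the window
# half-widths (15 C, 2 pH units) make the two axes commensurate
standard_conditions_distance <- function(temp, pH) {
  d <- abs(temp - 25) / 15 + abs(pH - 7) / 2
  d[is.na(temp) | is.na(pH)] <- Inf
  d
}

#' Merge replicate measurements of the same mutation
#'
#' Groups records by (structure id, chain, position, wt, mut). Groups
#' whose mean absolute pairwise ddG difference exceeds `max_spread`
#' kcal/mol are excluded entirely (irreconcilable replicates); otherwise
#' the single record closest to standard conditions (25 C, pH 7, under a
#' normalised L1 distance) is kept. Ties break to the first record in
#' input order; records with missing conditions are only chosen when no
#' replicate has complete conditions.
#'
#' @param records Mutation records.
#' @param max_spread Exclusion threshold on the mean absolute pairwise
#'   ddG difference (kcal/mol).
#' @return Surviving records with a `"stage"` attribute.
#' @export
merge_replicates <- function(records, max_spread = 1.0) {
  key <- paste(records$id, records$chain, records$resno, records$ins,
               records$wt, records$mut, sep = "|")
  keep <- logical(nrow(records))
  reason <- rep("", nrow(records))
  for (g in split(seq_len(nrow(records)), key)) {
    if (length(g) == 1L) {
      keep[g] <- TRUE
      next
    }
    dd <- records$ddg[g]
    pw <- abs(outer(dd, dd, "-"))
    spread <- mean(pw[upper.tri(pw)])
    if (spread > max_spread) {
      reason[g] <- "replicate spread"
      next
    }
    dist <- standard_conditions_distance(records$temp[g], records$pH[g])
    best <- g[which.min(dist)]
    keep[best] <- TRUE
    reason[setdiff(g, best)] <- "replicate merged"
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "stage") <- curation_stage("replicates", records, keep, reason)
  out
}

#' Trim extreme ddG values
#'
#' Removes outlier measurements outside `[-7, 5]` kcal/mol (inclusive
#' bounds: only strictly outside values are outliers).
#'
#' @param records Mutation records.
#' @param lo,hi Inclusive bounds in kcal/mol.
#' @return Surviving records with a `"stage"` attribute.
#' @export
filter_ddg_range <- function(records, lo = -7, hi = 5) {
  keep <- records$ddg >= lo & records$ddg <= hi
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "stage") <- curation_stage(
    "ddg range", records, keep, rep("ddg outside range", nrow(records)))
  out
}

#' Structure-quality screen
#'
#' Requires, per record: the structure present; resolution better than
#' or equal to `max_resolution` Angstrom; a monomeric oligomeric state;
#' and a backbone-complete residue at the mutation site (contacts are
#' backbone-complete by construction since only complete residues are
#' retained at parse time).
#'
#' @param records Mutation records.
#' @param structures Named list of structures keyed by id.
#' @param max_resolution Inclusive resolution cutoff in Angstrom.
#' @return Surviving records with a `"stage"` attribute.
#' @export
filter_structures <- function(records, structures, max_resolution = 2.5) {
  n <- nrow(records)
  keep <- logical(n)
  reason <- rep("", n)
  for (k in seq_len(n)) {
    s <- structures[[records$id[k]]]
    if (is.null(s)) {
      reason[k] <- "missing structure"
    } else if (is.na(s$resolution) || s$resolution > max_resolution) {
      reason[k] <- "resolution"
    } else if (s$oligomeric_state != "monomer") {
      reason[k] <- "not monomeric"
    } else if (is.na(resolve_site(s, records$chain[k], records$resno[k],
                                  records$ins[k]))) {
      reason[k] <- "incomplete backbone"
    } else {
      keep[k] <- TRUE
    }
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "stage") <- curation_stage("structures", records, keep, reason)
  out
}

#' Ligand-proximity screen
#'
#' Discards a record when any heavy atom of the mutated residue lies
#' strictly closer than `cutoff` Angstrom to any ligand (HETATM,
#' non-water) heavy atom. With backbone-only structures the mutated
#' residue's heavy atoms are its N, Calpha and C — an approximation
#' recorded in the stage metadata (`backbone_only = TRUE`).
#'
#' @param records Mutation records.
#' @param structures Named list of structures keyed by id.
#' @param cutoff Strict distance cutoff in Angstrom.
#' @return Surviving records with a `"stage"` attribute.
#' @export
filter_ligand_proximity <- function(records, structures, cutoff = 5) {
  n <- nrow(records)
  keep <- rep(TRUE, n)
  reason <- rep("", n)
  for (k in seq_len(n)) {
    s <- structures[[records$id[k]]]
    if (is.null(s) || nrow(s$het) == 0L) next
    site <- resolve_site(s, records$chain[k], records$resno[k],
                         records$ins[k])
    if (is.na(site)) next
    r <- s$residues[site, ]
    atoms <- rbind(c(r$nx, r$ny, r$nz), c(r$cax, r$cay, r$caz),
                   c(r$cx, r$cy, r$cz))
    lig <- as.matrix(s$het[, c("x", "y", "z")])
    d2 <- outer(rowSums(atoms^2), rowSums(lig^2), "+") -
      2 * atoms %*% t(lig)
    dmin <- sqrt(max(0, min(d2)))
    # strict < with a 1e-9 guard so exact boundary placements are kept
    if (dmin < cutoff - 1e-9) {
      keep[k] <- FALSE
      reason[k] <- "ligand proximity"
    }
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  st <- curation_stage("ligand proximity", records, keep, reason)
  st$backbone_only <- TRUE
  attr(out, "stage") <- st
  out
}

#' Blacklist filter
#'
#' Removes records matching a blacklist by (id, chain, position, wt,
#' mut) — e.g. to keep a training set disjoint from a benchmark set.
#'
#' @param records Mutation records.
#' @param blacklist Mutation records (or a `data.frame` with the same
#'   address columns) to exclude.
#' @return Surviving records with a `"stage"` attribute.
#' @export
filter_blacklist <- function(records, blacklist) {
  key <- function(x) paste(x$id, x$chain, x$resno, x$ins, x$wt, x$mut,
                           sep = "|")
  keep <- !(key(records) %in% key(blacklist))
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "stage") <- curation_stage(
    "blacklist", records, keep, rep("blacklisted", nrow(records)))
  out
}

#' Debias over-represented substitution classes
#'
#' Caps the number of records per ordered (wt, mut) amino-acid pair at
#' `cap`, removing by priority: first destabilizing mutations involving
#' alanine (stability databases over-represent alanine scanning), then
#' other destabilizing mutations, then seeded-random picks. A candidate
#' that is the last surviving record of its protein family is spared
#' while any other candidate remains in the same pair class, so the
#' balancing never silently erases a family.
#'
#' @param records Mutation records carrying `family` ids.
#' @param cap Maximum records per ordered (wt, mut) class.
#' @param seed Integer seed for the random tier.
#' @return Surviving records with a `"stage"` attribute.
#' @export
balance <- function(records, cap = 15L, seed = 1L) {
  n <- nrow(records)
  keep <- rep(TRUE, n)
  reason <- rep("", n)
  cls <- paste(records$wt, records$mut, sep = ">")
  destab <- records$ddg < 0
  ala <- records$wt == "A" | records$mut == "A"
  rng <- local({
    set.seed(seed)
    stats::runif(n)
  })
  # removal priority: lower tier first; random jitter orders within tier
  tier <- ifelse(destab & ala, 1L, ifelse(destab, 2L, 3L))
  fam <- ifelse(is.na(records$family), paste0("rec", seq_len(n)),
                records$family)
  fam_count <- table(fam)
  for (cl in unique(cls)) {
    idx <- which(cls == cl)
    excess <- length(idx) - cap
    if (excess <= 0L) next
    ord <- idx[order(tier[idx], rng[idx])]
    removed <- 0L
    deferred <- integer()
    for (cand in ord) {
      if (removed >= excess) break
      if (fam_count[fam[cand]] <= 1L) {
        deferred <- c(deferred, cand)
        next
      }
      keep[cand] <- FALSE
      reason[cand] <- "balance cap"
      fam_count[fam[cand]] <- fam_count[fam[cand]] - 1L
      removed <- removed + 1L
    }
    # only last-of-family candidates left: remove them, forced
    for (cand in deferred) {
      if (removed >= excess) break
      keep[cand] <- FALSE
      reason[cand] <- "balance cap (forced)"
      removed <- removed + 1L
    }
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "stage") <- curation_stage("balance", records, keep, reason)
  out
}

#' Run the full curation pipeline
#'
#' Applies, in order: condition window, replicate merging, ddG range
#' trimming, structure screen, ligand-proximity screen, optional
#' blacklist, balancing. Per-stage bookkeeping is composed so that the
#' initial count equals the sum of all removals plus the final survivor
#' count.
#'
#' @param records Mutation records.
#' @param structures Named list of structures keyed by id (skip the two
#'   structure-based screens by passing `NULL`).
#' @param blacklist Optional blacklist records.
#' @param cap,seed Balancing parameters.
#' @return Surviving records; attribute `"report"` is a
#'   `curation_report` with per-stage counts and removed records.
#' @export
curate <- function(records, structures = NULL, blacklist = NULL,
                   cap = 15L, seed = 1L) {
  stages <- list()
  step <- function(out) {
    stages[[length(stages) + 1L]] <<- attr(out, "stage")
    out
  }
  cur <- step(filter_conditions(records))
  cur <- step(merge_replicates(cur))
  cur <- step(filter_ddg_range(cur))
  if (!is.null(structures)) {
    cur <- step(filter_structures(cur, structures))
    cur <- step(filter_ligand_proximity(cur, structures))
  }
  if (!is.null(blacklist)) cur <- step(filter_blacklist(cur, blacklist))
  cur <- step(balance(cur, cap = cap, seed = seed))
  report <- structure(list(stages = stages, input = nrow(records),
                           surviving = nrow(cur)),
                      class = "curation_report")
  attr(cur, "report") <- report
  attr(cur, "stage") <- NULL
  cur
}

#' @export
print.curation_report <- function(x, ...) {
  cat(sprintf("<curation_report %d -> %d records>\n", x$input, x$surviving))
  for (st in x$stages) {
    cat(sprintf("  %-16s in %5d removed %5d kept %5d\n",
                st$stage, st$input, st$removed, st$surviving))
  }
  invisible(x)
}

#' Summary statistics of a mutation dataset
#'
#' Counts, family count, stabilizing/destabilizing fractions (sign of
#' ddG; positive = stabilizing), alanine involvement, and the ddG mean
#' and standard deviation — the descriptive statistics used to
#' characterise curated stability datasets.
#'
#' @param records Mutation records.
#' @return A one-row `data.frame`: `n`, `n_families`, `pct_destabilizing`,
#'   `pct_stabilizing`, `pct_alanine`, `mean_ddg`, `sd_ddg`.
#' @export
dataset_summary <- function(records) {
  fam <- records$family[!is.na(records$family)]
  data.frame(
    n = nrow(records),
    n_families = length(unique(fam)),
    pct_destabilizing = 100 * mean(records$ddg < 0),
    pct_stabilizing = 100 * mean(records$ddg > 0),
    pct_alanine = 100 * mean(records$wt == "A" | records$mut == "A"),
    mean_ddg = mean(records$ddg),
    sd_ddg = stats::sd(records$ddg))
}
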