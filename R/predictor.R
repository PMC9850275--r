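#' Contacts of a mutation site
#'
#' Enumerates the residues in contact with a site: every residue of the
#' scored unit whose Calpha lies within the potential's distance window
#' of the site's Calpha and which is either on another chain or at least
#' `min_seq_sep` apart in sequence. The site itself is excluded. By
#' default only the site's own chain is scored (the training data are
#' monomeric); `all_chains = TRUE` includes inter-chain contacts.
#'
#' @param structure A [new_structure()] object.
#' @param chain,resno,ins Author-numbered residue address of the site.
#' @param geom A [bin_geometry()].
#' @param all_chains Include contacts from other chains?
#' @return A `contact_set`: site row index, contact row indices, and the
#'   per-contact descriptors (site as side i).
#' @export
contacts_of <- function(structure, chain, resno, ins = "",
                        geom = bin_geometry(), all_chains = FALSE) {
  site <- resolve_site(structure, chain, resno, ins)
  if (is.na(site)) {
    stop(sprintf("cannot resolve site %s/%s%s in structure %s",
                 chain, resno, ins, structure$id))
  }
  res <- structure$residues
  cand <- setdiff(seq_len(nrow(res)), site)
  if (!all_chains) cand <- cand[res$chain[cand] == res$chain[site]]
  if (length(cand)) {
    ca <- as.matrix(res[, c("cax", "cay", "caz")])
    dvec <- sqrt(colSums((t(ca[cand, , drop = FALSE]) - ca[site, ])^2))
    same <- res$chain[cand] == res$chain[site]
    sep <- ifelse(same, res$resno[cand] - res$resno[site], NA_integer_)
    keep <- dvec >= geom$r_min & dvec < geom$r_max &
      (!same | abs(sep) >= geom$min_seq_sep)
    cand <- cand[keep]; sep <- sep[keep]
  } else {
    sep <- integer()
  }
  desc <- NULL
  if (length(cand)) {
    frames <- build_frames(structure)
    desc <- pair_descriptors_idx(frames, rep(site, length(cand)), cand, sep)
  }
  structure(list(site = site, contacts = cand, desc = desc,
                 geom = geom, structure_id = structure$id),
            class = "contact_set")
}

#' Predict the stability change of a point mutation
#'
#' Scores a mutation as the weighted difference of orientational-potential
#' sums over the native contacts of the mutated site:
#' `ddg = sum_i w(aa_i) w(mut) E(aa_i, mut, d_i)
#'       - sum_i w(aa_i) w(wt) E(aa_i, wt, d_i)`,
#' with descriptors `d_i` taken from the native backbone (identity swap
#' only, no remodelling). Positive values are stabilizing. Because both
#' sums use the same contacts and descriptors, predicting the reverse
#' substitution on the same structure gives the exact negation.
#'
#' @param structure A [new_structure()] object.
#' @param chain,resno,ins Site address.
#' @param wt_aa,mut_aa One-letter wild-type and mutant residue types. The
#'   structure's residue at the site must equal `wt_aa` unless
#'   `override = TRUE`.
#' @param weights A [weight_set()].
#' @param map A `potential_map` from [derive_potential()].
#' @param override Skip the wild-type identity check (for hypothetical
#'   scoring).
#' @param all_chains Passed to [contacts_of()].
#' @return A `ddg_prediction`: `ddg`, the two sums `term_mut` and
#'   `term_wt`, `n_contacts` and a per-contact energy breakdown.
#' @export
predict_ddg <- function(structure, chain, resno, wt_aa, mut_aa,
                        weights, map, ins = "", override = FALSE,
                        all_chains = FALSE) {
  cs <- contacts_of(structure, chain, resno, ins, geom = map$geom,
                    all_chains = all_chains)
  site_aa <- structure$residues$aa[cs$site]
  if (!override && site_aa != wt_aa) {
    stop(sprintf(
      "wild-type mismatch at %s/%s%s: structure has %s, record says %s",
      chain, resno, ins, site_aa, wt_aa))
  }
  wvec <- expand_weights(weights)
  if (length(cs$contacts) == 0L) {
    warning("empty contact set at ", chain, "/", resno, ins,
            ": ddg = 0")
    breakdown <- data.frame(contact = integer(), aa = character(),
                            e_wt = numeric(), e_mut = numeric())
    return(structure(list(ddg = 0, term_mut = 0, term_wt = 0,
                          n_contacts = 0L, breakdown = breakdown),
                     class = "ddg_prediction"))
  }
  aa_c <- structure$residues$aa[cs$contacts]
  e_mut <- energy(map, aa_c, mut_aa, cs$desc)
  e_wt <- energy(map, aa_c, wt_aa, cs$desc)
  wc <- wvec[aa_c]
  term_mut <- sum(wc * wvec[mut_aa] * e_mut)
  term_wt <- sum(wc * wvec[wt_aa] * e_wt)
  structure(list(ddg = term_mut - term_wt,
                 term_mut = term_mut, term_wt = term_wt,
                 n_contacts = length(cs$contacts),
                 breakdown = data.frame(contact = cs$contacts, aa = aa_c,
                                        e_wt = e_wt, e_mut = e_mut)),
            class = "ddg_prediction")
}

#' @export
print.ddg_prediction <- function(x, ...) {
  cat(sprintf(
    "<ddg_prediction ddg = %.4f kcal/mol (mut %.4f - wt %.4f), %d contacts>\n",
    x$ddg, x$term_mut, x$term_wt, x$n_contacts))
  invisible(x)
}

#' Predict a mutation and its reverse on the two end-state structures
#'
#' The direct substitution (wt -> mut) is scored on the wild-type
#' structure, the reverse (mut -> wt) on the mutated structure. An ideal
#' anti-symmetric predictor gives `direct + reverse = 0`; the reported
#' `delta` measures the deviation, which for this backbone-only predictor
#' arises solely from backbone differences between the two structures.
#'
#' @param wt_structure,mut_structure Wild-type and mutant structures.
#' @param chain,resno,ins Site address (valid in both structures).
#' @param wt_aa,mut_aa Residue types at the site in the wild-type and
#'   mutant structures respectively.
#' @param weights,map,override,all_chains As in [predict_ddg()].
#' @return List with `direct`, `reverse` (both `ddg_prediction`) and
#'   `delta = direct$ddg + reverse$ddg` (kcal/mol).
#' @export
predict_reverse <- function(wt_structure, mut_structure, chain, resno,
                            wt_aa, mut_aa, weights, map, ins = "",
                            override = FALSE, all_chains = FALSE) {
  direct <- predict_ddg(wt_structure, chain, resno, wt_aa, mut_aa,
                        weights, map, ins = ins, override = override,
                        all_chains = all_chains)
  reverse <- predict_ddg(mut_structure, chain, resno, mut_aa, wt_aa,
                         weights, map, ins = ins, override = override,
                         all_chains = all_chains)
  list(direct = direct, reverse = reverse,
       delta = direct$ddg + reverse$ddg)
}

#' Predict ddG for a table of mutation records
#'
#' Vectorised driver over [predict_ddg()]. Records whose structure or
#' site cannot be resolved are returned with `NA` predictions and a
#' reason instead of failing the whole batch.
#'
#' @param records Mutation records (see [read_mutation_table()]).
#' @param structures Named list of structures keyed by structure id.
#' @param weights,map,override,all_chains As in [predict_ddg()].
#' @return `records` with added columns `ddg_pred`, `n_contacts`,
#'   `note`.
#' @export
predict_table <- function(records, structures, weights, map,
                          override = FALSE, all_chains = FALSE) {
  ddg_pred <- rep(NA_real_, nrow(records))
  ncon <- rep(NA_integer_, nrow(records))
  note <- rep("", nrow(records))
  for (k in seq_len(nrow(records))) {
    s <- structures[[records$id[k]]]
    if (is.null(s)) {
      note[k] <- "missing structure"
      next
    }
    p <- tryCatch(
      withCallingHandlers(
        predict_ddg(s, records$chain[k], records$resno[k],
                    records$wt[k], records$mut[k], weights, map,
                    ins = records$ins[k], override = override,
                    all_chains = all_chains),
        warning = function(w) {
          note[k] <<- conditionMessage(w)
          invokeRestart("muffleWarning")
        }),
      error = function(e) conditionMessage(e))
    if (is.character(p)) {
      note[k] <- p
    } else {
      ddg_pred[k] <- p$ddg
      ncon[k] <- p$n_contacts
    }
  }
  records$ddg_pred <- ddg_pred
  records$n_contacts <- ncon
  records$note <- note
  records
}
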