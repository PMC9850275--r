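# Per-record design for fast weight fitting. For record m with mutant
# group gm and wild-type group gw, the prediction is bilinear in the
# group weights w:
#   pred_m(w) = w[gm_m] * (S_mut[m, ] %*% w) - w[gw_m] * (S_wt[m, ] %*% w)
# where S_mut[m, g] sums E(aa_i, mut, d_i) over contacts i in group g
# (and S_wt likewise for the wild-type identity).
build_design <- function(records, structures, map, weights_mode = 12L) {
  ws0 <- weight_set(rep(1, weights_mode), n_groups = weights_mode)
  ng <- ws0$n_groups
  n <- nrow(records)
  S_mut <- matrix(0, n, ng)
  S_wt <- matrix(0, n, ng)
  # placeholder group 1 for unusable rows: they are excluded from the
  # objective but still flow through the vectorised prediction
  gm <- rep(1L, n)
  gw <- rep(1L, n)
  usable <- rep(TRUE, n)
  note <- rep("", n)
  for (m in seq_len(n)) {
    s <- structures[[records$id[m]]]
    if (is.null(s)) {
      usable[m] <- FALSE
      note[m] <- "missing structure"
      next
    }
    cs <- tryCatch(
      contacts_of(s, records$chain[m], records$resno[m], records$ins[m],
                  geom = map$geom),
      error = function(e) conditionMessage(e))
    if (is.character(cs)) {
      usable[m] <- FALSE
      note[m] <- cs
      next
    }
    gm[m] <- weight_group_of(ws0, records$mut[m])
    gw[m] <- weight_group_of(ws0, records$wt[m])
    if (length(cs$contacts) == 0L) next
    aa_c <- s$residues$aa[cs$contacts]
    gc <- weight_group_of(ws0, aa_c)
    e_mut <- energy(map, aa_c, records$mut[m], cs$desc)
    e_wt <- energy(map, aa_c, records$wt[m], cs$desc)
    for (g in unique(gc)) {
      sel <- gc == g
      S_mut[m, g] <- sum(e_mut[sel])
      S_wt[m, g] <- sum(e_wt[sel])
    }
  }
  list(S_mut = S_mut, S_wt = S_wt, gm = gm, gw = gw,
       y = records$ddg, usable = usable, note = note, n_groups = ng)
}

design_predict <- function(design, w) {
  as.numeric(w[design$gm] * (design$S_mut %*% w) -
               w[design$gw] * (design$S_wt %*% w))
}

design_mae <- function(design, w) {
  u <- design$usable
  mean(abs(design_predict(design, w)[u] - design$y[u]))
}

#' Mean absolute error of a weight set on a mutation dataset
#'
#' The fitting objective: mean over records of |predicted - experimental|
#' ddG in kcal/mol. Records whose structure or site cannot be resolved
#' are excluded with a warning and the mean is taken over the resolvable
#' subset.
#'
#' @param weights A [weight_set()] (or bare numeric weight vector).
#' @param records Mutation records.
#' @param structures Named list of structures keyed by id.
#' @param map A `potential_map`.
#' @return MAE in kcal/mol.
#' @export
objective <- function(weights, records, structures, map) {
  if (inherits(weights, "weight_set")) weights <- weights$w
  design <- build_design(records, structures, map,
                         weights_mode = length(weights))
  if (!all(design$usable)) {
    warning(sum(!design$usable), " unresolvable record(s) excluded: ",
            paste(unique(design$note[!design$usable]), collapse = "; "))
  }
  if (!any(design$usable)) stop("no resolvable records")
  design_mae(design, weights)
}

#' Fit amino-acid group weights by MAE minimisation
#'
#' Minimises the mean absolute error between predicted and experimental
#' ddG over the group weights, under box constraints, with a
#' derivative-free pattern search (Hooke-Jeeves; the MAE surface is
#' piecewise smooth, so gradient-based methods are unsuitable). The
#' optimiser is monotone — the returned weights are never worse than the
#' start — and deterministic for identical inputs and settings.
#'
#' @param records Mutation records (>= 12 recommended; fewer flags an
#'   under-determined fit).
#' @param structures Named list of structures keyed by id.
#' @param map A `potential_map`.
#' @param init Initial weights (default all ones).
#' @param bounds Length-2 numeric: lower/upper box bound applied to every
#'   weight.
#' @param n_groups 12 (grouped, default) or 20 (per amino acid).
#' @param tol Termination tolerance on the pattern-search step /
#'   objective improvement.
#' @param max_evals Evaluation budget.
#' @param design Precomputed [build_design()] output (internal reuse by
#'   cross-validation); when given, `records`/`structures`/`map` are
#'   ignored.
#' @return A `fit_result`: `weights` ([weight_set()]), `mae_initial`,
#'   `mae` (final training MAE), `evaluations`, `converged`.
#' @export
fit_weights <- function(records = NULL, structures = NULL, map = NULL,
                        init = NULL, bounds = c(0, 5), n_groups = 12L,
                        tol = 1e-6, max_evals = 20000L, design = NULL) {
  if (is.null(design)) {
    if (is.null(records) || nrow(records) == 0L) {
      stop("empty record set")
    }
    design <- build_design(records, structures, map,
                           weights_mode = n_groups)
  }
  n_use <- sum(design$usable)
  if (n_use == 0L) stop("no resolvable records")
  if (n_use < design$n_groups) {
    warning("fewer records (", n_use, ") than weights (",
            design$n_groups, "): fit is under-determined")
  }
  if (is.null(init)) init <- rep(1, design$n_groups)
  init <- pmin(pmax(init, bounds[1]), bounds[2])
  f <- function(w) design_mae(design, w)
  mae0 <- f(init)
  # the pattern search shuffles its coordinate order through the global
  # RNG; pin it locally so fits are deterministic and leave the caller's
  # random stream untouched
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(285714L)
  sol <- pracma::hooke_jeeves(init, f,
                              lb = rep(bounds[1], design$n_groups),
                              ub = rep(bounds[2], design$n_groups),
                              tol = tol, maxfeval = max_evals)
  w <- pmin(pmax(sol$xmin, bounds[1]), bounds[2])
  mae1 <- f(w)
  if (mae1 > mae0) {  # monotonicity contract
    w <- init
    mae1 <- mae0
  }
  structure(list(weights = weight_set(w, n_groups = design$n_groups),
                 mae_initial = mae0, mae = mae1,
                 evaluations = sol$count,
                 converged = sol$convergence == 0 || sol$count < max_evals),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "<fit_result MAE %.4f (from %.4f) kcal/mol, %d evaluations%s>\n",
    x$mae, x$mae_initial, x$evaluations,
    if (x$converged) "" else ", budget exhausted"))
  print(round(x$weights$w, 4))
  invisible(x)
}

#' Repeated homology-aware k-fold cross-validation
#'
#' For each repeat, clusters are dealt into `k` folds
#' ([make_splits()]); per fold, weights are fitted on the training
#' records and scored (RMSE, Pearson correlation) on the held-out
#' validation records, which never share a homology cluster with the
#' training set. Aggregates are reported as mean and standard deviation
#' over all folds and repeats; per-fold weights are retained for
#' weight-stability statistics. Fully reproducible from `seed`.
#'
#' @param records Mutation records.
#' @param structures Named list of structures keyed by id.
#' @param map A `potential_map`.
#' @param cluster Integer cluster id per record.
#' @param k Number of folds.
#' @param repeats Number of repetitions (the protocol default is 100;
#'   scale down for quick checks).
#' @param seed Integer seed.
#' @param ... Passed to [fit_weights()] (e.g. `bounds`, `tol`,
#'   `n_groups`).
#' @return A `cv_result`: per-fold `data.frame` (`repeat_`, `fold`,
#'   `rmse`, `pcc`, `n_validation`), the fitted weight matrix (one row
#'   per fold x repeat), and aggregate `rmse_mean/sd`, `pcc_mean/sd`,
#'   `weight_sd`.
#' @export
cross_validate <- function(records, structures, map, cluster, k,
                           repeats = 100L, seed = 1L, ...) {
  stopifnot(length(cluster) == nrow(records))
  design <- build_design(records, structures, map)
  splits <- make_splits(cluster, k = k, repeats = repeats, seed = seed)
  rows <- list()
  wmat <- list()
  subset_design <- function(d, idx) {
    list(S_mut = d$S_mut[idx, , drop = FALSE],
         S_wt = d$S_wt[idx, , drop = FALSE],
         gm = d$gm[idx], gw = d$gw[idx], y = d$y[idx],
         usable = d$usable[idx], note = d$note[idx],
         n_groups = d$n_groups)
  }
  for (r in seq_len(repeats)) {
    for (f in seq_len(k)) {
      sp <- splits[[r]][[f]]
      fit <- fit_weights(design = subset_design(design, sp$train), ...)
      vd <- subset_design(design, sp$validation)
      u <- vd$usable
      pred <- design_predict(vd, fit$weights$w)[u]
      obs <- vd$y[u]
      rows[[length(rows) + 1L]] <- data.frame(
        repeat_ = r, fold = f,
        rmse = sqrt(mean((pred - obs)^2)),
        pcc = if (length(obs) >= 2L && stats::sd(obs) > 0 &&
                    stats::sd(pred) > 0)
          stats::cor(pred, obs) else NA_real_,
        n_validation = length(obs))
      wmat[[length(wmat) + 1L]] <- fit$weights$w
    }
  }
  folds <- do.call(rbind, rows)
  W <- do.call(rbind, wmat)
  structure(list(folds = folds, weights = W,
                 rmse_mean = mean(folds$rmse),
                 rmse_sd = stats::sd(folds$rmse),
                 pcc_mean = mean(folds$pcc, na.rm = TRUE),
                 pcc_sd = stats::sd(folds$pcc, na.rm = TRUE),
                 weight_mean = colMeans(W),
                 weight_sd = apply(W, 2, stats::sd),
                 k = k, repeats = repeats, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result %d-fold x %d repeats: RMSE %.3f +/- %.3f, PCC %.3f +/- %.3f>\n",
    x$k, x$repeats, x$rmse_mean, x$rmse_sd, x$pcc_mean, x$pcc_sd))
  invisible(x)
}
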