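#' Amino-acid-group weight sets
#'
#' The mutation predictor multiplies each contact energy by the weights
#' of the two residues involved. To limit free parameters, chemically
#' similar amino acids share a weight: 12 group weights expand to all 20
#' residues (see [AA_GROUPS]). A full 20-weight per-amino-acid mode is
#' available behind `n_groups = 20`. Weights are non-negative, which
#' breaks the global sign degeneracy of the product form
#' ((-w)(-w') = ww').
#'
#' @param w Numeric vector of 12 group weights (or 20 in per-amino-acid
#'   mode), named or in [AA_GROUP_NAMES] / [AA_CODES] order.
#' @param n_groups 12 (default, grouped) or 20 (one weight per residue).
#' @return A `weight_set` object.
#' @export
weight_set <- function(w = rep(1, 12), n_groups = c(12, 20)) {
  n_groups <- match.arg(as.character(n_groups[1]), c("12", "20"))
  n_groups <- as.integer(n_groups)
  if (length(w) != n_groups) {
    stop("expected ", n_groups, " weights, got ", length(w))
  }
  if (any(!is.finite(w)) || any(w < 0)) {
    stop("weights must be finite and non-negative")
  }
  names(w) <- if (n_groups == 12L) AA_GROUP_NAMES else AA_CODES
  structure(list(w = w, n_groups = n_groups), class = "weight_set")
}

#' @export
print.weight_set <- function(x, ...) {
  cat(sprintf("<weight_set %d groups>\n", x$n_groups))
  print(round(x$w, 4))
  invisible(x)
}

# group index of each amino-acid (indices into the weight vector)
weight_group_of <- function(ws, aa) {
  if (ws$n_groups == 12L) unname(AA_GROUPS[aa]) else aa_index(aa)
}

#' Per-amino-acid expansion of a weight set
#'
#' @param ws A [weight_set()].
#' @return Named numeric vector of length 20: each canonical amino acid's
#'   weight.
#' @export
expand_weights <- function(ws) {
  out <- ws$w[weight_group_of(ws, AA_CODES)]
  names(out) <- AA_CODES
  out
}

#' Write / read a weight set as JSON
#'
#' The file records the weights at full precision together with the group
#' map and mode, so read(write(ws)) reproduces every weight bit-exactly.
#'
#' @param ws A [weight_set()].
#' @param path File path.
#' @param extra Optional named list stored verbatim (e.g. fit metadata:
#'   bounds, seed, objective trace).
#' @return `path` invisibly; `read_weights` returns a `weight_set` with
#'   any extra metadata in attribute `"meta"`.
#' @export
write_weights <- function(ws, path, extra = list()) {
  obj <- c(list(format = "orientddg-weights", version = 1L,
                n_groups = ws$n_groups,
                names = names(ws$w),
                # 17 significant digits: exact IEEE round trip
                w = sprintf("%.17g", unname(ws$w)),
                group_map = as.list(stats::setNames(
                  weight_group_of(ws, AA_CODES), AA_CODES))),
           extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "orientddg-weights") {
    stop("incompatible weight file: ", path)
  }
  ws <- weight_set(as.numeric(obj$w), n_groups = obj$n_groups)
  meta <- obj[setdiff(names(obj), c("format", "version", "n_groups",
                                    "names", "w", "group_map"))]
  attr(ws, "meta") <- meta
  ws
}
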