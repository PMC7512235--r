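#' @title Plug-in information theory on small discrete alphabets
#' @description
#' Maximum-likelihood (frequency, "plug-in") estimates of entropy, mutual
#' information, conditional mutual information and transfer entropy, all in
#' bits (base-2 logarithms, with the 0 log 0 := 0 limit convention). No bias
#' correction is applied by default: the windowed empirical probabilities are
#' used as-is, which is the estimator the trace pipeline assumes.
#' @name info_measures
NULL

#' Discrete probability table
#'
#' A joint probability table over named discrete variables, stored as an array
#' whose dimnames declare the alphabet of each variable (so zero-probability
#' symbols stay representable in degenerate windows).
#'
#' @param probs Array (or vector for one variable) of probabilities with fully
#'   named dimnames: `names(dimnames(probs))` are the variable names, the
#'   dimnames themselves the supports.
#' @param counts Optional array of raw counts the table was estimated from.
#' @param n_samples Optional sample count backing the estimate.
#' @return An object of class `prob_table` with fields `probs`, `variables`,
#'   `support`, `counts`, `n_samples`.
#' @export
prob_table <- function(probs, counts = NULL, n_samples = NULL) {
  if (is.null(dim(probs))) {
    nm <- names(probs)
    if (is.null(nm)) nm <- as.character(seq_along(probs))
    probs <- array(as.numeric(probs), dim = length(probs), dimnames = list(x = nm))
  }
  dn <- dimnames(probs)
  if (is.null(dn) || is.null(names(dn)) || any(names(dn) == "")) {
    stop("probs must have fully named dimnames (variable names and supports)")
  }
  if (any(probs < -1e-12)) stop("probabilities must be non-negative")
  s <- sum(probs)
  if (abs(s - 1) > 1e-8) stop("probabilities must sum to 1 (got ", format(s), ")")
  structure(list(probs = probs, variables = names(dn), support = dn,
                 counts = counts, n_samples = n_samples),
            class = "prob_table")
}

#' @export
print.prob_table <- function(x, ...) {
  cat("prob_table over (", paste(x$variables, collapse = ", "), ")",
      if (!is.null(x$n_samples)) paste0(" from n = ", x$n_samples), "\n", sep = "")
  print(x$probs, ...)
  invisible(x)
}

#' Empirical joint distribution
#'
#' Frequency (maximum-likelihood) estimate of the joint distribution of one or
#' more discrete variables. Alphabets can be declared through `support`;
#' symbols never observed then carry probability zero rather than being
#' dropped.
#'
#' @param samples A data frame / named list of equal-length vectors (one per
#'   variable), or a single atomic vector.
#' @param support Optional named list giving the alphabet of each variable;
#'   defaults to the sorted observed values.
#' @return A [prob_table()] with counts and `n_samples` filled in.
#' @examples
#' empirical_dist(c("L", "L", "R", "R"))
#' @export
empirical_dist <- function(samples, support = NULL) {
  if (is.atomic(samples)) samples <- list(x = samples)
  samples <- as.list(samples)
  if (length(samples) == 0L) stop("no variables supplied")
  if (is.null(names(samples)) || any(names(samples) == "")) {
    names(samples) <- paste0("v", seq_along(samples))
  }
  n <- unique(lengths(samples))
  if (length(n) != 1L) stop("all variables must have equal length")
  if (n == 0L) stop("cannot estimate a distribution from an empty sample")
  facs <- lapply(names(samples), function(v) {
    lev <- if (!is.null(support[[v]])) support[[v]] else sort(unique(samples[[v]]))
    f <- factor(as.character(samples[[v]]), levels = as.character(lev))
    if (anyNA(f)) stop("variable '", v, "' has values outside its declared support")
    f
  })
  names(facs) <- names(samples)
  tab <- do.call(table, facs)
  counts <- array(as.numeric(tab), dim = dim(tab), dimnames = dimnames(tab))
  names(dimnames(counts)) <- names(samples)
  probs <- counts / n
  prob_table(probs, counts = counts, n_samples = n)
}

#' Marginalize a probability table
#'
#' @param p A [prob_table()].
#' @param vars Variable names to keep.
#' @return A [prob_table()] over `vars` (marginalization preserves counts when
#'   present).
#' @export
marginal <- function(p, vars) {
  stopifnot(inherits(p, "prob_table"))
  idx <- match(vars, p$variables)
  if (anyNA(idx)) stop("unknown variable(s): ", paste(vars[is.na(idx)], collapse = ", "))
  m <- apply(p$probs, idx, sum)
  if (length(idx) == 1L) {
    m <- array(m, dim = length(m), dimnames = p$support[idx])
  } else {
    names(dimnames(m)) <- p$variables[idx]
  }
  cnt <- NULL
  if (!is.null(p$counts)) {
    cnt <- apply(p$counts, idx, sum)
    if (length(idx) == 1L) {
      cnt <- array(cnt, dim = length(cnt), dimnames = p$support[idx])
    } else {
      names(dimnames(cnt)) <- p$variables[idx]
    }
  }
  prob_table(m, counts = cnt, n_samples = p$n_samples)
}

#' Collapse several variables into one joint variable
#'
#' @param p A [prob_table()].
#' @param vars Variables to merge.
#' @param name Name of the merged variable.
#' @return A [prob_table()] in which `vars` are replaced by a single variable
#'   whose symbols are the `|`-joined tuples.
#' @export
collapse_vars <- function(p, vars, name = "joint") {
  stopifnot(inherits(p, "prob_table"))
  idx <- match(vars, p$variables)
  if (anyNA(idx)) stop("unknown variable(s): ", paste(vars[is.na(idx)], collapse = ", "))
  keep <- setdiff(seq_along(p$variables), idx)
  df <- as.data.frame.table(p$probs, responseName = ".p", stringsAsFactors = FALSE)
  names(df)[seq_along(p$variables)] <- p$variables
  df[[name]] <- do.call(paste, c(df[vars], sep = "|"))
  by_vars <- c(name, p$variables[keep])
  agg <- stats::aggregate(list(.psum = df$.p), by = df[by_vars], FUN = sum)
  lev <- lapply(by_vars, function(v) sort(unique(agg[[v]])))
  names(lev) <- by_vars
  arr <- array(0, dim = vapply(lev, length, 1L), dimnames = lev)
  pos <- mapply(function(v, l) match(agg[[v]], l), by_vars, lev)
  arr[if (is.matrix(pos)) pos else matrix(pos, ncol = 1L)] <- agg$.psum
  prob_table(arr, n_samples = p$n_samples)
}

#' Shannon entropy (bits)
#'
#' @param p A [prob_table()] or a bare numeric probability vector.
#' @return Entropy in bits; 0 log 0 is treated as 0.
#' @examples
#' entropy(c(0.5, 0.5))   # 1 bit
#' entropy(c(0.25, 0.75)) # 0.8113 bits
#' @export
entropy <- function(p) {
  pv <- if (inherits(p, "prob_table")) as.numeric(p$probs) else as.numeric(p)
  pv <- pv[pv > 0]
  -sum(pv * log2(pv))
}

#' Mutual information (bits)
#'
#' Plug-in mutual information of a two-variable joint table,
#' I(x:y) = H(x) + H(y) - H(x,y).
#'
#' @param joint A [prob_table()] over exactly two variables.
#' @return Mutual information in bits (non-negative up to rounding).
#' @export
mutual_information <- function(joint) {
  stopifnot(inherits(joint, "prob_table"))
  if (length(joint$variables) != 2L) {
    stop("mutual_information needs a joint table over exactly 2 variables")
  }
  entropy(marginal(joint, joint$variables[1L])) +
    entropy(marginal(joint, joint$variables[2L])) -
    entropy(joint)
}

#' Conditional mutual information (bits)
#'
#' For a three-variable table over (x, y, z), computes I(x:y|z) =
#' H(x,z) + H(y,z) - H(x,y,z) - H(z). The conditioning variable is the third.
#'
#' @param joint A [prob_table()] over exactly three variables (x, y, z).
#' @return Conditional mutual information in bits.
#' @export
conditional_mutual_information <- function(joint) {
  stopifnot(inherits(joint, "prob_table"))
  if (length(joint$variables) != 3L) {
    stop("conditional_mutual_information needs a joint table over exactly 3 variables")
  }
  v <- joint$variables
  entropy(marginal(joint, v[c(1L, 3L)])) +
    entropy(marginal(joint, v[c(2L, 3L)])) -
    entropy(joint) -
    entropy(marginal(joint, v[3L]))
}

#' Transfer entropy (bits)
#'
#' Plug-in transfer entropy from a source series Y to a target series X:
#' T(Y -> X) = I(y_n : x_{n+1} | x_n^{(k)}) with history length k, estimated
#' over all valid n by lag-embedding the two series and applying
#' [conditional_mutual_information()] to the empirical joint.
#'
#' @param source,target Equal-length discrete series (any atomic type).
#' @param history Target history length k (default 1, the one-step
#'   conditioning used throughout the trace pipeline).
#' @return Transfer entropy in bits.
#' @export
transfer_entropy <- function(source, target, history = 1L) {
  history <- as.integer(history)
  if (history < 1L) stop("history must be a positive integer")
  n <- length(target)
  if (length(source) != n) stop("source and target must have equal length")
  if (n <= history) stop("series too short for history length ", history)
  idx <- history:(n - 1L)
  x_next <- as.character(target[idx + 1L])
  y_now <- as.character(source[idx])
  z_hist <- if (history == 1L) {
    as.character(target[idx])
  } else {
    apply(embed(as.character(target), history)[seq_along(idx), , drop = FALSE], 1L,
          function(r) paste(rev(r), collapse = "|"))
  }
  ed <- empirical_dist(list(x_next = x_next, source = y_now, target_hist = z_hist))
  conditional_mutual_information(ed)
}
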