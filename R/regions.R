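#' Construct a mixture dataset
#'
#' Bundles the observed data structure O = (W, A, Y): baseline covariates W
#' (n x p), multivariate exposures A (n x m) and a scalar outcome Y. All
#' values must be finite; column names must be unique across the three
#' blocks. This is the input container for region discovery and ARE
#' estimation.
#'
#' @param W Covariate matrix or data frame (n x p, p >= 0), numeric.
#' @param A Exposure matrix or data frame (n x m, m >= 1), numeric.
#' @param Y Numeric outcome vector of length n.
#' @return An object of class `mixture_dataset` with elements `W`, `A`
#'   (numeric matrices), `Y`, `n`, `m`, `p`.
#' @examples
#' d <- mixture_dataset(W = data.frame(w1 = rnorm(5)),
#'                      A = data.frame(a1 = runif(5)),
#'                      Y = rnorm(5))
#' d$n
#' @export
mixture_dataset <- function(W, A, Y) {
  A <- as_numeric_matrix(A, "A")
  if (is.null(W) || (is.data.frame(W) && ncol(W) == 0L)) {
    W <- matrix(numeric(0), nrow = nrow(A), ncol = 0L)
  } else {
    W <- as_numeric_matrix(W, "W")
  }
  Y <- as.numeric(Y)
  n <- length(Y)
  if (nrow(A) != n || nrow(W) != n) {
    stop("aretree_error_dims: W, A and Y must share the same number of rows")
  }
  if (n < 1L) stop("aretree_error_dims: need at least one observation")
  if (ncol(A) < 1L) stop("aretree_error_dims: need at least one exposure")
  if (anyNA(Y) || !all(is.finite(Y)) || anyNA(A) || !all(is.finite(A)) ||
      (ncol(W) > 0 && (anyNA(W) || !all(is.finite(W))))) {
    stop("aretree_error_missing: missing or non-finite values are rejected")
  }
  nms <- c(colnames(W), colnames(A))
  if (anyDuplicated(nms)) {
    stop("aretree_error_names: column names must be unique across W and A")
  }
  structure(list(W = W, A = A, Y = Y, n = n, m = ncol(A), p = ncol(W)),
            class = "mixture_dataset")
}

as_numeric_matrix <- function(x, what) {
  if (is.data.frame(x)) {
    ok <- vapply(x, is.numeric, logical(1))
    if (!all(ok)) {
      stop(sprintf("aretree_error_type: non-numeric column(s) in %s: %s",
                   what, paste(names(x)[!ok], collapse = ", ")))
    }
    x <- as.matrix(x)
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x)) && ncol(x) > 0) {
    colnames(x) <- paste0(what, seq_len(ncol(x)))
  }
  x
}

#' @export
print.mixture_dataset <- function(x, ...) {
  cat(sprintf("mixture_dataset: n = %d, %d exposure(s), %d covariate(s)\n",
              x$n, x$m, x$p))
  cat("  exposures:", paste(colnames(x$A), collapse = ", "), "\n")
  if (x$p > 0) cat("  covariates:", paste(colnames(x$W), collapse = ", "), "\n")
  invisible(x)
}

#' Threshold rule on one exposure
#'
#' A single axis-aligned constraint, either `A_j <= cutpoint` (operator
#' `"LE"`, inclusive) or `A_j > cutpoint` (operator `"GT"`, strictly
#' exclusive), so the two children of a split at a cutpoint partition the
#' data exactly.
#'
#' @param exposure_name Name of the exposure column the rule applies to.
#' @param operator `"LE"` for `<=`, `"GT"` for `>`.
#' @param cutpoint Finite numeric threshold, in exposure units.
#' @return An object of class `threshold_rule`.
#' @export
threshold_rule <- function(exposure_name, operator = c("LE", "GT"), cutpoint) {
  operator <- match.arg(operator)
  if (!is.character(exposure_name) || length(exposure_name) != 1L) {
    stop("aretree_error_rule: exposure_name must be a single string")
  }
  cutpoint <- as.numeric(cutpoint)
  if (length(cutpoint) != 1L || !is.finite(cutpoint)) {
    stop("aretree_error_rule: cutpoint must be a single finite number")
  }
  structure(list(exposure_name = exposure_name, operator = operator,
                 cutpoint = cutpoint), class = "threshold_rule")
}

#' @export
format.threshold_rule <- function(x, digits = 6, ...) {
  op <- if (x$operator == "LE") "<=" else ">"
  paste0(x$exposure_name, " ", op, " ",
         format(x$cutpoint, digits = digits, trim = TRUE))
}

#' @export
print.threshold_rule <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Exposure region as a conjunction of threshold rules
#'
#' A region is an axis-aligned hyper-rectangle in exposure space: the
#' intersection of threshold rules. An empty rule list denotes the full
#' exposure space. Rules are normalized on construction: at most one `<=`
#' and one `>` rule per exposure (the tightest bounds are kept), and the
#' implied interval must be nonempty.
#'
#' @param rules List of [threshold_rule()] objects (possibly empty).
#' @return An object of class `region`.
#' @seealso [normalize_region()], [region_membership()]
#' @export
region <- function(rules = list()) {
  normalize_region(rules)
}

#' Normalize a collection of threshold rules into a region
#'
#' Collapses duplicate rules on the same exposure and operator to the
#' tightest bound (smallest cutpoint for `<=`, largest for `>`), orders the
#' rules by exposure name, and verifies each implied interval is nonempty.
#'
#' @param rules List of [threshold_rule()] objects, or an existing `region`.
#' @return A `region` object satisfying the region invariants.
#' @examples
#' r <- normalize_region(list(threshold_rule("a1", "LE", 5),
#'                            threshold_rule("a1", "LE", 3)))
#' format(r)  # "a1 <= 3"
#' @export
normalize_region <- function(rules) {
  if (inherits(rules, "region")) rules <- rules$rules
  if (inherits(rules, "threshold_rule")) rules <- list(rules)
  stopifnot(is.list(rules))
  if (length(rules)) {
    ok <- vapply(rules, inherits, logical(1), what = "threshold_rule")
    if (!all(ok)) stop("aretree_error_rule: rules must be threshold_rule objects")
  }
  out <- list()
  if (length(rules)) {
    nms <- vapply(rules, function(r) r$exposure_name, character(1))
    for (nm in sort(unique(nms))) {
      sub <- rules[nms == nm]
      le <- vapply(sub, function(r) if (r$operator == "LE") r$cutpoint else NA_real_,
                   numeric(1))
      gt <- vapply(sub, function(r) if (r$operator == "GT") r$cutpoint else NA_real_,
                   numeric(1))
      le_cut <- if (all(is.na(le))) NA_real_ else min(le, na.rm = TRUE)
      gt_cut <- if (all(is.na(gt))) NA_real_ else max(gt, na.rm = TRUE)
      if (!is.na(le_cut) && !is.na(gt_cut) && le_cut <= gt_cut) {
        stop(sprintf(
          "aretree_error_empty_interval: rules on '%s' imply the empty interval (%g, %g]",
          nm, gt_cut, le_cut))
      }
      if (!is.na(gt_cut)) out[[length(out) + 1L]] <- threshold_rule(nm, "GT", gt_cut)
      if (!is.na(le_cut)) out[[length(out) + 1L]] <- threshold_rule(nm, "LE", le_cut)
    }
  }
  structure(list(rules = out), class = "region")
}

#' Region membership indicator
#'
#' Evaluates T = 1 if a row of the exposure matrix satisfies every rule of
#' the region (LE inclusive, GT strictly exclusive), else 0. The empty
#' region (full space) yields all ones.
#'
#' @param region A [region()] object.
#' @param A Exposure matrix or data frame with named columns.
#' @return Integer vector of 0/1 of length `nrow(A)`.
#' @export
region_membership <- function(region, A) {
  stopifnot(inherits(region, "region"))
  A <- as_numeric_matrix(A, "A")
  inside <- rep(TRUE, nrow(A))
  for (r in region$rules) {
    j <- match(r$exposure_name, colnames(A))
    if (is.na(j)) {
      stop(sprintf("aretree_error_unknown_exposure: '%s' is not a column of A",
                   r$exposure_name))
    }
    inside <- inside & (if (r$operator == "LE") A[, j] <= r$cutpoint
                        else A[, j] > r$cutpoint)
  }
  as.integer(inside)
}

#' Number of rules in a region
#' @param region A `region` object.
#' @return Integer count (0 for the full space).
#' @export
region_size <- function(region) length(region$rules)

#' Is the region the full exposure space?
#' @param region A `region` object.
#' @return `TRUE` if the region has no rules.
#' @export
is_full_space <- function(region) length(region$rules) == 0L

#' Variable signature of a region
#'
#' The sorted set of exposure names a region constrains. Used to group
#' fold-specific regions: two folds are said to find "the same solution"
#' when their regions constrain the same exposures, even if cutpoints
#' differ slightly.
#'
#' @param region A `region` object.
#' @return Character scalar, e.g. `"a1&a2"`; `""` for the full space.
#' @export
region_signature <- function(region) {
  if (is_full_space(region)) return("")
  paste(sort(unique(vapply(region$rules, function(r) r$exposure_name,
                           character(1)))), collapse = "&")
}

#' @export
format.region <- function(x, digits = 6, ...) {
  if (is_full_space(x)) return("<full exposure space>")
  paste(vapply(x$rules, format, character(1), digits = digits),
        collapse = " & ")
}

#' @export
print.region <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Structured (lossless) form of a region
#'
#' @param region A `region` object.
#' @return Data frame with columns `exposure`, `operator`, `cutpoint`; zero
#'   rows for the full space. [region_from_frame()] inverts it.
#' @export
region_to_frame <- function(region) {
  stopifnot(inherits(region, "region"))
  if (is_full_space(region)) {
    return(data.frame(exposure = character(0), operator = character(0),
                      cutpoint = numeric(0), stringsAsFactors = FALSE))
  }
  data.frame(
    exposure = vapply(region$rules, function(r) r$exposure_name, character(1)),
    operator = vapply(region$rules, function(r) r$operator, character(1)),
    cutpoint = vapply(region$rules, function(r) r$cutpoint, numeric(1)),
    stringsAsFactors = FALSE)
}

#' @rdname region_to_frame
#' @param frame Data frame as produced by `region_to_frame`.
#' @export
region_from_frame <- function(frame) {
  rules <- lapply(seq_len(nrow(frame)), function(i) {
    threshold_rule(frame$exposure[i], frame$operator[i], frame$cutpoint[i])
  })
  normalize_region(rules)
}

#' Add one rule to a region
#' @param region A `region`.
#' @param rule A `threshold_rule`.
#' @return The normalized extended region.
#' @export
region_add_rule <- function(region, rule) {
  normalize_region(c(region$rules, list(rule)))
}
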