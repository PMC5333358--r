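#' The 96 trinucleotide mutation context labels
#'
#' Standard lexicographic order: for each pyrimidine substitution class
#' (C>A, C>G, C>T, T>A, T>C, T>G), the 16 flanking-base contexts
#' `A[C>A]A`, `A[C>A]C`, ... in alphabetical order.
#'
#' @return Character vector of length 96.
#' @export
context_labels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s)
    as.vector(t(outer(bases, bases, function(l, r)
      paste0(l, "[", s, "]", r))))))
}

#' Refit a 96-context mutation spectrum onto known signatures
#'
#' Projects an observed mutation count vector onto a reference signature
#' matrix (96 contexts x K signatures, column-stochastic) with nonnegative
#' least squares: weights are physically exposures and cannot be negative.
#' Plain unconstrained least squares is available behind `method = "ols"`
#' for comparison (negative weights are then reported as-is and excluded
#' from the normalization only if the total is nonpositive).
#'
#' @param counts Nonnegative numeric 96-vector (total > 0), named by
#'   context or in the [context_labels()] order.
#' @param sigs 96 x K matrix with columns summing to 1.
#' @param method `"nnls"` (default) or `"ols"`.
#' @return Object of class `signature_fit`: `exposures` (normalized to sum
#'   1), `exposures_raw` (on the mutation-count scale), `residual_norm`,
#'   `fraction_explained` in `[0, 1]`, `fitted`, `method`.
#' @export
fit_exposures <- function(counts, sigs, method = c("nnls", "ols")) {
  method <- match.arg(method)
  counts <- as.numeric(counts)
  sigs <- as.matrix(sigs)
  if (length(counts) != nrow(sigs))
    stop("counts length must match nrow(sigs)")
  if (any(counts < 0)) stop("counts must be nonnegative")
  total <- sum(counts)
  if (total <= 0) stop("total mutation count must be positive")
  csums <- colSums(sigs)
  if (any(sigs < 0) || any(abs(csums - 1) > 1e-6))
    stop("signature columns must be nonnegative and sum to 1")
  y <- counts / total
  w <- if (method == "nnls") {
    pracma::lsqnonneg(sigs, y)$x
  } else {
    stats::lm.fit(sigs, y)$coefficients
  }
  w[is.na(w)] <- 0
  fitted <- as.numeric(sigs %*% w)
  resid <- y - fitted
  rn <- sqrt(sum(resid^2))
  fe <- max(0, min(1, 1 - sum(resid^2) / sum(y^2)))
  sw <- sum(w)
  structure(list(
    exposures = stats::setNames(if (sw > 0) w / sw else w, colnames(sigs)),
    exposures_raw = stats::setNames(w * total, colnames(sigs)),
    residual_norm = rn, fraction_explained = fe,
    fitted = fitted * total, method = method, total = total),
    class = "signature_fit")
}

#' @export
print.signature_fit <- function(x, digits = 3, ...) {
  cat("Signature refit (", x$method, "), ", x$total, " mutations\n", sep = "")
  top <- sort(x$exposures[x$exposures > 0], decreasing = TRUE)
  print(round(top, digits))
  cat("fraction explained:", round(x$fraction_explained, digits), "\n")
  invisible(x)
}

#' @export
coef.signature_fit <- function(object, ...) object$exposures

#' Read a signature reference matrix from TSV
#'
#' First column: context labels; remaining columns: one signature each.
#' Rows are reordered to the canonical [context_labels()] order when the
#' labels match it as a set; columns are renormalized to sum to 1 if they
#' are within 1e-3 of doing so already.
#'
#' @param path File path.
#' @return Numeric 96 x K matrix.
#' @export
read_signature_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  labs <- as.character(df[[1L]])
  m <- as.matrix(df[-1L])
  rownames(m) <- labs
  canon <- context_labels()
  if (setequal(labs, canon)) m <- m[canon, , drop = FALSE]
  cs <- colSums(m)
  if (any(abs(cs - 1) > 1e-3))
    stop("signature columns must sum to 1 (found ", round(min(cs), 3), "..",
         round(max(cs), 3), ")")
  sweep(m, 2L, cs, "/")
}
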