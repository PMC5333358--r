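#' Sector-rarefaction curve of detected somatic variability
#'
#' For each subsample size n (1..N sectors), `X_n` is the mean number of
#' distinct mutations detected in a random subsample of n sectors (sectors
#' drawn without replacement within a subsample). The fold increase
#' `X_n / X_1` measures how much variability additional biopsies reveal:
#' identical sectors give a flat curve at 1, disjoint sectors grow
#' linearly. When `choose(N, n) <= enum_limit` the subsampling mean is
#' computed by exhaustive enumeration of all subsets (exact, seed-free);
#' otherwise by Monte Carlo.
#'
#' @param sets List (named by sector) of per-sector mutation-id vectors, or
#'   a [presence_matrix()] / [mutation_table()] (converted with the shared
#'   detection threshold `min_alt`).
#' @param n_resamples Monte Carlo draws per n when enumeration is too
#'   costly (default 1000).
#' @param seed Integer seed (used only for the Monte Carlo path).
#' @param enum_limit Exhaustive enumeration budget (default 1000 subsets).
#' @param min_alt Detection threshold when `sets` is a [mutation_table()].
#' @return Object of class `rarefaction_curve`: data.frame-backed list with
#'   `n`, `X_n`, `fold`, plus `n_sectors`, `n_resamples`.
#' @export
rarefaction <- function(sets, n_resamples = 1000L, seed = 1L,
                        enum_limit = 1000L, min_alt = 3L) {
  if (inherits(sets, "mutation_table")) sets <- presence_matrix(sets, min_alt)
  if (is.matrix(sets))
    sets <- apply(unclass(sets), 1L, function(r) which(r > 0), simplify = FALSE)
  N <- length(sets)
  if (N < 2L) stop("need at least 2 sectors")
  if (n_resamples < 1L) stop("n_resamples must be >= 1")
  sets <- lapply(sets, unique)
  if (!length(unique(unlist(sets))))
    stop("all sector sets are empty: fold change is undefined")
  union_size <- function(idx) length(unique(unlist(sets[idx], use.names = FALSE)))
  set.seed(derive_seed(seed, "rarefaction"))
  X <- vapply(seq_len(N), function(n) {
    if (choose(N, n) <= enum_limit) {
      mean(utils::combn(N, n, union_size))
    } else {
      mean(vapply(seq_len(n_resamples),
                  function(i) union_size(sample.int(N, n)), 0))
    }
  }, 0)
  structure(list(n = seq_len(N), X_n = X, fold = X / X[1L],
                 n_sectors = N, n_resamples = n_resamples),
            class = "rarefaction_curve")
}

#' @export
print.rarefaction_curve <- function(x, ...) {
  cat("Rarefaction over", x$n_sectors, "sectors\n")
  print(data.frame(n = x$n, X_n = round(x$X_n, 2), fold = round(x$fold, 3)))
  invisible(x)
}

#' @export
plot.rarefaction_curve <- function(x, ...) {
  graphics::plot(x$n, x$fold, type = "b", pch = 16,
                 xlab = "sectors sampled (n)",
                 ylab = expression(X[n] / X[1]), ...)
  invisible(x)
}

#' ITH ranking statistic: the fold increase at n = 2
#'
#' The slope of the rarefaction trajectory at its first step (the value of
#' `X_n / X_1` at n = 2); patients are ranked by this value, larger meaning
#' more variability hidden from a single biopsy.
#'
#' @param curve A [rarefaction()] result.
#' @return `fold` at n = 2 (always >= 1).
#' @export
ith_slope <- function(curve) {
  stopifnot(inherits(curve, "rarefaction_curve"))
  if (curve$n_sectors < 2L) stop("curve needs n = 2")
  curve$fold[2L]
}

#' Compare high-VAF proportions of driver vs background mutations
#'
#' Tests whether driver mutations sit at higher allele frequencies than the
#' background: each set is split at `threshold` (strictly greater counts as
#' high) and the resulting 2x2 table is tested with Pearson's chi-square
#' without continuity correction.
#'
#' @param driver_vafs,background_vafs Numeric VAF vectors (both nonempty).
#' @param threshold VAF cut (default 0.15).
#' @return List with `chi2`, `p`, and the 2x2 `table`
#'   (rows driver/background, columns above/below).
#' @export
driver_vaf_test <- function(driver_vafs, background_vafs, threshold = 0.15) {
  if (!length(driver_vafs) || !length(background_vafs))
    stop("both VAF sets must be nonempty")
  tab <- rbind(driver = c(above = sum(driver_vafs > threshold),
                          below = sum(driver_vafs <= threshold)),
               background = c(above = sum(background_vafs > threshold),
                              below = sum(background_vafs <= threshold)))
  if (any(colSums(tab) == 0L))
    stop("degenerate margin: all mutations on one side of the threshold (",
         colnames(tab)[colSums(tab) == 0L][1L], ")")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ct$statistic), p = unname(ct$p.value), table = tab)
}
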