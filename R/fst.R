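#' Weir-Cockerham Fst between two sectors at one or many sites
#'
#' Two-population variance-components (ANOVA) estimator of theta, treating
#' sequencing reads as haploid allele samples (read counts are not diploid
#' genotypes, so there is no heterozygosity term). With allele frequencies
#' `p1 = alt1/n1`, `p2 = alt2/n2`, weighted mean `pbar` and
#' `nc = n1 + n2 - (n1^2 + n2^2)/(n1 + n2)`:
#' \deqn{MSP = n1 (p1-\bar p)^2 + n2 (p2-\bar p)^2}
#' \deqn{MSG = (n1 p1 (1-p1) + n2 p2 (1-p2)) / (n1 + n2 - 2)}
#' \deqn{\theta = (MSP - MSG) / (MSP + (nc - 1) MSG)}
#' A fixed difference with equal sample sizes gives exactly 1; identical
#' frequencies give a value <= 0 (the estimator is negatively biased near
#' zero differentiation). Sites monomorphic across the pooled pair have no
#' allele-frequency variance to partition and return `NA` (excluded
#' downstream).
#'
#' @param alt1,n1 Alternate read count and total depth in the first sector
#'   (vectorized over sites).
#' @param alt2,n2 Same for the second sector.
#' @return Numeric vector of theta values in `(-Inf, 1]`, `NA` where
#'   undefined (monomorphic pooled site or depth < 1 in either sector).
#' @references Weir & Cockerham (1984) Evolution 38:1358-1370.
#' @export
wc_fst <- function(alt1, n1, alt2, n2) {
  stopifnot(length(alt1) == length(n1), length(alt2) == length(n2),
            length(alt1) == length(alt2))
  bad <- n1 < 1 | n2 < 1 | alt1 < 0 | alt2 < 0 | alt1 > n1 | alt2 > n2
  p1 <- alt1 / n1
  p2 <- alt2 / n2
  ntot <- n1 + n2
  pbar <- (alt1 + alt2) / ntot
  mono <- pbar == 0 | pbar == 1
  msp <- n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2
  msg <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (ntot - 2)
  nc <- ntot - (n1^2 + n2^2) / ntot
  theta <- (msp - msg) / (msp + (nc - 1) * msg)
  # pure fixed difference: msg = 0 and msp > 0 -> theta = 1 (0/0 guarded)
  theta[msg == 0 & msp > 0] <- 1
  theta[bad | mono | ntot <= 2] <- NA_real_
  theta
}

#' Recalibrate allele counts for tumour purity at a common depth
#'
#' Observed variant allele frequencies are diluted by normal-cell
#' contamination; the purity-corrected frequency is
#' `f_adj = min(f_obs / purity, 1)`, and every sector is re-expressed at a
#' common read depth by drawing `alt ~ Binomial(target_depth, f_adj)`
#' (resampling the same number of reads for all sectors).
#'
#' @param mt A [mutation_table()].
#' @param purities Named numeric vector of purities in `(0, 1]`, one per
#'   sector of `mt` (names matched to sector ids).
#' @param target_depth Common depth; default `"min"` uses the minimum
#'   positive observed depth across all sites and sectors.
#' @param seed Integer seed.
#' @return A new [mutation_table()] with all depths equal to `target_depth`.
#' @export
purity_recalibrate <- function(mt, purities, target_depth = "min", seed = 1L) {
  stopifnot(inherits(mt, "mutation_table"))
  if (is.null(names(purities))) names(purities) <- mt$sectors
  purities <- purities[mt$sectors]
  if (any(is.na(purities) | purities <= 0 | purities > 1))
    stop("purities must be in (0, 1] and cover every sector")
  depth <- total_depth(mt)
  if (identical(target_depth, "min")) {
    pos <- depth[depth > 0]
    if (!length(pos)) stop("no site has positive depth")
    target_depth <- min(pos)
  }
  target_depth <- as.integer(target_depth)
  if (target_depth < 1L) stop("target_depth must be >= 1")
  f_obs <- mt$alt_count / depth
  f_obs[depth == 0] <- 0
  f_adj <- sweep(f_obs, 2L, purities, "/")
  f_adj <- pmin(f_adj, 1)
  set.seed(derive_seed(seed, "purity_recalibrate"))
  alt <- matrix(stats::rbinom(length(f_adj), target_depth, as.numeric(f_adj)),
                nrow = nrow(f_adj), dimnames = dimnames(mt$alt_count))
  mutation_table(mt$variants, ref_count = target_depth - alt, alt_count = alt)
}

#' Euclidean distances between sector positions
#' @param meta A [sector_metadata()].
#' @return Symmetric matrix of distances in millimetres.
#' @export
pairwise_distances <- function(meta) {
  pos <- as.matrix(meta[, c("x", "y", "z")])
  if (any(!is.finite(pos))) stop("missing or non-finite sector position")
  d <- as.matrix(stats::dist(pos))
  dimnames(d) <- list(meta$sector_id, meta$sector_id)
  d
}

#' Per-site, per-pair Fst records with physical distances
#'
#' For every pair of sectors and every site polymorphic across the pooled
#' pair, computes the Weir-Cockerham theta ([wc_fst()]) and attaches the
#' pair's Euclidean distance. Undefined (monomorphic) sites are excluded
#' and their count reported via the `"n_excluded"` attribute. Negative
#' theta values are retained: truncating them at zero would bias the
#' isolation-by-distance slope.
#'
#' @param mt A [mutation_table()] (typically after [purity_recalibrate()]).
#' @param meta A [sector_metadata()] covering the table's sectors.
#' @return data.frame with columns `mutation_id, sector1, sector2, fst,
#'   distance_mm`.
#' @export
fst_records <- function(mt, meta) {
  stopifnot(inherits(mt, "mutation_table"))
  if (!all(mt$sectors %in% meta$sector_id))
    stop("metadata missing sectors: ",
         paste(setdiff(mt$sectors, meta$sector_id), collapse = ", "))
  dmat <- pairwise_distances(meta)
  depth <- total_depth(mt)
  secs <- mt$sectors
  out <- vector("list", choose(length(secs), 2L))
  k <- 0L; n_excluded <- 0L
  for (i in seq_along(secs)[-length(secs)]) for (j in (i + 1L):length(secs)) {
    th <- wc_fst(mt$alt_count[, i], depth[, i], mt$alt_count[, j], depth[, j])
    keep <- !is.na(th)
    n_excluded <- n_excluded + sum(!keep)
    k <- k + 1L
    out[[k]] <- data.frame(mutation_id = mt$variants$mutation_id[keep],
                           sector1 = secs[i], sector2 = secs[j],
                           fst = th[keep],
                           distance_mm = dmat[secs[i], secs[j]],
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "n_excluded") <- n_excluded
  res
}

#' Isolation-by-distance regression of pooled per-site Fst on distance
#'
#' Ordinary least squares of Fst on physical distance over all pooled
#' per-site, per-pair records (`fst ~ distance`, fitted with `lm()`); the
#' slope's two-sided p-value comes from the classical t-test. Records are
#' treated as independent, a known simplification of pooling. A per-pair
#' mean variant (`pool = "pair_mean"`) averages Fst within each sector pair
#' first.
#'
#' @param records Output of [fst_records()] (needs >= 3 rows and >= 2
#'   distinct distances).
#' @param pool `"site"` (default, pool every per-site record) or
#'   `"pair_mean"`.
#' @return Object of class `ibd_fit` with elements `slope` (per mm),
#'   `intercept`, `p_value`, `n_points`, and the underlying `lm` fit.
#' @export
ibd_regression <- function(records, pool = c("site", "pair_mean")) {
  pool <- match.arg(pool)
  if (pool == "pair_mean") {
    agg <- stats::aggregate(fst ~ sector1 + sector2 + distance_mm,
                            data = records, FUN = mean)
    records <- agg
  }
  if (nrow(records) < 3L) stop("need >= 3 Fst records")
  if (length(unique(records$distance_mm)) < 2L)
    stop("all distances equal: slope is unidentifiable")
  fit <- stats::lm(fst ~ distance_mm, data = records)
  cf <- summary(fit)$coefficients
  structure(list(slope = unname(cf["distance_mm", "Estimate"]),
                 intercept = unname(cf["(Intercept)", "Estimate"]),
                 p_value = unname(cf["distance_mm", "Pr(>|t|)"]),
                 n_points = nrow(records), pool = pool, lm = fit),
            class = "ibd_fit")
}

#' @export
print.ibd_fit <- function(x, ...) {
  cat("Isolation-by-distance fit (", x$n_points, " pooled Fst records, ",
      x$pool, " pooling)\n", sep = "")
  cat(sprintf("  slope     %+.3g per mm\n  intercept %+.3g\n  p-value   %.3g\n",
              x$slope, x$intercept, x$p_value))
  invisible(x)
}

#' @export
coef.ibd_fit <- function(object, ...)
  c(intercept = object$intercept, slope = object$slope)

#' @export
summary.ibd_fit <- function(object, ...) summary(object$lm, ...)

#' @export
plot.ibd_fit <- function(x, ...) {
  d <- x$lm$model
  graphics::plot(d$distance_mm, d$fst, xlab = "distance (mm)", ylab = "Fst",
                 pch = 16, col = grDevices::grey(0.4, 0.4), ...)
  graphics::abline(x$lm, col = "firebrick", lwd = 2)
  invisible(x)
}

#' Boxplot summaries of Fst by physical distance
#'
#' Fst values from all sector pairs at the same physical distance are
#' summarised with the standard quartile rule (linear interpolation) and
#' the whisker convention
#' `upper = min(max(x), Q3 + 1.5 IQR)`, `lower = max(min(x), Q1 - 1.5 IQR)`;
#' values beyond the whiskers are listed as outliers.
#'
#' @param records Output of [fst_records()].
#' @param digits Distances are grouped after rounding to this many digits.
#' @return data.frame (one row per distance) with columns `distance_mm, n,
#'   lower_whisker, Q1, median, Q3, upper_whisker` and a list column
#'   `outliers`.
#' @export
distance_boxplots <- function(records, digits = 6L) {
  key <- round(records$distance_mm, digits)
  groups <- split(records$fst, key)
  summarise <- function(x) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3L] - q[1L]
    up <- min(max(x), q[3L] + 1.5 * iqr)
    lo <- max(min(x), q[1L] - 1.5 * iqr)
    list(lo, q[1L], q[2L], q[3L], up, list(x[x < lo | x > up]))
  }
  rows <- lapply(groups, summarise)
  out <- data.frame(distance_mm = as.numeric(names(groups)),
                    n = lengths(groups),
                    lower_whisker = vapply(rows, `[[`, 0, 1L),
                    Q1 = vapply(rows, `[[`, 0, 2L),
                    median = vapply(rows, `[[`, 0, 3L),
                    Q3 = vapply(rows, `[[`, 0, 4L),
                    upper_whisker = vapply(rows, `[[`, 0, 5L))
  out$outliers <- lapply(rows, function(r) r[[6L]][[1L]])
  out <- out[order(out$distance_mm), ]
  rownames(out) <- NULL
  out
}
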