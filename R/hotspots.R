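#' Sliding-window scan of integration sites for hotspot regions
#'
#' Tiles every chromosome with windows of `window` bp advancing by `step`
#' bp (windows anchored at 0; a final short window clipped at the
#' chromosome end is emitted), counts the integration sites falling in
#' each window, and flags windows whose count strictly exceeds
#' `min_sites_exclusive` as hotspots. The defaults are a 20 kb window, a
#' 10 kb step and the `> 3` sites rule. Sites are counted per occurrence,
#' so recurrent integration at one base in several samples counts
#' multiply (set `unique_positions = TRUE` to collapse them).
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based) and
#'   optionally `sample`, `support_reads`.
#' @param genome Named vector of chromosome lengths (bp).
#' @param window,step Window and stride in bp (`window >= step >= 1`).
#' @param min_sites_exclusive Hotspot if `site_count > ` this (default 3).
#' @param unique_positions Collapse duplicate (chrom, pos) before counting.
#' @return data.frame of class `hotspot_scan`: `chrom, start, end`
#'   (0-based half-open), `site_count`, `is_hotspot`, sorted by
#'   (chrom, start), with the window size in attributes.
#' @export
scan_hotspots <- function(sites, genome, window = 20000L, step = 10000L,
                          min_sites_exclusive = 3L, unique_positions = FALSE) {
  if (!(window >= step && step >= 1L)) stop("need window >= step >= 1")
  sites <- as.data.frame(sites)
  stopifnot(all(c("chrom", "pos") %in% names(sites)))
  if (is.null(names(genome))) stop("genome must be a named chrom-length map")
  unknown <- setdiff(unique(sites$chrom), names(genome))
  if (length(unknown)) stop("site on unknown chromosome: ", unknown[1L])
  if (unique_positions) sites <- unique(sites[c("chrom", "pos")])
  out <- vector("list", length(genome))
  for (ci in seq_along(genome)) {
    chrom <- names(genome)[ci]
    len <- genome[[ci]]
    p <- sites$pos[sites$chrom == chrom]
    if (length(p) && (any(p < 1L) || any(p > len))) {
      bad <- p[p < 1L | p > len][1L]
      stop("site at ", chrom, ":", bad, " outside chromosome length ", len)
    }
    starts <- seq.int(0L, max(0L, len - 1L), by = step)
    ends <- pmin(starts + window, len)
    p0 <- sort(p) - 1L  # 0-based; site in [s, e) iff s <= p-1 < e
    cnt <- findInterval(ends - 1L, p0, left.open = FALSE) -
      findInterval(starts - 1L, p0)
    # findInterval(x, p0) = #{p0 <= x}; count in [s, e) = #{p0 <= e-1} - #{p0 <= s-1}
    out[[ci]] <- data.frame(chrom = chrom, start = starts, end = ends,
                            site_count = as.integer(cnt),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res$is_hotspot <- res$site_count > min_sites_exclusive
  rownames(res) <- NULL
  structure(res, class = c("hotspot_scan", "data.frame"),
            window = as.integer(window), step = as.integer(step),
            min_sites_exclusive = as.integer(min_sites_exclusive))
}

#' Fraction of the genome covered by hotspot windows
#'
#' By default windows are counted without merging overlaps
#' (`n_windows x window_size / genome_length`), the arithmetic behind
#' per-window genome-fraction summaries; `merged = TRUE` instead unions
#' overlapping hotspot windows into intervals before measuring.
#'
#' @param scan A [scan_hotspots()] result (or any data.frame with `chrom`,
#'   `start`, `end`, `is_hotspot`).
#' @param genome_length Total genome length in bp (default 3e9 when no
#'   genome map is supplied; override with exact assembly lengths).
#' @param merged Merge overlapping hotspot windows first (default FALSE).
#' @return Percentage of the genome in hotspot windows.
#' @export
genome_fraction <- function(scan, genome_length = 3e9, merged = FALSE) {
  if (genome_length <= 0) stop("genome_length must be positive")
  hs <- scan[scan$is_hotspot, , drop = FALSE]
  if (!nrow(hs)) return(0)
  if (!merged) {
    bp <- sum(hs$end - hs$start)
  } else {
    bp <- 0
    for (chrom in unique(hs$chrom)) {
      h <- hs[hs$chrom == chrom, , drop = FALSE]
      h <- h[order(h$start), ]
      s <- h$start[1L]; e <- h$end[1L]
      for (i in seq_len(nrow(h))[-1L]) {
        if (h$start[i] <= e) e <- max(e, h$end[i])
        else { bp <- bp + (e - s); s <- h$start[i]; e <- h$end[i] }
      }
      bp <- bp + (e - s)
    }
  }
  100 * bp / genome_length
}

#' Write hotspot windows as BED
#'
#' Emits the hotspot windows (0-based half-open, as stored) one per line.
#' Input must already be sorted by (chrom, start).
#'
#' @param scan A [scan_hotspots()] result or compatible data.frame.
#' @param path Output path.
#' @param hotspots_only Write only flagged windows (default TRUE).
#' @export
write_hotspots <- function(scan, path, hotspots_only = TRUE) {
  df <- as.data.frame(scan)
  ord <- order(df$chrom, df$start)
  if (!identical(ord, seq_len(nrow(df))))
    stop("windows must be sorted by (chrom, start)")
  if (hotspots_only) df <- df[df$is_hotspot, , drop = FALSE]
  cols <- df[c("chrom", "start", "end", "site_count")]
  utils::write.table(cols, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an integration-site list (TSV with chrom, pos[, sample] columns)
#' @param path File path.
#' @return data.frame with `chrom`, `pos`, and any further columns present.
#' @export
read_integration_sites <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (!all(c("chrom", "pos") %in% names(df)))
    stop("integration-site TSV needs chrom and pos columns")
  df$pos <- as.integer(df$pos)
  df
}

#' Map integration sites onto the lineages of a sector phylogeny
#'
#' Each site, described by the set of sectors carrying it, is assigned to
#' the deepest tree edge whose descendant leaf set equals that sector set.
#' Sites present in every sector map to the trunk (ordered by genomic
#' coordinate); patterns matching no clade go to a `homoplasy` bucket.
#'
#' @param tree A `phylo` whose tips are sector ids.
#' @param site_sets Named list: for each site id, the character vector of
#'   sectors carrying it. Site ids of the form `chrom:pos` sort the trunk.
#' @return List with elements `trunk`, `homoplasy`, and one element per
#'   matched clade (named by the sorted sector set), each a character
#'   vector of site ids.
#' @export
annotate_tree_integrations <- function(tree, site_sets) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  bad <- setdiff(unique(unlist(site_sets)), tips)
  if (length(bad)) stop("site carried by unknown sector: ", bad[1L])
  # descendant tip sets of every edge (child side), rooted representation
  clades <- c(as.list(tips),
              lapply(ape::prop.part(tree), function(i) tips[i]))
  clade_keys <- vapply(lapply(clades, sort), paste, "", collapse = "|")
  coord_order <- function(ids) {
    parts <- strsplit(ids, ":")
    chrom <- vapply(parts, `[`, "", 1L)
    pos <- suppressWarnings(as.integer(vapply(parts, function(p)
      if (length(p) >= 2L) p[2L] else NA_character_, "")))
    ids[order(chrom, pos)]
  }
  out <- list(trunk = character(0), homoplasy = character(0))
  for (id in names(site_sets)) {
    key <- paste(sort(unique(site_sets[[id]])), collapse = "|")
    if (key == paste(sort(tips), collapse = "|")) {
      out$trunk <- c(out$trunk, id)
    } else if (key %in% clade_keys) {
      out[[key]] <- c(out[[key]], id)
    } else {
      out$homoplasy <- c(out$homoplasy, id)
    }
  }
  out$trunk <- coord_order(out$trunk)
  out
}
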