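#' Per-sector somatic mutation table
#'
#' The universal input of the package: somatic variant calls with per-sector
#' ref/alt read counts. Positions are 1-based inclusive, as in VCF; they are
#' converted to 0-based half-open coordinates only when writing BED.
#'
#' @param variants data.frame with columns `mutation_id`, `chrom`, `pos`
#'   (1-based), `ref`, `alt` (alleles). If `mutation_id` is missing it
#'   defaults to `"chrom:pos:ref:alt"`.
#' @param ref_count,alt_count Integer matrices, sites x sectors, of reference
#'   and alternate read counts. Column names are the ordered sector ids.
#' @return An object of class `mutation_table`: a list with elements
#'   `variants`, `ref_count`, `alt_count`, `sectors`.
#' @seealso [read_mutation_table()], [presence_matrix()]
#' @export
mutation_table <- function(variants, ref_count, alt_count) {
  variants <- as.data.frame(variants)
  ref_count <- as.matrix(ref_count)
  alt_count <- as.matrix(alt_count)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(variants)))
    stop("variants must have columns chrom, pos, ref, alt")
  if (is.null(variants$mutation_id))
    variants$mutation_id <- paste(variants$chrom, variants$pos,
                                  variants$ref, variants$alt, sep = ":")
  variants$mutation_id <- as.character(variants$mutation_id)
  variants$pos <- as.integer(variants$pos)
  if (anyDuplicated(variants$mutation_id))
    stop("duplicate mutation_id: ",
         variants$mutation_id[duplicated(variants$mutation_id)][1L])
  if (nrow(variants) && any(variants$pos < 1L))
    stop("pos must be >= 1 (1-based coordinates)")
  if (nrow(ref_count) != nrow(variants) || nrow(alt_count) != nrow(variants))
    stop("count matrices must have one row per variant")
  if (!identical(colnames(ref_count), colnames(alt_count)) ||
      is.null(colnames(ref_count)))
    stop("ref_count and alt_count must share identical sector column names")
  if (length(ref_count) && (any(ref_count < 0) || any(alt_count < 0)))
    stop("read counts must be non-negative")
  storage.mode(ref_count) <- "integer"
  storage.mode(alt_count) <- "integer"
  rownames(ref_count) <- rownames(alt_count) <- variants$mutation_id
  structure(list(variants = variants, ref_count = ref_count,
                 alt_count = alt_count, sectors = colnames(ref_count)),
            class = "mutation_table")
}

#' @export
print.mutation_table <- function(x, ...) {
  cat("mutation_table: ", nrow(x$variants), " variants x ",
      length(x$sectors), " sectors\n", sep = "")
  cat("  sectors:", paste(x$sectors, collapse = ", "), "\n")
  if (nrow(x$variants)) {
    d <- total_depth(x)
    cat("  mean depth: ", round(mean(d), 1), "\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.mutation_table <- function(x) c(nrow(x$variants), length(x$sectors))

#' Total read depth per site and sector
#' @param mt A [mutation_table()].
#' @return Integer matrix `ref_count + alt_count`.
#' @export
total_depth <- function(mt) mt$ref_count + mt$alt_count

#' Observed variant allele frequencies
#'
#' `alt / (ref + alt)`; sites with zero depth give `NaN`.
#' @param mt A [mutation_table()].
#' @return Numeric matrix, sites x sectors.
#' @export
vaf <- function(mt) mt$alt_count / (mt$ref_count + mt$alt_count)

#' Read a mutation table from TSV or a multi-sample VCF
#'
#' The TSV layout has one header row: `mutation_id chrom pos ref alt`
#' followed by two columns per sector named `<sector>_ref` and
#' `<sector>_alt`, in sector order (the `mutation_id` column may be
#' omitted). VCF input must be multi-sample with per-sample `AD`
#' (allelic depth) fields; only the first ALT allele is used.
#'
#' @param path File path.
#' @param format `"tsv"` (canonical interchange format) or `"vcf"`.
#' @return A [mutation_table()]. Sector order follows the header / VCF
#'   sample order.
#' @export
read_mutation_table <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "vcf") return(read_mutation_table_vcf(path))
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character", sep = "\t")
  fixed <- intersect(c("mutation_id", "chrom", "pos", "ref", "alt"), names(df))
  if (!all(c("chrom", "pos", "ref", "alt") %in% fixed))
    stop("TSV header must contain chrom, pos, ref, alt")
  cnt_cols <- setdiff(names(df), fixed)
  if (length(cnt_cols) %% 2L != 0L)
    stop("count columns must come in <sector>_ref/<sector>_alt pairs")
  sec_ref <- cnt_cols[grepl("_ref$", cnt_cols)]
  sec_alt <- cnt_cols[grepl("_alt$", cnt_cols)]
  sectors <- sub("_ref$", "", sec_ref)
  if (!identical(sectors, sub("_alt$", "", sec_alt)))
    stop("sector names disagree between _ref and _alt columns")
  parse_counts <- function(cols, kind) {
    m <- matrix(NA_integer_, nrow(df), length(cols),
                dimnames = list(NULL, sectors))
    for (j in seq_along(cols)) {
      v <- suppressWarnings(as.integer(df[[cols[j]]]))
      bad <- which(is.na(v) | v < 0L)
      if (length(bad))
        stop("malformed ", kind, " count in column '", cols[j],
             "' at line ", bad[1L] + 1L)  # +1 for the header row
      m[, j] <- v
    }
    m
  }
  pos <- suppressWarnings(as.integer(df$pos))
  bad <- which(is.na(pos) | pos < 1L)
  if (length(bad)) stop("malformed pos at line ", bad[1L] + 1L)
  variants <- data.frame(chrom = df$chrom, pos = pos,
                         ref = df$ref, alt = df$alt,
                         stringsAsFactors = FALSE)
  if ("mutation_id" %in% fixed) variants$mutation_id <- df$mutation_id
  mutation_table(variants,
                 ref_count = parse_counts(sec_ref, "ref"),
                 alt_count = parse_counts(sec_alt, "alt"))
}

read_mutation_table_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("VCF input requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")
  if (is.null(ad) || !ncol(ad)) stop("VCF has no per-sample AD fields")
  fix <- vcfR::getFIX(v)
  alt1 <- vapply(strsplit(fix[, "ALT"], ","), `[`, "", 1L)
  split_ad <- function(i) {
    parts <- strsplit(ad[, i], ",")
    ref <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
    alt <- suppressWarnings(as.integer(vapply(parts, function(p)
      if (length(p) >= 2L) p[2L] else NA_character_, "")))
    cbind(ref, alt)
  }
  n <- nrow(ad)
  ref_m <- alt_m <- matrix(0L, n, ncol(ad), dimnames = list(NULL, colnames(ad)))
  for (i in seq_len(ncol(ad))) {
    x <- split_ad(i)
    x[is.na(x)] <- 0L
    ref_m[, i] <- x[, 1L]; alt_m[, i] <- x[, 2L]
  }
  variants <- data.frame(chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]),
                         ref = fix[, "REF"], alt = alt1,
                         stringsAsFactors = FALSE)
  mutation_table(variants, ref_m, alt_m)
}

#' Write a mutation table as TSV
#'
#' Inverse of [read_mutation_table()]; `read(write(x))` is the identity.
#' @param mt A [mutation_table()].
#' @param path Output path.
#' @export
write_mutation_table <- function(mt, path) {
  df <- mt$variants[c("mutation_id", "chrom", "pos", "ref", "alt")]
  for (s in mt$sectors) {
    df[[paste0(s, "_ref")]] <- mt$ref_count[, s]
    df[[paste0(s, "_alt")]] <- mt$alt_count[, s]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Sector metadata: spatial position and tumour purity
#'
#' @param sector_id Character vector of unique sector ids.
#' @param position Numeric matrix, sectors x 3, of positions in millimetres.
#'   Linear sampling grids use `(x, 0, 0)`.
#' @param purity Numeric vector of tumour purities in `(0, 1]` (the fraction
#'   of tumour cells in each sector; it dilutes observed allele frequencies).
#' @return data.frame of class `sector_metadata` with columns
#'   `sector_id, x, y, z, purity`.
#' @export
sector_metadata <- function(sector_id, position, purity) {
  sector_id <- as.character(sector_id)
  position <- matrix(as.numeric(position), ncol = 3)
  purity <- as.numeric(purity)
  if (anyDuplicated(sector_id)) stop("sector ids must be unique")
  if (nrow(position) != length(sector_id) || length(purity) != length(sector_id))
    stop("sector_id, position and purity lengths disagree")
  if (any(!is.finite(position))) stop("positions must be finite")
  if (any(purity <= 0 | purity > 1)) stop("purity must lie in (0, 1]")
  structure(data.frame(sector_id = sector_id, x = position[, 1],
                       y = position[, 2], z = position[, 3],
                       purity = purity, stringsAsFactors = FALSE),
            class = c("sector_metadata", "data.frame"))
}

#' Read sector metadata from TSV (`sector_id x y z purity` header)
#' @param path File path.
#' @return A [sector_metadata()] data.frame.
#' @export
read_sector_metadata <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  need <- c("sector_id", "x", "y", "z", "purity")
  if (!all(need %in% names(df)))
    stop("sector TSV must have columns: ", paste(need, collapse = ", "))
  sector_metadata(df$sector_id, cbind(df$x, df$y, df$z), df$purity)
}

#' Write sector metadata as TSV
#' @param meta A [sector_metadata()].
#' @param path Output path.
#' @export
write_sector_metadata <- function(meta, path) {
  utils::write.table(as.data.frame(meta), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
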