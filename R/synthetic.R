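#' Generate a synthetic multi-sector tumour dataset
#'
#' Emulates the mutation structure of multi-region tumour sequencing with
#' no access to patient data: truncal mutations carried by every sector,
#' two spatially contiguous clades (`left`/`right` of the tumour centre)
#' each with its own clade mutations, and private mutations per sector.
#' Sectors sit on a linear grid (spacing `sector_spacing_mm`, default
#' 10 mm, i.e. about 1 cm apart) and carry a tumour purity drawn uniformly
#' on `purity_range` (default 0.5-0.9, bracketing a mean of 0.7, the
#' high-purity regime typical of hepatocellular carcinoma). Observed read
#' counts at each diploid heterozygous site are
#' `alt ~ Binomial(depth, purity x CCF / 2)` with
#' `depth ~ Poisson(mean_depth)`, CCF being the cancer-cell fraction (1 for
#' every mutation the sector carries under this clonal model, 0 otherwise).
#'
#' @param n_sectors Number of sectors (>= 2).
#' @param n_truncal,n_clade,n_private Mutation counts: truncal; per clade
#'   (length-2 vector or scalar recycled); private per sector (scalar or
#'   per-sector vector).
#' @param clade_assignment Optional character vector (`"left"`/`"right"`
#'   per sector); default splits the sector line at its centre.
#' @param sector_spacing_mm Spacing of the linear sector grid (default 10).
#' @param purity_range Uniform purity bounds in `(0, 1]` (default
#'   `c(0.5, 0.9)`).
#' @param purity Optional explicit per-sector purity vector overriding
#'   `purity_range`.
#' @param mean_depth Mean sequencing depth (default 100).
#' @param seed Integer seed.
#' @return List with `table` (a [mutation_table()]), `meta`
#'   (a [sector_metadata()]), and `truth` (class per mutation, per-sector
#'   true CCF matrix, the true tree as a newick string, clade assignment).
#' @export
generate_tumour <- function(n_sectors, n_truncal = 100L, n_clade = 50L,
                            n_private = 20L, clade_assignment = NULL,
                            sector_spacing_mm = 10, purity_range = c(0.5, 0.9),
                            purity = NULL, mean_depth = 100L, seed = 1L) {
  if (n_sectors < 2L) stop("need at least 2 sectors")
  n_clade <- rep_len(as.integer(n_clade), 2L)
  n_private <- rep_len(as.integer(n_private), n_sectors)
  stopifnot(n_truncal >= 0L, all(n_clade >= 0L), all(n_private >= 0L),
            mean_depth >= 1)
  sectors <- paste0("S", seq_len(n_sectors))
  if (is.null(clade_assignment)) {
    clade_assignment <- rep(c("left", "right"),
                            c(ceiling(n_sectors / 2), floor(n_sectors / 2)))
  }
  stopifnot(length(clade_assignment) == n_sectors,
            all(clade_assignment %in% c("left", "right")))
  names(clade_assignment) <- sectors

  set.seed(derive_seed(seed, "generate_tumour"))
  if (is.null(purity)) {
    stopifnot(length(purity_range) == 2L, purity_range[1L] > 0,
              purity_range[2L] <= 1)
    purity <- stats::runif(n_sectors, purity_range[1L], purity_range[2L])
  }
  meta <- sector_metadata(sectors,
                          cbind((seq_len(n_sectors) - 1) * sector_spacing_mm,
                                0, 0),
                          purity)

  classes <- c(rep("truncal", n_truncal),
               rep("clade_left", n_clade[1L]), rep("clade_right", n_clade[2L]),
               unlist(lapply(seq_len(n_sectors), function(s)
                 rep(paste0("private_", sectors[s]), n_private[s]))))
  n_mut <- length(classes)
  if (!n_mut) stop("no mutations requested")
  # true cancer-cell fraction: 1 where the sector's lineage carries it
  ccf <- matrix(0, n_mut, n_sectors, dimnames = list(NULL, sectors))
  ccf[classes == "truncal", ] <- 1
  ccf[classes == "clade_left", clade_assignment == "left"] <- 1
  ccf[classes == "clade_right", clade_assignment == "right"] <- 1
  for (s in seq_len(n_sectors))
    ccf[classes == paste0("private_", sectors[s]), s] <- 1

  depth <- matrix(stats::rpois(n_mut * n_sectors, mean_depth),
                  n_mut, n_sectors, dimnames = list(NULL, sectors))
  depth[depth < 1L] <- 1L
  evaf <- sweep(ccf / 2, 2L, purity, "*")  # diploid heterozygous, CN-neutral
  alt <- matrix(stats::rbinom(n_mut * n_sectors, depth, evaf),
                n_mut, n_sectors, dimnames = list(NULL, sectors))
  variants <- data.frame(mutation_id = paste0("m", seq_len(n_mut)),
                         chrom = "synth", pos = seq_len(n_mut),
                         ref = "A", alt = "T", stringsAsFactors = FALSE)
  tab <- mutation_table(variants, ref_count = depth - alt, alt_count = alt)

  left <- sectors[clade_assignment == "left"]
  right <- sectors[clade_assignment == "right"]
  true_tree <- paste0("((", paste(left, collapse = ","), "),(",
                      paste(right, collapse = ","), "));")
  list(table = tab, meta = meta,
       truth = list(class = stats::setNames(classes, variants$mutation_id),
                    ccf = ccf, tree = true_tree,
                    clade_assignment = clade_assignment, purity = purity))
}

#' Generate a synthetic viral integration-site list
#'
#' Background sites are uniform over the supplied genome; each hotspot
#' specification drops its sites uniformly within +/- 10 kb of a centre,
#' emulating regions of intense integration.
#'
#' @param n_background Number of uniform background sites.
#' @param hotspot_specs List of `list(chrom =, centre =, n_sites =)`.
#' @param genome Named vector of chromosome lengths.
#' @param seed Integer seed.
#' @param hotspot_halfwidth Half-width of a cluster (default 10000 bp).
#' @return data.frame with `chrom`, `pos` (1-based), `sample`.
#' @export
generate_integration_sites <- function(n_background, hotspot_specs = list(),
                                       genome, seed = 1L,
                                       hotspot_halfwidth = 10000L) {
  stopifnot(n_background >= 0, !is.null(names(genome)))
  set.seed(derive_seed(seed, "generate_integration_sites"))
  out <- list()
  if (n_background > 0L) {
    tot <- sum(as.numeric(genome))
    chrom <- sample(names(genome), n_background, replace = TRUE,
                    prob = as.numeric(genome) / tot)
    pos <- vapply(chrom, function(ch) sample.int(genome[[ch]], 1L), 0L)
    out[[1L]] <- data.frame(chrom = chrom, pos = as.integer(pos),
                            sample = "background", stringsAsFactors = FALSE)
  }
  for (i in seq_along(hotspot_specs)) {
    sp <- hotspot_specs[[i]]
    if (sp$n_sites < 0L) stop("n_sites must be >= 0")
    if (!sp$chrom %in% names(genome)) stop("unknown chromosome: ", sp$chrom)
    len <- genome[[sp$chrom]]
    if (sp$centre < 1L || sp$centre > len)
      stop("hotspot centre outside chromosome bounds: ", sp$chrom, ":",
           sp$centre)
    lo <- max(1L, sp$centre - hotspot_halfwidth)
    hi <- min(len, sp$centre + hotspot_halfwidth)
    if (sp$n_sites > 0L)
      out[[length(out) + 1L]] <- data.frame(
        chrom = sp$chrom,
        pos = as.integer(sample(seq.int(lo, hi), sp$n_sites, replace = TRUE)),
        sample = paste0("hotspot", i), stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(0), pos = integer(0),
                      sample = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate a multinomial 96-context count vector from signature exposures
#'
#' Draws `total` mutations from the mixture profile
#' `signature_matrix %*% exposures`; the standard generative model behind
#' signature refitting, used as its test oracle.
#'
#' @param exposures Nonnegative weights summing to 1 (length K).
#' @param signature_matrix 96 x K column-stochastic matrix.
#' @param total Number of mutations to draw (>= 0).
#' @param seed Integer seed.
#' @return Integer 96-vector of context counts.
#' @export
generate_signature_counts <- function(exposures, signature_matrix, total,
                                      seed = 1L) {
  exposures <- as.numeric(exposures)
  if (any(exposures < 0)) stop("exposures must be nonnegative")
  if (abs(sum(exposures) - 1) > 1e-8) stop("exposures must sum to 1")
  sm <- as.matrix(signature_matrix)
  if (ncol(sm) != length(exposures))
    stop("exposures length must match ncol(signature_matrix)")
  if (any(abs(colSums(sm) - 1) > 1e-6))
    stop("signature columns must sum to 1")
  if (total < 0) stop("total must be >= 0")
  p <- as.numeric(sm %*% exposures)
  set.seed(derive_seed(seed, "generate_signature_counts"))
  if (total == 0) return(integer(nrow(sm)))
  as.integer(stats::rmultinom(1L, total, p))
}

#' Random column-stochastic signature matrix (synthetic reference)
#'
#' Dirichlet-like columns for testing signature refitting; not a real
#' signature catalogue.
#'
#' @param k Number of signatures.
#' @param n_contexts Number of contexts (default 96).
#' @param seed Integer seed.
#' @param concentration Gamma shape; smaller gives spikier signatures.
#' @return `n_contexts x k` matrix with columns summing to 1 and the
#'   [context_labels()] as row names when `n_contexts == 96`.
#' @export
random_signature_matrix <- function(k, n_contexts = 96L, seed = 1L,
                                    concentration = 0.3) {
  set.seed(derive_seed(seed, "random_signature_matrix"))
  m <- matrix(stats::rgamma(n_contexts * k, concentration), n_contexts, k)
  m <- sweep(m, 2L, colSums(m), "/")
  colnames(m) <- paste0("Signature.", seq_len(k))
  if (n_contexts == 96L) rownames(m) <- context_labels()
  m
}
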