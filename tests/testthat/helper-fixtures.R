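# Shared fixtures, built in code at test time.

# small mutation table: 3 variants, 2 sectors
tiny_table <- function() {
  variants <- data.frame(mutation_id = c("m1", "m2", "m3"),
                         chrom = "chr1", pos = c(100L, 200L, 300L),
                         ref = c("A", "C", "G"), alt = c("T", "G", "A"))
  mutation_table(variants,
                 ref_count = cbind(S1 = c(45L, 50L, 48L),
                                   S2 = c(30L, 52L, 20L)),
                 alt_count = cbind(S1 = c(5L, 0L, 12L),
                                   S2 = c(20L, 0L, 30L)))
}

tiny_table_tsv <- function(path = tempfile(fileext = ".tsv")) {
  write_mutation_table(tiny_table(), path)
  path
}

# random mutation table with the given dimensions
random_table <- function(n_mut, n_sectors, mean_depth = 60, seed = 1) {
  set.seed(seed)
  depth <- matrix(rpois(n_mut * n_sectors, mean_depth) + 1L,
                  n_mut, n_sectors)
  alt <- matrix(rbinom(n_mut * n_sectors, depth, runif(n_mut * n_sectors)),
                n_mut, n_sectors)
  colnames(depth) <- colnames(alt) <- paste0("S", seq_len(n_sectors))
  variants <- data.frame(chrom = "chr1", pos = seq_len(n_mut),
                         ref = "A", alt = "T")
  mutation_table(variants, ref_count = depth - alt, alt_count = alt)
}

# presence matrix where sectors split into two clean clades
two_clade_pm <- function(n_per_clade = 2, n_clade_mut = 3, n_truncal = 2) {
  sectors <- paste0("S", seq_len(2 * n_per_clade))
  left <- seq_len(n_per_clade)
  m <- cbind(matrix(1L, 2 * n_per_clade, n_truncal),
             matrix(0L, 2 * n_per_clade, 2 * n_clade_mut))
  m[left, n_truncal + seq_len(n_clade_mut)] <- 1L
  m[-left, n_truncal + n_clade_mut + seq_len(n_clade_mut)] <- 1L
  dimnames(m) <- list(sectors, paste0("m", seq_len(ncol(m))))
  presence_matrix(m)
}

# unrooted splits of a phylo tree as a canonical character set (independent
# of spatialith's internals; used to compare topologies)
tree_splits <- function(tree) {
  tips <- sort(tree$tip.label)
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  keys <- vapply(pp, function(i) {
    side <- sort(labs[i])
    if (tips[1L] %in% side) side <- sort(setdiff(tips, side))
    paste(side, collapse = "|")
  }, "")
  sizes <- lengths(strsplit(keys, "|", fixed = TRUE))
  sort(unique(keys[sizes >= 2 & sizes <= length(tips) - 2]))
}
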