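#' Simulate 3D lattice range-expansion tumour growth
#'
#' A single founder cell is seeded at the centre of a 3D cubic grid and the
#' population expands outwards: at each event a cell with at least one free
#' von Neumann neighbour (the six axial directions) is chosen at random and
#' divides, its two daughters randomly allocated to the parental site and
#' the free neighbouring site. Each daughter genome independently gains
#' `Poisson(mutation_rate)` new mutations under the infinite-sites model
#' (every mutation id is unique, no back-mutation). Cells with no free
#' neighbour simply cannot divide (no pushing). Optional death (an attempted
#' division removes the cell instead) and selection (each driver mutation
#' multiplies a cell's division weight by `1 + selection_coeff`) are
#' available; the defaults give neutral growth, under which reaching N cells
#' takes exactly N - 1 division events.
#'
#' @param target_population Final number of cells (>= 1).
#' @param mutation_rate Mean new mutations per daughter genome per division
#'   (default 0.5).
#' @param death_prob Probability, per attempted division, that the chosen
#'   cell dies instead (default 0).
#' @param selection_coeff Advantage multiplier per driver mutation
#'   (default 0, neutral).
#' @param driver_mutation_prob Probability that a new mutation is a driver
#'   (default 0).
#' @param grid_extent Half-width of the grid; `NULL` picks one comfortably
#'   holding the target population.
#' @param founder_mutations Mutations carried by the founding cell (the
#'   clonal mutations accumulated before expansion begins; they form the
#'   trunk shared by every descendant). Default 0.
#' @param seed Integer seed.
#' @return Object of class `tumour_sim`: the final [cell population]
#'   (occupied sites, per-cell clone-tree node), the clone tree (parent,
#'   mutation ranges per node), and counters `n_divisions`, `n_mutations`,
#'   `n_deaths`.
#' @export
simulate_growth <- function(target_population, mutation_rate = 0.5,
                            death_prob = 0, selection_coeff = 0,
                            driver_mutation_prob = 0, grid_extent = NULL,
                            founder_mutations = 0L, seed = 1L) {
  stopifnot(target_population >= 1, mutation_rate >= 0,
            death_prob >= 0, death_prob < 1,
            selection_coeff >= 0,
            driver_mutation_prob >= 0, driver_mutation_prob <= 1,
            founder_mutations >= 0)
  N <- as.integer(target_population)
  if (is.null(grid_extent))
    grid_extent <- ceiling(1.5 * (3 * N / (4 * pi))^(1 / 3)) + 2L
  ext <- as.integer(grid_extent)
  L <- 2L * ext + 1L
  # interior capacity excludes the 1-cell boundary shell (kept empty so the
  # six linear-index neighbour offsets never wrap across grid faces)
  if (N > (L - 2L)^3)
    stop("target_population ", N, " exceeds grid capacity ", (L - 2L)^3)
  offs <- c(1L, -1L, L, -L, L * L, -(L * L))
  centre <- ext + ext * L + ext * L * L + 1L  # 1-based linear index

  set.seed(derive_seed(seed, "simulate_growth"))
  occ <- integer(L^3)
  cap <- max(2L * N, 64L)
  site <- node <- integer(cap)        # per cell id
  alive <- logical(cap)
  tcap <- max(4L * N, 128L)
  parent <- nmut <- mstart <- ndriver <- integer(tcap)  # clone-tree nodes

  n_cells <- 1L; n_nodes <- 1L; n_mut <- as.integer(founder_mutations)
  n_div <- 0L; n_death <- 0L
  site[1L] <- centre; node[1L] <- 1L; alive[1L] <- TRUE
  parent[1L] <- 0L; nmut[1L] <- n_mut; mstart[1L] <- 1L; ndriver[1L] <- 0L
  occ[centre] <- 1L
  front <- 1L                      # candidate dividing cells (lazily pruned)
  pop <- 1L
  selective <- selection_coeff > 0 && driver_mutation_prob > 0

  while (pop < N && length(front)) {
    i <- if (length(front) == 1L) 1L
         else if (selective)
           sample.int(length(front), 1L,
                      prob = (1 + selection_coeff)^ndriver[node[front]])
         else sample.int(length(front), 1L)
    cl <- front[i]
    ns <- site[cl] + offs
    free <- ns[occ[ns] == 0L]
    if (!length(free)) {                       # blocked: prune lazily
      front[i] <- front[length(front)]
      front <- front[-length(front)]
      next
    }
    if (death_prob > 0 && stats::runif(1L) < death_prob) {
      occ[site[cl]] <- 0L
      alive[cl] <- FALSE
      front[i] <- front[length(front)]
      front <- front[-length(front)]
      # the freed site may unblock neighbours pruned earlier
      nb <- occ[ns]
      nb <- nb[nb != 0L]
      nb <- nb[!(nb %in% front)]
      if (length(nb)) front <- c(front, nb)
      n_death <- n_death + 1L
      pop <- pop - 1L
      if (pop == 0L) break
      next
    }
    tgt <- if (length(free) == 1L) free else free[sample.int(length(free), 1L)]
    # two daughters: one keeps the parental site, one takes the free site
    k <- stats::rpois(2L, mutation_rate)
    while (n_nodes + 2L > length(parent)) {
      pad <- integer(length(parent))
      parent <- c(parent, pad); nmut <- c(nmut, pad)
      mstart <- c(mstart, pad); ndriver <- c(ndriver, pad)
    }
    for (d in 1:2) {
      n_nodes <- n_nodes + 1L
      parent[n_nodes] <- node[cl]
      nmut[n_nodes] <- k[d]
      mstart[n_nodes] <- n_mut + 1L
      nd <- if (driver_mutation_prob > 0 && k[d] > 0L)
        stats::rbinom(1L, k[d], driver_mutation_prob) else 0L
      ndriver[n_nodes] <- ndriver[node[cl]] + nd
      n_mut <- n_mut + k[d]
    }
    node[cl] <- n_nodes - 1L                   # daughter at the parental site
    while (n_cells + 1L > length(site)) {
      site <- c(site, integer(length(site)))
      node <- c(node, integer(length(node)))
      alive <- c(alive, logical(length(alive)))
    }
    n_cells <- n_cells + 1L
    site[n_cells] <- tgt; node[n_cells] <- n_nodes; alive[n_cells] <- TRUE
    occ[tgt] <- n_cells
    front <- c(front, n_cells)
    n_div <- n_div + 1L
    pop <- pop + 1L
  }

  keep <- which(alive[seq_len(n_cells)])
  structure(list(
    site = site[keep], node = node[keep], pop_size = pop,
    tree = list(parent = parent[seq_len(n_nodes)],
                nmut = nmut[seq_len(n_nodes)],
                mstart = mstart[seq_len(n_nodes)],
                ndriver = ndriver[seq_len(n_nodes)]),
    n_divisions = n_div, n_mutations = n_mut, n_deaths = n_death,
    L = L, extent = ext,
    config = list(target_population = N, mutation_rate = mutation_rate,
                  death_prob = death_prob, selection_coeff = selection_coeff,
                  driver_mutation_prob = driver_mutation_prob,
                  founder_mutations = as.integer(founder_mutations),
                  seed = seed)),
    class = "tumour_sim")
}

#' @export
print.tumour_sim <- function(x, ...) {
  cat("tumour_sim: ", x$pop_size, " cells, ", x$n_divisions, " divisions, ",
      x$n_mutations, " mutations", sep = "")
  if (x$n_deaths) cat(", ", x$n_deaths, " deaths", sep = "")
  cat("\n")
  invisible(x)
}

#' Lattice coordinates of the living cells, centred on the founder site
#' @param sim A [simulate_growth()] result.
#' @return Integer matrix, cells x 3.
#' @export
cell_coords <- function(sim) {
  idx <- sim$site - 1L
  L <- sim$L
  cbind(x = idx %% L - sim$extent,
        y = (idx %/% L) %% L - sim$extent,
        z = idx %/% (L * L) - sim$extent)
}

#' Mutation ids carried by a clone-tree node (its full genotype)
#' @param sim A [simulate_growth()] result.
#' @param node Node index into the clone tree.
#' @return Integer vector of mutation ids along the root-to-node lineage.
#' @export
genotype <- function(sim, node) {
  tr <- sim$tree
  out <- integer(0)
  while (node > 0L) {
    if (tr$nmut[node] > 0L)
      out <- c(out, seq.int(tr$mstart[node], length.out = tr$nmut[node]))
    node <- tr$parent[node]
  }
  sort(out)
}

#' Place evenly spaced sector centres along a transect through the tumour
#'
#' Mimics a linear grid of biopsies across one axis of the tumour: centres
#' are evenly spaced along the x-axis line through the founder cell,
#' clipped to the occupied span.
#'
#' @param sim A [simulate_growth()] result.
#' @param n_sectors Number of sectors (>= 2).
#' @return Integer matrix, n_sectors x 3, of centred lattice coordinates.
#' @export
linear_transect <- function(sim, n_sectors) {
  if (n_sectors < 2L) stop("need at least 2 sectors")
  co <- cell_coords(sim)
  on_axis <- co[co[, "y"] == 0L & co[, "z"] == 0L, "x"]
  if (!length(on_axis)) stop("no occupied cell on the transect axis")
  span <- range(on_axis)
  xs <- round(seq(span[1L], span[2L], length.out = n_sectors))
  if (anyDuplicated(xs))
    stop("occupied span too small for ", n_sectors, " distinct sectors")
  cbind(x = as.integer(xs), y = 0L, z = 0L)
}

#' Sample spherical sectors of cells and harvest their mutations
#'
#' Each sector captures every living cell within Euclidean `radius` of its
#' centre (a lattice ball); a mutation's within-sector frequency is the
#' fraction of captured cells carrying it.
#'
#' @param sim A [simulate_growth()] result.
#' @param centres Integer matrix, sectors x 3, of centred lattice
#'   coordinates (e.g. from [linear_transect()]).
#' @param radius Sector radius in lattice units.
#' @param sector_ids Optional character labels (default `S1, S2, ...`).
#' @return List of class `sector_samples`: per sector `n_cells` and the
#'   per-node carrier counts; plus the centres/radius. Convert to a
#'   [mutation_table()] with [sectors_to_table()].
#' @export
sample_sectors <- function(sim, centres, radius = 2L,
                           sector_ids = paste0("S", seq_len(nrow(centres)))) {
  centres <- matrix(as.integer(centres), ncol = 3L)
  L <- sim$L; ext <- sim$extent
  r <- as.integer(radius)
  ball <- as.matrix(expand.grid(dx = -r:r, dy = -r:r, dz = -r:r))
  ball <- ball[rowSums(ball^2) <= radius^2, , drop = FALSE]
  occ <- integer(L^3)
  occ[sim$site] <- seq_along(sim$site)
  tr <- sim$tree
  samples <- vector("list", nrow(centres))
  for (s in seq_len(nrow(centres))) {
    cc <- centres[s, ]
    pts <- sweep(ball, 2L, cc + ext, "+")
    ok <- pts >= 0L & pts <= L - 1L
    pts <- pts[rowSums(ok) == 3L, , drop = FALSE]
    idx <- pts[, 1L] + L * pts[, 2L] + L * L * pts[, 3L] + 1L
    cells <- occ[idx]
    cells <- cells[cells != 0L]
    if (!length(cells))
      stop("empty sector at centre (", paste(cc, collapse = ", "), ")")
    # carrier count per clone-tree node: walk each cell's lineage to the root
    counts <- integer(length(tr$parent))
    for (cl in cells) {
      u <- sim$node[cl]
      while (u > 0L) {
        counts[u] <- counts[u] + 1L
        u <- tr$parent[u]
      }
    }
    samples[[s]] <- list(n_cells = length(cells), node_counts = counts)
  }
  structure(list(samples = samples, sector_ids = sector_ids,
                 centres = centres, radius = radius),
            class = "sector_samples")
}

#' Per-mutation frequencies within each sampled sector
#' @param sim A [simulate_growth()] result.
#' @param ss A [sample_sectors()] result.
#' @return Numeric matrix, mutations x sectors (mutations carried by at
#'   least one sampled cell).
#' @export
sector_frequencies <- function(sim, ss) {
  tab <- sectors_to_table(sim, ss)
  vaf_hap <- tab$alt_count / total_depth(tab)  # carriers / cells sampled
  vaf_hap
}

#' Convert sampled sectors to a mutation table
#'
#' Depth is the number of cells sampled in the sector and the alternate
#' count is the number of carriers, so downstream detection thresholds,
#' presence matrices and Fst apply unchanged. Mutations are laid out on a
#' single synthetic chromosome `"sim"` at `pos = mutation id`.
#'
#' @param sim A [simulate_growth()] result.
#' @param ss A [sample_sectors()] result.
#' @return A [mutation_table()] over all mutations observed in >= 1 sector.
#' @export
sectors_to_table <- function(sim, ss) {
  tr <- sim$tree
  counts <- vapply(ss$samples, `[[`, integer(length(tr$parent)), "node_counts")
  if (is.null(dim(counts))) counts <- matrix(counts, ncol = length(ss$samples))
  seen <- which(rowSums(counts) > 0L & tr$nmut > 0L)
  if (!length(seen)) stop("no mutation observed in any sector")
  reps <- tr$nmut[seen]
  mut_ids <- unlist(lapply(seen, function(u)
    seq.int(tr$mstart[u], length.out = tr$nmut[u])))
  alt <- counts[rep(seen, reps), , drop = FALSE]
  ncells <- vapply(ss$samples, `[[`, 0L, "n_cells")
  depth <- matrix(ncells, nrow = length(mut_ids), ncol = length(ncells),
                  byrow = TRUE)
  colnames(alt) <- colnames(depth) <- ss$sector_ids
  ord <- order(mut_ids)
  variants <- data.frame(mutation_id = paste0("m", mut_ids[ord]),
                         chrom = "sim", pos = mut_ids[ord],
                         ref = "A", alt = "T", stringsAsFactors = FALSE)
  mutation_table(variants, ref_count = depth - alt[ord, , drop = FALSE],
                 alt_count = alt[ord, , drop = FALSE])
}

#' Sector metadata for simulated sectors
#' @param ss A [sample_sectors()] result.
#' @param mm_per_unit Physical size of one lattice unit in millimetres
#'   (default 1).
#' @param purity Tumour purity assigned to every sector (default 1: the
#'   simulation has no normal-cell contamination).
#' @return A [sector_metadata()].
#' @export
sectors_to_metadata <- function(ss, mm_per_unit = 1, purity = 1) {
  sector_metadata(ss$sector_ids, ss$centres * mm_per_unit,
                  rep(purity, length.out = length(ss$sector_ids)))
}
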