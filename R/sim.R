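#' Simulation configuration
#'
#' Collects the parameters of the built-in coalescent generators. All
#' generators are pure functions of `(config, seed)`: the same config
#' (including its `seed`) yields byte-identical output.
#'
#' @param n_haplotypes haplotypes per population.
#' @param theta population mutation rate 4*N*mu for the whole locus.
#' @param locus_bp locus length in bp.
#' @param demes number of island-model demes.
#' @param migration scaled migration rate M = 4*N*m between demes.
#' @param split_time optional divergence time (units of 2N generations)
#'   for the no-migration mode of [simulate_island()].
#' @param sweep_pos core-site position of the selective sweep (bp,
#'   0-based); default mid-locus.
#' @param sweep_freq final derived-allele frequency at the sweep core.
#' @param sweep_fidelity probability a site inside a copied founder
#'   tract takes the founder allele (1 = perfect copying).
#' @param crossover per-bp probability terminating a founder-copy tract
#'   (geometric breakpoint rate); 0 means tracts span the locus.
#' @param beta SFS skew exponent for [skew_sfs()] (1 = neutral).
#' @param seed RNG seed; `NULL` leaves the RNG state alone.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_haplotypes = 50, theta = 10, locus_bp = 10000,
                       demes = 1, migration = 1, split_time = NULL,
                       sweep_pos = NULL, sweep_freq = 0.7,
                       sweep_fidelity = 1, crossover = 2e-6,
                       beta = 1, seed = NULL) {
  if (theta <= 0) stop("theta must be > 0")
  if (beta < 1) stop("beta must be >= 1")
  if (sweep_freq <= 0 || sweep_freq >= 1)
    stop("sweep_freq must be in (0, 1)")
  if (is.null(sweep_pos)) sweep_pos <- floor(locus_bp / 2)
  structure(list(n_haplotypes = n_haplotypes, theta = theta,
                 locus_bp = locus_bp, demes = demes, migration = migration,
                 split_time = split_time, sweep_pos = sweep_pos,
                 sweep_freq = sweep_freq, sweep_fidelity = sweep_fidelity,
                 crossover = crossover, beta = beta, seed = seed),
            class = "sim_config")
}

#' Derive a replicate seed from a master seed
#'
#' Deterministic counter scheme: `(master + i * 1000003) mod (2^31 - 1)`.
#'
#' @param master master seed (integer).
#' @param i replicate counter (integer >= 0).
#' @return derived seed, a positive integer below 2^31.
#' @export
derive_seed <- function(master, i) {
  as.integer((as.numeric(master) + as.numeric(i) * 1000003) %% 2147483647)
}

# Kingman coalescent genealogy for n tips in a single panmictic deme.
# Returns branches as list(tips = list of integer vectors, len = numeric).
.coalescent_branches <- function(n) {
  tips <- as.list(seq_len(n))
  birth <- rep(0, n)
  out_tips <- vector("list", 2L * (n - 1L))
  out_len <- numeric(2L * (n - 1L))
  nb <- 0L
  t <- 0
  k <- n
  while (k > 1L) {
    t <- t + stats::rexp(1L, rate = choose(k, 2))
    pair <- sample.int(k, 2L)
    for (p in pair) {
      nb <- nb + 1L
      out_tips[[nb]] <- tips[[p]]
      out_len[nb] <- t - birth[p]
    }
    merged <- c(tips[[pair[1L]]], tips[[pair[2L]]])
    keep <- setdiff(seq_len(k), pair)
    tips <- c(tips[keep], list(merged))
    birth <- c(birth[keep], t)
    k <- k - 1L
  }
  list(tips = out_tips[seq_len(nb)], len = out_len[seq_len(nb)])
}

# Structured coalescent for `demes` demes of n tips each, migration M/2
# per lineage, or clean-split mode (migration 0, merge at split_time).
.island_branches <- function(n_per_deme, demes, migration, split_time) {
  n <- n_per_deme * demes
  tips <- as.list(seq_len(n))
  deme <- rep(seq_len(demes), each = n_per_deme)
  birth <- rep(0, n)
  out_tips <- list()
  out_len <- numeric(0)
  t <- 0
  split_mode <- migration <= 0      # isolated demes until split_time
  post_split <- FALSE               # post-split single ancestral deme
  repeat {
    k <- length(tips)
    if (k == 1L) break
    kd <- tabulate(deme, nbins = demes)
    coal_rates <- choose(kd, 2)
    mig_rate <- if (split_mode || post_split) 0 else k * migration / 2
    total <- sum(coal_rates) + mig_rate
    if (total <= 0) {
      # isolated demes each down to one lineage; jump to the split
      t <- max(t, split_time)
      deme[] <- 1L
      post_split <- TRUE
      split_mode <- FALSE
      next
    }
    dt <- stats::rexp(1L, rate = total)
    if (split_mode && t + dt > split_time) {
      t <- split_time
      deme[] <- 1L
      post_split <- TRUE
      split_mode <- FALSE
      next
    }
    t <- t + dt
    if (stats::runif(1L) < mig_rate / total) {
      l <- sample.int(k, 1L)
      deme[l] <- sample(setdiff(seq_len(demes), deme[l]), 1L)
    } else {
      d <- sample.int(demes, 1L, prob = coal_rates / sum(coal_rates))
      in_d <- which(deme == d)
      pair <- in_d[sample.int(length(in_d), 2L)]
      for (p in pair) {
        out_tips[[length(out_tips) + 1L]] <- tips[[p]]
        out_len <- c(out_len, t - birth[p])
      }
      merged <- c(tips[[pair[1L]]], tips[[pair[2L]]])
      keep <- setdiff(seq_len(k), pair)
      tips <- c(tips[keep], list(merged))
      birth <- c(birth[keep], t)
      deme <- c(deme[keep], d)
    }
  }
  list(tips = out_tips, len = out_len)
}

# Drop infinite-sites mutations on a branch set and build the block.
.mutate_branches <- function(br, theta, locus_bp, chrom, sample_ids) {
  n <- length(sample_ids)
  tbl <- sum(br$len)
  S <- stats::rpois(1L, theta / 2 * tbl)
  S <- min(S, locus_bp)  # infinite-sites positions live on distinct bp
  if (S > 0L) {
    which_branch <- sample.int(length(br$len), S, replace = TRUE,
                               prob = br$len)
    pos <- sort(sample.int(locus_bp, S)) - 1
    alleles <- matrix(0L, n, S)
    for (j in seq_len(S)) alleles[br$tips[[which_branch[j]]], j] <- 1L
  } else {
    pos <- numeric(0)
    alleles <- matrix(0L, n, 0L)
  }
  haplotype_block(alleles, pos, chrom = chrom,
                  sample_ids = sample_ids, length_bp = locus_bp)
}

.default_hap_ids <- function(pops, n_per_pop) {
  unlist(lapply(pops, function(p)
    paste0(p, "_ind", rep(seq_len(ceiling(n_per_pop / 2)), each = 2L),
           "_h", rep(1:2, length.out = n_per_pop))))
}

#' Simulate a neutral panmictic locus
#'
#' Standard Kingman coalescent with infinite-sites mutation: genealogy
#' with exponential coalescence times (rate `choose(k,2)` in units of 2N
#' generations), Poisson(`theta/2` x branch length) mutations, derived
#' allele = mutant lineage, site positions uniform on the locus.
#'
#' @param config a [sim_config()].
#' @return a `haplotype_block`.
#' @export
simulate_neutral <- function(config) {
  if (config$n_haplotypes < 2) stop("n_haplotypes must be >= 2")
  if (!is.null(config$seed)) set.seed(config$seed)
  br <- .coalescent_branches(config$n_haplotypes)
  ids <- .default_hap_ids("pop1", config$n_haplotypes)
  .mutate_branches(br, config$theta, config$locus_bp, "chr1", ids)
}

#' Simulate an island-model locus with population labels
#'
#' Structured coalescent over `demes` demes of `n_haplotypes` lineages
#' each, with symmetric scaled migration `M = 4Nm` (per-lineage backward
#' migration rate M/2). With `migration = 0` a `split_time` must be
#' supplied: demes evolve in isolation until `split_time` (in units of
#' 2N), then merge into a single ancestral deme.
#'
#' @param config a [sim_config()] with `demes >= 2`.
#' @return `list(block = haplotype_block, panel = population_panel)`.
#' @export
simulate_island <- function(config) {
  d <- config$demes
  if (d < 2) stop("simulate_island needs demes >= 2")
  if (config$migration <= 0 && is.null(config$split_time))
    stop("migration <= 0 requires a split_time (isolated demes never find a common ancestor)")
  if (!is.null(config$seed)) set.seed(config$seed)
  br <- .island_branches(config$n_haplotypes, d, config$migration,
                         config$split_time)
  pops <- paste0("pop", seq_len(d))
  ids <- .default_hap_ids(pops, config$n_haplotypes)
  block <- .mutate_branches(br, config$theta, config$locus_bp, "chr1", ids)
  sample_ids <- unique(sub("_h[12]$", "", ids))
  panel <- population_panel(data.frame(
    sample_id = sample_ids,
    population = sub("_ind.*$", "", sample_ids),
    superpopulation = sub("_ind.*$", "", sample_ids),
    stringsAsFactors = FALSE))
  list(block = block, panel = panel)
}

#' Simulate a selective sweep by founder copying
#'
#' Starts from a neutral locus, inserts a core site at `sweep_pos` with
#' derived frequency `sweep_freq`, and gives every derived-core carrier
#' the flanking sequence of a single founder haplotype out to
#' per-haplotype, per-side geometric breakpoints (per-bp termination
#' probability `crossover`). Copying is faithful per site with
#' probability `sweep_fidelity`. This produces the long shared
#' homozygosity on the derived background that EHH/iHS detects, while
#' the ancestral background keeps its neutral haplotype diversity.
#'
#' @param config a [sim_config()].
#' @return a `haplotype_block` with attribute `core_index` (column of
#'   the core site) and `core_pos`.
#' @export
simulate_sweep <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  cfg <- config
  cfg$seed <- NULL
  block <- simulate_neutral(cfg)
  n <- n_haplotypes(block)
  m <- round(config$sweep_freq * n)
  if (abs(m - config$sweep_freq * n) > 1e-9)
    message(sprintf("sweep carrier count rounded to %d/%d (target frequency %.3f)",
                    m, n, config$sweep_freq))
  m <- max(1L, min(n - 1L, m))
  core_pos <- config$sweep_pos
  while (core_pos %in% block$positions) core_pos <- core_pos + 1
  carriers <- sample.int(n, m)
  founder <- carriers[1L]
  r <- config$crossover
  for (h in carriers) {
    d_left <- if (r > 0) stats::rgeom(1L, r) else Inf
    d_right <- if (r > 0) stats::rgeom(1L, r) else Inf
    in_tract <- block$positions >= core_pos - d_left &
      block$positions <= core_pos + d_right
    if (any(in_tract)) {
      copy <- stats::runif(sum(in_tract)) < config$sweep_fidelity
      idx <- which(in_tract)[copy]
      block$alleles[h, idx] <- block$alleles[founder, idx]
    }
  }
  core_col <- as.integer(rep(0L, n)); core_col[carriers] <- 1L
  at <- sum(block$positions < core_pos)
  alleles <- cbind(block$alleles[, seq_len(at), drop = FALSE], core_col,
                   block$alleles[, seq_len(ncol(block$alleles)) > at,
                                 drop = FALSE])
  positions <- append(block$positions, core_pos, after = at)
  out <- haplotype_block(alleles, positions, chrom = block$chrom,
                         sample_ids = block$sample_ids,
                         length_bp = block$length_bp)
  attr(out, "core_index") <- at + 1L
  attr(out, "core_pos") <- core_pos
  out
}

#' Skew the site-frequency spectrum inside constrained elements
#'
#' Emulates purifying selection: for every site falling inside the
#' given element intervals, the allele column is replaced by one drawn
#' from the constrained-site pool via rejection sampling with acceptance
#' probability `(1/i)^(beta-1)` (`i` = derived count), so the stationary
#' derived-count distribution is proportional to `1/i^beta`. `beta = 1`
#' accepts every draw and leaves the SFS unchanged in distribution;
#' larger `beta` piles mass onto rare derived alleles. Sites outside the
#' elements are untouched and the number of sites is preserved.
#'
#' @param block a `haplotype_block`.
#' @param elements an `element_track` (or plain data.frame with
#'   `chrom,start,end,class`); all its intervals are treated as
#'   constrained unless `classes` narrows them.
#' @param beta skew exponent (>= 1).
#' @param classes optional subset of element classes to constrain.
#' @return a `haplotype_block` with resampled constrained columns.
#' @export
skew_sfs <- function(block, elements, beta, classes = NULL) {
  if (beta < 1) stop("beta must be >= 1")
  iv <- as.data.frame(elements)
  if (!is.null(classes)) iv <- iv[iv$class %in% classes, , drop = FALSE]
  iv <- iv[iv$chrom == block$chrom, , drop = FALSE]
  inside <- rep(FALSE, n_sites(block))
  for (r in seq_len(nrow(iv)))
    inside <- inside | (block$positions >= iv$start[r] &
                          block$positions < iv$end[r])
  pool <- which(inside)
  if (length(pool) == 0L) {
    message("skew_sfs: no sites fall inside constrained elements; no-op")
    return(block)
  }
  if (beta == 1) accept_all <- TRUE else accept_all <- FALSE
  pool_cols <- block$alleles[, pool, drop = FALSE]
  pool_counts <- colSums(pool_cols)
  new_alleles <- block$alleles
  for (j in pool) {
    repeat {
      cand <- sample.int(length(pool), 1L)
      if (accept_all ||
          stats::runif(1L) < (1 / pool_counts[cand])^(beta - 1)) break
    }
    new_alleles[, j] <- pool_cols[, cand]
  }
  haplotype_block(new_alleles, block$positions, chrom = block$chrom,
                  ancestral_known = block$ancestral_known,
                  sample_ids = block$sample_ids,
                  length_bp = block$length_bp)
}

#' Generate element, conservation, and gene tracks
#'
#' Lays non-overlapping labelled element intervals along one chromosome
#' (each class split into `pieces` intervals, shuffled, separated by
#' random gaps), covers constrained classes with high conservation
#' scores at a stated per-chunk probability (low scores elsewhere), and
#' places genes so that downstream 5 kb flank annotation sees hits
#' inside, near, and far from genes.
#'
#' @param chrom_len chromosome length (bp).
#' @param class_lengths named numeric vector: total bp per element class.
#' @param constrained_classes classes whose bases receive high scores.
#' @param p_conserved probability a constrained chunk scores high.
#' @param score_high,score_low scores for conserved / background chunks.
#' @param pieces intervals per class.
#' @param n_genes,gene_bp gene count and length.
#' @param chrom chromosome name.
#' @return `list(elements, conservation, genes)` of the three track types.
#' @export
make_tracks <- function(chrom_len, class_lengths,
                        constrained_classes = character(0),
                        p_conserved = 0.9, score_high = 4,
                        score_low = 0, pieces = 4,
                        n_genes = 5, gene_bp = 2000, chrom = "chr1") {
  if (sum(class_lengths) > chrom_len)
    stop("requested element lengths exceed chromosome length")
  pieces_of <- function(total) {
    k <- max(1L, min(pieces, floor(total / 100)))
    base <- floor(total / k)
    len <- rep(base, k)
    len[k] <- total - base * (k - 1L)
    len
  }
  cls <- rep(names(class_lengths),
             vapply(class_lengths, function(x) length(pieces_of(x)), 1L))
  lens <- unlist(lapply(class_lengths, pieces_of), use.names = FALSE)
  ord <- sample.int(length(lens))
  cls <- cls[ord]; lens <- lens[ord]
  slack <- chrom_len - sum(lens)
  gaps <- if (slack > 0)
    as.vector(stats::rmultinom(1L, size = slack,
                               prob = rep(1, length(lens))))
  else rep(0L, length(lens))
  start <- cumsum(c(0, lens[-length(lens)])) + cumsum(gaps)
  elements <- element_track(data.frame(
    chrom = chrom, start = start, end = start + lens, class = cls,
    stringsAsFactors = FALSE))

  cons <- list()
  for (r in seq_len(nrow(elements))) {
    hi <- elements$class[r] %in% constrained_classes
    s <- elements$start[r]; e <- elements$end[r]
    bounds <- unique(c(seq(s, e, by = max(100, floor((e - s) / 10))), e))
    for (k in seq_len(length(bounds) - 1L)) {
      score <- if (hi && stats::runif(1L) < p_conserved) score_high else score_low
      cons[[length(cons) + 1L]] <- data.frame(
        chrom = chrom, start = bounds[k], end = bounds[k + 1L],
        score = score, stringsAsFactors = FALSE)
    }
  }
  conservation <- conservation_track(do.call(rbind, cons))

  gstart <- sort(sample.int(max(1L, chrom_len - gene_bp), n_genes))
  # enforce non-overlap by pushing starts right
  for (k in seq_len(n_genes)[-1])
    gstart[k] <- max(gstart[k], gstart[k - 1L] + gene_bp + 1L)
  gstart <- gstart[gstart + gene_bp <= chrom_len]
  genes <- gene_track(data.frame(
    chrom = chrom, start = gstart, end = gstart + gene_bp,
    gene = paste0("gene", seq_along(gstart)), stringsAsFactors = FALSE))

  list(elements = elements, conservation = conservation, genes = genes)
}
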