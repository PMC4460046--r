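#' Concatenate the sites of one element class onto a gapless axis
#'
#' Restricts the block to sites falling inside intervals of the given
#' class and re-addresses them to a concatenated coordinate axis in
#' which the class intervals abut in genomic order. The returned map
#' retains original coordinates for traceability, and the block's
#' `length_bp` becomes the total class length, so per-site statistics
#' use the concatenated length as denominator.
#'
#' @param block a `haplotype_block`.
#' @param elements an `element_track`.
#' @param class element class to concatenate.
#' @return `list(block, map)` where `map` is a data.frame with
#'   `original` and `concatenated` positions per retained site.
#' @export
concatenate_element <- function(block, elements, class) {
  iv <- elements[elements$class == class & elements$chrom == block$chrom, ,
                 drop = FALSE]
  total <- sum(iv$end - iv$start)
  if (nrow(iv) == 0 || total <= 0)
    stop(sprintf("element class '%s' has zero total length on %s",
                 class, block$chrom))
  iv <- iv[order(iv$start), , drop = FALSE]
  offset <- cumsum(c(0, (iv$end - iv$start)[-nrow(iv)]))
  newpos <- rep(NA_real_, n_sites(block))
  for (r in seq_len(nrow(iv))) {
    inside <- block$positions >= iv$start[r] & block$positions < iv$end[r]
    newpos[inside] <- block$positions[inside] - iv$start[r] + offset[r]
  }
  keep <- which(!is.na(newpos))
  map <- data.frame(original = block$positions[keep],
                    concatenated = newpos[keep])
  out <- subset_sites(block, keep, positions = newpos[keep],
                      length_bp = total)
  list(block = out, map = map)
}

#' Sliding-window SFS summaries on a concatenated axis
#'
#' Windows are `[k*step, k*step + size)` for `k = 0, 1, ...`; terminal
#' partial windows (shorter than `size`) are dropped so every summary
#' shares the same length denominator. Empty windows yield `S = 0`
#' summaries with undefined (flagged) test statistics.
#'
#' @param block a `haplotype_block` (typically from
#'   [concatenate_element()]).
#' @param size window size in bp.
#' @param step step in bp.
#' @return data.frame of per-window [sfs_summary()] rows with
#'   `window_start` / `window_end` columns.
#' @export
sliding_windows <- function(block, size = 10000, step = 5000) {
  if (size <= 0 || step <= 0) stop("size and step must be > 0")
  L <- block$length_bp
  starts <- seq(0, max(0, L - size), by = step)
  starts <- starts[starts + size <= L]
  if (length(starts) == 0)
    return(data.frame())
  rows <- lapply(starts, function(s) {
    idx <- block$positions >= s & block$positions < s + size
    w <- subset_sites(block, idx, length_bp = size)
    cbind(window_start = s, window_end = s + size, sfs_summary(w))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bootstrap mean of window statistics
#'
#' Resamples the values with replacement to the original count,
#' `n_boot` times; returns the mean of the resample means and their SD
#' (the bootstrap SE). NA values (undefined windows) must be removed by
#' the caller or are dropped here with a count.
#'
#' @param values numeric vector of window statistics.
#' @param n_boot number of bootstrap replicates.
#' @param seed optional RNG seed.
#' @return list with `mean`, `se`, `n_used`, `n_boot`.
#' @export
bootstrap_mean <- function(values, n_boot = 1000, seed = NULL) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("no defined values to bootstrap")
  if (!is.null(seed)) set.seed(seed)
  if (length(values) == 1L)
    return(list(mean = values, se = 0, n_used = 1L, n_boot = n_boot))
  means <- vapply(seq_len(n_boot), function(i)
    mean(values[sample.int(length(values), replace = TRUE)]), numeric(1))
  list(mean = mean(means), se = stats::sd(means),
       n_used = length(values), n_boot = n_boot)
}

#' Permutation test of an element mean against the background
#'
#' Observed statistic is the absolute difference in group means
#' (two-sided; set `two_sided = FALSE` for the one-sided version using
#' the signed difference). Group labels are permuted over the pooled
#' values preserving group sizes; the P-value uses the +1 finite-
#' resampling correction, `P = (1 + #{|d_perm| >= |d_obs|}) /
#' (n_perm + 1)`, so it is never zero. Undefined (NA) values are
#' dropped from both groups symmetrically.
#'
#' @param element_values numeric vector (element windows).
#' @param background_values numeric vector (genome-wide windows).
#' @param n_perm number of permutations.
#' @param seed optional RNG seed.
#' @param two_sided compare `|d|` (default) or signed `d`.
#' @return list with `p`, `delta_obs`, `mean_element`,
#'   `mean_background`, `n_perm`.
#' @export
permutation_test <- function(element_values, background_values,
                             n_perm = 10000, seed = NULL,
                             two_sided = TRUE) {
  x <- element_values[!is.na(element_values)]
  y <- background_values[!is.na(background_values)]
  if (length(x) == 0 || length(y) == 0)
    stop("both groups must contain at least one defined value")
  if (!is.null(seed)) set.seed(seed)
  nx <- length(x)
  pool <- c(x, y)
  d_obs <- mean(x) - mean(y)
  stat_obs <- if (two_sided) abs(d_obs) else d_obs
  total <- sum(pool)
  n <- length(pool)
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    sx <- sum(pool[sample.int(n, nx)])
    d <- sx / nx - (total - sx) / (n - nx)
    stat <- if (two_sided) abs(d) else d
    if (stat >= stat_obs) exceed <- exceed + 1L
  }
  list(p = (1 + exceed) / (n_perm + 1),
       delta_obs = d_obs,
       mean_element = mean(x), mean_background = mean(y),
       n_perm = n_perm)
}

#' Compare an element class to the genome-wide background
#'
#' Convenience wrapper: concatenates the element class, computes
#' 10 kb / 5 kb sliding-window summaries, bootstrap means, and a
#' permutation test of the chosen statistic against background windows.
#'
#' @param block a `haplotype_block` covering the region.
#' @param elements an `element_track`.
#' @param class element class to test.
#' @param background_windows data.frame of genome-wide window summaries
#'   (from [sliding_windows()] on the full block or a concatenated
#'   genome-wide track).
#' @param stat column to compare (`"D"`, `"D_star"`, `"F_star"`, `"H"`,
#'   `"pi_site"`).
#' @param size,step window size and step (bp).
#' @param n_boot,n_perm bootstrap and permutation replicates.
#' @param seed optional RNG seed.
#' @return one-row data.frame (element class, statistic, bootstrap mean
#'   and SE, background mean, observed difference, permutation P).
#' @export
compare_element_background <- function(block, elements, class,
                                       background_windows,
                                       stat = "D", size = 10000,
                                       step = 5000, n_boot = 1000,
                                       n_perm = 10000, seed = NULL) {
  cc <- concatenate_element(block, elements, class)
  win <- sliding_windows(cc$block, size = size, step = step)
  ev <- if (nrow(win)) win[[stat]] else numeric(0)
  bv <- background_windows[[stat]]
  bs <- bootstrap_mean(ev, n_boot = n_boot, seed = seed)
  pt <- permutation_test(ev, bv, n_perm = n_perm,
                         seed = if (is.null(seed)) NULL else seed + 1L)
  data.frame(element_class = class, statistic = stat,
             n_windows = sum(!is.na(ev)),
             boot_mean = bs$mean, boot_se = bs$se,
             mean_element = pt$mean_element,
             mean_background = pt$mean_background,
             delta_obs = pt$delta_obs, p_perm = pt$p,
             n_perm = n_perm, stringsAsFactors = FALSE)
}
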