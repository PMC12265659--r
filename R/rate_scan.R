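#' Build the grid of focal test positions
#'
#' Positions are placed uniformly in genetic distance, anchored at each
#' chromosome's first map position: \code{first_cm + k * step_cm} for
#' \code{k = 0..floor(span/step)}. Physical coordinates come from inverse
#' interpolation of the map.
#'
#' @param map a \code{genetic_map}.
#' @param step_cm spacing between consecutive focal positions in cM
#'   (default 0.05).
#' @return A \code{scan_grid}: data.table with columns \code{chrom}, \code{cm},
#'   \code{bp}, and attribute \code{step_cm}.
#' @export
build_grid <- function(map, step_cm = 0.05) {
  stopifnot(step_cm > 0)
  chroms <- unique(map$chrom)
  if (!length(chroms)) stop("genetic map has no chromosomes")
  pieces <- lapply(chroms, function(ch) {
    anchors <- map_chrom(map, ch)
    lo <- anchors$cm[1]
    hi <- anchors$cm[nrow(anchors)]
    k <- floor((hi - lo) / step_cm + 1e-9)
    cm <- lo + step_cm * (0:k)
    data.table(chrom = ch, cm = cm, bp = cm_to_bp(map, ch, cm))
  })
  grid <- rbindlist(pieces)
  data.table::setattr(grid, "class", c("scan_grid", class(grid)))
  data.table::setattr(grid, "step_cm", step_cm)
  grid
}

#' @export
print.scan_grid <- function(x, ...) {
  cat("scan grid:", nrow(x), "positions on", length(unique(x$chrom)),
      "chromosomes, step", attr(x, "step_cm"), "cM\n")
  invisible(x)
}

#' Genome layout of a scan
#'
#' Summarizes the tested genome: per-chromosome tested span, total length L in
#' Morgans, chromosome count C, test spacing delta in Morgans, and the number
#' of tests M. Construct either from a \code{scan_grid} or from explicit
#' chromosome lengths.
#'
#' @param chrom_cm numeric vector of chromosome lengths in cM.
#' @param step_cm test spacing in cM.
#' @return A \code{genome_layout} list with elements \code{lengths_cm},
#'   \code{C}, \code{L} (Morgans), \code{delta} (Morgans), \code{M},
#'   \code{m_per_chrom}.
#' @export
genome_layout <- function(chrom_cm, step_cm) {
  stopifnot(all(chrom_cm > 0), step_cm > 0)
  m_per <- floor(chrom_cm / step_cm + 1e-9) + 1L
  layout <- list(lengths_cm = as.numeric(chrom_cm),
                 C = length(chrom_cm),
                 L = sum((m_per - 1L) * step_cm) / 100,
                 delta = step_cm / 100,
                 M = sum(m_per),
                 m_per_chrom = m_per)
  class(layout) <- "genome_layout"
  layout
}

#' @rdname genome_layout
#' @param grid a \code{scan_grid}.
#' @export
grid_layout <- function(grid) {
  step_cm <- attr(grid, "step_cm")
  spans <- grid[, list(span = max(cm) - min(cm)), by = "chrom"]$span
  genome_layout(pmax(spans, step_cm), step_cm)
}

# canonical haplotype-pair key; unordered, so (a,2,b,1) == (b,1,a,2)
pair_key <- function(sample1, hap1, sample2, hap2) {
  h1 <- paste0(sample1, "|", hap1)
  h2 <- paste0(sample2, "|", hap2)
  ifelse(h1 < h2, paste0(h1, "~", h2), paste0(h2, "~", h1))
}

#' Per-position IBD sharing rate for one sample group
#'
#' The rate at focal position m is the number of distinct haplotype pairs
#' (between distinct individuals, both group members) having at least one
#' detected segment overlapping m, divided by the number of eligible pairs
#' \code{choose(2n, 2) - n} for n diploid group members. A pair contributes at
#' most 1 at a position regardless of how many of its segments overlap.
#'
#' @param segments an \code{ibd_segments} table.
#' @param grid a \code{scan_grid}.
#' @param group_ids character vector of sample ids in the group (>= 2).
#' @return A \code{rate_series} list: \code{rate} (length = grid size),
#'   \code{n_pairs}, \code{n_samples}.
#' @export
ibd_rate <- function(segments, grid, group_ids) {
  group_ids <- unique(as.character(group_ids))
  n <- length(group_ids)
  if (n < 2L) stop("need at least 2 samples to form pairs")
  n_pairs <- choose(2 * n, 2) - n
  counts <- numeric(nrow(grid))

  seg <- segments[segments$sample1 %in% group_ids &
                    segments$sample2 %in% group_ids &
                    segments$sample1 != segments$sample2]
  if (nrow(seg)) {
    chroms <- unique(grid$chrom)
    offset <- 0L
    for (ch in chroms) {
      gb <- grid$bp[grid$chrom == ch]
      s <- seg[seg$chrom == ch]
      n_pos <- length(gb)
      if (nrow(s)) {
        # index range of grid positions p with start <= p < end
        j <- findInterval(s$start_bp, gb)
        lo <- ifelse(j >= 1L & gb[pmax(j, 1L)] >= s$start_bp, j, j + 1L)
        j2 <- findInterval(s$end_bp, gb)
        hi <- ifelse(j2 >= 1L & gb[pmax(j2, 1L)] >= s$end_bp, j2 - 1L, j2)
        keep <- lo <= hi & hi >= 1L & lo <= n_pos
        if (any(keep)) {
          iv <- data.table(
            pk = pair_key(s$sample1[keep], s$hap1[keep],
                          s$sample2[keep], s$hap2[keep]),
            lo = pmax(lo[keep], 1L), hi = pmin(hi[keep], n_pos))
          setorder(iv, pk, lo, hi)
          # merge a pair's overlapping index intervals so it counts once per position
          run_max <- iv[, list(lo = lo, hi = cummax(hi)), by = "pk"]
          prev_hi <- run_max[, shift(hi, fill = -1L), by = "pk"]$V1
          new_run <- iv$lo > prev_hi
          iv$grp <- cumsum(new_run)
          merged <- iv[, list(lo = min(lo), hi = max(hi)), by = c("pk", "grp")]
          add <- numeric(n_pos + 1L)
          tab_lo <- tabulate(merged$lo, nbins = n_pos)
          tab_hi <- tabulate(merged$hi + 1L, nbins = n_pos + 1L)
          add[seq_len(n_pos)] <- tab_lo
          add <- add - tab_hi
          counts[(offset + 1L):(offset + n_pos)] <- cumsum(add[seq_len(n_pos)])
        }
      }
      offset <- offset + n_pos
    }
  }
  structure(list(rate = counts / n_pairs, n_pairs = n_pairs, n_samples = n),
            class = "rate_series")
}

#' Outlier-robust standardization of case and control rate tracks
#'
#' Implements the three-step robust procedure used before any threshold is
#' applied. (1) Per group, an initial median and standard deviation over all M
#' positions give an outlier cutoff of median + 4 sd. (2) Positions where the
#' case or the control rate exceeds its cutoff are masked; revised means and
#' standard deviations are computed over the unmasked positions and used to
#' standardize each track at all positions. (3) The difference of the
#' standardized tracks is itself restandardized (mean/sd over unmasked
#' positions) to unit variance, giving the scan statistic. Masked positions
#' carry reportable statistic values but never enter any moment estimate.
#'
#' @param case_series,control_series \code{rate_series} objects on the same
#'   grid (see \code{\link{ibd_rate}}).
#' @param grid the \code{scan_grid} both series were computed on.
#' @return An \code{ibd_scan} data.table with columns \code{chrom}, \code{bp},
#'   \code{cm}, \code{rate_case}, \code{rate_control}, \code{z_case},
#'   \code{z_control}, \code{z_diff}, \code{pvalue}, \code{excluded}, and a
#'   \code{standardization} attribute recording all moments and cutoffs.
#' @export
robust_standardize <- function(case_series, control_series, grid) {
  y1 <- case_series$rate
  y0 <- control_series$rate
  if (length(y1) != nrow(grid) || length(y0) != nrow(grid))
    stop("rate series length does not match grid")

  med1 <- median(y1); sd1_init <- sd(y1)
  med0 <- median(y0); sd0_init <- sd(y0)
  cut1 <- med1 + 4 * sd1_init
  cut0 <- med0 + 4 * sd0_init
  excluded <- (y1 > cut1) | (y0 > cut0)
  if (all(excluded)) stop("all positions excluded by the outlier rule")

  mu1 <- mean(y1[!excluded]); s1 <- sd(y1[!excluded])
  mu0 <- mean(y0[!excluded]); s0 <- sd(y0[!excluded])
  if (!is.finite(s1) || s1 == 0) stop("revised case standard deviation is zero")
  if (!is.finite(s0) || s0 == 0) stop("revised control standard deviation is zero")

  z1 <- (y1 - mu1) / s1
  z0 <- (y0 - mu0) / s0
  d <- z1 - z0
  mu_d <- mean(d[!excluded]); s_d <- sd(d[!excluded])
  if (!is.finite(s_d) || s_d == 0)
    stop("difference track has zero variance; case and control tracks are identical")
  z_diff <- (d - mu_d) / s_d

  track <- data.table(
    chrom = grid$chrom, bp = grid$bp, cm = grid$cm,
    rate_case = y1, rate_control = y0,
    z_case = z1, z_control = z0, z_diff = z_diff,
    pvalue = pointwise_pvalue(z_diff), excluded = excluded)
  data.table::setattr(track, "class", c("ibd_scan", class(track)))
  data.table::setattr(track, "step_cm", attr(grid, "step_cm"))
  data.table::setattr(track, "standardization", list(
    case = list(median = med1, sd_init = sd1_init, cutoff = cut1, mean = mu1, sd = s1),
    control = list(median = med0, sd_init = sd0_init, cutoff = cut0, mean = mu0, sd = s0),
    diff = list(mean = mu_d, sd = s_d),
    n_excluded = sum(excluded)))
  track
}

#' One-sample excess-IBD selection scan track
#'
#' Applies the same robust standardization to a single group's rates: the null
#' model is that the group's IBD rates share one genome-wide mean, and the
#' alternative is a locally elevated rate (e.g. recent positive selection).
#' The standardized track occupies \code{z_diff} so that thresholding and
#' region calling are identical to the two-sample scan.
#'
#' @param segments an \code{ibd_segments} table.
#' @param all_ids sample ids forming the scanned set (>= 2).
#' @param grid a \code{scan_grid}.
#' @return An \code{ibd_scan} track; \code{rate_control}, \code{z_control} are
#'   NA and \code{z_diff} holds the one-sample standardized rate.
#' @export
selection_scan <- function(segments, all_ids, grid) {
  series <- ibd_rate(segments, grid, all_ids)
  y <- series$rate
  med <- median(y); sd_init <- sd(y)
  cutoff <- med + 4 * sd_init
  excluded <- y > cutoff
  if (all(excluded)) stop("all positions excluded by the outlier rule")
  mu <- mean(y[!excluded]); s <- sd(y[!excluded])
  if (!is.finite(s) || s == 0) stop("revised standard deviation is zero")
  z <- (y - mu) / s
  track <- data.table(
    chrom = grid$chrom, bp = grid$bp, cm = grid$cm,
    rate_case = y, rate_control = NA_real_,
    z_case = z, z_control = NA_real_, z_diff = z,
    pvalue = pointwise_pvalue(z), excluded = excluded)
  data.table::setattr(track, "class", c("ibd_scan", class(track)))
  data.table::setattr(track, "step_cm", attr(grid, "step_cm"))
  data.table::setattr(track, "standardization", list(
    case = list(median = med, sd_init = sd_init, cutoff = cutoff, mean = mu, sd = s),
    control = NULL, diff = NULL, n_excluded = sum(excluded)))
  track
}

#' Upper-tail standard normal p-value
#'
#' @param z standardized statistic (vectorized).
#' @return \code{P(Z >= z)} under the standard normal null.
#' @export
pointwise_pvalue <- function(z) {
  pnorm(z, lower.tail = FALSE)
}

#' Call significant regions from a scan track
#'
#' A region is a maximal run of consecutive grid positions on one chromosome
#' with statistic \code{z_diff >= z_star}. Masked (outlier-excluded) positions
#' cannot form or extend regions unless \code{test_excluded = TRUE}. A run of
#' k positions at spacing delta reports size k * delta cM, so a single
#' significant position at the default 0.05 cM step has size 0.05 cM.
#'
#' @param track an \code{ibd_scan}.
#' @param z_star critical value on the standard normal scale.
#' @param test_excluded allow masked positions to be significant.
#' @return data.table with one row per region: \code{chrom}, \code{max_z},
#'   \code{argmax_bp}, \code{argmax_cm}, \code{start_bp}, \code{end_bp},
#'   \code{start_cm}, \code{end_cm}, \code{size_cm}, \code{n_positions},
#'   \code{pvalue} (pointwise p of the max).
#' @export
call_regions <- function(track, z_star, test_excluded = FALSE) {
  stopifnot(is.finite(z_star))
  step_cm <- attr(track, "step_cm")
  sig <- track$z_diff >= z_star & is.finite(track$z_diff)
  if (!test_excluded) sig <- sig & !track$excluded
  empty <- data.table(chrom = character(), max_z = numeric(),
                      argmax_bp = numeric(), argmax_cm = numeric(),
                      start_bp = numeric(), end_bp = numeric(),
                      start_cm = numeric(), end_cm = numeric(),
                      size_cm = numeric(), n_positions = integer(),
                      pvalue = numeric())
  if (!any(sig)) return(empty)
  out <- list()
  for (ch in unique(track$chrom)) {
    idx <- which(track$chrom == ch)
    s <- sig[idx]
    if (!any(s)) next
    r <- rle(s)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      run <- idx[starts[j]:ends[j]]
      zmax <- max(track$z_diff[run])
      at <- run[which.max(track$z_diff[run])]
      out[[length(out) + 1L]] <- data.table(
        chrom = ch, max_z = zmax,
        argmax_bp = track$bp[at], argmax_cm = track$cm[at],
        start_bp = track$bp[run[1]], end_bp = track$bp[run[length(run)]],
        start_cm = track$cm[run[1]], end_cm = track$cm[run[length(run)]],
        size_cm = length(run) * step_cm, n_positions = length(run),
        pvalue = pointwise_pvalue(zmax))
    }
  }
  if (!length(out)) return(empty)
  rbindlist(out)
}

#' Case-control scan with randomized phenotype labels
#'
#' Confounding check: phenotype labels are permuted uniformly at random
#' (half cases, half controls; an odd sample count assigns the extra sample to
#' controls) and the full case-control scan is re-run on the same segment
#' table. A locus whose signal survives label randomization is inflated by a
#' phenotype-independent mechanism (e.g. a selective sweep or population
#' structure), not by case enrichment.
#'
#' @param segments an \code{ibd_segments} table.
#' @param phenotypes a \code{phenotype_table} (only the sample ids are used).
#' @param grid a \code{scan_grid}.
#' @param seed integer seed for the label permutation.
#' @return An \code{ibd_scan} track computed under the permuted labels, with a
#'   \code{permuted_cases} attribute listing the fake case ids.
#' @export
randomized_phenotype_scan <- function(segments, phenotypes, grid, seed) {
  ids <- phenotypes$id
  if (length(ids) < 4L) stop("need at least 4 samples to permute")
  n_case <- floor(length(ids) / 2)
  perm <- with_seed(seed, sample(ids, length(ids), replace = FALSE))
  fake_cases <- perm[seq_len(n_case)]
  fake_controls <- setdiff(ids, fake_cases)
  case_series <- ibd_rate(segments, grid, fake_cases)
  control_series <- ibd_rate(segments, grid, fake_controls)
  track <- robust_standardize(case_series, control_series, grid)
  data.table::setattr(track, "permuted_cases", fake_cases)
  track
}
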