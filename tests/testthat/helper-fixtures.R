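# shared fixture builders; everything is generated in code at test time

write_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# linear 1 cM/Mb map over the given chromosome lengths (cM)
linear_map <- function(chrom_cm) {
  chroms <- as.character(seq_along(chrom_cm))
  genetic_map(chrom = rep(chroms, each = 2L),
              bp = as.vector(rbind(0, chrom_cm * 1e6)),
              cm = as.vector(rbind(0, chrom_cm)))
}

seg_line <- function(s1, h1, s2, h2, chrom, start, end, len) {
  paste(s1, h1, s2, h2, chrom, start, end, len, sep = "\t")
}

# brute-force pair x position oracle for the IBD sharing rate
brute_rate <- function(segments, grid, group_ids) {
  ids <- sort(unique(group_ids))
  n <- length(ids)
  haps <- expand.grid(id = ids, hap = 1:2, stringsAsFactors = FALSE)
  haps <- haps[order(haps$id, haps$hap), ]
  nh <- nrow(haps)
  n_pairs <- 0L
  counts <- numeric(nrow(grid))
  for (i in seq_len(nh - 1L)) {
    for (j in (i + 1L):nh) {
      if (haps$id[i] == haps$id[j]) next
      n_pairs <- n_pairs + 1L
      sel <- (segments$sample1 == haps$id[i] & segments$hap1 == haps$hap[i] &
                segments$sample2 == haps$id[j] & segments$hap2 == haps$hap[j]) |
             (segments$sample1 == haps$id[j] & segments$hap1 == haps$hap[j] &
                segments$sample2 == haps$id[i] & segments$hap2 == haps$hap[i])
      if (!any(sel)) next
      seg <- segments[sel, ]
      for (m in seq_len(nrow(grid))) {
        hit <- any(seg$chrom == grid$chrom[m] &
                     seg$start_bp <= grid$bp[m] & grid$bp[m] < seg$end_bp)
        if (hit) counts[m] <- counts[m] + 1
      }
    }
  }
  list(rate = counts / n_pairs, n_pairs = n_pairs)
}

# random segment fixture over a linear map
random_segments <- function(n_seg, ids, chrom_cm, seed, min_len_cm = 2,
                            max_len_cm = 10) {
  set.seed(seed)
  chroms <- as.character(seq_along(chrom_cm))
  ci <- sample(seq_along(chrom_cm), n_seg, replace = TRUE)
  start_cm <- runif(n_seg, 0, chrom_cm[ci] - max_len_cm)
  len <- runif(n_seg, min_len_cm, max_len_cm)
  pick <- function() {
    repeat {
      a <- sample(ids, 1); b <- sample(ids, 1)
      if (a != b) return(c(a, b))
    }
  }
  ab <- t(vapply(seq_len(n_seg), function(i) pick(), character(2)))
  ibd_segment_table(sample1 = ab[, 1], hap1 = sample(1:2, n_seg, TRUE),
                    sample2 = ab[, 2], hap2 = sample(1:2, n_seg, TRUE),
                    chrom = chroms[ci],
                    start_bp = round(start_cm * 1e6),
                    end_bp = round((start_cm + len) * 1e6),
                    length_cm = len)
}

# series definition of the discreteness correction (independent oracle)
nu_series <- function(y, kmax = 10000L) {
  vapply(y, function(yy) {
    k <- seq_len(kmax)
    (2 / yy^2) * exp(-2 * sum(pnorm(-yy * sqrt(k) / 2) / k))
  }, numeric(1))
}

# standard null scan on a synthetic dataset; returns track + analytic threshold
scan_synthetic <- function(x, step_cm = 0.05, alpha = 0.05) {
  grid <- build_grid(x$map, step_cm)
  cases <- x$phenotypes$id[x$phenotypes$status == 1L]
  controls <- x$phenotypes$id[x$phenotypes$status == 0L]
  track <- robust_standardize(ibd_rate(x$segments, grid, cases),
                              ibd_rate(x$segments, grid, controls), grid)
  ou <- fit_ou_model(track)
  thr <- analytic_threshold(alpha, ou$theta, grid_layout(grid))
  list(track = track, grid = grid, ou = ou, threshold = thr)
}
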