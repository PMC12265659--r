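#' Specification for a synthetic IBD dataset
#'
#' Describes a seedable generator of per-haplotype-pair IBD segments whose
#' position-wise overlap counts produce genome tracks with approximately
#' Gaussian marginals and exponentially decaying autocovariance. Defaults
#' mirror a whole-genome null validation design: 1250 cases and 1250 controls
#' on ten 100 cM chromosomes with a 2.0 cM detection cutoff. The default
#' initiation rate of 0.025 per Morgan per pair gives a mean pair-sharing
#' probability of about \code{lambda * (mean_len + min_cm) / 100 = 1e-3},
#' sparse and realistic for >= 2 cM detected segments.
#'
#' @param n_cases,n_controls diploid sample counts.
#' @param chrom_cm chromosome lengths in cM.
#' @param lambda per-pair segment initiation rate, per Morgan.
#' @param mean_len_cm mean of the exponential excess-length law in cM; segment
#'   length is \code{min_cm + Exp(mean_len_cm)} so every generated segment
#'   survives the detection cutoff.
#' @param min_cm detection cutoff in cM.
#' @return A \code{synthetic_spec} list.
#' @export
synthetic_spec <- function(n_cases = 1250L, n_controls = 1250L,
                           chrom_cm = rep(100, 10), lambda = 0.025,
                           mean_len_cm = 2.0, min_cm = 2.0) {
  stopifnot(n_cases >= 1L, n_controls >= 1L, all(chrom_cm > 0),
            lambda >= 0, mean_len_cm > 0, min_cm >= 0)
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 chrom_cm = as.numeric(chrom_cm), lambda = lambda,
                 mean_len_cm = mean_len_cm, min_cm = min_cm),
            class = "synthetic_spec")
}

# haplotype index h in 1..2N -> (sample index, hap 1|2)
hap_sample <- function(h) (h + 1L) %/% 2L
hap_index <- function(h) 2L - (h %% 2L)

# draw k haplotype pairs uniformly among between-individual pairs
draw_hap_pairs <- function(k, n_hap, distinct = FALSE) {
  if (k == 0L) return(data.table(h1 = integer(), h2 = integer()))
  got <- data.table(h1 = integer(), h2 = integer())
  while (nrow(got) < k) {
    need <- k - nrow(got)
    a <- sample.int(n_hap, 2L * need, replace = TRUE)
    b <- sample.int(n_hap, 2L * need, replace = TRUE)
    ok <- hap_sample(a) != hap_sample(b)
    a <- a[ok]; b <- b[ok]
    lo <- pmin(a, b); hi <- pmax(a, b)
    new <- data.table(h1 = lo, h2 = hi)
    got <- rbind(got, new)
    if (distinct) got <- unique(got)
    if (nrow(got) > k) got <- got[seq_len(k)]
  }
  got
}

# sample ids, padded for stable lexicographic order
sample_ids <- function(n) sprintf("S%05d", seq_len(n))

segments_from_haps <- function(h1, h2, chrom, start_cm, end_cm, length_cm, ids) {
  start_bp <- round(start_cm * 1e6)
  end_bp <- round(end_cm * 1e6)
  ok <- end_bp > start_bp  # degenerate boundary clips are unobservable
  ibd_segment_table(
    sample1 = ids[hap_sample(h1[ok])], hap1 = hap_index(h1[ok]),
    sample2 = ids[hap_sample(h2[ok])], hap2 = hap_index(h2[ok]),
    chrom = if (length(chrom) == 1L) chrom else chrom[ok],
    start_bp = start_bp[ok], end_bp = end_bp[ok],
    length_cm = length_cm[ok])
}

#' Generate a null synthetic IBD dataset
#'
#' For every between-individual haplotype pair, segments initiate as a Poisson
#' process with rate lambda per Morgan along each chromosome; lengths are
#' \code{min_cm + Exp(mean_len_cm)}. Initiations are drawn on an interval
#' extended to the left of each chromosome so that coverage is stationary over
#' the whole chromosome (a segment overlapping position p may have started
#' before the chromosome's first position; its bp coordinates are clipped to
#' the chromosome while \code{length_cm} keeps the full detected length).
#' Physical coordinates use a linear 1 cM/Mb map. Case/control labels are
#' assigned by random permutation of the sample ids.
#'
#' At any focal position the expected pair-sharing probability is
#' \code{lambda * (mean_len_cm + min_cm) / 100} (stationary coverage of a
#' renewal process: rate times mean length in Morgans).
#'
#' @param spec a \code{synthetic_spec}.
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @return A \code{synthetic_ibd} list: \code{segments}, \code{phenotypes},
#'   \code{map} (a \code{genetic_map}), \code{spec}, \code{seed}.
#' @export
generate_null <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_cases + spec$n_controls
  n_hap <- 2L * n
  ids <- sample_ids(n)
  n_pairs <- choose(n_hap, 2) - n
  chroms <- as.character(seq_along(spec$chrom_cm))
  # left extension capturing essentially all segments overlapping [0, len]
  ext <- spec$min_cm + 20 * spec$mean_len_cm

  out <- with_seed(seed, {
    status <- integer(n)
    status[sample.int(n, spec$n_cases)] <- 1L
    seg_list <- vector("list", length(chroms))
    for (ci in seq_along(chroms)) {
      len <- spec$chrom_cm[ci]
      n_seg <- rpois(1L, n_pairs * spec$lambda * (len + ext) / 100)
      if (n_seg == 0L) next
      pairs <- draw_hap_pairs(n_seg, n_hap)
      start <- runif(n_seg, min = -ext, max = len)
      seg_len <- spec$min_cm + rexp(n_seg, rate = 1 / spec$mean_len_cm)
      end <- start + seg_len
      keep <- end > 0 & start < len
      seg_list[[ci]] <- data.table(
        h1 = pairs$h1[keep], h2 = pairs$h2[keep], chrom = chroms[ci],
        start_cm = pmax(start[keep], 0), end_cm = pmin(end[keep], len),
        length_cm = seg_len[keep])
    }
    list(status = status, seg = rbindlist(seg_list))
  })

  seg <- out$seg
  segments <- if (!is.null(seg) && nrow(seg)) {
    segments_from_haps(seg$h1, seg$h2, seg$chrom, seg$start_cm, seg$end_cm,
                       seg$length_cm, ids)
  } else {
    ibd_segment_table(character(), integer(), character(), integer(),
                      character(), numeric(), numeric(), numeric())
  }
  data.table::setattr(segments, "min_cm", spec$min_cm)
  map <- genetic_map(chrom = rep(chroms, each = 2L),
                     bp = as.vector(rbind(0, spec$chrom_cm * 1e6)),
                     cm = as.vector(rbind(0, spec$chrom_cm)))
  structure(list(segments = segments,
                 phenotypes = phenotype_table(ids, out$status),
                 map = map, spec = spec, seed = seed),
            class = "synthetic_ibd")
}

#' @export
print.synthetic_ibd <- function(x, ...) {
  cat("synthetic IBD dataset:", nrow(x$segments), "segments,",
      attr(x$phenotypes, "n_cases"), "cases /",
      attr(x$phenotypes, "n_controls"), "controls, seed", x$seed, "\n")
  invisible(x)
}

locus_chrom_len <- function(x, locus) {
  ci <- match(as.character(locus$chrom), as.character(seq_along(x$spec$chrom_cm)))
  if (is.na(ci)) stop("locus chromosome not in genome: ", locus$chrom)
  len <- x$spec$chrom_cm[ci]
  if (locus$cm < 0 || locus$cm > len)
    stop("locus position ", locus$cm, " cM outside chromosome ", locus$chrom,
         " (0-", len, " cM)")
  len
}

# one segment overlapping locus_cm per row: stationary overlap geometry
locus_segments <- function(n_seg, spec, locus_cm, chrom_len) {
  seg_len <- spec$min_cm + rexp(n_seg, rate = 1 / spec$mean_len_cm)
  start <- locus_cm - runif(n_seg) * seg_len
  end <- start + seg_len
  data.table(start_cm = pmax(start, 0), end_cm = pmin(end, chrom_len),
             length_cm = seg_len)
}

#' Inject a case-enriched risk locus
#'
#' A random fraction q of distinct case-case haplotype pairs gains one extra
#' segment overlapping the locus (length from the generator's length law,
#' placed so the locus is uniformly positioned within the segment). Control
#' pairs are untouched, emulating a disease haplotype enriched among cases.
#'
#' @param x a \code{synthetic_ibd} dataset.
#' @param locus list with \code{chrom} and \code{cm}.
#' @param q fraction of case-case haplotype pairs gaining a segment, in
#'   \[0, 1\].
#' @param seed integer seed.
#' @return The modified \code{synthetic_ibd} dataset.
#' @export
inject_risk_locus <- function(x, locus, q, seed = 1L) {
  stopifnot(inherits(x, "synthetic_ibd"), q >= 0, q <= 1)
  chrom_len <- locus_chrom_len(x, locus)
  if (q == 0) return(x)
  case_ids <- x$phenotypes$id[x$phenotypes$status == 1L]
  n1 <- length(case_ids)
  n_hap <- 2L * n1
  n_cc <- choose(n_hap, 2) - n1
  new <- with_seed(seed, {
    k <- rbinom(1L, n_cc, q)
    if (k == 0L) NULL else {
      pairs <- draw_hap_pairs(k, n_hap, distinct = TRUE)
      cbind(pairs, locus_segments(nrow(pairs), x$spec, locus$cm, chrom_len))
    }
  })
  if (is.null(new)) return(x)
  extra <- segments_from_haps(new$h1, new$h2, as.character(locus$chrom),
                              new$start_cm, new$end_cm, new$length_cm, case_ids)
  x$segments <- rbind(x$segments, extra)
  data.table::setattr(x$segments, "class",
                      c("ibd_segments", "data.table", "data.frame"))
  data.table::setattr(x$segments, "min_cm", x$spec$min_cm)
  x
}

#' Inject a phenotype-blind carrier confounder
#'
#' Emulates the footprint of a selective sweep: \code{floor(f * 2n)} carrier
#' haplotypes are drawn uniformly across ALL samples (ignoring phenotype), and
#' every between-individual carrier-carrier haplotype pair gains one segment
#' overlapping the locus. Both case and control rates spike at the locus;
#' whether the one-sided case-control scan rejects there depends only on the
#' chance imbalance of carriers between the label groups.
#'
#' @param x a \code{synthetic_ibd} dataset.
#' @param locus list with \code{chrom} and \code{cm}.
#' @param f carrier haplotype frequency in (0, 1).
#' @param seed integer seed.
#' @return The modified \code{synthetic_ibd} dataset with a \code{carriers}
#'   attribute (haplotype indices).
#' @export
inject_carrier_confounder <- function(x, locus, f, seed = 1L) {
  stopifnot(inherits(x, "synthetic_ibd"), f > 0, f < 1)
  chrom_len <- locus_chrom_len(x, locus)
  n <- nrow(x$phenotypes)
  n_hap <- 2L * n
  k <- floor(f * n_hap)
  if (k < 2L) stop("f * 2n = ", k, " carrier haplotypes; need at least 2")
  new <- with_seed(seed, {
    carriers <- sort(sample.int(n_hap, k))
    cp <- t(utils::combn(carriers, 2L))
    between <- hap_sample(cp[, 1L]) != hap_sample(cp[, 2L])
    cp <- cp[between, , drop = FALSE]
    segs <- locus_segments(nrow(cp), x$spec, locus$cm, chrom_len)
    list(carriers = carriers, h1 = cp[, 1L], h2 = cp[, 2L], segs = segs)
  })
  extra <- segments_from_haps(new$h1, new$h2, as.character(locus$chrom),
                              new$segs$start_cm, new$segs$end_cm,
                              new$segs$length_cm, x$phenotypes$id)
  x$segments <- rbind(x$segments, extra)
  data.table::setattr(x$segments, "class",
                      c("ibd_segments", "data.table", "data.frame"))
  data.table::setattr(x$segments, "min_cm", x$spec$min_cm)
  attr(x, "carriers") <- new$carriers
  x
}

#' Write a synthetic dataset to disk
#'
#' Writes \code{<prefix>.ibd.tsv} (8-column segment dialect),
#' \code{<prefix>.pheno.tsv} and \code{<prefix>.map} (PLINK MAP, linear
#' 1 cM/Mb).
#'
#' @param x a \code{synthetic_ibd} dataset.
#' @param prefix output path prefix.
#' @return Character vector of paths written, invisibly.
#' @export
write_synthetic <- function(x, prefix) {
  ibd <- paste0(prefix, ".ibd.tsv")
  pheno <- paste0(prefix, ".pheno.tsv")
  mapf <- paste0(prefix, ".map")
  write_ibd_segments(x$segments, ibd)
  write_phenotypes(x$phenotypes, pheno)
  write_genetic_map(x$map, mapf)
  invisible(c(ibd, pheno, mapf))
}
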