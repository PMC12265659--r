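#' Construct an IBD segment table
#'
#' Builds and validates the container used throughout the package for detected
#' IBD segments between haplotypes of distinct individuals. Segment base-pair
#' intervals are treated as half-open \code{[start_bp, end_bp)}: a focal
#' position \code{p} overlaps a segment iff \code{start_bp <= p < end_bp}.
#'
#' @param sample1,sample2 character sample identifiers.
#' @param hap1,hap2 haplotype indices in \{1, 2\}.
#' @param chrom chromosome labels (character).
#' @param start_bp,end_bp integer-valued segment endpoints, \code{start_bp < end_bp}.
#' @param length_cm segment genetic length in centiMorgans.
#' @return A \code{data.table} of class \code{ibd_segments} with one row per
#'   segment and attributes \code{n_self_dropped} and \code{min_cm}.
#' @export
ibd_segment_table <- function(sample1, hap1, sample2, hap2, chrom,
                              start_bp, end_bp, length_cm) {
  dt <- data.table(
    sample1 = as.character(sample1), hap1 = as.integer(hap1),
    sample2 = as.character(sample2), hap2 = as.integer(hap2),
    chrom = as.character(chrom),
    start_bp = as.numeric(start_bp), end_bp = as.numeric(end_bp),
    length_cm = as.numeric(length_cm)
  )
  if (nrow(dt)) {
    if (any(!dt$hap1 %in% c(1L, 2L)) || any(!dt$hap2 %in% c(1L, 2L)))
      stop("haplotype indices must be 1 or 2")
    if (any(dt$start_bp < 0)) stop("start_bp must be >= 0")
    if (any(dt$end_bp <= dt$start_bp)) stop("end_bp must exceed start_bp")
    if (any(dt$length_cm < 0)) stop("length_cm must be >= 0")
  }
  data.table::setattr(dt, "class", c("ibd_segments", class(dt)))
  data.table::setattr(dt, "n_self_dropped", 0L)
  data.table::setattr(dt, "min_cm", 0)
  dt
}

#' Read an IBD segment file
#'
#' Parses the 8-column tab-separated dialect emitted by haplotype-based IBD
#' detection tools: ID1, HAP1, ID2, HAP2, CHROM, START(bp), END(bp), LEN(cM).
#' Input may be gzip-compressed; compression is detected from magic bytes.
#' Within-individual segments (ID1 == ID2, homozygosity by descent) are
#' excluded from all downstream pair counts and are dropped here with a count
#' kept in the \code{n_self_dropped} attribute. Records shorter than
#' \code{min_cm} are discarded, mirroring the detection-length threshold used
#' when calling segments.
#'
#' @param path file path (plain or gzipped TSV).
#' @param min_cm minimum segment length in cM to retain (default 2.0, the
#'   usual sequence-data detection threshold).
#' @return An \code{ibd_segments} table; row order of retained records is
#'   preserved.
#' @export
read_ibd_segments <- function(path, min_cm = 2.0) {
  lines <- read_lines_auto(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    out <- ibd_segment_table(character(), integer(), character(), integer(),
                             character(), numeric(), numeric(), numeric())
    data.table::setattr(out, "min_cm", min_cm)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 8L)) {
    bad <- which(nf != 8L)[1]
    stop("parse error at line ", bad, ": expected 8 tab-separated columns, found ", nf[bad])
  }
  m <- matrix(unlist(fields), ncol = 8L, byrow = TRUE)
  num <- function(col, name) {
    x <- suppressWarnings(as.numeric(m[, col]))
    if (anyNA(x)) {
      bad <- which(is.na(x))[1]
      stop("parse error at line ", bad, ": non-numeric ", name, " '", m[bad, col], "'")
    }
    x
  }
  hap1 <- num(2L, "HAP1"); hap2 <- num(4L, "HAP2")
  start_bp <- num(6L, "START"); end_bp <- num(7L, "END"); len <- num(8L, "LEN")
  dt <- data.table(sample1 = m[, 1], hap1 = as.integer(hap1),
                   sample2 = m[, 3], hap2 = as.integer(hap2),
                   chrom = m[, 5], start_bp = start_bp, end_bp = end_bp,
                   length_cm = len)
  self <- dt$sample1 == dt$sample2
  n_self <- sum(self)
  dt <- dt[!self & dt$length_cm >= min_cm]
  out <- ibd_segment_table(dt$sample1, dt$hap1, dt$sample2, dt$hap2,
                           dt$chrom, dt$start_bp, dt$end_bp, dt$length_cm)
  data.table::setattr(out, "n_self_dropped", n_self)
  data.table::setattr(out, "min_cm", min_cm)
  out
}

#' Filter an IBD segment table by length
#'
#' Idempotent: filtering an already filtered table at the same threshold is a
#' no-op.
#'
#' @param segments an \code{ibd_segments} table.
#' @param min_cm minimum length in cM.
#' @return Filtered \code{ibd_segments} table.
#' @export
filter_segments <- function(segments, min_cm) {
  out <- segments[segments$length_cm >= min_cm]
  data.table::setattr(out, "class", class(segments))
  data.table::setattr(out, "n_self_dropped", attr(segments, "n_self_dropped"))
  data.table::setattr(out, "min_cm", max(min_cm, attr(segments, "min_cm") %||% 0))
  out
}

#' Construct a genetic map
#'
#' @param chrom chromosome label per anchor.
#' @param bp physical position per anchor (strictly increasing within a
#'   chromosome).
#' @param cm genetic position per anchor (non-decreasing within a chromosome).
#' @return A \code{genetic_map}: a keyed \code{data.table} of anchors sorted by
#'   bp within chromosome.
#' @export
genetic_map <- function(chrom, bp, cm) {
  dt <- data.table(chrom = as.character(chrom), bp = as.numeric(bp), cm = as.numeric(cm))
  if (!nrow(dt)) stop("genetic map has no anchors")
  setorder(dt, chrom, bp)
  chk <- dt[, list(n = .N,
                   bp_ok = all(diff(bp) > 0),
                   cm_ok = all(diff(cm) >= 0)), by = "chrom"]
  if (any(chk$n < 2L))
    stop("chromosome ", chk$chrom[chk$n < 2L][1], " has fewer than 2 map anchors")
  if (any(!chk$bp_ok))
    stop("bp positions not strictly increasing on chromosome ",
         chk$chrom[!chk$bp_ok][1])
  if (any(!chk$cm_ok))
    stop("cM positions decrease on chromosome ", chk$chrom[!chk$cm_ok][1])
  data.table::setattr(dt, "class", c("genetic_map", class(dt)))
  dt
}

#' Read a PLINK-format genetic map
#'
#' Expects whitespace-separated columns CHROM, SNP_ID, CM, BP. Rows may appear
#' in any order; anchors are sorted by bp within chromosome.
#'
#' @param path file path (plain or gzipped).
#' @return A \code{genetic_map}.
#' @export
read_genetic_map <- function(path) {
  lines <- read_lines_auto(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty genetic map file: ", path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 4L)) {
    bad <- which(nf != 4L)[1]
    stop("parse error at line ", bad, ": expected 4 columns, found ", nf[bad])
  }
  m <- matrix(unlist(fields), ncol = 4L, byrow = TRUE)
  cm <- suppressWarnings(as.numeric(m[, 3]))
  bp <- suppressWarnings(as.numeric(m[, 4]))
  if (anyNA(cm) || anyNA(bp)) {
    bad <- which(is.na(cm) | is.na(bp))[1]
    stop("parse error at line ", bad, ": non-numeric map coordinate")
  }
  genetic_map(m[, 1], bp, cm)
}

map_chrom <- function(map, chrom_label) {
  anchors <- map[which(map$chrom == chrom_label)]
  if (!nrow(anchors)) stop("chromosome not in genetic map: ", chrom_label)
  anchors
}

#' Interpolate between physical and genetic coordinates
#'
#' Piecewise-linear interpolation between map anchors. Queries outside the
#' anchor span are clamped to the terminal anchor value (constant
#' extrapolation); scan grids are always built inside the span, so clamping
#' only affects reporting.
#'
#' @param map a \code{genetic_map}.
#' @param chrom chromosome label.
#' @param bp,cm query positions (vectorized).
#' @return Numeric vector of interpolated coordinates.
#' @export
bp_to_cm <- function(map, chrom, bp) {
  anchors <- map_chrom(map, chrom)
  approx(anchors$bp, anchors$cm, xout = bp, rule = 2, ties = "ordered")$y
}

#' @rdname bp_to_cm
#' @export
cm_to_bp <- function(map, chrom, cm) {
  anchors <- map_chrom(map, chrom)
  approx(anchors$cm, anchors$bp, xout = cm, rule = 2, ties = "ordered")$y
}

#' Read a two-column phenotype table
#'
#' Whitespace- or tab-separated file of sample id and 0/1 status (0 = control,
#' 1 = case).
#'
#' @param path file path.
#' @return A \code{phenotype_table}: data.table with columns \code{id},
#'   \code{status}, plus \code{n_cases}/\code{n_controls} attributes.
#' @export
read_phenotypes <- function(path) {
  lines <- read_lines_auto(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty phenotype file: ", path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 2L)) {
    bad <- which(nf != 2L)[1]
    stop("parse error at line ", bad, ": expected 2 columns, found ", nf[bad])
  }
  m <- matrix(unlist(fields), ncol = 2L, byrow = TRUE)
  phenotype_table(m[, 1], m[, 2])
}

#' @rdname read_phenotypes
#' @param id sample ids (unique).
#' @param status 0/1 vector; 1 = case.
#' @export
phenotype_table <- function(id, status) {
  id <- as.character(id)
  status_num <- suppressWarnings(as.numeric(as.character(status)))
  if (anyNA(status_num) || any(!status_num %in% c(0, 1)))
    stop("phenotype status must be 0 (control) or 1 (case)")
  if (anyDuplicated(id))
    stop("duplicated sample id in phenotypes: ", id[duplicated(id)][1])
  dt <- data.table(id = id, status = as.integer(status_num))
  data.table::setattr(dt, "class", c("phenotype_table", class(dt)))
  data.table::setattr(dt, "n_cases", sum(dt$status == 1L))
  data.table::setattr(dt, "n_controls", sum(dt$status == 0L))
  dt
}

#' @export
print.phenotype_table <- function(x, ...) {
  cat("phenotype table:", attr(x, "n_cases"), "cases,",
      attr(x, "n_controls"), "controls\n")
  invisible(x)
}

#' Write / read a scan table
#'
#' The scan table has one row per grid position with deterministic column
#' order: CHROM, BP, CM, RATE_CASE, RATE_CONTROL, Z_CASE, Z_CONTROL, Z_DIFF,
#' PVALUE, EXCLUDED. One-sample (selection) scans leave the control and
#' difference columns NA.
#'
#' @param track an \code{ibd_scan} track (see \code{\link{robust_standardize}}).
#' @param path output TSV path.
#' @return \code{write_scan_table} returns \code{path} invisibly;
#'   \code{read_scan_table} returns a data.table.
#' @export
write_scan_table <- function(track, path) {
  out <- data.table(
    CHROM = track$chrom, BP = track$bp, CM = track$cm,
    RATE_CASE = track$rate_case, RATE_CONTROL = track$rate_control,
    Z_CASE = track$z_case, Z_CONTROL = track$z_control,
    Z_DIFF = track$z_diff, PVALUE = track$pvalue,
    EXCLUDED = as.integer(track$excluded))
  fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_scan_table
#' @export
read_scan_table <- function(path) {
  fread(path, sep = "\t", na.strings = "NA")
}

#' Write called regions as TSV and BED
#'
#' Writes \code{<prefix>.regions.tsv} with the full region annotation and
#' \code{<prefix>.regions.bed} with 0-based half-open intervals. Internal bp
#' coordinates are already 0-based, so BED start equals the region's first
#' significant bp.
#'
#' @param regions data.table from \code{\link{call_regions}}.
#' @param prefix output path prefix.
#' @return Character vector of the two paths written, invisibly.
#' @export
write_regions <- function(regions, prefix) {
  tsv <- paste0(prefix, ".regions.tsv")
  bed <- paste0(prefix, ".regions.bed")
  cols <- c("chrom", "max_z", "argmax_bp", "argmax_cm", "start_bp", "end_bp",
            "start_cm", "end_cm", "size_cm", "pvalue")
  if (nrow(regions)) {
    fwrite(regions[, cols, with = FALSE], tsv, sep = "\t", quote = FALSE)
    bed_dt <- data.table(chrom = regions$chrom,
                         start = format(floor(regions$start_bp), scientific = FALSE, trim = TRUE),
                         end = format(ceiling(regions$end_bp), scientific = FALSE, trim = TRUE),
                         name = sprintf("region_%d", seq_len(nrow(regions))),
                         score = regions$max_z)
    fwrite(bed_dt, bed, sep = "\t", quote = FALSE, col.names = FALSE)
  } else {
    writeLines(paste(cols, collapse = "\t"), tsv)
    file.create(bed)
  }
  invisible(c(tsv, bed))
}

#' Write a segment table in the 8-column IBD dialect
#'
#' @param segments an \code{ibd_segments} table.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_ibd_segments <- function(segments, path) {
  out <- data.table(segments$sample1, segments$hap1, segments$sample2,
                    segments$hap2, segments$chrom,
                    format(segments$start_bp, scientific = FALSE, trim = TRUE),
                    format(segments$end_bp, scientific = FALSE, trim = TRUE),
                    segments$length_cm)
  fwrite(out, path, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a genetic map in PLINK MAP format
#'
#' @param map a \code{genetic_map}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_genetic_map <- function(map, path) {
  out <- data.table(map$chrom, sprintf("anchor_%d", seq_len(nrow(map))),
                    map$cm, format(map$bp, scientific = FALSE, trim = TRUE))
  fwrite(out, path, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a phenotype table
#'
#' @param phenotypes a \code{phenotype_table}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_phenotypes <- function(phenotypes, path) {
  fwrite(phenotypes[, c("id", "status"), with = FALSE], path, sep = "\t",
         quote = FALSE, col.names = FALSE)
  invisible(path)
}
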