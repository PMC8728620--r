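# Third-tier confirmation by low-coverage whole-genome sequencing: binned read
# counts over chr15q11-q13, log2-ratio copy-number segmentation, breakpoint
# snapping (BP1-BP5) and imprinting-disorder subtype assignment.
#
# Coordinates: bins and segments are 0-based half-open internally; emitted HGVS
# g. descriptions are 1-based inclusive (start + 1, same end).

.LCWGS_REGION <- c(20000000, 35000000)
.LCWGS_BIN <- 50000

#' Simulate a binned LC-WGS read-count track over chr15
#'
#' Per-bin counts are Poisson with mean `coverage * copies / 2`; the log2 ratio
#' is taken against the median count of the reference bins (outside the
#' CNV-prone BP1-BP5 neighbourhood), with a 0.5 pseudo-count floor so
#' zero-count bins stay finite. Bins are uniform: GC correction is out of scope
#' for the simulator (a hook for real data would normalise counts upstream).
#'
#' @param cn_profile data.frame (`start`, `end`, `copies`) of non-diploid
#'   regions (0-based half-open), or `NULL` for all 2 copies
#' @param coverage mean reads per bin at 2 copies (> 0)
#' @param region modeled interval (0-based half-open)
#' @param bin_width bin width in bp (bins tile the region)
#' @param reference_margin distance beyond BP1/BP5 excluded from the
#'   normalisation baseline
#' @param bp_map breakpoint landmark coordinates
#' @param seed integer seed
#' @return data.frame of class `"bin_track"`: `contig`, `bin_start`, `bin_end`,
#'   `raw_count`, `log2_ratio`
#' @export
simulate_bins <- function(cn_profile = NULL, coverage = 100,
                          region = .LCWGS_REGION, bin_width = .LCWGS_BIN,
                          reference_margin = 1e6, bp_map = default_bp_map(),
                          seed = NULL) {
  stopifnot(coverage > 0, bin_width > 0, region[2] > region[1])
  starts <- seq(region[1], region[2] - bin_width, by = bin_width)
  mids <- starts + bin_width / 2
  copies <- rep(2L, length(starts))
  if (!is.null(cn_profile)) {
    for (i in seq_len(nrow(cn_profile))) {
      sel <- mids >= cn_profile$start[i] & mids < cn_profile$end[i]
      copies[sel] <- cn_profile$copies[i]
    }
  }
  counts <- with_seed(seed, stats::rpois(length(starts), coverage * copies / 2))
  ref <- mids < (min(bp_map) - reference_margin) | mids >= (max(bp_map) + reference_margin)
  if (!any(ref)) stop("no reference bins outside the breakpoint neighbourhood")
  baseline <- stats::median(counts[ref])
  if (baseline <= 0) stop("zero coverage: normalisation baseline is empty")
  out <- data.frame(
    contig = "NC_000015.9",
    bin_start = starts, bin_end = starts + bin_width,
    raw_count = counts,
    log2_ratio = log2(pmax(counts, 0.5) / baseline),
    stringsAsFactors = FALSE
  )
  class(out) <- c("bin_track", "data.frame")
  out
}

#' HGVS g. description for a copy-number segment
#' @param start,end segment bounds (0-based half-open)
#' @param copies integer copy number (< 2 renders `del`, > 2 renders `[n]`)
#' @param contig accession prefix
#' @return character HGVS string (1-based inclusive coordinates)
#' @export
#' @examples
#' hgvs_segment(23100000, 28300000, 1)  # "NC_000015.9:g.23100001_28300000del"
hgvs_segment <- function(start, end, copies, contig = "NC_000015.9") {
  suffix <- ifelse(copies < 2, "del", sprintf("[%d]", copies))
  sprintf("%s:g.%d_%d%s", contig, start + 1, end, suffix)
}

#' Parse an HGVS g. description back to 0-based half-open coordinates
#' @param hgvs string as produced by [hgvs_segment()]
#' @return list: `contig`, `start`, `end` (0-based half-open), `copies`
#'   (`NA` for `del` without stated count; 1 is assumed by callers)
#' @export
parse_hgvs_segment <- function(hgvs) {
  m <- regmatches(hgvs, regexec("^([^:]+):g\\.(\\d+)_(\\d+)(del|\\[(\\d+)\\])$", hgvs))[[1]]
  if (length(m) == 0) stop("unparseable HGVS segment: ", hgvs)
  list(contig = m[2], start = as.numeric(m[3]) - 1, end = as.numeric(m[4]),
       copies = if (m[5] == "del") 1L else as.integer(m[6]))
}

#' Segment a bin track into integer copy-number calls
#'
#' Log2 ratios are median-smoothed, classified to the nearest copy band
#' (`log2(c/2)` for c = 1..`cn_max`, within `tol`), adjacent same-CN bins are
#' merged, and runs shorter than `min_bins` (or unclassifiable bins) are
#' absorbed into their left neighbour (right neighbour at the track start).
#' Only non-2-copy segments are reported, with HGVS descriptions.
#'
#' @param track a `bin_track`
#' @param tol log2 distance tolerated around each copy band
#' @param min_bins shortest run of bins kept as its own segment
#' @param cn_max largest copy number considered
#' @param smooth_k running-median window (odd)
#' @return data.frame of class `"cn_segments"`: `start`, `end` (0-based
#'   half-open), `copies`, `n_bins`, `hgvs`
#' @export
segment_and_call <- function(track, tol = 0.25, min_bins = 4L, cn_max = 8L,
                             smooth_k = 5L) {
  stopifnot(nrow(track) > 0)
  l2 <- stats::runmed(track$log2_ratio, k = smooth_k, endrule = "median")
  bands <- log2(seq_len(cn_max) / 2)
  cn <- vapply(l2, function(x) {
    i <- which.min(abs(bands - x))
    if (abs(bands[i] - x) <= tol) i else NA_integer_
  }, integer(1))

  # absorb unclassifiable bins and sub-threshold runs into whichever flanking
  # kept run has the closer copy band (by the run's mean raw log2 ratio)
  r <- rle(ifelse(is.na(cn), -1L, cn))
  keep <- r$values != -1L & r$lengths >= min_bins
  if (!any(keep)) {
    out <- data.frame(start = numeric(0), end = numeric(0), copies = integer(0),
                      n_bins = integer(0), hgvs = character(0))
    class(out) <- c("cn_segments", "data.frame")
    return(out)
  }
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  run_mean <- vapply(seq_along(r$lengths), function(i) {
    mean(track$log2_ratio[run_start[i]:run_end[i]])
  }, numeric(1))
  kept_pos <- which(keep)
  filled <- r$values
  for (i in which(!keep)) {
    prev <- kept_pos[kept_pos < i]
    nxt <- kept_pos[kept_pos > i]
    cand <- c(if (length(prev)) r$values[max(prev)],
              if (length(nxt)) r$values[min(nxt)])
    filled[i] <- cand[which.min(abs(bands[cand] - run_mean[i]))]
  }
  cn_filled <- inverse.rle(list(lengths = r$lengths, values = filled))

  r2 <- rle(cn_filled)
  idx_end <- cumsum(r2$lengths)
  idx_start <- idx_end - r2$lengths + 1L

  # segment-level recall: per-bin calls fix the boundaries, but each segment's
  # copy number is re-assigned from the mean raw log2 ratio over its bins
  # (averaging n bins shrinks the noise by sqrt(n), suppressing short spurious
  # band crossings), then adjacent equal-CN segments are re-merged
  seg_cn <- vapply(seq_along(idx_start), function(i) {
    mu <- mean(track$log2_ratio[idx_start[i]:idx_end[i]])
    which.min(abs(bands - mu))
  }, integer(1))
  r3 <- rle(seg_cn)
  grp_end <- cumsum(r3$lengths)
  grp_start <- grp_end - r3$lengths + 1L
  seg <- data.frame(
    start = track$bin_start[idx_start[grp_start]],
    end = track$bin_end[idx_end[grp_end]],
    copies = r3$values,
    n_bins = idx_end[grp_end] - idx_start[grp_start] + 1L
  )
  seg <- seg[seg$copies != 2L, , drop = FALSE]
  seg$hgvs <- if (nrow(seg)) {
    hgvs_segment(seg$start, seg$end, seg$copies, contig = track$contig[1])
  } else character(0)
  rownames(seg) <- NULL
  class(seg) <- c("cn_segments", "data.frame")
  seg
}

#' Render copy-number segments back onto a bin grid (for idempotence checks)
#' @param segments a `cn_segments` data.frame
#' @param region,bin_width grid definition (defaults match [simulate_bins()])
#' @return a noise-free `bin_track` with exact band log2 ratios
#' @export
segments_to_track <- function(segments, region = .LCWGS_REGION,
                              bin_width = .LCWGS_BIN) {
  starts <- seq(region[1], region[2] - bin_width, by = bin_width)
  mids <- starts + bin_width / 2
  copies <- rep(2L, length(starts))
  for (i in seq_len(nrow(segments))) {
    sel <- mids >= segments$start[i] & mids < segments$end[i]
    copies[sel] <- segments$copies[i]
  }
  out <- data.frame(
    contig = "NC_000015.9", bin_start = starts, bin_end = starts + bin_width,
    raw_count = 100 * copies / 2, log2_ratio = log2(copies / 2),
    stringsAsFactors = FALSE
  )
  class(out) <- c("bin_track", "data.frame")
  out
}

.snap_bp <- function(pos, bp_map, window) {
  d <- abs(bp_map - pos)
  i <- which.min(d)
  if (d[i] <= window) names(bp_map)[i] else NA_character_
}

#' Assign breakpoints and an imprinting-disorder subtype to CN segments
#'
#' Segment boundaries are snapped to the nearest BP1-BP5 landmark within
#' `window`. The subtype follows from the copy number over the imprinted
#' centre (the SNRPN locus) and the snapped breakpoint set: CN=1 spanning
#' BP1-BP3 is a type I deletion, BP2-BP3 type II (AS vs PWS disambiguated by
#' the first-tier methylation band: low = AS, high = PWS); CN=4 over the centre
#' is idic15 (breakpoints reported at the distal CN transitions, where the
#' supernumerary chromosome's arms end); CN=3 alone is an interstitial
#' duplication; CN>=5 a tricentric chromosome. Boundaries with no landmark in
#' range leave the call unclassified with raw coordinates retained.
#'
#' @param segments a `cn_segments` data.frame
#' @param bp_map named landmark coordinates (needs BP1-BP5)
#' @param window snap distance in bp
#' @param meth_band first-tier band of the sample (`"low"`, `"high"` or `NA`)
#' @param imprinted_core interval whose dominant copy number drives the call
#'   (the PWS/AS imprinted centre around the SNRPN locus); the copy number is
#'   the length-weighted mode over this interval, so short spurious segments
#'   cannot flip the subtype
#' @return object of class `"subtype_call"`: `label`, `breakpoints`,
#'   `segments`, `raw_boundaries`
#' @export
assign_breakpoints <- function(segments, bp_map = default_bp_map(),
                               window = 5e5, meth_band = NA_character_,
                               imprinted_core = c(23600000, 27800000)) {
  stopifnot(all(c("BP1", "BP2", "BP3", "BP4", "BP5") %in% names(bp_map)))
  mk <- function(label, bps, raw = NULL) {
    structure(list(label = label, breakpoints = bps, segments = segments,
                   raw_boundaries = raw), class = "subtype_call")
  }
  if (nrow(segments) == 0) return(mk("normal", character(0)))

  # length-weighted modal copy number over the imprinted core (uncovered
  # stretches count as 2 copies)
  ov <- pmax(0, pmin(segments$end, imprinted_core[2]) -
               pmax(segments$start, imprinted_core[1]))
  wt <- tapply(ov, segments$copies, sum)
  core_len <- diff(imprinted_core)
  wt["2"] <- (if ("2" %in% names(wt)) wt[["2"]] else 0) + core_len - sum(ov)
  cn_centre <- as.integer(names(wt)[which.max(wt)])
  centre_seg <- segments[segments$copies == cn_centre & ov > 0, , drop = FALSE]

  if (cn_centre == 1L) {
    del_start <- min(centre_seg$start)
    del_end <- max(centre_seg$end)
    bp_s <- .snap_bp(del_start, bp_map, window)
    bp_e <- .snap_bp(del_end, bp_map, window)
    if (is.na(bp_s) || is.na(bp_e)) {
      return(mk("unclassified", character(0), raw = c(del_start, del_end)))
    }
    type <- if (identical(c(bp_s, bp_e), c("BP1", "BP3"))) "typeI"
            else if (identical(c(bp_s, bp_e), c("BP2", "BP3"))) "typeII"
            else NA_character_
    if (is.na(type)) {
      return(mk("unclassified", c(bp_s, bp_e),
                raw = c(centre_seg$start[1], centre_seg$end[1])))
    }
    cond <- if (identical(meth_band, "low")) "AS"
            else if (identical(meth_band, "high")) "PWS" else NA_character_
    if (is.na(cond)) return(mk("unclassified", c(bp_s, bp_e)))
    return(mk(paste(cond, "del", type, sep = "_"), c(bp_s, bp_e)))
  }

  if (cn_centre >= 5L) {
    bps <- unique(stats::na.omit(c(
      vapply(seq_len(nrow(segments)), function(i)
        .snap_bp(segments$end[i], bp_map, window), character(1))
    )))
    return(mk("tricentric", bps))
  }

  if (cn_centre == 4L) {
    # distal structure of the supernumerary: end of the CN=4 body and end of
    # any CN=3 shoulder are the reported breakpoints
    ends <- segments$end[segments$copies >= 3L]
    bps <- unique(stats::na.omit(vapply(ends, .snap_bp, character(1),
                                        bp_map = bp_map, window = window)))
    if (length(bps) == 0) {
      return(mk("unclassified", character(0), raw = c(segments$start, segments$end)))
    }
    return(mk("idic15", bps))
  }

  if (cn_centre == 3L) {
    gains <- segments[segments$copies >= 3L, , drop = FALSE]
    bp_s <- .snap_bp(min(gains$start), bp_map, window)
    bp_e <- .snap_bp(max(gains$end), bp_map, window)
    return(mk("interstitial_dup", stats::na.omit(c(bp_s, bp_e))))
  }

  mk("unclassified", character(0), raw = c(segments$start, segments$end))
}

#' @export
print.subtype_call <- function(x, ...) {
  cat("LC-WGS subtype:", x$label)
  if (length(x$breakpoints)) cat("  [", paste(x$breakpoints, collapse = ", "), "]")
  cat("\n")
  if (nrow(x$segments)) {
    cat("  segments:\n")
    for (i in seq_len(nrow(x$segments))) {
      cat("   ", x$segments$hgvs[i], sprintf("(%d bins)", x$segments$n_bins[i]), "\n")
    }
  }
  invisible(x)
}
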