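#' Build per-chromosome ancestry tracks ("graphical genotypes")
#'
#' Turns the ordered per-site genotype classes of the focal individual into
#' one track per chromosome, the raw material for chromosome painting.
#' Sites in the `other` bucket (non-diagnostic alleles) are dropped with a
#' message, since tracks carry only the three ancestry classes.
#'
#' @param classes Per-site class data.frame (`chrom`, `pos`, `class`) from
#'   [classify_focal_genotypes()], sorted by (chrom, pos).
#' @return List of `ancestry_track` objects, one per chromosome, in order
#'   of appearance.
#' @export
paint_chromosomes <- function(classes) {
  keep <- classes$class %in% c("AA", "Aa", "aa")
  if (any(!keep))
    message("dropping ", sum(!keep), " site(s) with non-diagnostic alleles")
  classes <- classes[keep, , drop = FALSE]
  chroms <- unique(as.character(classes$chrom))
  lapply(chroms, function(ch) {
    rows <- classes$chrom == ch
    pos <- classes$pos[rows]
    if (is.unsorted(pos, strictly = TRUE))
      stop("positions on ", ch, " are not strictly increasing")
    structure(
      list(chrom = ch, pos = pos,
           class = as.character(classes$class[rows]),
           smoothed = NULL, window = NA_integer_, min_sites = NA_integer_),
      class = "ancestry_track"
    )
  })
}

#' @export
print.ancestry_track <- function(x, ...) {
  cat("<ancestry_track> ", x$chrom, ": ", length(x$pos), " sites",
      if (!is.null(x$smoothed))
        paste0("; ", nrow(x$smoothed), " smoothed segment(s) (window=",
               x$window, ", min_sites=", x$min_sites, ")"),
      "\n", sep = "")
  invisible(x)
}

#' Smooth an ancestry track into segments
#'
#' Each site's class is replaced by the majority class in a centred window
#' of `window` sites (truncated at chromosome ends); ties are broken toward
#' the site's own unsmoothed class, which makes smoothing deterministic and
#' idempotent. Runs of identical smoothed class are merged into segments,
#' and segments with fewer than `min_sites` sites are absorbed into the
#' larger neighbouring segment (repeatedly, smallest first) so that short
#' blips — typically genotyping error — do not fragment the painting.
#' Windows are counted in sites, not base pairs, so smoothing is robust to
#' marker-density variation.
#'
#' @param track An `ancestry_track` from [paint_chromosomes()].
#' @param window Odd window size in sites (>= 1; 1 = no smoothing).
#' @param min_sites Minimum sites per retained segment (>= 1).
#' @param mask_aa If `TRUE`, aa-class sites (mostly error under a
#'   backcross-to-A pedigree) are removed before smoothing instead of being
#'   treated as a class of their own.
#' @return The track with a `smoothed` data.frame of segments: `start`,
#'   `end` (1-based inclusive site positions), `class`, `n_sites`.
#' @export
smooth_track <- function(track, window = 101L, min_sites = 10L,
                         mask_aa = FALSE) {
  stopifnot(inherits(track, "ancestry_track"))
  if (window < 1L || window %% 2L == 0L)
    stop("window must be a positive odd number of sites")
  if (min_sites < 1L) stop("min_sites must be >= 1")
  pos <- track$pos
  cls <- track$class
  if (mask_aa) {
    keep <- cls != "aa"
    pos <- pos[keep]; cls <- cls[keep]
  }
  n <- length(pos)
  if (n == 0L) {
    track$smoothed <- data.frame(start = integer(), end = integer(),
                                 class = character(), n_sites = integer(),
                                 stringsAsFactors = FALSE)
    track$window <- as.integer(window); track$min_sites <- as.integer(min_sites)
    return(track)
  }
  levels3 <- c("AA", "Aa", "aa")
  ci <- match(cls, levels3)
  half <- (window - 1L) %/% 2L
  # windowed class counts by cumulative sums (edges truncated)
  ind <- matrix(0L, n, 3L)
  ind[cbind(seq_len(n), ci)] <- 1L
  cum <- matrix(apply(ind, 2, cumsum), nrow = n)
  lo <- pmax(seq_len(n) - half, 1L) - 1L
  hi <- pmin(seq_len(n) + half, n)
  counts <- cum[hi, , drop = FALSE] -
    rbind(0, cum)[lo + 1L, , drop = FALSE]
  maxc <- pmax(counts[, 1], counts[, 2], counts[, 3])
  own <- counts[cbind(seq_len(n), ci)] == maxc
  smoothed <- ifelse(own, ci, max.col(counts, ties.method = "first"))
  segs <- runs_to_segments(pos, levels3[smoothed])
  segs <- absorb_small_segments(segs, min_sites)
  track$smoothed <- segs
  track$window <- as.integer(window)
  track$min_sites <- as.integer(min_sites)
  track
}

runs_to_segments <- function(pos, cls) {
  r <- rle(cls)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  data.frame(start = pos[starts], end = pos[ends], class = r$values,
             n_sites = r$lengths, stringsAsFactors = FALSE)
}

absorb_small_segments <- function(segs, min_sites) {
  repeat {
    if (nrow(segs) <= 1L) break
    small <- which(segs$n_sites < min_sites)
    if (!length(small)) break
    i <- small[which.min(segs$n_sites[small])]
    left <- if (i > 1L) segs$n_sites[i - 1L] else -1L
    right <- if (i < nrow(segs)) segs$n_sites[i + 1L] else -1L
    j <- if (left >= right) i - 1L else i + 1L
    # the absorbed segment's sites take the neighbour's class
    segs$n_sites[j] <- segs$n_sites[j] + segs$n_sites[i]
    segs$start[j] <- min(segs$start[j], segs$start[i])
    segs$end[j] <- max(segs$end[j], segs$end[i])
    segs <- segs[-i, , drop = FALSE]
    # merging may have created adjacent same-class segments
    segs <- merge_adjacent(segs)
  }
  rownames(segs) <- NULL
  segs
}

merge_adjacent <- function(segs) {
  if (nrow(segs) <= 1L) return(segs)
  grp <- cumsum(c(TRUE, segs$class[-1] != segs$class[-nrow(segs)]))
  if (max(grp) == nrow(segs)) return(segs)
  out <- do.call(rbind, lapply(split(seq_len(nrow(segs)), grp), function(ix) {
    data.frame(start = min(segs$start[ix]), end = max(segs$end[ix]),
               class = segs$class[ix[1]], n_sites = sum(segs$n_sites[ix]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Count ancestry segments per chromosome
#'
#' @param tracks List of smoothed `ancestry_track`s.
#' @return List of class `segment_summary`: `per_chromosome` data.frame
#'   (`chrom`, `n_segments`) and `summary` (min/median/max over
#'   chromosomes).
#' @export
count_segments <- function(tracks) {
  if (inherits(tracks, "ancestry_track")) tracks <- list(tracks)
  if (any(vapply(tracks, function(t) is.null(t$smoothed), TRUE)))
    stop("all tracks must be smoothed before counting segments")
  per <- data.frame(
    chrom = vapply(tracks, `[[`, "", "chrom"),
    n_segments = vapply(tracks, function(t) nrow(t$smoothed), 0L),
    stringsAsFactors = FALSE
  )
  structure(
    list(per_chromosome = per,
         summary = c(min = min(per$n_segments),
                     median = stats::median(per$n_segments),
                     max = max(per$n_segments))),
    class = "segment_summary"
  )
}

#' @export
print.segment_summary <- function(x, ...) {
  cat("<segment_summary>", nrow(x$per_chromosome), "chromosome(s); segments",
      "min/median/max =", paste(x$summary, collapse = "/"), "\n")
  invisible(x)
}

#' Write smoothed segments as BED
#'
#' BED is 0-based half-open: a segment spanning 1-based inclusive positions
#' `[start, end]` becomes `start-1 .. end`. Column 4 carries the class,
#' column 5 the number of supporting sites.
#'
#' @param tracks List of smoothed `ancestry_track`s.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
segments_to_bed <- function(tracks, path) {
  if (inherits(tracks, "ancestry_track")) tracks <- list(tracks)
  rows <- lapply(tracks, function(t) {
    if (is.null(t$smoothed)) stop("track ", t$chrom, " is not smoothed")
    if (!nrow(t$smoothed)) return(NULL)
    data.frame(chrom = t$chrom, start = t$smoothed$start - 1L,
               end = t$smoothed$end, class = t$smoothed$class,
               n_sites = t$smoothed$n_sites, stringsAsFactors = FALSE)
  })
  bed <- do.call(rbind, rows)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
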