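#' Crosslink track constructor
#'
#' A `CrosslinkTrack` stores strand-specific per-nucleotide crosslink event
#' counts as a sparse keyed data.table (`chrom`, `pos`, `strand`, `count`),
#' tagged with replicate id, condition and a control flag.
#'
#' @param events data.frame with columns `chrom`, `pos` (0-based bp),
#'   `strand` (`+`/`-`), `count` (positive integers).
#' @param genome a [binned_genome()] for coordinate validation.
#' @param replicate replicate identifier.
#' @param condition condition label.
#' @param is_control negative-control flag.
#' @return an object of class `CrosslinkTrack`.
#' @export
crosslink_track <- function(events, genome, replicate = 1L,
                            condition = NA_character_, is_control = FALSE) {
  stopifnot(inherits(genome, "BinnedGenome"))
  dt <- data.table::as.data.table(events)
  need <- c("chrom", "pos", "strand", "count")
  if (!all(need %in% names(dt)))
    stop("events must have columns: ", paste(need, collapse = ", "))
  dt <- dt[, .(chrom = as.character(chrom), pos = as.integer(pos),
               strand = as.character(strand), count = as.integer(count))]
  if (nrow(dt)) {
    check_chrom(genome, dt$chrom)
    if (!all(dt$strand %in% c("+", "-"))) stop("strand must be + or -")
    if (any(dt$count <= 0)) stop("counts must be positive integers")
    if (any(dt$pos < 0) || any(dt$pos >= unname(genome$length[dt$chrom])))
      stop("position outside chromosome")
    dt <- dt[, .(count = sum(count)), by = .(chrom, strand, pos)]
  }
  data.table::setkey(dt, chrom, strand, pos)
  structure(dt, class = c("CrosslinkTrack", class(dt)), genome = genome,
            replicate = replicate, condition = condition,
            is_control = is_control)
}

#' Extract crosslink sites from read alignments
#'
#' The crosslinked nucleotide is the position one bp 5' of the read's 5'
#' end: a plus-strand read `[s, e)` contributes one event at `s - 1` on the
#' plus strand; a minus-strand read `[s, e)` (whose 5' end is its right
#' edge) contributes one event at `e` on the minus strand.  Events falling
#' at position -1 or at/beyond the chromosome end are dropped and tallied
#' in the `n_dropped` attribute.
#'
#' @param alignments data.frame with `chrom`, `start`, `end` (0-based
#'   half-open), `strand` (`+`/`-` only).
#' @param genome a [binned_genome()].
#' @inheritParams crosslink_track
#' @return a [crosslink_track()] with attribute `n_dropped`.
#' @export
extract_crosslink_sites <- function(alignments, genome, replicate = 1L,
                                    condition = NA_character_,
                                    is_control = FALSE) {
  al <- data.table::as.data.table(alignments)
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(al)))
  if (nrow(al) && !all(al$strand %in% c("+", "-")))
    stop("unstranded or invalid-strand reads")
  check_chrom(genome, al$chrom)
  pos <- ifelse(al$strand == "+", al$start - 1L, al$end)
  ok <- pos >= 0 & pos < unname(genome$length[al$chrom])
  ev <- data.table::data.table(chrom = al$chrom[ok], pos = pos[ok],
                               strand = al$strand[ok], count = 1L)
  tr <- crosslink_track(ev, genome, replicate, condition, is_control)
  attr(tr, "n_dropped") <- sum(!ok)
  tr
}

#' Merge crosslink tracks by summing counts
#'
#' @param tracks list of [crosslink_track()] objects over one genome.
#' @return a merged `CrosslinkTrack` (replicate id `"merged"`).
#' @export
merge_tracks <- function(tracks) {
  stopifnot(length(tracks) >= 1,
            all(vapply(tracks, inherits, logical(1), "CrosslinkTrack")))
  genome <- attr(tracks[[1]], "genome")
  for (tr in tracks[-1]) if (!same_genome(genome, attr(tr, "genome")))
    stop("tracks must share one BinnedGenome")
  dt <- data.table::rbindlist(lapply(tracks, function(tr)
    data.table::as.data.table(tr)[, .(chrom, pos, strand, count)]))
  crosslink_track(dt, genome, replicate = "merged",
                  condition = attr(tracks[[1]], "condition"))
}

# sum of counts in [center - hw, center + hw] for sorted positions
window_sums <- function(pos, counts, centers, hw) {
  cs <- c(0, cumsum(counts))
  hi <- findInterval(centers + hw, pos)
  lo <- findInterval(centers - hw - 1L, pos)
  cs[hi + 1L] - cs[lo + 1L]
}

#' Call candidate crosslink summits by local Poisson enrichment
#'
#' Per strand, each nonzero position's count `k` is tested against
#' `lambda_local = max(flanking mean, global mean)`, where the flanking
#' mean is the event rate in a `bg_window`-nt centered window excluding the
#' position itself and the global mean is the track's per-nucleotide rate
#' on that strand.  p-values are upper-tail Poisson `P(X >= k)`,
#' BH-adjusted over all nonzero positions; significant positions closer
#' than `gap` nt are clustered and each cluster's summit is its
#' maximum-count position (leftmost on ties).
#'
#' @param track a merged [crosslink_track()].
#' @param bg_window centered local-background window in nt (odd; default
#'   20001).
#' @param alpha q-value threshold (default 0.01).
#' @param gap maximum nt between significant positions in one cluster
#'   (default 15).
#' @return data.table of summits: `chrom`, `pos`, `strand`, `count`,
#'   `q_value`, `cluster_start`, `cluster_end` (span of significant
#'   positions, half-open).
#' @export
call_candidate_peaks <- function(track, bg_window = 20001L, alpha = 0.01,
                                 gap = 15L) {
  stopifnot(inherits(track, "CrosslinkTrack"))
  genome <- attr(track, "genome")
  dt <- data.table::as.data.table(track)
  empty <- data.table::data.table(
    chrom = character(), pos = integer(), strand = character(),
    count = integer(), q_value = numeric(), cluster_start = integer(),
    cluster_end = integer())
  if (nrow(dt) == 0) return(empty)
  hw <- (bg_window - 1L) %/% 2L
  total_len <- sum(unname(genome$length))
  dt[, global := sum(count) / total_len, by = strand]
  dt[, lam := {
    ws <- window_sums(pos, count, pos, hw)
    lo <- pmax(0, pos - hw)
    hi <- pmin(unname(genome$length[[chrom[1]]]) - 1, pos + hw)
    flank <- (ws - count) / pmax(1, hi - lo)  # window minus the center nt
    pmax(flank, global)
  }, by = .(chrom, strand)]
  dt[, p_value := stats::ppois(count - 1, lam, lower.tail = FALSE)]
  dt[, q_value := bh_adjust(p_value)]
  sig <- dt[q_value <= alpha]
  if (nrow(sig) == 0) return(empty)
  data.table::setkey(sig, chrom, strand, pos)
  sig[, cluster := cumsum(c(1L, diff(pos) > gap)), by = .(chrom, strand)]
  summits <- sig[, {
    top <- which(count == max(count))[1]  # leftmost maximum
    .(pos = pos[top], count = count[top], q_value = q_value[top],
      cluster_start = pos[1], cluster_end = pos[.N] + 1L)
  }, by = .(chrom, strand, cluster)]
  summits[, cluster := NULL]
  data.table::setcolorder(summits, c("chrom", "pos", "strand", "count",
                                     "q_value", "cluster_start", "cluster_end"))
  data.table::setkey(summits, chrom, strand, pos)
  summits[]
}

#' Standardize summits to fixed-width CLIP peaks
#'
#' Each summit becomes the window `[summit - width/2, summit + width/2)`,
#' clipped at chromosome boundaries.  Same-strand overlapping windows are
#' resolved greedily by descending summit count (leftmost kept on ties);
#' discarded summits are reported in the `n_discarded` attribute.
#'
#' @param summits a [call_candidate_peaks()] result.
#' @param genome a [binned_genome()].
#' @param width fixed peak width in nt (default 300).
#' @return data.table of class `ClipPeakSet`: `chrom`, `start`, `end`,
#'   `strand`, `summit`, `summit_count`, `name`; attribute `n_discarded`.
#' @export
standardize_peaks <- function(summits, genome, width = 300L) {
  stopifnot(inherits(genome, "BinnedGenome"))
  s <- data.table::as.data.table(summits)
  if (nrow(s) == 0) {
    out <- data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), strand = character(),
                                  summit = integer(), summit_count = integer(),
                                  name = character())
    return(structure(out, class = c("ClipPeakSet", class(out)),
                     n_discarded = 0L, genome = genome))
  }
  hw <- width %/% 2L
  s[, start := pmax(0L, pos - hw)]
  s[, end := pmin(as.integer(unname(genome$length[chrom])), pos + hw)]
  # greedy: descending count, then chrom/strand/position for determinism
  s <- s[order(-count, chrom, strand, pos)]
  kept <- logical(nrow(s))
  for (cn in unique(s$chrom)) for (st in c("+", "-")) {
    idx <- which(s$chrom == cn & s$strand == st)
    taken_s <- integer(0); taken_e <- integer(0)
    for (i in idx) {
      if (!any(s$start[i] < taken_e & s$end[i] > taken_s)) {
        kept[i] <- TRUE
        taken_s <- c(taken_s, s$start[i]); taken_e <- c(taken_e, s$end[i])
      }
    }
  }
  n_disc <- sum(!kept)
  out <- s[kept, .(chrom, start, end, strand, summit = pos,
                   summit_count = count)]
  data.table::setkey(out, chrom, strand, start)
  out[, name := sprintf("clip_peak_%04d", seq_len(.N))]
  structure(out, class = c("ClipPeakSet", class(out)), n_discarded = n_disc,
            genome = genome)
}

#' Per-peak crosslink event counts from a track
#'
#' Sums strand-matched event counts within each peak's `[start, end)`.
#'
#' @param peaks a [standardize_peaks()] result (or data.table with `chrom`,
#'   `start`, `end`, `strand`).
#' @param track a [crosslink_track()].
#' @return integer vector, one count per peak.
#' @export
peak_event_counts <- function(peaks, track) {
  pk <- data.table::as.data.table(peaks)
  tr <- data.table::as.data.table(track)
  out <- integer(nrow(pk))
  if (nrow(pk) == 0 || nrow(tr) == 0) return(out)
  for (grp in split(seq_len(nrow(pk)), list(pk$chrom, pk$strand), drop = TRUE)) {
    sub <- tr[.(pk$chrom[grp[1]], pk$strand[grp[1]]), on = c("chrom", "strand"),
              nomatch = NULL]
    if (nrow(sub) == 0) next
    cs <- c(0, cumsum(sub$count))
    hi <- findInterval(pk$end[grp] - 1L, sub$pos)
    lo <- findInterval(pk$start[grp] - 1L, sub$pos)
    out[grp] <- cs[hi + 1L] - cs[lo + 1L]
  }
  out
}

#' Replicate reproducibility filter for CLIP peaks
#'
#' Implements the percentile-cutoff rule: for each replicate, the cutoff is
#' the `percentile`-th percentile (linear interpolation) of that
#' replicate's per-peak crosslink event counts over all candidate peaks,
#' floored at 1.  A peak is reproducible iff its count meets the cutoff in
#' at least `min_required` replicates (e.g. 3 of 4; 2 of 3).
#'
#' @param peaks a [standardize_peaks()] result.
#' @param replicate_tracks list of per-replicate [crosslink_track()]s.
#' @param percentile cutoff percentile in (0, 100) (default 10).
#' @param min_required replicates that must meet their cutoff.
#' @return the peaks table with per-replicate count columns (`rep_1`, ...),
#'   `n_reproducing` and logical `reproducible`; attribute `cutoffs`.
#' @export
reproducibility_filter <- function(peaks, replicate_tracks, percentile = 10,
                                   min_required = 3L) {
  pk <- data.table::copy(data.table::as.data.table(peaks))
  if (nrow(pk) == 0) stop("zero candidate peaks")
  nrep <- length(replicate_tracks)
  if (percentile <= 0 || percentile >= 100) stop("percentile must be in (0, 100)")
  if (min_required < 1 || min_required > nrep)
    stop("min_required must be between 1 and the number of replicates")
  cutoffs <- numeric(nrep)
  met <- matrix(FALSE, nrow(pk), nrep)
  for (r in seq_len(nrep)) {
    cnt <- peak_event_counts(pk, replicate_tracks[[r]])
    pk[, (sprintf("rep_%d", r)) := cnt]
    cutoffs[r] <- max(1, unname(stats::quantile(cnt, percentile / 100, type = 7)))
    met[, r] <- cnt >= cutoffs[r]
  }
  pk[, n_reproducing := rowSums(met)]
  pk[, reproducible := n_reproducing >= min_required]
  structure(pk, class = class(peaks), cutoffs = cutoffs,
            genome = attr(peaks, "genome"),
            n_discarded = attr(peaks, "n_discarded"))
}

#' Negative-control overlap filter
#'
#' Removes peaks whose width is covered at least `max_overlap_fraction` by
#' the union of same-strand control peaks (boundary inclusive: exactly 20%
#' coverage is removed at the default).
#'
#' @param peaks a candidate peak table (`chrom`, `start`, `end`, `strand`).
#' @param control_peaks control peak intervals standardized the same way.
#' @param max_overlap_fraction removal threshold (default 0.20).
#' @return the retained peaks, with a `control_overlap_fraction` column;
#'   attribute `n_removed`.
#' @export
control_filter <- function(peaks, control_peaks, max_overlap_fraction = 0.20) {
  pk <- data.table::copy(data.table::as.data.table(peaks))
  ctl <- data.table::as.data.table(control_peaks)
  if (nrow(pk) == 0 || nrow(ctl) == 0) {
    pk[, control_overlap_fraction := numeric(nrow(pk))]
    return(structure(pk, class = class(peaks), n_removed = 0L,
                     genome = attr(peaks, "genome")))
  }
  qg <- intervals_to_granges(pk)
  sg <- GenomicRanges::reduce(intervals_to_granges(ctl))
  ov <- GenomicRanges::findOverlaps(qg, sg, minoverlap = 1L,
                                    ignore.strand = FALSE)
  cov_bp <- numeric(nrow(pk))
  if (length(ov)) {
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    w <- pmin(pk$end[qh], GenomicRanges::end(sg)[sh]) -
      pmax(pk$start[qh], GenomicRanges::start(sg)[sh] - 1L)
    cov_bp <- as.numeric(rowsum(w, qh)[match(seq_len(nrow(pk)),
                                             sort(unique(qh))), 1])
    cov_bp[is.na(cov_bp)] <- 0
  }
  pk[, control_overlap_fraction := cov_bp / (end - start)]
  keep <- pk$control_overlap_fraction < max_overlap_fraction
  structure(pk[keep], class = class(peaks), n_removed = sum(!keep),
            genome = attr(peaks, "genome"))
}

#' Assign CLIP peaks to genes
#'
#' A peak is assigned to the strand-matched gene whose body
#' `[min(tss, tes), max(tss, tes))` contains the peak midpoint
#' `floor((start + end) / 2)`.  Ties are broken by the largest peak-gene
#' overlap, then by lexicographic gene id.  Unassigned peaks are flagged
#' intergenic.
#'
#' @param peaks a candidate peak table (`chrom`, `start`, `end`, `strand`).
#' @param genes a gene table (`id`, `chrom`, `strand`, `tss`, `tes`).
#' @return the peaks with `gene_id` (NA when intergenic) and `intergenic`
#'   columns.
#' @export
assign_genes <- function(peaks, genes) {
  pk <- data.table::copy(data.table::as.data.table(peaks))
  g <- data.table::as.data.table(genes)
  pk[, gene_id := NA_character_]
  if (nrow(pk) && nrow(g)) {
    bodies <- gene_bodies(g)
    mid <- (pk$start + pk$end) %/% 2L
    for (i in seq_len(nrow(pk))) {
      hit <- which(bodies$chrom == pk$chrom[i] & bodies$strand == pk$strand[i] &
                     bodies$start <= mid[i] & mid[i] < bodies$end)
      if (!length(hit)) next
      if (length(hit) > 1) {
        ovl <- pmin(bodies$end[hit], pk$end[i]) -
          pmax(bodies$start[hit], pk$start[i])
        hit <- hit[order(-ovl, bodies$name[hit])][1]
      }
      pk[i, gene_id := bodies$name[hit]]
    }
  }
  pk[, intergenic := is.na(gene_id)]
  pk[]
}

#' Per-gene crosslink counts over gene bodies
#'
#' Total strand-matched crosslink events from TSS to TES per gene and
#' track: the count matrix for differential CLIP analysis.
#'
#' @param genes a gene table.
#' @param tracks named list of [crosslink_track()]s (one column each).
#' @return integer matrix, genes x tracks.
#' @export
clip_gene_counts <- function(genes, tracks) {
  g <- data.table::as.data.table(genes)
  bodies <- gene_bodies(g)
  out <- matrix(0L, nrow(g), length(tracks),
                dimnames = list(g$id, names(tracks)))
  for (k in seq_along(tracks))
    out[, k] <- peak_event_counts(
      bodies[, .(chrom, start, end, strand)], tracks[[k]])
  out
}

#' Differential CLIP genes between two conditions
#'
#' Compares per-gene crosslink counts over gene bodies with the
#' negative-binomial Wald test ([nb_test()]) at the CLIP thresholds
#' (|log2FC| >= 1, adjusted p <= 0.05).  Unit size factors are used:
#' median-of-ratios is undefined on sparse CLIP gene-count matrices
#' (most genes have zero events in some replicate), and crosslink tracks
#' are compared at matched depth.
#'
#' @param gene_counts genes x samples count matrix (e.g. from
#'   [clip_gene_counts()] over both conditions' replicates).
#' @param condition_labels two-level labels, one per column.
#' @param lfc_threshold,alpha thresholds (defaults 1 and 0.05).
#' @return a [nb_test()] `DifferentialResult`.
#' @export
differential_clip_genes <- function(gene_counts, condition_labels,
                                    lfc_threshold = 1, alpha = 0.05) {
  nb_test(gene_counts, condition_labels, lfc_threshold = lfc_threshold,
          alpha = alpha, size_factors = rep(1, ncol(as.matrix(gene_counts))))
}

#' Run the CLIP peak pipeline end to end
#'
#' Merge replicates, call candidate summits, standardize to fixed-width
#' peaks, apply the replicate reproducibility filter, filter against
#' control peaks (standardized from the control track by the same caller),
#' and assign genes.
#'
#' @param replicate_tracks list of crosslinked-replicate
#'   [crosslink_track()]s.
#' @param control_track the non-crosslinked control track (or NULL to skip
#'   control filtering).
#' @param genes optional gene table for assignment.
#' @param bg_window,alpha,gap summit-caller parameters
#'   (see [call_candidate_peaks()]).
#' @param width fixed peak width (default 300).
#' @param percentile,min_required reproducibility rule (defaults 10 and
#'   3).
#' @param max_overlap_fraction control filter threshold (default 0.20).
#' @return list with `peaks` (final reproducible, control-filtered,
#'   gene-assigned peaks), `candidates` (all standardized candidates with
#'   reproducibility columns), `control_peaks` and `cutoffs`.
#' @export
clip_peaks <- function(replicate_tracks, control_track = NULL, genes = NULL,
                       bg_window = 20001L, alpha = 0.01, gap = 15L,
                       width = 300L, percentile = 10, min_required = 3L,
                       max_overlap_fraction = 0.20) {
  genome <- attr(replicate_tracks[[1]], "genome")
  merged <- merge_tracks(replicate_tracks)
  summits <- call_candidate_peaks(merged, bg_window = bg_window,
                                  alpha = alpha, gap = gap)
  cand <- standardize_peaks(summits, genome, width = width)
  if (nrow(cand) == 0)
    return(list(peaks = cand, candidates = cand,
                control_peaks = NULL, cutoffs = numeric(0)))
  cand <- reproducibility_filter(cand, replicate_tracks,
                                 percentile = percentile,
                                 min_required = min_required)
  final <- cand[cand$reproducible]
  ctl_peaks <- NULL
  if (!is.null(control_track)) {
    ctl_summits <- call_candidate_peaks(control_track, bg_window = bg_window,
                                        alpha = alpha, gap = gap)
    ctl_peaks <- standardize_peaks(ctl_summits, genome, width = width)
    final <- control_filter(final, ctl_peaks,
                            max_overlap_fraction = max_overlap_fraction)
  }
  if (!is.null(genes)) final <- assign_genes(final, genes)
  list(peaks = final, candidates = cand, control_peaks = ctl_peaks,
       cutoffs = attr(cand, "cutoffs"))
}

#' Write a crosslink track as a strand-suffixed bedGraph pair
#'
#' Produces `<prefix>.plus.bedgraph` and `<prefix>.minus.bedgraph` with
#' one line per nonzero position (`chrom pos pos+1 count`).
#'
#' @param track a [crosslink_track()].
#' @param prefix output path prefix.
#' @return character vector of the two paths, invisibly.
#' @export
write_crosslink_track <- function(track, prefix) {
  dt <- data.table::as.data.table(track)
  paths <- c(paste0(prefix, ".plus.bedgraph"), paste0(prefix, ".minus.bedgraph"))
  for (k in 1:2) {
    sub <- dt[strand == c("+", "-")[k]][order(chrom, pos)]
    data.table::fwrite(sub[, .(chrom, start = pos, end = pos + 1L, count)],
                       paths[k], sep = "\t", col.names = FALSE)
  }
  invisible(paths)
}

#' Read a crosslink track from a strand-suffixed bedGraph pair
#'
#' @param prefix path prefix as used by [write_crosslink_track()].
#' @param genome a [binned_genome()].
#' @inheritParams crosslink_track
#' @return a [crosslink_track()].
#' @export
read_crosslink_track <- function(prefix, genome, replicate = 1L,
                                 condition = NA_character_,
                                 is_control = FALSE) {
  parts <- list()
  for (k in 1:2) {
    path <- paste0(prefix, c(".plus.bedgraph", ".minus.bedgraph")[k])
    if (!file.exists(path)) stop("missing bedGraph file: ", path)
    lines <- readLines(path)
    keep <- which(nzchar(trimws(lines)))
    if (!length(keep)) next
    fld <- strsplit(lines[keep], "\t", fixed = TRUE)
    bad <- which(lengths(fld) < 4)
    if (length(bad)) parse_error(path, keep[bad[1]], "fewer than 4 bedGraph fields")
    dt <- data.table::data.table(
      chrom = vapply(fld, `[`, "", 1),
      pos = suppressWarnings(as.integer(vapply(fld, `[`, "", 2))),
      end = suppressWarnings(as.integer(vapply(fld, `[`, "", 3))),
      count = suppressWarnings(as.integer(vapply(fld, `[`, "", 4))),
      line = keep)
    bad <- which(is.na(dt$pos) | is.na(dt$end) | is.na(dt$count))
    if (length(bad)) parse_error(path, dt$line[bad[1]], "malformed bedGraph line")
    bad <- which(dt$end != dt$pos + 1L)
    if (length(bad)) parse_error(path, dt$line[bad[1]],
                                 "crosslink bedGraph intervals must be 1 nt")
    dt[, `:=`(strand = c("+", "-")[k], end = NULL, line = NULL)]
    parts[[length(parts) + 1]] <- dt
  }
  ev <- if (length(parts)) data.table::rbindlist(parts) else
    data.table::data.table(chrom = character(), pos = integer(),
                           strand = character(), count = integer())
  crosslink_track(ev, genome, replicate, condition, is_control)
}
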