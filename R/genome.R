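#' Binned genome
#'
#' A `BinnedGenome` tiles each chromosome left to right into fixed-size bins
#' in 0-based half-open base-pair coordinates.  Bin `b` of a chromosome covers
#' `[b * bin_size, (b + 1) * bin_size)`; the last bin may be short.  All
#' contact maps, loop calls and per-bin tracks in this package refer to a
#' `BinnedGenome`.
#'
#' @param chroms character vector of chromosome names (unique, non-empty).
#' @param lengths numeric vector of chromosome lengths in bp, parallel to
#'   `chroms`.
#' @param bin_size bin width in bp (default 5000, i.e. 5-kb resolution).
#'
#' @return An object of class `BinnedGenome`: a list with elements `chrom`,
#'   `length` (named), `bin_size`, `n_bins` (named) and `offset` (named,
#'   cumulative global bin offset per chromosome).
#' @export
#' @examples
#' bg <- binned_genome(c("chr1", "chr2"), c(2e7, 2e7), bin_size = 5000)
#' n_bins(bg, "chr1")
binned_genome <- function(chroms, lengths, bin_size = 5000) {
  stopifnot(is.character(chroms), length(chroms) >= 1,
            !anyDuplicated(chroms), all(nzchar(chroms)))
  lengths <- as.numeric(lengths)
  stopifnot(length(lengths) == length(chroms), all(lengths > 0))
  bin_size <- as.integer(bin_size)
  stopifnot(length(bin_size) == 1, bin_size > 0)
  nb <- as.integer(ceiling(lengths / bin_size))
  names(lengths) <- chroms
  names(nb) <- chroms
  off <- c(0L, cumsum(nb))[seq_along(chroms)]
  names(off) <- chroms
  structure(list(chrom = chroms, length = lengths, bin_size = bin_size,
                 n_bins = nb, offset = off),
            class = "BinnedGenome")
}

#' @export
print.BinnedGenome <- function(x, ...) {
  cat(sprintf("BinnedGenome: %d chromosome(s), bin size %d bp, %d bins total\n",
              length(x$chrom), x$bin_size, sum(x$n_bins)))
  invisible(x)
}

#' Number of bins on a chromosome
#' @param genome a [binned_genome()].
#' @param chrom chromosome name; if missing, a named vector for all.
#' @return integer bin count(s).
#' @export
n_bins <- function(genome, chrom) {
  stopifnot(inherits(genome, "BinnedGenome"))
  if (missing(chrom)) return(genome$n_bins)
  check_chrom(genome, chrom)
  genome$n_bins[[chrom]]
}

#' Map base-pair positions to bin indices
#'
#' @param genome a [binned_genome()].
#' @param chrom chromosome name (scalar or parallel to `pos`).
#' @param pos 0-based positions in bp.
#' @return 0-based bin indices: `floor(pos / bin_size)`.
#' @export
bin_index <- function(genome, chrom, pos) {
  stopifnot(inherits(genome, "BinnedGenome"))
  check_chrom(genome, chrom)
  as.integer(pos %/% genome$bin_size)
}

#' Base-pair interval of a bin
#' @inheritParams bin_index
#' @param bin 0-based bin indices.
#' @return a `data.table` with columns `chrom`, `start`, `end` (half-open bp),
#'   clipped to the chromosome end.
#' @export
bin_interval <- function(genome, chrom, bin) {
  stopifnot(inherits(genome, "BinnedGenome"))
  check_chrom(genome, chrom)
  bs <- genome$bin_size
  data.table::data.table(
    chrom = chrom,
    start = as.numeric(bin) * bs,
    end = pmin(as.numeric(bin + 1) * bs, unname(genome$length[chrom])))
}

check_chrom <- function(genome, chrom) {
  bad <- setdiff(unique(chrom), genome$chrom)
  if (length(bad))
    stop("unknown chromosome(s): ", paste(bad, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

same_genome <- function(a, b) {
  identical(a$chrom, b$chrom) && identical(unname(a$length), unname(b$length)) &&
    identical(a$bin_size, b$bin_size)
}
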