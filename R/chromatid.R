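#' Chromatid construction
#'
#' A chromatid is the simulator's unit of exchange: an ordered tiling of
#' `[1, length]` by haplotype-source segments, plus cassette copies (with
#' orientation state) and deleted intervals. Haplotype sources are coded
#' `1` (hapA) and `2` (hapB). Segments are stored run-length style as a
#' vector of segment end positions (`ends`, last element = chromosome
#' length) and the matching source codes (`haps`); segment `i` covers
#' `(ends[i-1], ends[i]]`.
#'
#' @param chrom Chromosome name.
#' @param len Chromosome length in bp.
#' @param hap Founding haplotype source (1 or 2).
#' @param cas_pos Cassette positions (bp).
#' @param cas_inv Logical: `FALSE` = default N orientation, `TRUE` =
#'   Cre-inverted P orientation.
#' @return An object of class `chromatid`.
#' @export
new_chromatid <- function(chrom, len, hap, cas_pos = numeric(0),
                          cas_inv = logical(0)) {
  stopifnot(length(cas_pos) == length(cas_inv))
  structure(list(chrom = chrom, len = as.numeric(len),
                 ends = as.numeric(len), haps = as.integer(hap),
                 cas_pos = as.numeric(cas_pos), cas_inv = as.logical(cas_inv),
                 del = matrix(numeric(0), ncol = 2)),
            class = "chromatid")
}

hap_label <- function(code) c("hapA", "hapB")[code]
hap_code <- function(label) match(label, c("hapA", "hapB"))

#' Haplotype source at positions
#'
#' @param ch A [new_chromatid()] object.
#' @param pos Positions in bp (vectorised).
#' @return Integer vector of source codes (1 = hapA, 2 = hapB).
#' @export
hap_at <- function(ch, pos) {
  ch$haps[findInterval(pos, c(0, ch$ends), left.open = TRUE)]
}

#' Is a position deleted on this chromatid?
#' @inheritParams hap_at
#' @return Logical vector.
#' @export
is_deleted_at <- function(ch, pos) {
  if (nrow(ch$del) == 0) return(rep(FALSE, length(pos)))
  out <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(ch$del)))
    out <- out | (pos >= ch$del[i, 1] & pos <= ch$del[i, 2])
  out
}

# merge adjacent segments with equal source, drop empty segments
normalize_chromatid <- function(ch) {
  keep <- c(diff(ch$ends) > 0, TRUE)
  if (length(ch$ends) == 1) keep <- TRUE
  ends <- ch$ends[keep]; haps <- ch$haps[keep]
  if (length(haps) > 1) {
    same <- c(haps[-1] == haps[-length(haps)], FALSE)
    ends <- ends[!same]; haps <- haps[!same]
  }
  ch$ends <- ends; ch$haps <- haps
  ch
}

# split segment vectors at real coordinate b: low covers (0,b], high (b,len]
split_segments <- function(ch, b) {
  lo <- ch$ends < b
  low_ends <- c(ch$ends[lo], b)
  low_haps <- ch$haps[seq_len(sum(lo) + 1)]
  high_ends <- ch$ends[!lo]
  high_haps <- ch$haps[!lo]
  list(low = list(ends = low_ends, haps = low_haps),
       high = list(ends = high_ends, haps = high_haps))
}

# split deletion intervals at b
split_del <- function(del, b) {
  if (nrow(del) == 0) return(list(low = del, high = del))
  cross <- del[, 1] <= b & del[, 2] > b
  low <- del[del[, 2] <= b, , drop = FALSE]
  high <- del[del[, 1] > b, , drop = FALSE]
  if (any(cross)) {
    cr <- del[cross, , drop = FALSE]
    low <- rbind(low, cbind(cr[, 1], b))
    high <- rbind(high, cbind(b + 1, cr[, 2]))
  }
  list(low = low, high = high)
}

#' Reciprocal crossover between two chromatids
#'
#' Exchanges all material distal (telomeric, i.e. away from the
#' centromere) to breakpoint `b` between chromatids `x` and `y`. Cassette
#' copies and deletion intervals travel with their segment; the exchange is
#' reciprocal by construction, so total material of each haplotype source
#' is conserved.
#'
#' @param x,y [new_chromatid()] objects on the same chromosome.
#' @param b Breakpoint in bp, strictly outside the centromere.
#' @param spec The [chromosome_spec()].
#' @return List with elements `x` and `y`, the recombinant chromatids.
#' @export
cross_chromatids <- function(x, y, b, spec) {
  stopifnot(x$chrom == y$chrom)
  on_q <- b > spec$cen_end
  if (!on_q && b >= spec$cen_start) stop("breakpoint inside centromere")
  sx <- split_segments(x, b); sy <- split_segments(y, b)
  dx <- split_del(x$del, b); dy <- split_del(y$del, b)
  cx_hi <- x$cas_pos > b; cy_hi <- y$cas_pos > b
  if (on_q) {
    # telomeric side = high coordinates
    x$ends <- c(sx$low$ends, sy$high$ends); x$haps <- c(sx$low$haps, sy$high$haps)
    y$ends <- c(sy$low$ends, sx$high$ends); y$haps <- c(sy$low$haps, sx$high$haps)
    new_cx <- c(x$cas_pos[!cx_hi], y$cas_pos[cy_hi])
    new_ix <- c(x$cas_inv[!cx_hi], y$cas_inv[cy_hi])
    new_cy <- c(y$cas_pos[!cy_hi], x$cas_pos[cx_hi])
    new_iy <- c(y$cas_inv[!cy_hi], x$cas_inv[cx_hi])
    ndx <- rbind(dx$low, dy$high); ndy <- rbind(dy$low, dx$high)
  } else {
    # p arm: telomeric side = low coordinates
    x$ends <- c(sy$low$ends, sx$high$ends); x$haps <- c(sy$low$haps, sx$high$haps)
    y$ends <- c(sx$low$ends, sy$high$ends); y$haps <- c(sx$low$haps, sy$high$haps)
    new_cx <- c(y$cas_pos[!cy_hi], x$cas_pos[cx_hi])
    new_ix <- c(y$cas_inv[!cy_hi], x$cas_inv[cx_hi])
    new_cy <- c(x$cas_pos[!cx_hi], y$cas_pos[cy_hi])
    new_iy <- c(x$cas_inv[!cx_hi], y$cas_inv[cy_hi])
    ndx <- rbind(dy$low, dx$high); ndy <- rbind(dx$low, dy$high)
  }
  x$cas_pos <- new_cx; x$cas_inv <- new_ix
  y$cas_pos <- new_cy; y$cas_inv <- new_iy
  x$del <- ndx; y$del <- ndy
  list(x = normalize_chromatid(x), y = normalize_chromatid(y))
}

#' Overwrite a tract with another haplotype source (gene conversion)
#'
#' Replaces the source of `[s, e]` on `ch` with `hap`; cassettes and
#' deletions are unchanged (conversion tracts are short and do not move
#' the cassette in this model).
#'
#' @param ch A chromatid.
#' @param s,e Tract bounds in bp (closed).
#' @param hap Donor source code (1 or 2).
#' @return The modified chromatid.
#' @export
set_tract <- function(ch, s, e, hap) {
  stopifnot(s <= e, s >= 1, e <= ch$len)
  s1 <- split_segments(ch, s - 1)
  hi <- split_segments(ch, e)$high
  if (s <= 1) {
    ch$ends <- c(e, hi$ends); ch$haps <- c(as.integer(hap), hi$haps)
  } else {
    ch$ends <- c(s1$low$ends, e, hi$ends)
    ch$haps <- c(s1$low$haps, as.integer(hap), hi$haps)
  }
  normalize_chromatid(ch)
}

#' Apply a deletion to a chromatid
#'
#' Adds `[s, e]` to the deleted intervals and removes any cassette copy
#' that falls inside it.
#'
#' @inheritParams set_tract
#' @return The modified chromatid.
#' @export
add_deletion <- function(ch, s, e) {
  stopifnot(s <= e)
  s <- max(1, s); e <- min(ch$len, e)
  ch$del <- rbind(ch$del, c(s, e))
  drop <- ch$cas_pos >= s & ch$cas_pos <= e
  ch$cas_pos <- ch$cas_pos[!drop]
  ch$cas_inv <- ch$cas_inv[!drop]
  ch
}

# duplicate cassette copy k in place (locus amplification)
duplicate_cassette <- function(ch, k, inverted) {
  ch$cas_pos <- c(ch$cas_pos, ch$cas_pos[k])
  ch$cas_inv <- c(ch$cas_inv, inverted)
  ch
}
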