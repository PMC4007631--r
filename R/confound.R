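#' Pair probes across two array designs
#'
#' Constructs a 1-1 mapping between the probes of two tiling designs sharing
#' a coordinate system: a pair is kept iff each probe is the other's nearest
#' probe on the same chromosome (mutual nearest neighbours, which guarantees
#' the 1-1 property) and the distance between their start positions is at
#' most `max_dist` bp (default 150). Equidistant neighbours are resolved
#' toward the lower coordinate, deterministically.
#'
#' @param design_a,design_b data frames with probe_id, chrom, start (e.g.
#'   `layout$probes`).
#' @param max_dist maximum pairing distance in bp.
#' @return A list of class `probe_pairing` with `pairs` (probe_a, probe_b,
#'   distance) and the unpaired counts per design.
#' @export
pair_probes <- function(design_a, design_b, max_dist = 150) {
  nearest <- function(from, to) {
    # index into 'to' of the nearest position, ties toward lower coordinate
    o <- order(to$start)
    ts <- to$start[o]
    i <- findInterval(from$start, ts)
    lo <- pmax(i, 1L); hi <- pmin(i + 1L, length(ts))
    dl <- abs(from$start - ts[lo]); dh <- abs(from$start - ts[hi])
    pick <- ifelse(i == 0, hi, ifelse(dl <= dh, lo, hi))
    o[pick]
  }
  res <- lapply(intersect(unique(design_a$chrom), unique(design_b$chrom)),
                function(ch) {
    a <- design_a[design_a$chrom == ch, ]
    b <- design_b[design_b$chrom == ch, ]
    if (!nrow(a) || !nrow(b)) return(NULL)
    ab <- nearest(a, b)           # for each a, its nearest b
    ba <- nearest(b, a)           # for each b, its nearest a
    mutual <- ba[ab] == seq_len(nrow(a))
    d <- abs(a$start - b$start[ab])
    keep <- mutual & d <= max_dist
    if (!any(keep)) return(NULL)
    data.frame(probe_a = a$probe_id[keep], probe_b = b$probe_id[ab[keep]],
               distance = d[keep], stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, res)
  if (is.null(pairs))
    pairs <- data.frame(probe_a = character(0), probe_b = character(0),
                        distance = numeric(0))
  out <- list(pairs = pairs,
              n_unpaired_a = nrow(design_a) - nrow(pairs),
              n_unpaired_b = nrow(design_b) - nrow(pairs))
  class(out) <- "probe_pairing"
  out
}

#' @export
print.probe_pairing <- function(x, ...) {
  cat(sprintf("Probe pairing: %d pairs (unpaired: %d in A, %d in B)\n",
              nrow(x$pairs), x$n_unpaired_a, x$n_unpaired_b))
  invisible(x)
}
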