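#' Tile a contig into windows of equal accessible-base content
#'
#' Windows are defined so that each one contains exactly
#' `window_accessible_bases` accessible positions (the last window of a
#' contig may hold fewer). Window bounds are reported in physical 1-based
#' inclusive coordinates: a window starts at its first accessible base and
#' ends at its last, so inaccessible stretches are absorbed silently and
#' windows tile the accessible coordinate space without gaps.
#'
#' @param mask named list of per-contig logical accessibility vectors
#'   (as from [read_bed_mask()]), or a single logical vector when `contig`
#'   names it directly.
#' @param contig contig name to tile.
#' @param window_accessible_bases accessible bases per window (default 1e5).
#' @return A tibble (`contig`, `start`, `end`, `n_accessible`); zero rows
#'   when the contig has no accessible base.
#' @export
accessible_windows <- function(mask, contig, window_accessible_bases = 100000L) {
  if (is.list(mask)) {
    if (!contig %in% names(mask)) abort(paste0("contig not in mask: ", contig))
    m <- mask[[contig]]
  } else {
    m <- mask
  }
  acc <- which(m)
  if (length(acc) == 0L) {
    return(tibble(contig = character(), start = integer(),
                  end = integer(), n_accessible = integer()))
  }
  w <- as.integer(window_accessible_bases)
  if (w < 1L) abort("`window_accessible_bases` must be >= 1")
  n_win <- ceiling(length(acc) / w)
  first <- (seq_len(n_win) - 1L) * w + 1L
  last <- pmin(seq_len(n_win) * w, length(acc))
  tibble(
    contig = contig,
    start = acc[first],
    end = acc[last],
    n_accessible = as.integer(last - first + 1L)
  )
}

#' Assign variant positions to windows
#'
#' @param windows window tibble from [accessible_windows()].
#' @param contig,pos variant coordinates.
#' @return Integer window index per variant (`NA` outside all windows).
#' @export
window_index <- function(windows, contig, pos) {
  idx <- rep(NA_integer_, length(pos))
  for (ctg in unique(contig)) {
    wi <- which(windows$contig == ctg)
    if (!length(wi)) next
    sel <- which(contig == ctg)
    j <- findInterval(pos[sel], windows$start[wi])
    ok <- j >= 1 & j <= length(wi)
    ok[ok] <- pos[sel][ok] <= windows$end[wi][j[ok]]
    idx[sel[ok]] <- wi[j[ok]]
  }
  idx
}
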