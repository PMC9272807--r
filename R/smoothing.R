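#' Align copy number boundaries between two binned profiles
#'
#' Segmentation noise places copy number transitions of near-identical
#' profiles at slightly different bins. This window-based smoothing step
#' aligns such boundaries before comparison: whenever one profile changes
#' copy number at bin i and the other changes within +/- `window` bins, the
#' later transition is shifted to the earlier position by re-assigning the
#' intervening bins to the flanking (post-transition) value, so both
#' profiles change value at the same bin index. Transitions with no
#' near-coincident counterpart are left untouched.
#'
#' The operation is symmetric in its two arguments and idempotent. A shift
#' that would erase an intervening copy number run (a run shorter than the
#' window sitting between the two boundaries) is skipped, so the set of
#' distinct copy number levels in each profile is preserved. Transitions are
#' never moved across chromosome boundaries, and bins missing in either
#' profile break the runs they interrupt.
#'
#' @param a,b Two [segments_to_bins()] profiles on the same grid.
#' @param window Maximum boundary offset, in bins, that is considered the
#'   same boundary (default 1). `0` disables smoothing.
#' @return A list with elements `a` and `b`: the aligned profiles.
#' @export
align_boundaries <- function(a, b, window = 1) {
  stopifnot(inherits(a, "cn_profile"), inherits(b, "cn_profile"))
  if (!same_grid(a$grid, b$grid))
    stop("profiles are on different bin grids", call. = FALSE)
  if (!is.numeric(window) || length(window) != 1L || window < 0)
    stop("'window' must be a single non-negative number", call. = FALSE)
  window <- as.integer(window)
  if (window == 0L) return(list(a = a, b = b))
  va <- a$values
  vb <- b$values
  chrom <- a$grid$bins$chrom
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    x <- va[idx]; y <- vb[idx]
    ## snapping can expose a new near-coincident pair (dense transitions);
    ## iterate to the fixed point so the operation is idempotent. Each
    ## applied shift moves a transition strictly earlier, so this terminates.
    repeat {
      snapped <- snap_transitions(x, y, window)
      if (identical(snapped$x, x) && identical(snapped$y, y)) break
      x <- snapped$x; y <- snapped$y
    }
    va[idx] <- x
    vb[idx] <- y
  }
  list(a = new_cn_profile(a$sample_id, a$grid, va),
       b = new_cn_profile(b$sample_id, b$grid, vb))
}

## transition positions within one chromosome vector: i such that
## v[i] != v[i-1], both non-missing
transitions_of <- function(v) {
  i <- seq_along(v)[-1L]
  i[!is.na(v[i]) & !is.na(v[i - 1L]) & v[i] != v[i - 1L]]
}

## pair up near-coincident transitions of x and y (each used once,
## closest pairs first, ties by leftmost position) and shift the later
## transition of each pair onto the earlier one
snap_transitions <- function(x, y, window) {
  tx <- transitions_of(x)
  ty <- transitions_of(y)
  if (!length(tx) || !length(ty)) return(list(x = x, y = y))
  d <- abs(outer(tx, ty, "-"))
  keep <- which(d <= window & d > 0L)
  if (!length(keep)) return(list(x = x, y = y))
  ci <- (keep - 1L) %% length(tx) + 1L
  cj <- (keep - 1L) %/% length(tx) + 1L
  ord <- order(d[keep], pmin(tx[ci], ty[cj]))
  used_x <- logical(length(tx))
  used_y <- logical(length(ty))
  for (r in ord) {
    i <- ci[r]; j <- cj[r]
    if (used_x[i] || used_y[j]) next
    used_x[i] <- TRUE; used_y[j] <- TRUE
    if (tx[i] < ty[j]) {
      y <- shift_transition(y, from = ty[j], to = tx[i])
    } else {
      x <- shift_transition(x, from = tx[i], to = ty[j])
    }
  }
  list(x = x, y = y)
}

## move the transition of v at bin `from` to the earlier bin `to` by
## re-assigning bins to..from-1 to the post-transition value; refuse when
## that would consume another run or the pre-transition value's last bin
shift_transition <- function(v, from, to) {
  pre <- v[from - 1L]
  span <- to:(from - 1L)
  if (any(is.na(v[span])) || any(v[span] != pre)) return(v)  # run in between
  if (to == 1L || is.na(v[to - 1L]) || v[to - 1L] != pre) return(v)
  v[span] <- v[from]
  v
}
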