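#' Strict local maxima of a numeric series
#'
#' Interior frames only (the two endpoints are never maxima). A plateau -- a
#' run of equal values strictly higher than its flanking values -- counts once,
#' at its first frame. Plateaus running into a series boundary are not maxima.
#'
#' @param x numeric vector.
#' @return integer vector of peak frame indices (1-based), strictly increasing.
#' @export
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  s <- sign(diff(x))
  # carry the NEXT nonzero slope backwards over zero runs so that a plateau
  # inherits the direction the series eventually takes
  nz <- which(s != 0L)
  if (length(nz) == 0L) return(integer(0))
  pos <- findInterval(seq_along(s) - 1L, nz) + 1L  # index of first nz >= i
  filled <- ifelse(pos <= length(nz), s[nz[pmin(pos, length(nz))]], 0)
  filled[s != 0] <- s[s != 0]
  # peak at frame i iff slope into i is +1 and slope out of i is -1
  i <- which(filled[-length(filled)] == 1 & filled[-1L] == -1) + 1L
  as.integer(i)
}

# run fn with a private RNG stream; the caller's .Random.seed is untouched
with_local_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

# timestamped logging to stderr; per-cycle diagnostics only when verbose
speakr_log <- function(..., verbose_only = FALSE) {
  if (verbose_only && !isTRUE(getOption("speakr.verbose", FALSE))) return(invisible())
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), ...)
  invisible()
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
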