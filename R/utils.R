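#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; published clinical tables
#' conventionally round half up.  Used for all reported percentages.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded with ties going away from zero.
#' @export
#' @examples
#' round_half_up(c(0.125, 0.135), 2) # 0.13, 0.14
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stop_bad <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_bad(name, " must be a finite numeric scalar")
  if (positive && x <= 0) stop_bad(name, " must be > 0")
  invisible(x)
}

# evaluate `code` under a temporary RNG seed, restoring global RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(code))
}

as_aami_factor <- function(y) {
  y <- as.character(y)
  bad <- setdiff(unique(y), AAMI_CLASSES)
  if (length(bad))
    stop_bad("labels outside {N,S,V,F}: ", paste(bad, collapse = ", "))
  factor(y, levels = AAMI_CLASSES)
}
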